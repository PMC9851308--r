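abbreviation	headgroup	backbone	n_positions	category
PC	phosphocholine	glycerol	2	glycerophospholipid
PE	phosphoethanolamine	glycerol	2	glycerophospholipid
PS	phosphoserine	glycerol	2	glycerophospholipid
PI	phosphoinositol	glycerol	2	glycerophospholipid
PG	phosphoglycerol	glycerol	2	glycerophospholipid
PA	phosphate	glycerol	2	glycerophospholipid
LPC	phosphocholine	glycerol	1	lysophospholipid
LPE	phosphoethanolamine	glycerol	1	lysophospholipid
LPS	phosphoserine	glycerol	1	lysophospholipid
LPI	phosphoinositol	glycerol	1	lysophospholipid
LPG	phosphoglycerol	glycerol	1	lysophospholipid
LPA	phosphate	glycerol	1	lysophospholipid
MG	none	glycerol	1	glycerolipid
DG	none	glycerol	2	glycerolipid
TG	none	glycerol	3	glycerolipid
CL	bis-phosphoglycerol	glycerol	4	glycerophospholipid
CE	cholesteryl	sterol	1	sterollipid
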