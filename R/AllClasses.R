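#' @importFrom S4Vectors metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## ---------------------------------------------------------------------------
## Lipid data model
## ---------------------------------------------------------------------------

#' LipidSpecies: a measured lipid at sum or molecular level
#'
#' A lipid species is a lipid class plus a fatty-acyl content. At the
#' *molecular* level the individual acyl chains are resolved (sn-position is
#' deliberately not; chains form an unordered multiset, e.g. `PC(16:0_18:1)`).
#' At the *sum* level only the total carbons, double bonds and hydroxylations
#' are known (e.g. `PC(34:1)`).
#'
#' @slot name canonical shorthand name.
#' @slot lipidClass class abbreviation (must be present in the registry used
#'   to parse the name).
#' @slot level `"sum"` or `"molecular"`.
#' @slot acyls character vector of canonical acyl strings (molecular level;
#'   empty for sum species).
#' @slot sumC,sumDB,sumOH integer totals over all chains.
#' @slot ether `"none"`, `"plasmanyl"` or `"plasmenyl"`.
#' @seealso [parseLipidName()], [enumerateMolecularSpecies()]
#' @export
setClass("LipidSpecies", representation(
  name = "character", lipidClass = "character", level = "character",
  acyls = "character", sumC = "integer", sumDB = "integer",
  sumOH = "integer", ether = "character"))

setValidity("LipidSpecies", function(object) {
  if (!object@level %in% c("sum", "molecular"))
    return("level must be 'sum' or 'molecular'")
  if (object@level == "molecular" && length(object@acyls) == 0L)
    return("molecular species must carry acyl chains")
  if (object@sumC < 1L || object@sumDB < 0L || object@sumOH < 0L)
    return("invalid sum composition")
  TRUE
})

#' @describeIn LipidSpecies class abbreviation
#' @param x object
#' @export
setMethod("lipidClass", "LipidSpecies", function(x) x@lipidClass)

#' @describeIn LipidSpecies canonical name
#' @export
setMethod("speciesName", "LipidSpecies", function(x) x@name)

#' @describeIn LipidSpecies annotation level (`"sum"` or `"molecular"`)
#' @export
setMethod("speciesLevel", "LipidSpecies", function(x) x@level)

#' @describeIn LipidSpecies acyl chain multiset (canonical order)
#' @export
setMethod("acylChains", "LipidSpecies", function(x) x@acyls)

#' @describeIn LipidSpecies named integer vector `c(carbons, doubleBonds,
#'   hydroxyls)`; for molecular species this is the componentwise sum over
#'   the chains
#' @export
setMethod("sumComposition", "LipidSpecies", function(x)
  c(carbons = x@sumC, doubleBonds = x@sumDB, hydroxyls = x@sumOH))

setMethod("show", "LipidSpecies", function(object) {
  cat(sprintf("LipidSpecies %s [%s, %s level]\n", object@name,
              object@lipidClass, object@level))
})

#' ClassRegistry: the lipid class nomenclature table
#'
#' Maps class abbreviations (PC, LPC, DG, ...) to headgroup, backbone, number
#' of acyl positions and lipid category. The bundled default registry
#' ([defaultClassRegistry()]) is a curated subset of common
#' glycerophospholipid / glycerolipid classes.
#'
#' @slot table data.frame with columns `abbreviation`, `headgroup`,
#'   `backbone`, `n_positions`, `category`.
#' @export
setClass("ClassRegistry", representation(table = "data.frame"))

setValidity("ClassRegistry", function(object) {
  need <- c("abbreviation", "headgroup", "backbone", "n_positions", "category")
  if (!all(need %in% colnames(object@table)))
    return(paste("registry table lacks columns:",
                 paste(setdiff(need, colnames(object@table)), collapse = ", ")))
  if (anyDuplicated(object@table$abbreviation))
    return("duplicated class abbreviations")
  if (any(object@table$n_positions < 1L))
    return("n_positions must be >= 1")
  TRUE
})

setMethod("show", "ClassRegistry", function(object) {
  cat(sprintf("ClassRegistry with %d lipid classes: %s\n",
              nrow(object@table),
              paste(utils::head(object@table$abbreviation, 8), collapse = ", ")))
})

#' FattyAcylPool: candidate acyls for sum-species expansion
#'
#' The pool of fatty acyls considered when a sum species is expanded into
#' molecular candidates. A global pool applies to every class unless a
#' per-class override is given.
#'
#' @slot global character vector of canonical acyl strings.
#' @slot overrides named list (class abbreviation -> character vector).
#' @export
setClass("FattyAcylPool",
         representation(global = "character", overrides = "list"))

setValidity("FattyAcylPool", function(object) {
  if (length(object@global) == 0L && length(object@overrides) == 0L)
    return("acyl pool must not be empty")
  TRUE
})

setMethod("show", "FattyAcylPool", function(object) {
  cat(sprintf("FattyAcylPool: %d global acyls, %d class overrides\n",
              length(object@global), length(object@overrides)))
})

## ---------------------------------------------------------------------------
## Reaction knowledge base
## ---------------------------------------------------------------------------

#' ClassReaction: a curated multispecific lipid-class reaction template
#'
#' One enzymatic transformation template between lipid classes, e.g. the
#' acyl transfer LPI + acyl-CoA -> PI (cofactors are implicit: only lipid
#' participants are recorded; the transferred acyl is resolved at species
#' level). Categories follow the curation scheme: `headgroup_modification`,
#' `headgroup_addition_removal`, `fa_addition_removal` (all 1 substrate /
#' 1 product class) and `lipid_merging` (2 substrate classes, 1 product).
#'
#' @slot reactionId stable identifier.
#' @slot category one of the four category labels above.
#' @slot substrateClasses,productClasses class abbreviations.
#' @slot dbRefs database cross references (e.g. `"RHEA:33195"`).
#' @slot geneRefs gene / protein labels.
#' @slot organisms organism codes; empty means unrestricted.
#' @export
setClass("ClassReaction", representation(
  reactionId = "character", category = "character",
  substrateClasses = "character", productClasses = "character",
  dbRefs = "character", geneRefs = "character", organisms = "character"))

reactionCategories <- c("headgroup_modification", "headgroup_addition_removal",
                        "fa_addition_removal", "lipid_merging")

setValidity("ClassReaction", function(object) {
  if (!object@category %in% reactionCategories)
    return(sprintf("unknown category '%s'", object@category))
  ns <- length(object@substrateClasses); np <- length(object@productClasses)
  if (object@category == "lipid_merging") {
    if (ns != 2L || np != 1L)
      return("lipid_merging requires 2 substrate classes and 1 product class")
  } else if (ns != 1L || np != 1L) {
    return(sprintf("%s requires exactly 1 substrate and 1 product class",
                   object@category))
  }
  TRUE
})

#' @describeIn ClassReaction stable identifier
#' @param x object
#' @export
setMethod("reactionId", "ClassReaction", function(x) x@reactionId)

setMethod("show", "ClassReaction", function(object) {
  cat(sprintf("ClassReaction %s [%s]: %s -> %s (%s)\n", object@reactionId,
              object@category, paste(object@substrateClasses, collapse = " + "),
              paste(object@productClasses, collapse = " + "),
              paste(object@geneRefs, collapse = ",")))
})

## ---------------------------------------------------------------------------
## Species-level network
## ---------------------------------------------------------------------------

#' SpeciesReaction: a class reaction instantiated on measured species
#'
#' The hyperedge unit of the enrichment: a set of measured substrate species
#' and a set of measured product species connected by one class reaction (or
#' by a heuristic fatty-acid / ether rule). For fatty-acyl transfer reactions
#' the transferred acyl(s) supported by the molecular candidates are recorded.
#'
#' @slot id unique reproducible identifier (class reaction id plus sorted
#'   participant names).
#' @slot classReaction id of the class reaction, or a rule id
#'   (`FA:elongation`, `FA:desaturation`, `FA:hydroxylation`,
#'   `ether_conversion`) for heuristic reactions.
#' @slot category reaction category or rule name.
#' @slot substrates,products measured lipid names.
#' @slot transferredAcyls acyl strings supported by at least one candidate
#'   pair (empty when no acyl is transferred).
#' @slot heuristic `TRUE` for fatty-acid-rule and ether-conversion reactions.
#' @export
setClass("SpeciesReaction", representation(
  id = "character", classReaction = "character", category = "character",
  substrates = "character", products = "character",
  transferredAcyls = "character", heuristic = "logical"))

setValidity("SpeciesReaction", function(object) {
  if (length(intersect(object@substrates, object@products)))
    return("substrates and products must be disjoint")
  TRUE
})

#' @describeIn SpeciesReaction unique identifier
#' @param x object
#' @export
setMethod("reactionId", "SpeciesReaction", function(x) x@id)

#' @describeIn SpeciesReaction measured substrate species
#' @export
setMethod("substrates", "SpeciesReaction", function(x) x@substrates)

#' @describeIn SpeciesReaction measured product species
#' @export
setMethod("products", "SpeciesReaction", function(x) x@products)

#' @describeIn SpeciesReaction supported transferred acyl(s)
#' @export
setMethod("transferredAcyls", "SpeciesReaction", function(x) x@transferredAcyls)

#' @describeIn SpeciesReaction whether the reaction is a connectivity
#'   heuristic (fatty-acid rule or ether conversion)
#' @export
setMethod("isHeuristic", "SpeciesReaction", function(x) x@heuristic)

setMethod("show", "SpeciesReaction", function(object) {
  cat(sprintf("SpeciesReaction %s%s\n  %s -> %s\n", object@id,
              if (object@heuristic) " [heuristic]" else "",
              paste(object@substrates, collapse = " + "),
              paste(object@products, collapse = " + ")))
})

#' LipidNetwork: the dataset-specific lipid species network
#'
#' Nodes are the measured lipid species; undirected edges connect species
#' that participate in a common species reaction, with multiple edges
#' allowed for multi-participant reactions. Sum species that could not be
#' expanded into any molecular candidate are kept as isolated nodes and
#' reported in the expansion table.
#'
#' @slot graph igraph with vertex attributes `name`, `lipidClass`, `level`
#'   and edge attributes `reaction`, `category`, `heuristic`.
#' @slot reactions named list of [SpeciesReaction-class] objects.
#' @slot species named list of [LipidSpecies-class] nodes.
#' @slot expansion data.frame reporting per-lipid molecular candidate counts
#'   and exclusions.
#' @export
setClass("LipidNetwork", representation(
  graph = "ANY", reactions = "list", species = "list",
  expansion = "data.frame"))

#' @describeIn LipidNetwork the underlying igraph
#' @param x object
#' @export
setMethod("networkGraph", "LipidNetwork", function(x) x@graph)

#' @describeIn LipidNetwork named list of species reactions
#' @export
setMethod("speciesReactions", "LipidNetwork", function(x) x@reactions)

setMethod("show", "LipidNetwork", function(object) {
  g <- object@graph
  cat(sprintf(paste0("LipidNetwork: %d lipid species, %d edges, ",
                     "%d species reactions (%d heuristic)\n"),
              igraph::vcount(g), igraph::ecount(g), length(object@reactions),
              sum(vapply(object@reactions, function(r) r@heuristic, TRUE))))
})

#' ReactionNetwork: species reactions as nodes
#'
#' The representation the enrichment operates on: every species reaction of a
#' [LipidNetwork-class] becomes a node; two reaction nodes are joined iff
#' they belong to the same lipid class reaction or share at least one lipid
#' species.
#'
#' @slot graph igraph with vertex attributes `name` (reaction id),
#'   `classReaction`, `heuristic`.
#' @slot reactions named list of [SpeciesReaction-class] objects.
#' @export
setClass("ReactionNetwork", representation(graph = "ANY", reactions = "list"))

#' @describeIn ReactionNetwork the underlying igraph
#' @param x object
#' @export
setMethod("networkGraph", "ReactionNetwork", function(x) x@graph)

#' @describeIn ReactionNetwork named list of species reactions
#' @export
setMethod("speciesReactions", "ReactionNetwork", function(x) x@reactions)

setMethod("show", "ReactionNetwork", function(object) {
  g <- object@graph
  comp <- igraph::components(g)
  cat(sprintf("ReactionNetwork: %d reaction nodes, %d edges, %d component(s)\n",
              igraph::vcount(g), igraph::ecount(g), comp$no))
})

## ---------------------------------------------------------------------------
## Grouped data container
## ---------------------------------------------------------------------------

#' LipidomicsExperiment: two-group lipid abundance data
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the lipids x samples abundance matrix in assay `"abundance"`, the
#' two-level sample grouping in `colData(x)$group`, and parsed species
#' annotation (class, level, sum composition) in `rowData`. The case
#' (disease) and control labels are kept in `metadata`.
#'
#' @export
setClass("LipidomicsExperiment", contains = "SummarizedExperiment")

setValidity("LipidomicsExperiment", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) return("colData must contain 'group'")
  md <- S4Vectors::metadata(object)
  if (is.null(md$caseLabel) || is.null(md$controlLabel))
    return("metadata caseLabel/controlLabel are required")
  g <- unique(as.character(cd$group))
  if (!setequal(g, c(md$caseLabel, md$controlLabel)))
    return("groups must be exactly the case and control labels")
  TRUE
})

## ---------------------------------------------------------------------------
## Enrichment configuration and result
## ---------------------------------------------------------------------------

#' EnrichmentConfig: tuning parameters of the network enrichment
#'
#' See [enrichmentConfig()] for defaults and parameter meaning.
#'
#' @export
setClass("EnrichmentConfig", representation(
  t0 = "numeric", alpha = "numeric", maxIter = "integer",
  minSize = "integer", maxSize = "integer", classPenalty = "numeric",
  heuristicScore = "numeric", scoreMode = "character",
  nPvalueSamples = "integer", nRestarts = "integer",
  alwaysStochastic = "logical", epsilon = "numeric"))

setValidity("EnrichmentConfig", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (object@t0 < 0) return("t0 must be >= 0")
  if (object@minSize < 1L || object@minSize > object@maxSize)
    return("need 1 <= minSize <= maxSize")
  if (object@classPenalty <= 0) return("classPenalty must be > 0")
  if (!object@scoreMode %in% c("relative", "absolute"))
    return("scoreMode must be 'relative' or 'absolute'")
  if (object@nPvalueSamples < 1L) return("nPvalueSamples must be >= 1")
  if (object@nRestarts < 1L) return("nRestarts must be >= 1")
  TRUE
})

setMethod("show", "EnrichmentConfig", function(object) {
  cat(sprintf(paste0("EnrichmentConfig: T0=%g alpha=%g size=[%d,%d] ",
                     "penalty=%g mode=%s restarts=%d pvalueSamples=%d\n"),
              object@t0, object@alpha, object@minSize, object@maxSize,
              object@classPenalty, object@scoreMode, object@nRestarts,
              object@nPvalueSamples))
})

#' EnrichmentResult: per-component subnetworks from the local search
#'
#' One entry per connected component of the reaction network, each holding
#' the best subnetwork found, its objective, the objective trajectory of the
#' winning search run and the empirical p-value.
#'
#' @slot components list of per-component results (`component`, `nodes`,
#'   `subnetwork`, `objective`, `trajectory`, `pvalue`, `skipped`).
#' @slot scores named reaction score vector used by the search.
#' @slot config the [EnrichmentConfig-class] used.
#' @slot seed integer seed used (NA when none was set).
#' @export
setClass("EnrichmentResult", representation(
  components = "list", scores = "numeric", config = "EnrichmentConfig",
  seed = "integer"))

#' @describeIn EnrichmentResult list of reaction-id vectors (one per
#'   component; skipped components give `character(0)`)
#' @param x object
#' @export
setMethod("subnetworks", "EnrichmentResult", function(x)
  lapply(x@components, function(cc) cc$subnetwork))

#' @describeIn EnrichmentResult numeric vector of per-component objectives
#' @export
setMethod("objectives", "EnrichmentResult", function(x)
  vapply(x@components, function(cc) cc$objective, 0))

#' @describeIn EnrichmentResult numeric vector of per-component empirical
#'   p-values
#' @export
setMethod("pvalues", "EnrichmentResult", function(x)
  vapply(x@components, function(cc)
    if (is.null(cc$pvalue)) NA_real_ else cc$pvalue, 0))

#' @describeIn EnrichmentResult reaction ids of the highest-objective
#'   component's subnetwork
#' @export
setMethod("bestSubnetwork", "EnrichmentResult", function(x) {
  o <- objectives(x)
  if (!length(o) || all(is.na(o))) return(character(0))
  x@components[[which.max(o)]]$subnetwork
})

#' @describeIn EnrichmentResult named reaction score vector
#' @export
setMethod("nodeScores", "EnrichmentResult", function(x) x@scores)

setMethod("show", "EnrichmentResult", function(object) {
  o <- objectives(object); p <- pvalues(object)
  cat(sprintf("EnrichmentResult: %d component(s)\n", length(object@components)))
  for (i in seq_along(object@components)) {
    cc <- object@components[[i]]
    if (isTRUE(cc$skipped)) {
      cat(sprintf("  [%d] skipped (%d nodes < minSize)\n", i, length(cc$nodes)))
    } else {
      cat(sprintf("  [%d] |subnetwork|=%d objective=%.4g p=%.4g\n", i,
                  length(cc$subnetwork), o[i], p[i]))
    }
  }
})

## ---------------------------------------------------------------------------
## Moiety features
## ---------------------------------------------------------------------------

#' MoietyFeatures: abundance-weighted lipid substructure matrix
#'
#' Samples x features matrix of abundance-weighted substructure occurrences
#' (headgroup, backbone, individual fatty acyls, sum chain length, sum double
#' bonds, sum hydroxylations, and optionally pairs thereof).
#'
#' @slot matrix samples x features numeric matrix.
#' @slot info data.frame (`feature`, `kind`) describing the columns.
#' @export
setClass("MoietyFeatures", representation(matrix = "matrix",
                                          info = "data.frame"))

#' @describeIn MoietyFeatures the samples x features matrix
#' @param x object
#' @export
setMethod("featureMatrix", "MoietyFeatures", function(x) x@matrix)

#' @describeIn MoietyFeatures feature annotation (label and substructure kind)
#' @export
setMethod("featureInfo", "MoietyFeatures", function(x) x@info)

setMethod("show", "MoietyFeatures", function(object) {
  cat(sprintf("MoietyFeatures: %d samples x %d features (%s)\n",
              nrow(object@matrix), ncol(object@matrix),
              paste(unique(object@info$kind), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

#' SimulationSpec: conditions of a synthetic two-group lipidomics experiment
#'
#' See [simulationSpec()] for defaults and the meaning of every field.
#'
#' @export
setClass("SimulationSpec", representation(
  classes = "character", nLipidsPerClass = "integer",
  nSamplesPerGroup = "integer", logMeanRange = "numeric", logSd = "numeric",
  sn1Pool = "character", sn2Pool = "character",
  plantedReaction = "character", effectMultiplier = "numeric",
  preferenceMinCarbons = "integer", preferenceMinDoubleBonds = "integer",
  direction = "character", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  if (object@effectMultiplier <= 0) return("effectMultiplier must be > 0")
  if (object@nSamplesPerGroup < 2L) return("need >= 2 samples per group")
  if (!object@direction %in% c("product_increase", "substrate_decrease"))
    return("direction must be 'product_increase' or 'substrate_decrease'")
  if (!setequal(names(object@nLipidsPerClass), object@classes))
    return("nLipidsPerClass must be named by the classes")
  TRUE
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: classes %s (%s lipids), %d+%d samples, ",
                     "%gx effect on %s (acyl >= %d:%d), seed %d\n"),
              paste(object@classes, collapse = "/"),
              paste(object@nLipidsPerClass, collapse = "/"),
              object@nSamplesPerGroup, object@nSamplesPerGroup,
              object@effectMultiplier, object@plantedReaction,
              object@preferenceMinCarbons, object@preferenceMinDoubleBonds,
              object@seed))
})

#' SimulatedDataset: synthetic data plus its ground truth
#'
#' @slot experiment the generated [LipidomicsExperiment-class].
#' @slot network the [LipidNetwork-class] built on the generated lipidome.
#' @slot truth list with the planted class reaction, the qualifying species
#'   reactions and the affected lipid species.
#' @slot spec the generating [SimulationSpec-class].
#' @export
setClass("SimulatedDataset", representation(
  experiment = "LipidomicsExperiment", network = "LipidNetwork",
  truth = "list", spec = "SimulationSpec"))

#' @describeIn SimulatedDataset the planted ground truth
#' @param x object
#' @export
setMethod("groundTruth", "SimulatedDataset", function(x) x@truth)

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf(paste0("SimulatedDataset: %d lipids x %d samples; planted %s ",
                     "on %d species reaction(s), %d affected lipid(s)\n"),
              nrow(object@experiment), ncol(object@experiment),
              object@spec@plantedReaction,
              length(object@truth$qualifyingReactions),
              length(object@truth$affectedLipids)))
})
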