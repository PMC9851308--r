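#' Fatty acyl pools
#'
#' `fattyAcylPool()` builds a [FattyAcylPool-class] from a global acyl set
#' and optional per-class overrides; `defaultAcylPool()` returns the default
#' pool of even-chain acyls with 12-24 carbons and 0-6 double bonds (no
#' hydroxylations), which covers the fatty acids commonly observed in
#' glycerophospholipids; `loadAcylPool()` reads a TSV with columns `class`
#' (`"*"` for the global pool) and `acyl`.
#'
#' @param global character vector of canonical acyl strings.
#' @param overrides named list mapping class abbreviations to acyl vectors;
#'   lookup for a class falls back to the global pool.
#' @return a [FattyAcylPool-class].
#' @examples
#' poolAcyls(defaultAcylPool(), "PC")
#' @export
fattyAcylPool <- function(global, overrides = list()) {
  parseAcyls(global)                      # validate
  for (v in overrides) parseAcyls(v)
  new("FattyAcylPool", global = unique(global), overrides = overrides)
}

#' @rdname fattyAcylPool
#' @export
defaultAcylPool <- function() {
  grid <- expand.grid(carbons = seq(12L, 24L, by = 2L), db = 0:6)
  fattyAcylPool(formatAcyls(grid$carbons, grid$db))
}

#' @rdname fattyAcylPool
#' @param path TSV file with columns `class` and `acyl`.
#' @export
loadAcylPool <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("class", "acyl") %in% colnames(tab)))
    stop(schemaError("acyl pool file needs columns 'class' and 'acyl'"))
  glob <- tab$acyl[tab$class == "*"]
  rest <- tab[tab$class != "*", , drop = FALSE]
  fattyAcylPool(glob, split(rest$acyl, rest$class))
}

#' @rdname fattyAcylPool
#' @param pool a [FattyAcylPool-class].
#' @param lipidClass class abbreviation.
#' @return `poolAcyls()` returns the acyl strings applying to that class.
#' @export
poolAcyls <- function(pool, lipidClass) {
  ov <- pool@overrides[[lipidClass]]
  if (!is.null(ov)) ov else pool@global
}

#' Enumerate molecular candidates of a sum species
#'
#' Expands a sum species into every molecular species whose acyl multiset is
#' drawn from the class pool and sums exactly to the sum composition
#' (carbons, double bonds, hydroxylations). Candidates are deduplicated up
#' to acyl multiset equality; sn-position is ignored. An empty result means
#' the sum species has no valid expansion under the pool and is excluded
#' from class-reaction evaluation downstream. Ether sum species are not
#' expanded unless the class pool itself contains ether acyls.
#'
#' @param species a sum-level [LipidSpecies-class].
#' @param pool a [FattyAcylPool-class].
#' @param registry a [ClassRegistry-class].
#' @return list of molecular [LipidSpecies-class] candidates (possibly
#'   empty), sorted by canonical name.
#' @examples
#' reg <- defaultClassRegistry()
#' pool <- fattyAcylPool(c("14:0", "16:0", "16:1", "18:0", "18:1", "20:1"))
#' dg <- parseLipidName("DG(34:1)", reg)
#' vapply(enumerateMolecularSpecies(dg, pool, reg), speciesName, "")
#' @export
enumerateMolecularSpecies <- function(species, pool,
                                      registry = defaultClassRegistry()) {
  stopifnot(is(species, "LipidSpecies"))
  if (species@level != "sum")
    stop("enumerateMolecularSpecies expects a sum-level species")
  k <- nAcylPositions(registry, species@lipidClass)
  acyls <- poolAcyls(pool, species@lipidClass)
  p <- parseAcyls(acyls)
  if (species@ether == "none") {
    keep <- p$ether == "none"
    acyls <- acyls[keep]; p <- p[keep, , drop = FALSE]
  } else {
    ## an ether sum species needs exactly one ether chain from the pool
    if (!any(p$ether == species@ether)) return(list())
  }
  sets <- enumerateMultisets(p, k,
                             c(species@sumC, species@sumDB, species@sumOH),
                             species@ether)
  out <- lapply(sets, function(idx) molecularSpecies(species@lipidClass,
                                                     acyls[idx]))
  nm <- vapply(out, speciesName, "")
  out <- out[!duplicated(nm)]
  out[order(vapply(out, speciesName, ""))]
}

## Enumerate non-decreasing index multisets of size k over the pool rows `p`
## whose (carbons, doubleBonds, hydroxyls) sum to `target`. For ether species
## exactly one chain must carry the matching ether bond.
enumerateMultisets <- function(p, k, target, ether = "none") {
  n <- nrow(p)
  if (n == 0L) return(list())
  ord <- order(p$carbons, p$doubleBonds, p$hydroxyls)
  p <- p[ord, , drop = FALSE]
  minC <- min(p$carbons)
  res <- list()
  recurse <- function(start, left, remC, remDB, remOH, nEther, acc) {
    if (left == 0L) {
      if (remC == 0L && remDB == 0L && remOH == 0L &&
          nEther == (ether != "none")) res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    for (i in start:n) {
      ci <- p$carbons[i]
      if (ci > remC - (left - 1L) * minC) break   # pool sorted by carbons
      if (p$doubleBonds[i] > remDB || p$hydroxyls[i] > remOH) next
      ne <- nEther + (p$ether[i] != "none")
      if (ne > (ether != "none")) next
      if (p$ether[i] != "none" && p$ether[i] != ether) next
      recurse(i, left - 1L, remC - ci, remDB - p$doubleBonds[i],
              remOH - p$hydroxyls[i], ne, c(acc, i))
    }
  }
  recurse(1L, k, target[1], target[2], target[3], 0L, integer(0))
  lapply(res, function(idx) ord[idx])
}
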