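#' Parse a shorthand lipid name
#'
#' Parses names of the form `CLASS(C:D[;O])` (sum species, e.g. `PC(34:1)`)
#' or `CLASS(C:D[_C:D]...)` (molecular species, e.g. `PC(16:0_18:1)`); the
#' level is inferred from the presence of `_`. An `O-`/`P-` prefix on the
#' composition (or on an individual chain) marks plasmanyl/plasmenyl ether
#' species. sn-positions are not modelled: chains are an unordered multiset,
#' and `parseLipidName` canonicalises their order.
#'
#' @param name lipid name in shorthand nomenclature.
#' @param registry a [ClassRegistry-class]; the class token must be present.
#' @return a [LipidSpecies-class].
#' @examples
#' reg <- defaultClassRegistry()
#' parseLipidName("PC(34:1)", reg)
#' parseLipidName("DG(16:0_18:1)", reg)
#' @export
parseLipidName <- function(name, registry = defaultClassRegistry()) {
  stopifnot(length(name) == 1L)
  m <- regmatches(name, regexec("^([A-Za-z][A-Za-z0-9]*)\\((.+)\\)$", name))[[1]]
  if (length(m) == 0L)
    stop(malformedNameError(sprintf(
      "cannot parse lipid name '%s': expected CLASS(composition)", name)))
  cls <- m[2]; comp <- m[3]
  if (!cls %in% registry@table$abbreviation)
    stop(unknownClassError(sprintf("unknown lipid class '%s' in '%s'",
                                   cls, name)))
  nPos <- nAcylPositions(registry, cls)
  if (grepl("_", comp, fixed = TRUE)) {
    acyls <- strsplit(comp, "_", fixed = TRUE)[[1]]
    p <- parseAcyls(acyls)                       # errors on malformed tokens
    if (length(acyls) != nPos)
      stop(malformedNameError(sprintf(
        "'%s': %d chains given but class %s has %d acyl positions",
        name, length(acyls), cls, nPos)))
    acyls <- sortAcyls(acyls)
    p <- parseAcyls(acyls)
    ether <- if (any(p$ether != "none")) p$ether[p$ether != "none"][1] else "none"
    newSpecies(cls, "molecular", acyls,
               sum(p$carbons), sum(p$doubleBonds), sum(p$hydroxyls), ether)
  } else {
    p <- parseAcyls(comp)
    newSpecies(cls, "sum", character(0),
               p$carbons, p$doubleBonds, p$hydroxyls, p$ether)
  }
}

newSpecies <- function(cls, level, acyls, sumC, sumDB, sumOH, ether) {
  name <- if (level == "molecular") {
    paste0(cls, "(", paste(acyls, collapse = "_"), ")")
  } else {
    paste0(cls, "(", formatAcyls(sumC, sumDB, sumOH, ether), ")")
  }
  new("LipidSpecies", name = name, lipidClass = cls, level = level,
      acyls = acyls, sumC = as.integer(sumC), sumDB = as.integer(sumDB),
      sumOH = as.integer(sumOH), ether = ether)
}

molecularSpecies <- function(cls, acyls) {
  acyls <- sortAcyls(acyls)
  p <- parseAcyls(acyls)
  ether <- if (any(p$ether != "none")) p$ether[p$ether != "none"][1] else "none"
  newSpecies(cls, "molecular", acyls, sum(p$carbons), sum(p$doubleBonds),
             sum(p$hydroxyls), ether)
}

#' Parse a vector of lipid names
#'
#' Vectorised wrapper around [parseLipidName()] that collects failures
#' instead of stopping.
#'
#' @param names character vector of lipid names.
#' @param registry a [ClassRegistry-class].
#' @return list with `species` (named list of [LipidSpecies-class] for the
#'   parseable names) and `failed` (character vector of unparseable names).
#' @export
parseLipidNames <- function(names, registry = defaultClassRegistry()) {
  species <- list(); failed <- character(0)
  for (nm in names) {
    sp <- tryCatch(parseLipidName(nm, registry), lipidnetError = function(e) NULL)
    if (is.null(sp)) failed <- c(failed, nm) else species[[nm]] <- sp
  }
  list(species = species, failed = failed)
}
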