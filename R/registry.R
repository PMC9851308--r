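#' Load a lipid class registry
#'
#' Reads a TSV with columns `abbreviation`, `headgroup`, `backbone`,
#' `n_positions`, `category` into a [ClassRegistry-class].
#'
#' @param path path to a tab-separated registry file.
#' @return a [ClassRegistry-class].
#' @examples
#' reg <- defaultClassRegistry()
#' classAbbreviations(reg)
#' @export
loadClassRegistry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("abbreviation", "headgroup", "backbone", "n_positions", "category")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop(schemaError(paste("registry file lacks column(s):",
                           paste(miss, collapse = ", "))))
  tab$n_positions <- as.integer(tab$n_positions)
  new("ClassRegistry", table = tab[need])
}

#' @rdname loadClassRegistry
#' @details `defaultClassRegistry()` returns the bundled registry covering
#'   common glycerophospholipid, lysophospholipid, glycerolipid and sterol
#'   ester classes (a curated subset of standard shorthand nomenclature, not
#'   a complete class catalogue).
#' @export
defaultClassRegistry <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- loadClassRegistry(system.file("extdata", "class_registry.tsv",
                                              package = "lipidnet",
                                              mustWork = TRUE))
    cache
  }
})

#' @rdname loadClassRegistry
#' @param registry a [ClassRegistry-class].
#' @export
classAbbreviations <- function(registry) registry@table$abbreviation

registryRow <- function(registry, abbreviation) {
  i <- match(abbreviation, registry@table$abbreviation)
  if (is.na(i))
    stop(unknownClassError(sprintf("unknown lipid class '%s'", abbreviation)))
  registry@table[i, , drop = FALSE]
}

#' Number of acyl positions of a lipid class
#'
#' @param registry a [ClassRegistry-class].
#' @param abbreviation class abbreviation, e.g. `"PC"`.
#' @return integer number of fatty acyl positions.
#' @export
nAcylPositions <- function(registry, abbreviation)
  registryRow(registry, abbreviation)$n_positions
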