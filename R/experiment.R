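#' Construct a two-group lipidomics experiment
#'
#' Wraps a lipids x samples abundance matrix and a two-level sample grouping
#' into a [LipidomicsExperiment-class]. Row names are parsed as shorthand
#' lipid names and the parsed annotation (class, level, sum composition) is
#' stored in `rowData`; unparseable rows are dropped with a warning (their
#' names are attached as attribute `"droppedLipids"`).
#'
#' @param abundance numeric matrix, lipids in rows (row names = lipid
#'   names), samples in columns.
#' @param groups named character vector or factor assigning each sample
#'   (by name, or positionally when unnamed) to one of two groups.
#' @param case,control the group labels for the case (disease) and control
#'   condition. Defaults to `"D"` and `"C"` when those labels are present,
#'   otherwise the sorted unique labels are used in order (case first).
#' @param registry a [ClassRegistry-class] used to parse row names.
#' @param parseNames set to `FALSE` to keep rows as-is (no species
#'   annotation; moiety analysis then refuses the object).
#' @return a [LipidomicsExperiment-class].
#' @examples
#' m <- matrix(rlnorm(12), nrow = 3,
#'             dimnames = list(c("PC(34:1)", "LPC(16:0)", "DG(34:1)"),
#'                             paste0("s", 1:4)))
#' le <- lipidomicsExperiment(m, c(s1 = "D", s2 = "D", s3 = "C", s4 = "C"))
#' caseSamples(le)
#' @export
lipidomicsExperiment <- function(abundance, groups, case = NULL,
                                 control = NULL,
                                 registry = defaultClassRegistry(),
                                 parseNames = TRUE) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop(schemaError("abundance matrix needs lipid row names"))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample", seq_len(ncol(abundance)))
  groupNames <- names(groups)
  groups <- as.character(if (is.factor(groups)) as.character(groups)
                         else groups)
  names(groups) <- groupNames
  if (!is.null(names(groups))) {
    common <- intersect(colnames(abundance), names(groups))
    if (!length(common))
      stop(noOverlapError("no sample name overlaps the groups assignment"))
    abundance <- abundance[, common, drop = FALSE]
    groups <- groups[common]
  } else if (length(groups) != ncol(abundance)) {
    stop(schemaError("unnamed groups must match the number of samples"))
  }
  u <- unique(groups)
  if (length(u) != 2L)
    stop(schemaError(sprintf("exactly two groups required, got: %s",
                             paste(u, collapse = ", "))))
  if (is.null(case))
    case <- if ("D" %in% u) "D" else sort(u)[1]
  if (is.null(control))
    control <- setdiff(u, case)
  if (!all(c(case, control) %in% u))
    stop(schemaError("case/control labels not present in groups"))

  dropped <- character(0)
  rd <- S4Vectors::DataFrame(row.names = rownames(abundance))
  if (parseNames) {
    parsed <- parseLipidNames(rownames(abundance), registry)
    dropped <- parsed$failed
    if (length(dropped)) {
      warning(lipidnetWarning(sprintf(
        "dropping %d unparseable lipid name(s): %s", length(dropped),
        paste(utils::head(dropped, 5), collapse = ", ")),
        "unparseableLipidWarning"))
      abundance <- abundance[setdiff(rownames(abundance), dropped), ,
                             drop = FALSE]
    }
    sp <- parsed$species[rownames(abundance)]
    rd <- S4Vectors::DataFrame(
      lipidClass = vapply(sp, lipidClass, ""),
      level = vapply(sp, speciesLevel, ""),
      sumC = vapply(sp, function(s) s@sumC, 1L),
      sumDB = vapply(sp, function(s) s@sumDB, 1L),
      sumOH = vapply(sp, function(s) s@sumOH, 1L),
      row.names = rownames(abundance))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(abundance)),
    rowData = rd)
  S4Vectors::metadata(se)$caseLabel <- case
  S4Vectors::metadata(se)$controlLabel <- control
  out <- new("LipidomicsExperiment", se)
  attr(out, "droppedLipids") <- dropped
  out
}

#' @describeIn lipidomicsExperiment the abundance matrix
#' @param x a [LipidomicsExperiment-class].
#' @export
setMethod("abundances", "LipidomicsExperiment", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @describeIn lipidomicsExperiment sample-to-group assignment (named
#'   character vector)
#' @export
setMethod("sampleGroups", "LipidomicsExperiment", function(x) {
  g <- as.character(SummarizedExperiment::colData(x)$group)
  names(g) <- colnames(x)
  g
})

#' @describeIn lipidomicsExperiment names of case (disease) samples
#' @export
setMethod("caseSamples", "LipidomicsExperiment", function(x) {
  g <- sampleGroups(x)
  names(g)[g == S4Vectors::metadata(x)$caseLabel]
})

#' @describeIn lipidomicsExperiment names of control samples
#' @export
setMethod("controlSamples", "LipidomicsExperiment", function(x) {
  g <- sampleGroups(x)
  names(g)[g == S4Vectors::metadata(x)$controlLabel]
})

groupSamples <- function(x, group = c("case", "control")) {
  switch(match.arg(group), case = caseSamples(x), control = controlSamples(x))
}
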