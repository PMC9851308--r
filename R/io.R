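#' Read a lipid abundance matrix with a group assignment
#'
#' Reads a CSV/TSV abundance table (first column lipid names, remaining
#' columns samples) and a two-column groups table (`sample`, `group`) into
#' a [LipidomicsExperiment-class]. Rows whose name does not parse as a
#' lipid species are dropped and reported. With `minFraction`, lipids
#' measured (finite and positive) in less than that fraction of all samples
#' are removed; remaining missing values are imputed with half the lipid's
#' minimum measured abundance (disable with `impute = FALSE`).
#'
#' @param path abundance table (`.csv` is comma-, anything else
#'   tab-separated).
#' @param groupsPath groups table with header columns `sample` and `group`.
#' @param case,control group labels (see [lipidomicsExperiment()]).
#' @param minFraction optional minimum fraction of samples a lipid must be
#'   measured in (e.g. `0.5`).
#' @param impute impute remaining missing values by half-minimum.
#' @param registry a [ClassRegistry-class].
#' @return a [LipidomicsExperiment-class].
#' @export
readAbundanceMatrix <- function(path, groupsPath, case = NULL, control = NULL,
                                minFraction = NULL, impute = TRUE,
                                registry = defaultClassRegistry()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop(schemaError("abundance table needs a lipid column plus samples"))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  gt <- utils::read.table(groupsPath, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "group") %in% colnames(gt)))
    stop(schemaError("groups table needs columns 'sample' and 'group'"))
  groups <- stats::setNames(as.character(gt$group), as.character(gt$sample))

  if (!is.null(minFraction)) {
    measured <- rowMeans(is.finite(m) & m > 0)
    drop <- measured < minFraction
    if (any(drop)) {
      message(sprintf("removing %d lipid(s) measured in < %d%% of samples",
                      sum(drop), round(100 * minFraction)))
      m <- m[!drop, , drop = FALSE]
    }
  }
  if (impute && any(!is.finite(m) | m <= 0)) {
    for (i in seq_len(nrow(m))) {
      bad <- !is.finite(m[i, ]) | m[i, ] <= 0
      if (any(bad) && !all(bad))
        m[i, bad] <- min(m[i, !bad]) / 2
    }
  }
  lipidomicsExperiment(m, groups, case = case, control = control,
                       registry = registry)
}

#' Write a network as GraphML
#'
#' For a [LipidNetwork-class], `reactions` restricts the export to edges
#' belonging to those species reactions (e.g. a subnetwork from
#' [enrichNetwork()]).
#'
#' @param x a [LipidNetwork-class] or [ReactionNetwork-class].
#' @param path output file.
#' @param reactions optional character vector of species-reaction ids.
#' @param ... passed on to methods.
#' @return the path, invisibly.
#' @rdname writeGraphML
#' @export
setMethod("writeGraphML", "LipidNetwork", function(x, path, reactions = NULL) {
  g <- networkGraph(x)
  if (!is.null(reactions)) {
    keep <- igraph::E(g)$reaction %in% reactions
    g <- igraph::subgraph_from_edges(g, igraph::E(g)[keep],
                                     delete.vertices = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
})

#' @rdname writeGraphML
#' @export
setMethod("writeGraphML", "ReactionNetwork", function(x, path, ...) {
  igraph::write_graph(networkGraph(x), path, format = "graphml")
  invisible(path)
})

#' Export a lipid network as JSON
#'
#' Nodes carry name, class and level (plus group statistics when an
#' experiment is given); edges carry the species reaction id, category,
#' heuristic flag and transferred acyl(s).
#'
#' @param net a [LipidNetwork-class].
#' @param path output file.
#' @param x optional [LipidomicsExperiment-class] for node statistics.
#' @export
writeNetworkJSON <- function(net, path, x = NULL) {
  g <- networkGraph(net)
  nodes <- data.frame(name = igraph::V(g)$name,
                      lipidClass = igraph::V(g)$lipidClass,
                      level = igraph::V(g)$level, stringsAsFactors = FALSE)
  if (!is.null(x)) {
    ns <- nodeStatistics(x)
    nodes <- merge(nodes, ns, by.x = "name", by.y = "lipid",
                   all.x = TRUE, sort = FALSE)
  }
  el <- igraph::as_edgelist(g)
  rxns <- speciesReactions(net)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      reaction = igraph::E(g)$reaction,
                      category = igraph::E(g)$category,
                      heuristic = igraph::E(g)$heuristic,
                      stringsAsFactors = FALSE)
  edges$transferredAcyls <- lapply(edges$reaction, function(id)
    rxns[[id]]@transferredAcyls)
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

configAsList <- function(config) {
  list(t0 = config@t0, alpha = config@alpha, maxIter = config@maxIter,
       minSize = config@minSize, maxSize = config@maxSize,
       classPenalty = config@classPenalty,
       heuristicScore = config@heuristicScore,
       scoreMode = config@scoreMode,
       nPvalueSamples = config@nPvalueSamples,
       nRestarts = config@nRestarts,
       alwaysStochastic = config@alwaysStochastic,
       epsilon = config@epsilon)
}

#' Write an enrichment result as JSON
#'
#' The file holds the seed, an echo of the exact configuration used, and
#' per component the subnetwork, objective, objective trajectory and
#' empirical p-value; skipped components are marked explicitly. Output is
#' deterministic given the seed.
#'
#' @param result an [EnrichmentResult-class].
#' @param path output file.
#' @export
writeEnrichmentJSON <- function(result, path) {
  comps <- lapply(result@components, function(cc) {
    list(component = cc$component, skipped = isTRUE(cc$skipped),
         subnetwork = cc$subnetwork,
         objective = if (is.na(cc$objective)) NULL else cc$objective,
         trajectory = cc$trajectory,
         pvalue = cc$pvalue)
  })
  jsonlite::write_json(
    list(seed = result@seed, config = configAsList(result@config),
         components = comps),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param tab data.frame.
#' @param path output file.
#' @export
writeTSV <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
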