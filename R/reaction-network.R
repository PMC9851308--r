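#' Build the reaction network
#'
#' Converts a [LipidNetwork-class] into the representation the enrichment
#' operates on: distinct species reactions become nodes, and two reaction
#' nodes are joined iff they belong to the same lipid class reaction or
#' share at least one lipid species. No self loops.
#'
#' @param net a [LipidNetwork-class].
#' @param lipids optional character vector of quantified lipid names;
#'   reactions with any participant outside this set are dropped (all
#'   participants of a reaction must be quantified to score it).
#' @return a [ReactionNetwork-class].
#' @export
buildReactionNetwork <- function(net, lipids = NULL) {
  rxns <- speciesReactions(net)
  if (!is.null(lipids)) {
    keep <- vapply(rxns, function(r)
      all(c(r@substrates, r@products) %in% lipids), TRUE)
    if (!all(keep))
      warning(lipidnetWarning(sprintf(
        "dropping %d reaction(s) with unquantified participants",
        sum(!keep)), "unquantifiedReactionWarning"))
    rxns <- rxns[keep]
  }
  if (!length(rxns))
    stop(schemaError("network has no (quantifiable) species reaction"))
  ids <- names(rxns)
  crOf <- vapply(rxns, function(r) r@classReaction, "")
  heur <- vapply(rxns, function(r) r@heuristic, TRUE)

  pairUp <- function(groups) {
    out <- list()
    for (g in groups) {
      if (length(g) < 2L) next
      g <- sort(g)
      out[[length(out) + 1L]] <- t(utils::combn(g, 2L))
    }
    out
  }
  sameCr <- pairUp(split(ids, crOf))
  lipidToRxn <- list()
  for (i in seq_along(rxns)) {
    for (l in c(rxns[[i]]@substrates, rxns[[i]]@products))
      lipidToRxn[[l]] <- c(lipidToRxn[[l]], ids[i])
  }
  shareLipid <- pairUp(lipidToRxn)
  allPairs <- do.call(rbind, c(sameCr, shareLipid))
  if (is.null(allPairs)) allPairs <- matrix(character(0), ncol = 2)
  allPairs <- unique(allPairs)
  vertices <- data.frame(name = ids, classReaction = crOf, heuristic = heur,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = allPairs[, 1], to = allPairs[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices)
  new("ReactionNetwork", graph = g, reactions = rxns)
}

#' Assemble a reaction network directly
#'
#' Low-level constructor used for testing and for synthetic reaction
#' networks: takes an igraph whose vertices carry `name`, `classReaction`
#' and `heuristic` attributes.
#'
#' @param graph undirected igraph with the vertex attributes above.
#' @param reactions optional named list of [SpeciesReaction-class].
#' @return a [ReactionNetwork-class].
#' @export
reactionNetwork <- function(graph, reactions = list()) {
  stopifnot(!is.null(igraph::V(graph)$name),
            !is.null(igraph::V(graph)$classReaction),
            !is.null(igraph::V(graph)$heuristic))
  new("ReactionNetwork", graph = igraph::simplify(graph),
      reactions = reactions)
}
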