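#' Simulated-annealing local search for the heaviest connected subnetwork
#'
#' Runs the enrichment's local search independently on every connected
#' component of the reaction network. Starting from a random connected seed
#' of `minSize` nodes, each iteration evaluates all legal moves -- adding a
#' neighbouring node, deleting a node (keeping the subnetwork connected and
#' at least `minSize` large), or substituting a node for a neighbour -- and
#' applies the best improving one. When no move improves the objective, a
#' random move is drawn and accepted iff
#' `exp((o_prev - o_new) / (-T)) > uniform(0, 1)` with temperature
#' `T = t0 * alpha^n`; a rejection terminates the run, as does move
#' exhaustion or the iteration cap. The best subnetwork seen across
#' `nRestarts` independent runs is returned per component. Components
#' smaller than `minSize` are skipped with a warning.
#'
#' @param rn a [ReactionNetwork-class].
#' @param scores named numeric score vector covering every reaction node
#'   (see [reactionScores()]).
#' @param config an [EnrichmentConfig-class].
#' @param seed optional integer seed (set once before all restarts).
#' @param recordStates keep every visited state (for diagnostics/tests).
#' @return an [EnrichmentResult-class] (p-values unset; see
#'   [empiricalPvalue()] and [enrichNetwork()]).
#' @export
localSearch <- function(rn, scores, config = enrichmentConfig(), seed = NULL,
                        recordStates = FALSE) {
  g <- networkGraph(rn)
  ids <- igraph::V(g)$name
  if (!all(ids %in% names(scores)))
    stop(schemaError("scores must cover every reaction node"))
  if (!is.null(seed)) set.seed(seed)
  crAll <- igraph::V(g)$classReaction
  names(crAll) <- ids
  comp <- igraph::components(g)
  results <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    nodes <- sort(ids[comp$membership == ci])
    if (length(nodes) < config@minSize) {
      warning(lipidnetWarning(sprintf(
        "component %d has %d node(s) < minSize = %d; skipped",
        ci, length(nodes), config@minSize), "componentTooSmallWarning"))
      results[[ci]] <- list(component = ci, nodes = nodes,
                            subnetwork = character(0), objective = NA_real_,
                            trajectory = numeric(0), pvalue = NULL,
                            skipped = TRUE)
      next
    }
    A <- adjacencyFor(g, nodes)
    res <- searchComponent(A, scores[nodes], crAll[nodes], config,
                           recordStates)
    results[[ci]] <- c(list(component = ci, nodes = nodes, pvalue = NULL,
                            skipped = FALSE), res)
  }
  new("EnrichmentResult", components = results, scores = scores[ids],
      config = config,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

adjacencyFor <- function(g, nodes) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    igraph::induced_subgraph(g, nodes), sparse = FALSE))
  A <- A[nodes, nodes] > 0
  diag(A) <- FALSE
  A
}

## TRUE iff the nodes `keep` (indices into A) induce a connected subgraph.
isConnectedSubset <- function(A, keep) {
  k <- length(keep)
  if (k <= 1L) return(TRUE)
  sub <- A[keep, keep, drop = FALSE]
  seen <- logical(k)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(sub[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

searchComponent <- function(A, s, cr, config, recordStates = FALSE) {
  n <- nrow(A)
  crCode <- as.integer(factor(cr))
  nCrTotal <- max(crCode)
  p <- config@classPenalty
  minS <- config@minSize
  maxS <- min(config@maxSize, n)
  objOf <- function(idx)
    unname(sum(s[idx]) / (length(idx) * p * length(unique(crCode[idx]))))

  bestIdx <- NULL; bestObj <- -Inf; bestTraj <- numeric(0)
  bestStates <- list()

  for (restart in seq_len(config@nRestarts)) {
    ## random connected seed of size minSize
    idx <- sample.int(n, 1L)
    while (length(idx) < minS) {
      nb <- which(colSums(A[idx, , drop = FALSE]) > 0)
      nb <- setdiff(nb, idx)
      idx <- c(idx, if (length(nb) == 1L) nb else sample(nb, 1L))
    }
    idx <- sort(idx)
    curObj <- objOf(idx)
    runBestIdx <- idx; runBestObj <- curObj
    traj <- numeric(0)
    states <- if (recordStates) list(idx) else NULL

    for (iter in seq_len(config@maxIter)) {
      k <- length(idx)
      inSet <- logical(n); inSet[idx] <- TRUE
      linksIn <- colSums(A[idx, , drop = FALSE])
      nb <- which(!inSet & linksIn > 0)
      tab <- tabulate(crCode[idx], nbins = nCrTotal)
      nCR <- sum(tab > 0)
      sumS <- sum(s[idx])

      moveType <- integer(0); moveU <- integer(0); moveV <- integer(0)
      moveObj <- numeric(0)
      ## additions (connectivity preserved by construction)
      if (k < maxS && length(nb)) {
        newCR <- nCR + (tab[crCode[nb]] == 0L)
        moveType <- c(moveType, rep(1L, length(nb)))
        moveU <- c(moveU, rep(NA_integer_, length(nb)))
        moveV <- c(moveV, nb)
        moveObj <- c(moveObj, (sumS + s[nb]) / ((k + 1) * p * newCR))
      }
      ## removable nodes: deleting them keeps the subnetwork connected
      removable <- idx[vapply(seq_along(idx), function(j)
        isConnectedSubset(A, idx[-j]), TRUE)]
      if (k > minS && length(removable)) {
        newCR <- nCR - (tab[crCode[removable]] == 1L)
        moveType <- c(moveType, rep(2L, length(removable)))
        moveU <- c(moveU, removable)
        moveV <- c(moveV, rep(NA_integer_, length(removable)))
        moveObj <- c(moveObj, (sumS - s[removable]) / ((k - 1) * p * newCR))
      }
      ## substitutions: drop removable u, add v still adjacent to the rest
      if (length(removable) && length(nb)) {
        for (u in removable) {
          vOk <- if (k == 1L) nb else nb[linksIn[nb] - A[nb, u] > 0]
          if (!length(vOk)) next
          tabU <- tab; tabU[crCode[u]] <- tabU[crCode[u]] - 1L
          nCRu <- nCR - (tab[crCode[u]] == 1L)
          newCR <- nCRu + (tabU[crCode[vOk]] == 0L)
          moveType <- c(moveType, rep(3L, length(vOk)))
          moveU <- c(moveU, rep(u, length(vOk)))
          moveV <- c(moveV, vOk)
          moveObj <- c(moveObj, (sumS - s[u] + s[vOk]) / (k * p * newCR))
        }
      }
      if (!length(moveObj)) break                       # (a) no moves left

      pick <- which.max(moveObj)
      accepted <- FALSE
      if (moveObj[pick] > curObj + 1e-12 && !config@alwaysStochastic) {
        accepted <- TRUE
      } else {
        pick <- sample.int(length(moveObj), 1L)
        if (moveObj[pick] >= curObj) {
          accepted <- TRUE
        } else {
          temp <- config@t0 * config@alpha^iter
          if (temp > 0 &&
              exp((curObj - moveObj[pick]) / (-temp)) > stats::runif(1L))
            accepted <- TRUE
        }
        if (!accepted && !config@alwaysStochastic) break # (b) SA rejection
      }
      if (accepted) {
        idx <- switch(moveType[pick],
                      sort(c(idx, moveV[pick])),
                      setdiff(idx, moveU[pick]),
                      sort(c(setdiff(idx, moveU[pick]), moveV[pick])))
        curObj <- unname(moveObj[pick])
        if (curObj > runBestObj) { runBestObj <- curObj; runBestIdx <- idx }
      }
      traj <- c(traj, curObj)
      if (recordStates && accepted) states[[length(states) + 1L]] <- idx
    }
    if (runBestObj > bestObj) {
      bestObj <- runBestObj; bestIdx <- runBestIdx; bestTraj <- traj
      if (recordStates) bestStates <- states
    }
  }
  out <- list(subnetwork = rownames(A)[bestIdx], objective = bestObj,
              trajectory = bestTraj)
  if (recordStates)
    out$states <- lapply(bestStates, function(ii) rownames(A)[ii])
  out
}

#' Empirical p-value of a subnetwork objective
#'
#' Draws random *unconnected* sets of reaction nodes with sizes uniform in
#' `[minSize, maxSize]`, scores each with the subnetwork objective, and
#' returns `(1 + #\{sampled o >= observed\}) / (nPvalueSamples + 1)` -- a
#' one-sided empirical p-value with a pseudocount, so it is never 0. The
#' rationale: the connected (mechanistic) solution is compared against
#' equally sized non-mechanistic reaction sets.
#'
#' @param rn a [ReactionNetwork-class].
#' @param scores named score vector covering the sampled nodes.
#' @param observed the observed subnetwork objective.
#' @param config an [EnrichmentConfig-class].
#' @param nodes node ids to sample from (default: all reaction nodes; the
#'   full enrichment samples within the subnetwork's component).
#' @param seed optional integer seed.
#' @return numeric p-value with the sampled objectives attached as
#'   attribute `"samples"`.
#' @export
empiricalPvalue <- function(rn, scores, observed, config = enrichmentConfig(),
                            nodes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- networkGraph(rn)
  if (is.null(nodes)) nodes <- igraph::V(g)$name
  cr <- igraph::V(g)$classReaction[match(nodes, igraph::V(g)$name)]
  crCode <- as.integer(factor(cr))
  sv <- scores[nodes]
  N <- length(nodes)
  minS <- config@minSize
  maxS <- min(config@maxSize, N)
  nSamp <- config@nPvalueSamples
  sizes <- if (minS == maxS) rep.int(minS, nSamp)
           else sample(seq.int(minS, maxS), nSamp, replace = TRUE)
  os <- vapply(sizes, function(sz) {
    pick <- sample.int(N, sz)
    sum(sv[pick]) / (sz * config@classPenalty * length(unique(crCode[pick])))
  }, 0)
  p <- (1 + sum(os >= observed)) / (nSamp + 1)
  attr(p, "samples") <- os
  p
}

#' Run the full network enrichment
#'
#' Convenience wrapper tying the stages together: builds the reaction
#' network restricted to quantified lipids, scores every reaction node,
#' runs the simulated-annealing local search per component and computes a
#' per-component empirical p-value.
#'
#' @param x a [LipidomicsExperiment-class].
#' @param net the [LipidNetwork-class] of the measured lipidome.
#' @param config an [EnrichmentConfig-class].
#' @param seed optional integer seed covering search and p-value sampling.
#' @return an [EnrichmentResult-class].
#' @export
enrichNetwork <- function(x, net, config = enrichmentConfig(), seed = NULL) {
  rn <- buildReactionNetwork(net, lipids = rownames(x))
  scores <- reactionScores(x, rn, config)
  if (!is.null(seed)) set.seed(seed)
  res <- localSearch(rn, scores, config, seed = NULL)
  res@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  for (i in seq_along(res@components)) {
    cc <- res@components[[i]]
    if (isTRUE(cc$skipped)) next
    cc$pvalue <- as.numeric(empiricalPvalue(rn, scores, cc$objective, config,
                                            nodes = cc$nodes))
    res@components[[i]] <- cc
  }
  attr(res, "reactionNetwork") <- rn
  res
}
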