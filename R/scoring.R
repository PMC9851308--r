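#' Enrichment configuration
#'
#' Collects the tuning parameters of the network enrichment.
#'
#' @param t0 initial simulated-annealing temperature.
#' @param alpha cooling rate in (0, 1); the temperature at iteration n is
#'   `t0 * alpha^n`.
#' @param maxIter iteration cap per search run.
#' @param minSize,maxSize subnetwork size bounds.
#' @param classPenalty penalty `p > 0` applied per distinct class reaction
#'   in the subnetwork objective.
#' @param heuristicScore fixed score of heuristic reactions (default -1,
#'   penalising their selection).
#' @param scoreMode `"relative"` (geometric-mean substrate-product ratios;
#'   unit-free, the default) or `"absolute"` (mean differences).
#' @param nPvalueSamples number of random reaction sets drawn for the
#'   empirical p-value.
#' @param nRestarts independent random restarts of the local search; the
#'   best subnetwork across restarts is returned.
#' @param alwaysStochastic run plain simulated annealing (random move every
#'   iteration) instead of best-improvement search with annealing escapes at
#'   local optima.
#' @param epsilon floor for the control-group denominator of the score.
#' @return an [EnrichmentConfig-class].
#' @export
enrichmentConfig <- function(t0 = 1, alpha = 0.95, maxIter = 1e5L,
                             minSize = 3L, maxSize = 15L, classPenalty = 1,
                             heuristicScore = -1, scoreMode = "relative",
                             nPvalueSamples = 1e4L, nRestarts = 5L,
                             alwaysStochastic = FALSE, epsilon = 1e-12) {
  new("EnrichmentConfig", t0 = t0, alpha = alpha,
      maxIter = as.integer(maxIter), minSize = as.integer(minSize),
      maxSize = as.integer(maxSize), classPenalty = classPenalty,
      heuristicScore = heuristicScore, scoreMode = scoreMode,
      nPvalueSamples = as.integer(nPvalueSamples),
      nRestarts = as.integer(nRestarts),
      alwaysStochastic = alwaysStochastic, epsilon = epsilon)
}

reactionParticipants <- function(x, reaction) {
  L <- abundances(x)
  miss <- setdiff(c(reaction@substrates, reaction@products), rownames(L))
  if (length(miss))
    stop(missingLipidError(paste("lipid(s) not quantified:",
                                 paste(miss, collapse = ", "))))
  L
}

#' Substrate-product change of a reaction in one group
#'
#' `gammaAbs()` computes the absolute substrate-product difference: the mean
#' over the group's samples of (mean product abundance - mean substrate
#' abundance). `gammaRel()` computes the relative difference: the mean over
#' the group's samples of (geometric mean of product abundances / geometric
#' mean of substrate abundances). The mean / root corrects for bias towards
#' reactions with several substrates or products.
#'
#' @param x a [LipidomicsExperiment-class].
#' @param reaction a [SpeciesReaction-class] whose participants are all
#'   quantified in `x`.
#' @param group `"case"` or `"control"`.
#' @return a single numeric value.
#' @export
gammaAbs <- function(x, reaction, group = c("case", "control")) {
  L <- reactionParticipants(x, reaction)
  ss <- groupSamples(x, group)
  prodMeans <- colMeans(L[reaction@products, ss, drop = FALSE])
  subMeans <- colMeans(L[reaction@substrates, ss, drop = FALSE])
  mean(prodMeans - subMeans)
}

#' @rdname gammaAbs
#' @export
gammaRel <- function(x, reaction, group = c("case", "control")) {
  L <- reactionParticipants(x, reaction)
  ss <- groupSamples(x, group)
  sub <- L[c(reaction@substrates, reaction@products), ss, drop = FALSE]
  if (any(!is.finite(sub)) || any(sub <= 0))
    stop(nonPositiveAbundanceError(
      "relative substrate-product change requires positive abundances"))
  gmProd <- exp(colMeans(log(L[reaction@products, ss, drop = FALSE])))
  gmSub <- exp(colMeans(log(L[reaction@substrates, ss, drop = FALSE])))
  mean(gmProd / gmSub)
}

#' Reaction node score
#'
#' The dysregulation score of a reaction node:
#' `|gammaCase - gammaControl| / |gammaControl|` for regular reactions (the
#' control denominator is floored at `epsilon` in relative mode, and raises
#' a `degenerateControlError` in absolute mode when it vanishes), and the
#' fixed `heuristicScore` (default -1) for heuristic reactions, which
#' favours the selection of non-heuristic reactions.
#'
#' @param gammaCase,gammaControl group-wise substrate-product changes
#'   computed with the same mode ([gammaAbs()] or [gammaRel()]).
#' @param heuristic whether the reaction is a connectivity heuristic.
#' @param config an [EnrichmentConfig-class].
#' @return a single numeric score.
#' @export
reactionScore <- function(gammaCase, gammaControl, heuristic = FALSE,
                          config = enrichmentConfig()) {
  if (heuristic) return(config@heuristicScore)
  den <- abs(gammaControl)
  if (den < config@epsilon) {
    if (config@scoreMode == "absolute")
      stop(degenerateControlError(
        "control-group substrate-product change is (numerically) zero"))
    den <- config@epsilon
  }
  abs(gammaCase - gammaControl) / den
}

#' Score every reaction node of a reaction network
#'
#' @param x a [LipidomicsExperiment-class].
#' @param rn a [ReactionNetwork-class] whose reactions' participants are all
#'   quantified in `x`.
#' @param config an [EnrichmentConfig-class]; `scoreMode` selects
#'   [gammaAbs()] or [gammaRel()].
#' @return named numeric vector of scores (one per reaction node).
#' @export
reactionScores <- function(x, rn, config = enrichmentConfig()) {
  gamma <- if (config@scoreMode == "relative") gammaRel else gammaAbs
  rxns <- speciesReactions(rn)
  vapply(rxns, function(r) {
    if (r@heuristic) return(config@heuristicScore)
    reactionScore(gamma(x, r, "case"), gamma(x, r, "control"),
                  heuristic = FALSE, config = config)
  }, 0)
}

#' Subnetwork objective
#'
#' The objective of a reaction subnetwork: the sum of its node scores
#' divided by (number of nodes x (classPenalty x number of distinct class
#' reactions among the nodes)).
#'
#' @param scores numeric scores of the subnetwork's reaction nodes.
#' @param classReactions class-reaction id of each node (same length).
#' @param classPenalty penalty `p > 0`.
#' @return a single numeric value.
#' @examples
#' subnetworkObjective(c(1, 2), c("A", "A"))   # 1.5
#' subnetworkObjective(c(1, 2), c("A", "B"))   # 0.75
#' @export
subnetworkObjective <- function(scores, classReactions, classPenalty = 1) {
  stopifnot(length(scores) == length(classReactions), length(scores) >= 1L)
  sum(scores) /
    (length(scores) * (classPenalty * length(unique(classReactions))))
}
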