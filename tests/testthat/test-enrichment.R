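test_that("reaction-network edges follow the share-a-class-reaction-or-a-lipid
          rule", {
  rxns <- list(
    speciesReactionFixture("A", "B", cr = "CR1"),
    speciesReactionFixture("C", "D", cr = "CR1"),     # same CR, disjoint
    speciesReactionFixture("D", "E", cr = "CR2"),     # shares lipid D
    speciesReactionFixture("F", "G", cr = "CR3"))     # disjoint, other CR
  names(rxns) <- vapply(rxns, reactionId, "")
  net <- new("LipidNetwork",
             graph = igraph::graph_from_data_frame(
               do.call(rbind, lapply(rxns, function(r)
                 data.frame(from = r@substrates, to = r@products,
                            reaction = r@id, category = r@category,
                            heuristic = r@heuristic))),
               directed = FALSE),
             reactions = rxns, species = list(), expansion = data.frame())
  rn <- buildReactionNetwork(net)
  g <- networkGraph(rn)
  ids <- names(rxns)
  connected <- function(i, j)
    igraph::are_adjacent(g, ids[i], ids[j])
  expect_true(connected(1, 2))    # same class reaction
  expect_true(connected(2, 3))    # share lipid D
  expect_false(connected(1, 3))
  expect_false(connected(1, 4))
  expect_false(connected(3, 4))
  ## no self loops
  expect_equal(sum(igraph::which_loop(g)), 0L)
})

test_that("reactions with unquantified participants are dropped before
          scoring", {
  rxns <- list(speciesReactionFixture("A", "B", cr = "CR1"),
               speciesReactionFixture("B", "Z", cr = "CR2"))
  names(rxns) <- vapply(rxns, reactionId, "")
  net <- new("LipidNetwork",
             graph = igraph::graph_from_data_frame(
               do.call(rbind, lapply(rxns, function(r)
                 data.frame(from = r@substrates, to = r@products,
                            reaction = r@id, category = r@category,
                            heuristic = r@heuristic))),
               directed = FALSE),
             reactions = rxns, species = list(), expansion = data.frame())
  expect_warning(rn <- buildReactionNetwork(net, lipids = c("A", "B")),
                 class = "unquantifiedReactionWarning")
  expect_length(speciesReactions(rn), 1L)
})

test_that("gamma and score formulas match their spelled-out examples", {
  L <- rbind(S1 = c(2, 2), S2 = c(4, 4), P1 = c(6, 4), P2 = c(8, 8))
  colnames(L) <- c("d1", "c1")
  x <- suppressWarnings(syntheticExperiment(L, 1, 1))

  r11 <- speciesReactionFixture("S1", "P1")
  expect_equal(gammaAbs(x, r11, "case"), 4)      # 6 - 2
  r12 <- speciesReactionFixture("S1", c("P1", "P2"))
  expect_equal(gammaAbs(x, r12, "case"), 5)      # (6+8)/2 - 2
  rEq <- speciesReactionFixture("S2", "P1")
  expect_equal(gammaAbs(x, rEq, "control"), 0)   # 4 - 4

  rRel <- speciesReactionFixture("S1", "P1")
  expect_equal(gammaRel(x, rRel, "control"), 2)  # 4 / 2
  L2 <- rbind(S1 = 4, P1 = 2, P2 = 8); colnames(L2) <- "d1"
  x2 <- suppressWarnings(syntheticExperiment(cbind(L2, c1 = c(1, 1, 1)), 1, 1))
  expect_equal(gammaRel(x2, speciesReactionFixture("S1", c("P1", "P2")),
                        "case"), 1)              # sqrt(16) / 4

  cfg <- enrichmentConfig()
  expect_equal(reactionScore(3, 2, FALSE, cfg), 0.5)
  expect_equal(reactionScore(2, 2, FALSE, cfg), 0)
  expect_equal(reactionScore(100, 7, TRUE, cfg), -1)
  expect_error(reactionScore(1, 0, FALSE, enrichmentConfig(
    scoreMode = "absolute")), class = "degenerateControlError")

  expect_error(gammaAbs(x, speciesReactionFixture("S1", "missing"), "case"),
               class = "missingLipidError")
  xNeg <- suppressWarnings(syntheticExperiment(
    rbind(S1 = c(-1, 1), P1 = c(2, 2)) |>
      (\(m) { colnames(m) <- c("d1", "c1"); m })(), 1, 1))
  expect_error(gammaRel(xNeg, speciesReactionFixture("S1", "P1"), "case"),
               class = "nonPositiveAbundanceError")
})

test_that("the subnetwork objective matches its closed form", {
  expect_equal(subnetworkObjective(c(1, 2), c("A", "A")), 1.5)
  expect_equal(subnetworkObjective(c(1, 2), c("A", "B")), 0.75)
  expect_equal(subnetworkObjective(5, "A"), 5)
  expect_equal(subnetworkObjective(c(1, 2, 3), c("A", "B", "B"),
                                   classPenalty = 2), 6 / (3 * 2 * 2))
})

test_that("relative mode is invariant to per-sample rescaling", {
  set.seed(7)
  L <- matrix(rlnorm(5 * 6), 5, 6,
              dimnames = list(paste0("L", 1:5), paste0("s", 1:6)))
  x <- syntheticExperiment(L, 3, 3)
  L2 <- L; L2[, 2] <- L2[, 2] * 17; L2[, 5] <- L2[, 5] * 0.01
  x2 <- syntheticExperiment(L2, 3, 3)
  r <- speciesReactionFixture(c("L1", "L2"), c("L3", "L4"))
  expect_equal(gammaRel(x, r, "case"), gammaRel(x2, r, "case"))
  expect_equal(gammaRel(x, r, "control"), gammaRel(x2, r, "control"))
})

test_that("local search solves a path with one heavy node exactly", {
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  rn <- makeReactionNetworkFixture(A, rep("CR1", 3))
  sc <- stats::setNames(c(0, 10, 0), sprintf("R%02d", 1:3))
  cfg <- enrichmentConfig(minSize = 1L, maxSize = 1L, nRestarts = 3L)
  res <- localSearch(rn, sc, cfg, seed = 1)
  expect_equal(bestSubnetwork(res), "R02")
  expect_equal(max(objectives(res)), 10)
})

test_that("zero-temperature search is greedy and never falls below its
          seed", {
  for (seed in 1:10) {
    x <- largestComponentFixture(randomReactionNetworkFixture(10, 900 + seed))
    if (igraph::vcount(networkGraph(x$rn)) < 4) next
    cfg <- enrichmentConfig(t0 = 0, minSize = 3L, maxSize = 6L,
                            nRestarts = 1L)
    res <- localSearch(x$rn, x$scores, cfg, seed = seed, recordStates = TRUE)
    cc <- res@components[[1]]
    objOf <- function(nodes) oracleObjective(x$scores[nodes], x$cr[nodes])
    ## the returned subnetwork is at least as good as the recorded seed
    expect_gte(cc$objective, objOf(cc$states[[1]]) - 1e-12)
    ## greedy: the running objective never decreases
    if (length(cc$trajectory) > 1)
      expect_true(all(diff(cc$trajectory) >= -1e-12))
  }
})

test_that("the objective of every visited state equals the hand formula and
          states stay connected within size bounds", {
  x <- largestComponentFixture(randomReactionNetworkFixture(12, 314))
  cfg <- enrichmentConfig(minSize = 3L, maxSize = 8L, nRestarts = 2L)
  res <- localSearch(x$rn, x$scores, cfg, seed = 9, recordStates = TRUE)
  cc <- res@components[[1]]
  g <- networkGraph(x$rn)
  for (state in cc$states) {
    expect_gte(length(state), cfg@minSize)
    expect_lte(length(state), cfg@maxSize)
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, state)))
    expect_equal(subnetworkObjective(x$scores[state], x$cr[state]),
                 oracleObjective(x$scores[state], x$cr[state]))
  }
  expect_equal(cc$objective,
               max(vapply(cc$states, function(s)
                 oracleObjective(x$scores[s], x$cr[s]), 0)))
})

test_that("search recovers a planted heavy clique against brute force", {
  ## 6-node network: a 3-clique of heavy nodes in one class reaction plus a
  ## low-scoring tail
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[3, 4] <- A[4, 3] <- A[4, 5] <- A[5, 4] <- A[5, 6] <- A[6, 5] <- 1
  diag(A) <- 0
  cr <- c("CR1", "CR1", "CR1", "CR2", "CR2", "CR3")
  rn <- makeReactionNetworkFixture(A, cr)
  sc <- stats::setNames(c(5, 6, 7, 0.5, 0.2, 0.1), sprintf("R%02d", 1:6))
  crN <- stats::setNames(cr, names(sc))
  bb <- bruteForceBestSubnetwork(A, sc, crN, 2L, 4L)
  cfg <- enrichmentConfig(minSize = 2L, maxSize = 4L)
  hits <- 0L
  for (seed in 1:100) {
    res <- localSearch(rn, sc, cfg, seed = seed)
    if (abs(max(objectives(res)) - bb$objective) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  expect_true(all(bb$set %in% 1:3))   # optimum sits inside the heavy clique
})

test_that("components below the minimum size are skipped with a warning", {
  A <- matrix(0, 5, 5)
  A[1:3, 1:3] <- 1; A[4, 5] <- A[5, 4] <- 1; diag(A) <- 0
  rn <- makeReactionNetworkFixture(A, rep("CR1", 5))
  sc <- stats::setNames(rep(1, 5), sprintf("R%02d", 1:5))
  expect_warning(res <- localSearch(rn, sc, enrichmentConfig(minSize = 3L),
                                    seed = 1),
                 class = "componentTooSmallWarning")
  skipped <- vapply(res@components, function(cc) isTRUE(cc$skipped), TRUE)
  expect_equal(sum(skipped), 1L)
  expect_equal(length(res@components), 2L)
})

test_that("empirical p-values use the pseudocount and match exhaustive
          enumeration", {
  A <- matrix(1, 4, 4); diag(A) <- 0
  cr <- c("CR1", "CR1", "CR2", "CR2")
  rn <- makeReactionNetworkFixture(A, cr)
  sc <- stats::setNames(c(0.1, 0.4, 0.9, 1.4), sprintf("R%02d", 1:4))
  crN <- stats::setNames(cr, names(sc))
  cfg <- enrichmentConfig(minSize = 2L, maxSize = 2L,
                          nPvalueSamples = 10000L)

  ## observed larger than anything samplable -> p = 1/(n+1)
  p <- empiricalPvalue(rn, sc, observed = 99, config = cfg, seed = 5)
  expect_equal(as.numeric(p), 1 / 10001)
  ## observed of -Inf -> p = 1
  p <- empiricalPvalue(rn, sc, observed = -Inf, config = cfg, seed = 5)
  expect_equal(as.numeric(p), 1)

  ## against exact enumeration of all 6 unordered pairs
  pairs <- utils::combn(4, 2)
  exact <- apply(pairs, 2, function(ij)
    oracleObjective(sc[ij], crN[ij]))
  obs <- stats::median(exact)
  pHat <- as.numeric(empiricalPvalue(rn, sc, observed = obs, config = cfg,
                                     seed = 11))
  expect_equal(pHat, mean(exact >= obs), tolerance = 0.02)
})

test_that("the full enrichment wrapper returns scored, significant planted
          mechanisms", {
  sim <- simulateLipidome(simulationSpec(seed = 21L))
  res <- enrichNetwork(sim@experiment, sim@network,
                       enrichmentConfig(nPvalueSamples = 499L), seed = 22L)
  expect_s4_class(res, "EnrichmentResult")
  o <- objectives(res)
  best <- res@components[[which.max(o)]]
  expect_gte(length(best$subnetwork), 3L)
  expect_lte(length(best$subnetwork), 15L)
  expect_lte(best$pvalue, 0.05)
  ## heuristic reactions carry the fixed penalty score
  rn <- attr(res, "reactionNetwork")
  heur <- igraph::V(networkGraph(rn))$heuristic
  expect_true(all(nodeScores(res)[heur] == -1))
})
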