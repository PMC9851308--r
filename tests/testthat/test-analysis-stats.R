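ratioFixture <- function() {
  lipids <- c("LPC(16:0)", "LPC(18:1)", "PC(34:1)", "PC(34:2)", "PC(36:2)")
  set.seed(11)
  L <- matrix(rlnorm(5 * 8, meanlog = 3), 5, 8,
              dimnames = list(lipids, paste0("s", 1:8)))
  x <- lipidomicsExperiment(
    L, stats::setNames(rep(c("D", "C"), each = 4), colnames(L)))
  net <- buildSpeciesNetwork(lipids,
                             pool = fattyAcylPool(c("16:0", "16:1", "18:0",
                                                    "18:1", "18:2", "20:2")))
  list(x = x, net = net, L = L)
}

test_that("per-sample reaction ratios match the geometric-mean formula", {
  L <- rbind(S1 = c(2, 1), S2 = c(2, 4), P1 = c(4, 4), P2 = c(4, 4))
  colnames(L) <- c("a", "b")
  x <- syntheticExperiment(L, 1, 1)
  rxns <- list(speciesReactionFixture("S1", "P1"),
               speciesReactionFixture(c("S1", "S2"), "P1"))
  names(rxns) <- vapply(rxns, reactionId, "")
  fakeNet <- new("LipidNetwork", graph = igraph::make_empty_graph(),
                 reactions = rxns, species = list(), expansion = data.frame())
  tab <- reactionRatios(x, fakeNet)
  one <- function(r, s) tab$ratio[tab$reaction == r & tab$sample == s]
  expect_equal(one(names(rxns)[1], "a"), 2)            # 4 / 2
  expect_equal(one(names(rxns)[2], "b"), 2)            # 4 / gm(1,4)
  ## products identical to substrates -> unit ratio in every sample
  rEq <- speciesReactionFixture("S1", "S1x")
  xx <- syntheticExperiment(rbind(L, S1x = L["S1", ]), 1, 1)
  fakeNet2 <- new("LipidNetwork", graph = igraph::make_empty_graph(),
                  reactions = stats::setNames(list(rEq), reactionId(rEq)),
                  species = list(), expansion = data.frame())
  expect_true(all(reactionRatios(xx, fakeNet2)$ratio == 1))
})

test_that("group means of per-sample ratios recover gammaRel for every
          reaction", {
  f <- ratioFixture()
  tab <- reactionRatios(f$x, f$net)
  for (id in unique(tab$reaction)) {
    r <- speciesReactions(f$net)[[id]]
    for (grp in c("case", "control")) {
      lbl <- if (grp == "case") "D" else "C"
      m <- mean(tab$ratio[tab$reaction == id & tab$group == lbl])
      expect_equal(m, gammaRel(f$x, r, grp), tolerance = 1e-12)
    }
  }
})

test_that("node statistics: fold change, Welch test and BH adjustment", {
  L <- rbind(A = c(4, 4, 4, 2, 2, 2), B = c(3, 3.1, 2.9, 3, 3.1, 2.9))
  colnames(L) <- paste0("s", 1:6)
  x <- syntheticExperiment(L, 3, 3)
  tab <- nodeStatistics(x)
  expect_equal(tab$log2FC[tab$lipid == "A"], 1)       # mean ratio 2
  expect_equal(tab$log2FC[tab$lipid == "B"], 0, tolerance = 1e-12)
  expect_gt(tab$p[tab$lipid == "B"], 0.9)
  ## hand-checked BH adjustment
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.9), "BH"),
               c(0.03, 0.03, 0.9))
  ## too few samples: fold change only, with a warning
  x2 <- syntheticExperiment(L[, c(1, 4), drop = FALSE], 1, 1)
  expect_warning(tab2 <- nodeStatistics(x2),
                 class = "insufficientSamplesWarning")
  expect_true(all(is.na(tab2$p)))
  expect_equal(tab2$log2FC[tab2$lipid == "A"], 1)
})

test_that("moiety features are abundance-weighted occurrence counts", {
  L <- rbind("PC(16:0_18:1)" = c(10, 1))
  colnames(L) <- c("s1", "s2")
  x <- lipidomicsExperiment(L, c(s1 = "D", s2 = "C"))
  m <- moietyFeatures(x)
  M <- featureMatrix(m)
  expect_equal(M["s1", "headgroup:phosphocholine"], 10)
  expect_equal(M["s1", "acyl:18:1"], 10)
  expect_equal(M["s1", "sum_length:34"], 10)
  expect_equal(M["s1", "sum_db:1"], 10)

  ## additivity over lipids sharing a feature
  L2 <- rbind("PC(16:0_18:1)" = c(3, 1), "PC(34:1)" = c(7, 1))
  colnames(L2) <- c("s1", "s2")
  x2 <- lipidomicsExperiment(L2, c(s1 = "D", s2 = "C"))
  expect_equal(featureMatrix(moietyFeatures(x2))["s1",
                                                 "headgroup:phosphocholine"],
               10)
  ## sum species contribute no acyl features
  xSum <- lipidomicsExperiment(rbind("PC(34:1)" = c(s1 = 2, s2 = 3)),
                               c(s1 = "D", s2 = "C"))
  expect_false("acyl" %in% featureInfo(moietyFeatures(xSum))$kind)

  ## pair features multiply occurrences within a lipid (acyl multiplicity 2)
  L3 <- rbind("PC(16:0_16:0)" = c(5, 1))
  colnames(L3) <- c("s1", "s2")
  x3 <- lipidomicsExperiment(L3, c(s1 = "D", s2 = "C"))
  m3 <- moietyFeatures(x3, pairs = TRUE)
  expect_equal(featureMatrix(m3)["s1", "acyl:16:0&headgroup:phosphocholine"],
               10)
})

test_that("moiety features are linear in abundances and acyl occurrences sum
          to the chain count", {
  f <- ratioFixture()
  m1 <- featureMatrix(moietyFeatures(f$x))
  xScaled <- lipidomicsExperiment(abundances(f$x) * 3, sampleGroups(f$x))
  expect_equal(featureMatrix(moietyFeatures(xScaled)), m1 * 3)
  ## per-lipid acyl occurrences total the class chain count
  sp <- parseLipidName("TG(16:0_16:0_18:1)")
  occ <- lipidnet:::moietyOccurrences(sp, defaultClassRegistry())
  expect_equal(sum(occ$occurrence[occ$kind == "acyl"]), 3)
})

test_that("moiety discrimination ranks a constructed separator first with
          the right sign", {
  set.seed(99)
  n <- 20
  M <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:6)))
  grp <- rep(c("D", "C"), each = n / 2)
  M[, "f3"] <- ifelse(grp == "D", 1, -1) + rnorm(n, sd = 0.05)
  M <- cbind(M, f7 = 5)                       # constant feature
  m <- new("MoietyFeatures", matrix = M,
           info = data.frame(feature = colnames(M),
                             kind = "synthetic"))
  x <- syntheticExperiment(t(M) + 10, n / 2, n / 2)   # groups carrier only
  tab <- moietyDiscrimination(m, x)
  expect_equal(tab$feature[1], "f3")
  expect_gt(tab$coefficient[1], 0)
  expect_equal(tab$coefficient[tab$feature == "f7"], 0)
})

test_that("a null feature matrix shows no coefficient outside its own
          permutation distribution", {
  set.seed(123)
  n <- 24
  M <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:8)))
  m <- new("MoietyFeatures", matrix = M,
           info = data.frame(feature = colnames(M), kind = "synthetic"))
  groups <- rep(c("D", "C"), each = n / 2)
  x <- syntheticExperiment(t(M) + 100, n / 2, n / 2)
  obs <- max(abs(moietyDiscrimination(m, x)$coefficient))
  perms <- vapply(1:100, function(i) {
    g <- sample(groups)
    xp <- suppressWarnings(lipidomicsExperiment(
      t(M) + 100, stats::setNames(g, rownames(M)), case = "D",
      control = "C", parseNames = FALSE))
    max(abs(moietyDiscrimination(m, xp)$coefficient))
  }, 0)
  expect_lte(obs, stats::quantile(perms, 0.95))
})
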