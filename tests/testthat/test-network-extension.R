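toyNpos <- function(reg = defaultClassRegistry()) {
  tab <- reg@table
  stats::setNames(tab$n_positions, tab$abbreviation)
}

test_that("expandDataset maps molecular species to themselves and reports
          exclusions", {
  pool <- fattyAcylPool(c("14:0", "16:0", "16:1", "18:0", "18:1", "20:1"))
  ex <- expandDataset(c("PC(16:0_18:1)", "DG(34:1)", "PC(34:1)"),
                      pool = fattyAcylPool("16:0"))
  ## identity map for molecular species
  expect_equal(ex$candidates[["PC(16:0_18:1)"]], list(c("16:0", "18:1")))
  ## infeasible sum species flagged excluded
  expect_true(ex$report$excluded[ex$report$lipid == "PC(34:1)"])
  ## worked expansion: three candidates
  ex2 <- expandDataset("DG(34:1)", pool = pool)
  expect_equal(ex2$report$nCandidates, 3L)
  expect_false(ex2$report$excluded)
})

test_that("matching rules reproduce the worked species edges", {
  ## acyl transfer via a shared molecular candidate: LPI(18:1) - PI(38:5)
  net <- buildSpeciesNetwork(c("LPI(18:1)", "PI(38:5)"))
  rxns <- speciesReactions(net)
  expect_length(rxns, 1L)
  r <- rxns[[1]]
  expect_equal(r@classReaction, "FAAR_LPI_PI")
  expect_equal(substrates(r), "LPI(18:1)")
  expect_equal(products(r), "PI(38:5)")
  expect_equal(transferredAcyls(r), "20:4")
  expect_false(isHeuristic(r))

  ## desaturation heuristic: LPC(18:0) -> LPC(18:1)
  net <- buildSpeciesNetwork(c("LPC(18:0)", "LPC(18:1)"))
  ids <- names(speciesReactions(net))
  expect_true("FA:desaturation|LPC(18:0)>LPC(18:1)" %in% ids)
  expect_true(all(vapply(speciesReactions(net), isHeuristic, TRUE)))

  ## headgroup removal with identical acyl sets: PC(16:0_18:1) -> DG(16:0_18:1)
  net <- buildSpeciesNetwork(c("PC(16:0_18:1)", "DG(16:0_18:1)"))
  expect_true("HGAR_PC_DG|PC(16:0_18:1)>DG(16:0_18:1)" %in%
              names(speciesReactions(net)))

  ## differing acyl sets: no headgroup edge
  net <- suppressWarnings(
    buildSpeciesNetwork(c("PC(16:0_18:1)", "DG(16:0_16:0)")))
  expect_false(any(vapply(speciesReactions(net), function(r)
    r@classReaction == "HGAR_PC_DG", TRUE)))

  ## merging requires all participants measured, and matches acyl unions
  net <- buildSpeciesNetwork(c("PA(16:0_18:1)", "PG(18:0_18:1)",
                               "CL(16:0_18:0_18:1_18:1)"))
  ids <- names(speciesReactions(net))
  expect_true(any(grepl("^MERGE_PA_PG_CL", ids)))
  expect_warning(
    net2 <- buildSpeciesNetwork(c("PG(18:0_18:1)", "CL(16:0_18:0_18:1_18:1)"),
                                faRules = faReactionRules(FALSE, FALSE,
                                                          FALSE)),
    class = "emptyNetworkWarning")
  expect_length(speciesReactions(net2), 0L)

  ## ether conversion heuristic links ether and diacyl counterparts
  net <- buildSpeciesNetwork(c("PC(O-34:1)", "PC(34:1)"))
  expect_true("ether_conversion|PC(34:1)>PC(O-34:1)" %in%
              names(speciesReactions(net)))
  expect_warning(
    net <- buildSpeciesNetwork(c("PC(O-34:1)", "PC(34:1)"),
                               allowEtherHeuristic = FALSE),
    class = "emptyNetworkWarning")
  expect_false(any(grepl("ether", names(speciesReactions(net)))))
})

test_that("network edges match the brute-force all-pairs evaluator", {
  poolAc <- c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "20:1", "20:4")
  pool <- fattyAcylPool(poolAc)
  reg <- defaultClassRegistry()
  rxnTab <- utils::read.delim(system.file("extdata", "class_reactions.tsv",
                                          package = "lipidnet"),
                              comment.char = "#")
  lipids <- c("LPC(16:0)", "LPC(18:1)", "LPC(18:2)",
              "PC(34:1)", "PC(34:2)", "PC(16:0_18:1)", "PC(36:2)",
              "DG(34:1)", "DG(16:0_18:1)", "DG(36:5)",
              "PA(34:1)", "PA(36:2)", "PG(36:1)", "PG(34:1)",
              "CL(70:2)", "LPI(18:1)", "LPI(20:4)",
              "PI(38:5)", "PI(34:1)", "PE(34:1)")
  expect_length(lipids, 20L)
  net <- buildSpeciesNetwork(lipids, pool = pool, registry = reg,
                             allowEtherHeuristic = FALSE)
  want <- oracleNetworkEdges(lipids, rxnTab, poolAc, toyNpos(reg))
  expect_identical(packageNetworkIds(net), want)
})

test_that("adding a lipid never removes edges and ids are deterministic", {
  pool <- fattyAcylPool(c("16:0", "16:1", "18:0", "18:1", "18:2", "20:4"))
  base <- c("LPC(16:0)", "PC(34:1)", "PC(34:2)", "DG(34:1)", "LPI(18:1)",
            "PI(38:5)")
  net1 <- buildSpeciesNetwork(base, pool = pool)
  for (extra in c("PA(34:1)", "LPC(18:1)", "PC(36:4)")) {
    net2 <- buildSpeciesNetwork(c(base, extra), pool = pool)
    expect_true(all(packageNetworkIds(net1) %in% packageNetworkIds(net2)))
  }
  ## determinism: identical inputs yield identical reaction ids and edges
  net3 <- buildSpeciesNetwork(base, pool = pool)
  expect_identical(packageNetworkIds(net1), packageNetworkIds(net3))
  expect_identical(igraph::as_edgelist(networkGraph(net1)),
                   igraph::as_edgelist(networkGraph(net3)))
})

test_that("a dataset without any matching rule warns about an empty
          network", {
  expect_warning(
    buildSpeciesNetwork(c("PC(34:1)", "CE(18:1)"),
                        pool = fattyAcylPool(c("16:0", "18:1")),
                        faRules = faReactionRules(FALSE, FALSE, FALSE)),
    class = "emptyNetworkWarning")
})

test_that("banned acyl pairs suppress fatty-acid rule edges", {
  net <- suppressWarnings(
    buildSpeciesNetwork(c("LPC(18:0)", "LPC(18:1)"),
                        faRules = faReactionRules(bannedPairs = "18:0>18:1")))
  expect_false("FA:desaturation|LPC(18:0)>LPC(18:1)" %in%
               names(speciesReactions(net)))
})
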