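#' Specify a synthetic two-group lipidomics experiment
#'
#' The generator emulates a two-group lipidomics study with a planted
#' multispecific enzymatic dysregulation. Lipid species are drawn by
#' sampling acyl multisets per class: single-position (lyso) classes draw
#' from the sn-1-like pool of saturated/monounsaturated chains, while
#' two-position classes pair an sn-1-like chain with an sn-2-like chain
#' drawn from a pool that includes long polyunsaturated acyls, mirroring
#' the acyl asymmetry of glycerophospholipids; multi-chain species are
#' emitted at sum level. Abundances are i.i.d. log-normal per lipid with a
#' lipid-specific log-mean. In the case group, products of every network
#' edge of the planted class reaction whose transferred acyl satisfies the
#' preference predicate (at least `preferenceMinCarbons` carbons and
#' `preferenceMinDoubleBonds` double bonds -- the arachidonoyl-preference
#' scenario of an MBOAT7-like acyl transferase) are multiplied by the
#' effect multiplier (or the substrates divided, with
#' `direction = "substrate_decrease"`).
#'
#' @param classes lipid classes to simulate.
#' @param nLipidsPerClass named integer vector of species counts per class.
#' @param nSamplesPerGroup samples per group (case `"D"`, control `"C"`).
#' @param logMeanRange per-lipid log-mean drawn uniformly from this range.
#' @param logSd log-scale standard deviation of the abundances.
#' @param sn1Pool,sn2Pool acyl pools described above.
#' @param plantedReaction class-reaction id (of [defaultClassReactions()])
#'   carrying the planted dysregulation.
#' @param effectMultiplier multiplicative effect size (1 = null model).
#' @param preferenceMinCarbons,preferenceMinDoubleBonds acyl preference
#'   thresholds of the planted enzyme.
#' @param direction `"product_increase"` or `"substrate_decrease"`.
#' @param seed integer seed making the dataset reproducible.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(classes = c("LPI", "PI", "LPC", "PC"),
                           nLipidsPerClass = c(LPI = 8L, PI = 22L,
                                               LPC = 8L, PC = 22L),
                           nSamplesPerGroup = 15L,
                           logMeanRange = c(3, 6), logSd = 0.25,
                           sn1Pool = c("14:0", "16:0", "16:1", "18:0",
                                       "18:1", "18:2", "20:1", "22:0"),
                           sn2Pool = c("16:0", "18:1", "18:2", "20:4",
                                       "20:5", "22:4", "22:5", "22:6"),
                           plantedReaction = "FAAR_LPI_PI",
                           effectMultiplier = 8,
                           preferenceMinCarbons = 20L,
                           preferenceMinDoubleBonds = 4L,
                           direction = "product_increase",
                           seed = 1L) {
  new("SimulationSpec", classes = classes,
      nLipidsPerClass = stats::setNames(as.integer(nLipidsPerClass),
                                        names(nLipidsPerClass)),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      logMeanRange = logMeanRange, logSd = logSd,
      sn1Pool = sn1Pool, sn2Pool = sn2Pool,
      plantedReaction = plantedReaction,
      effectMultiplier = effectMultiplier,
      preferenceMinCarbons = as.integer(preferenceMinCarbons),
      preferenceMinDoubleBonds = as.integer(preferenceMinDoubleBonds),
      direction = direction, seed = as.integer(seed))
}

#' Whether acyls satisfy an acyl-preference predicate
#'
#' @param acyls character vector of acyl strings.
#' @param minCarbons,minDoubleBonds thresholds.
#' @return logical vector.
#' @export
acylPreference <- function(acyls, minCarbons = 20L, minDoubleBonds = 4L) {
  if (!length(acyls)) return(logical(0))
  p <- parseAcyls(acyls)
  p$carbons >= minCarbons & p$doubleBonds >= minDoubleBonds
}

#' Generate a synthetic two-group lipidomics dataset
#'
#' See [simulationSpec()] for the generative model. The species network is
#' built on the generated lipidome with the bundled class reactions and
#' default acyl pool, so the returned ground-truth species reactions are by
#' construction edges of that network.
#'
#' @param spec a [SimulationSpec-class].
#' @param reactions,registry knowledge base used to build the network.
#' @param pool [FattyAcylPool-class] for sum-species expansion; by default
#'   the union of the spec's sn-1/sn-2 pools, i.e. exactly the acyls the
#'   simulated lipidome can contain (an expansion pool wider than the
#'   generating pools would propose molecular candidates that cannot occur
#'   in the simulated experiment).
#' @return a [SimulatedDataset-class].
#' @export
simulateLipidome <- function(spec = simulationSpec(),
                     reactions = defaultClassReactions(),
                     registry = defaultClassRegistry(),
                     pool = NULL) {
  stopifnot(is(spec, "SimulationSpec"))
  if (is.null(pool))
    pool <- fattyAcylPool(unique(c(spec@sn1Pool, spec@sn2Pool)))
  set.seed(spec@seed)
  lipids <- character(0)
  for (cls in spec@classes) {
    nWant <- spec@nLipidsPerClass[[cls]]
    nPos <- nAcylPositions(registry, cls)
    got <- character(0)
    tries <- 0L
    while (length(got) < nWant && tries < 1000L) {
      tries <- tries + 1L
      nm <- if (nPos == 1L) {
        paste0(cls, "(", sample(spec@sn1Pool, 1L), ")")
      } else {
        ac <- c(sample(spec@sn1Pool, 1L),
                sample(spec@sn2Pool, nPos - 1L, replace = TRUE))
        p <- parseAcyls(ac)
        paste0(cls, "(",
               formatAcyls(sum(p$carbons), sum(p$doubleBonds),
                           sum(p$hydroxyls)), ")")
      }
      if (!nm %in% got) got <- c(got, nm)
    }
    if (length(got) < nWant)
      stop(specError(sprintf(
        "cannot draw %d distinct %s species from the acyl pools",
        nWant, cls)))
    lipids <- c(lipids, got)
  }

  n <- spec@nSamplesPerGroup
  samples <- c(paste0("D", seq_len(n)), paste0("C", seq_len(n)))
  groups <- stats::setNames(rep(c("D", "C"), each = n), samples)
  mu <- stats::runif(length(lipids), spec@logMeanRange[1],
                     spec@logMeanRange[2])
  L <- matrix(stats::rlnorm(length(lipids) * 2L * n,
                            meanlog = rep(mu, times = 2L * n),
                            sdlog = spec@logSd),
              nrow = length(lipids), dimnames = list(lipids, samples))

  net <- buildSpeciesNetwork(lipids, reactions = reactions, pool = pool,
                             registry = registry)
  rxns <- speciesReactions(net)
  planted <- rxns[vapply(rxns, function(r)
    r@classReaction == spec@plantedReaction, TRUE)]
  if (!length(planted))
    stop(specError(sprintf(
      "planted class reaction %s yields no species reaction on this lipidome",
      spec@plantedReaction)))
  qualifying <- planted[vapply(planted, function(r)
    any(acylPreference(r@transferredAcyls, spec@preferenceMinCarbons,
                       spec@preferenceMinDoubleBonds)), TRUE)]
  if (!length(qualifying))
    stop(specError(
      "no planted species reaction satisfies the acyl preference"))

  if (spec@effectMultiplier != 1) {
    if (spec@direction == "product_increase") {
      hit <- unique(unlist(lapply(qualifying, products)))
      L[hit, groups == "D"] <- L[hit, groups == "D"] * spec@effectMultiplier
    } else {
      hit <- unique(unlist(lapply(qualifying, substrates)))
      L[hit, groups == "D"] <- L[hit, groups == "D"] / spec@effectMultiplier
    }
  } else {
    hit <- character(0)
  }

  exp <- lipidomicsExperiment(L, groups, case = "D", control = "C",
                              registry = registry)
  truth <- list(plantedReaction = spec@plantedReaction,
                qualifyingReactions = names(qualifying),
                plantedSpeciesReactions = names(planted),
                affectedLipids = hit)
  new("SimulatedDataset", experiment = exp, network = net, truth = truth,
      spec = spec)
}
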