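#' Per-sample reaction ratios
#'
#' For every species reaction and every sample, the ratio of the geometric
#' mean of the product abundances over the geometric mean of the substrate
#' abundances -- the per-sample analogue of the relative substrate-product
#' change, without averaging over individuals. Averaging the ratios over a
#' group's samples recovers [gammaRel()] of that group.
#'
#' @param x a [LipidomicsExperiment-class] with positive abundances.
#' @param net a [LipidNetwork-class] (or [ReactionNetwork-class]).
#' @return data.frame with columns `classReaction`, `reaction`, `sample`,
#'   `group`, `ratio`.
#' @export
reactionRatios <- function(x, net) {
  L <- abundances(x)
  if (any(!is.finite(L)) || any(L <= 0))
    stop(nonPositiveAbundanceError(
      "reaction ratios require positive abundances"))
  grp <- sampleGroups(x)
  rxns <- speciesReactions(net)
  rxns <- rxns[vapply(rxns, function(r)
    all(c(r@substrates, r@products) %in% rownames(L)), TRUE)]
  logL <- log(L)
  out <- lapply(rxns, function(r) {
    ratio <- exp(colMeans(logL[r@products, , drop = FALSE]) -
                 colMeans(logL[r@substrates, , drop = FALSE]))
    data.frame(classReaction = r@classReaction, reaction = r@id,
               sample = colnames(L), group = unname(grp[colnames(L)]),
               ratio = unname(ratio), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(classReaction = character(0), reaction = character(0),
                      sample = character(0), group = character(0),
                      ratio = numeric(0))
  res
}

#' Per-lipid group statistics
#'
#' Log2 fold change (case over control, on group means), Welch two-sample
#' t-test on log2 abundances and Benjamini-Hochberg adjusted q-values.
#' With fewer than two samples in a group only fold changes are computed
#' (with an `insufficientSamplesWarning`).
#'
#' @param x a [LipidomicsExperiment-class].
#' @return data.frame with columns `lipid`, `meanCase`, `meanControl`,
#'   `log2FC`, `p`, `q`.
#' @export
nodeStatistics <- function(x) {
  L <- abundances(x)
  cs <- caseSamples(x); ct <- controlSamples(x)
  meanCase <- rowMeans(L[, cs, drop = FALSE])
  meanControl <- rowMeans(L[, ct, drop = FALSE])
  log2FC <- log2(meanCase / meanControl)
  if (length(cs) < 2L || length(ct) < 2L) {
    warning(lipidnetWarning(
      "need >= 2 samples per group for tests; returning fold changes only",
      "insufficientSamplesWarning"))
    p <- rep(NA_real_, nrow(L))
  } else {
    lg <- if (all(L > 0)) log2(L) else L
    p <- vapply(seq_len(nrow(L)), function(i) {
      a <- lg[i, cs]; b <- lg[i, ct]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      stats::t.test(a, b)$p.value
    }, 0)
  }
  data.frame(lipid = rownames(L), meanCase = unname(meanCase),
             meanControl = unname(meanControl), log2FC = unname(log2FC),
             p = p, q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Substructure occurrences of one lipid species. Sum species contribute
## only headgroup / backbone / sum features; molecular species additionally
## contribute one occurrence per acyl chain.
moietyOccurrences <- function(sp, registry) {
  row <- registryRow(registry, sp@lipidClass)
  feats <- c(paste0("headgroup:", row$headgroup),
             paste0("backbone:", row$backbone),
             paste0("sum_length:", sp@sumC),
             paste0("sum_db:", sp@sumDB),
             paste0("sum_oh:", sp@sumOH))
  occ <- rep(1, 5)
  kinds <- c("headgroup", "backbone", "sum_length", "sum_db", "sum_oh")
  if (sp@level == "molecular") {
    tabAc <- table(sp@acyls)
    feats <- c(feats, paste0("acyl:", names(tabAc)))
    occ <- c(occ, as.numeric(tabAc))
    kinds <- c(kinds, rep("acyl", length(tabAc)))
  }
  data.frame(feature = feats, kind = kinds, occurrence = occ,
             stringsAsFactors = FALSE)
}

#' Lipid moiety (substructure) features
#'
#' Decomposes the lipidome into abundance-weighted substructure features:
#' headgroup, backbone, individual fatty acyls, sum chain length, sum double
#' bonds and sum hydroxylations. The value of feature f in sample s is the
#' sum over lipids of abundance(lipid, s) x occurrence(f in lipid); acyl
#' occurrences count chain multiplicity. With `pairs`, combination features
#' are added whose occurrence is the product of the two single occurrences
#' within the same lipid.
#'
#' @param x a [LipidomicsExperiment-class] whose row names parse as lipid
#'   species (acyl features require molecular-level species).
#' @param registry a [ClassRegistry-class].
#' @param pairs `FALSE` (default) for single features only, `TRUE` for all
#'   cross-kind pairs, or a two-column matrix/data.frame of feature labels.
#' @return a [MoietyFeatures-class] (samples x features).
#' @export
moietyFeatures <- function(x, registry = defaultClassRegistry(),
                           pairs = FALSE) {
  L <- abundances(x)
  parsed <- parseLipidNames(rownames(L), registry)
  if (length(parsed$failed))
    stop(malformedNameError(paste(
      "unparseable lipid name(s):",
      paste(utils::head(parsed$failed, 5), collapse = ", "))))
  occTabs <- lapply(parsed$species, moietyOccurrences, registry = registry)
  features <- sort(unique(unlist(lapply(occTabs, `[[`, "feature"))))
  W <- matrix(0, nrow = length(features), ncol = nrow(L),
              dimnames = list(features, rownames(L)))
  for (nm in names(occTabs)) {
    tb <- occTabs[[nm]]
    W[tb$feature, nm] <- tb$occurrence
  }
  kindOf <- unlist(lapply(occTabs, function(tb)
    stats::setNames(tb$kind, tb$feature)))
  kindOf <- kindOf[!duplicated(names(kindOf))]
  info <- data.frame(feature = features, kind = unname(kindOf[features]),
                     stringsAsFactors = FALSE)

  pairList <- NULL
  if (isTRUE(pairs)) {
    pairList <- do.call(rbind, lapply(occTabs, function(tb) {
      if (nrow(tb) < 2L) return(NULL)
      cmb <- utils::combn(order(tb$feature), 2L)
      keep <- tb$kind[cmb[1, ]] != tb$kind[cmb[2, ]]
      cbind(tb$feature[cmb[1, keep]], tb$feature[cmb[2, keep]])
    }))
    pairList <- unique(pairList)
  } else if (!isFALSE(pairs)) {
    pairList <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  if (!is.null(pairList) && nrow(pairList)) {
    pw <- W[pairList[, 1], , drop = FALSE] * W[pairList[, 2], , drop = FALSE]
    rownames(pw) <- paste0(pairList[, 1], "&", pairList[, 2])
    keep <- !duplicated(rownames(pw))
    W <- rbind(W, pw[keep, , drop = FALSE])
    info <- rbind(info, data.frame(feature = rownames(pw)[keep],
                                   kind = "pair", stringsAsFactors = FALSE))
  }
  M <- t(W %*% L)                               # samples x features
  new("MoietyFeatures", matrix = M, info = info)
}

#' Group-discriminating moiety features
#'
#' Standardises the moiety feature matrix and fits an L2-regularised
#' (ridge) logistic regression of group membership on the features; the
#' coefficients, ranked by absolute value, order the substructures by how
#' strongly they discriminate the two groups. Constant features get a
#' coefficient of exactly 0.
#'
#' @param m a [MoietyFeatures-class].
#' @param x the [LipidomicsExperiment-class] providing the sample groups.
#' @param lambda ridge penalty (small fixed default).
#' @return data.frame with columns `feature`, `kind`, `coefficient`,
#'   ordered by decreasing `|coefficient|`.
#' @export
moietyDiscrimination <- function(m, x, lambda = 0.01) {
  M <- featureMatrix(m)
  grp <- sampleGroups(x)[rownames(M)]
  if (anyNA(grp)) stop(schemaError("feature matrix samples not in groups"))
  y <- as.integer(grp == S4Vectors::metadata(x)$caseLabel)
  sds <- apply(M, 2L, stats::sd)
  keep <- sds > 0
  Z <- scale(M[, keep, drop = FALSE])
  coefs <- stats::setNames(rep(0, ncol(M)), colnames(M))
  if (any(keep)) {
    fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    beta <- as.numeric(fit$beta[, 1L])
    coefs[colnames(Z)] <- beta
  }
  info <- featureInfo(m)
  out <- data.frame(feature = names(coefs),
                    kind = info$kind[match(names(coefs), info$feature)],
                    coefficient = unname(coefs), stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient)), , drop = FALSE]
}
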