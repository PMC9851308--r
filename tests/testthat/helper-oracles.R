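## Independent oracles and fixture builders. Everything here is written
## deliberately as plain brute force, separate from the package's code
## paths, so tests compare two independent routes to the same quantity.

## --- tiny independent lipid-name helpers -----------------------------------

oracleSplitName <- function(name) {
  cls <- sub("\\(.*$", "", name)
  comp <- sub("^[^(]*\\(", "", sub("\\)$", "", name))
  list(class = cls, comp = comp)
}

oracleAcyl <- function(a) {
  parts <- strsplit(sub("^[OP]-", "", a), "[:;]")[[1]]
  c(as.integer(parts[1]), as.integer(parts[2]),
    if (length(parts) > 2) as.integer(parts[3]) else 0L)
}

## all acyl multisets (sorted character vectors) from `pool` of size k whose
## componentwise sums equal target; plain expand.grid enumeration
oracleExpansions <- function(k, pool, target) {
  grids <- do.call(expand.grid,
                   c(rep(list(seq_along(pool)), k), KEEP.OUT.ATTRS = FALSE))
  comp <- t(vapply(pool, oracleAcyl, integer(3)))
  out <- list()
  for (i in seq_len(nrow(grids))) {
    idx <- as.integer(grids[i, ])
    if (all(colSums(comp[idx, , drop = FALSE]) == target)) {
      key <- paste(sort(pool[idx]), collapse = "|")
      out[[key]] <- sort(pool[idx])
    }
  }
  unname(out)
}

## candidate acyl multisets of a measured lipid, by brute force
oracleCandidates <- function(name, pool, npos) {
  sp <- oracleSplitName(name)
  k <- npos[[sp$class]]
  if (grepl("_", sp$comp, fixed = TRUE)) {
    return(list(sort(strsplit(sp$comp, "_", fixed = TRUE)[[1]])))
  }
  oracleExpansions(k, pool, oracleAcyl(sp$comp))
}

## all-pairs / all-reactions rule evaluator over measured lipids; returns a
## sorted character vector of "crId|substrate(s)>product(s)" labels with
## participant names sorted, directly comparable to package reaction ids
oracleNetworkEdges <- function(lipids, reactionTable, pool, npos,
                               faDeltas = list(elongation = c(2L, 0L, 0L),
                                               desaturation = c(0L, 1L, 0L),
                                               hydroxylation = c(0L, 0L, 1L))) {
  cls <- vapply(lipids, function(l) oracleSplitName(l)$class, "")
  cand <- lapply(lipids, oracleCandidates, pool = pool, npos = npos)
  names(cand) <- lipids
  keyset <- lapply(cand, function(cs)
    vapply(cs, paste, "", collapse = "|"))
  ids <- character(0)
  addId <- function(cr, subs, prods)
    ids <<- c(ids, paste0(cr, "|", paste(sort(subs), collapse = "+"), ">",
                          paste(sort(prods), collapse = "+")))
  for (ri in seq_len(nrow(reactionTable))) {
    cr <- reactionTable$reaction_id[ri]
    catg <- reactionTable$category[ri]
    subsCls <- strsplit(reactionTable$substrates[ri], "+", fixed = TRUE)[[1]]
    prodCls <- reactionTable$products[ri]
    if (catg %in% c("headgroup_modification", "headgroup_addition_removal")) {
      for (x in lipids[cls == subsCls]) for (y in lipids[cls == prodCls])
        if (length(intersect(keyset[[x]], keyset[[y]]))) addId(cr, x, y)
    } else if (catg == "fa_addition_removal") {
      swap <- npos[[subsCls]] > npos[[prodCls]]
      for (x in lipids[cls == subsCls]) for (y in lipids[cls == prodCls]) {
        small <- if (swap) y else x; large <- if (swap) x else y
        hit <- FALSE
        for (lc in cand[[large]]) for (sc in cand[[small]]) {
          for (j in seq_along(lc)) {
            if (identical(sort(lc[-j]), sc)) hit <- TRUE
          }
        }
        if (hit) addId(cr, x, y)
      }
    } else if (catg == "lipid_merging") {
      for (x in lipids[cls == subsCls[1]]) for (y in lipids[cls == subsCls[2]]) {
        if (x == y) next
        for (z in lipids[cls == prodCls]) {
          hit <- FALSE
          for (ca in cand[[x]]) for (cb in cand[[y]]) for (cz in cand[[z]])
            if (identical(sort(c(ca, cb)), cz)) hit <- TRUE
          if (hit) addId(cr, c(x, y), z)
        }
      }
    }
  }
  for (rule in names(faDeltas)) {
    d <- faDeltas[[rule]]
    for (x in lipids) for (y in lipids[cls == cls[match(x, lipids)]]) {
      if (x == y) next
      hit <- FALSE
      for (cx in cand[[x]]) for (cy in cand[[y]]) {
        for (j in seq_along(cx)) {
          shifted <- cx
          a <- oracleAcyl(cx[j]) + d
          if (a[2] > a[1]) next
          shifted[j] <- paste0(a[1], ":", a[2],
                               if (a[3] > 0) paste0(";", a[3]) else "")
          if (identical(sort(shifted), cy)) hit <- TRUE
        }
      }
      if (hit) addId(paste0("FA:", rule), x, y)
    }
  }
  sort(unique(ids))
}

## package network edges in the same label space
packageNetworkIds <- function(net) sort(names(speciesReactions(net)))

## --- scoring oracles (plain loops) ------------------------------------------

oracleGammaAbs <- function(L, subs, prods, samples) {
  tot <- 0
  for (s in samples) {
    pm <- 0; for (p in prods) pm <- pm + L[p, s]
    sm <- 0; for (q in subs) sm <- sm + L[q, s]
    tot <- tot + pm / length(prods) - sm / length(subs)
  }
  tot / length(samples)
}

oracleGammaRel <- function(L, subs, prods, samples) {
  tot <- 0
  for (s in samples) {
    pm <- 1; for (p in prods) pm <- pm * L[p, s]
    sm <- 1; for (q in subs) sm <- sm * L[q, s]
    tot <- tot + pm^(1 / length(prods)) / sm^(1 / length(subs))
  }
  tot / length(samples)
}

oracleScore <- function(gD, gC) abs(gD - gC) / abs(gC)

oracleObjective <- function(scores, crIds, p = 1)
  sum(scores) / (length(scores) * p * length(unique(crIds)))

oracleRatio <- function(L, subs, prods, sample) {
  pm <- 1; for (p in prods) pm <- pm * L[p, sample]
  sm <- 1; for (q in subs) sm <- sm * L[q, sample]
  pm^(1 / length(prods)) / sm^(1 / length(subs))
}

## --- reaction-network fixtures ----------------------------------------------

makeReactionNetworkFixture <- function(adjacency, classReactions,
                                       heuristic = NULL) {
  n <- nrow(adjacency)
  if (is.null(heuristic)) heuristic <- rep(FALSE, n)
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0,
                                           mode = "undirected")
  igraph::V(g)$name <- sprintf("R%02d", seq_len(n))
  igraph::V(g)$classReaction <- classReactions
  igraph::V(g)$heuristic <- heuristic
  reactionNetwork(g)
}

randomReactionNetworkFixture <- function(n, seed, nCr = 4L, pHeur = 0.2,
                                         pExtra = 0.2) {
  set.seed(seed)
  cr <- sample(paste0("CR", seq_len(nCr)), n, replace = TRUE)
  heur <- stats::runif(n) < pHeur
  sc <- ifelse(heur, -1, round(abs(stats::rnorm(n, 1, 1)), 3))
  A <- matrix(FALSE, n, n)
  for (k in unique(cr)) { idx <- which(cr == k); A[idx, idx] <- TRUE }
  extra <- matrix(stats::runif(n * n) < pExtra, n, n)
  A <- A | extra | t(extra)
  diag(A) <- FALSE
  rn <- makeReactionNetworkFixture(A, cr, heur)
  nm <- igraph::V(networkGraph(rn))$name
  list(rn = rn, A = A, scores = stats::setNames(sc, nm),
       cr = stats::setNames(cr, nm))
}

## exhaustive optimum over connected subsets with size in [minS, maxS]
bruteForceBestSubnetwork <- function(A, scores, cr, minS, maxS, penalty = 1) {
  n <- nrow(A)
  connected <- function(keep) {
    k <- length(keep)
    if (k < 2L) return(TRUE)
    sub <- A[keep, keep, drop = FALSE]
    seen <- logical(k); seen[1] <- TRUE; fr <- 1L
    while (length(fr)) {
      nx <- which(colSums(sub[fr, , drop = FALSE]) > 0 & !seen)
      seen[nx] <- TRUE; fr <- nx
    }
    all(seen)
  }
  best <- -Inf; bestSet <- integer(0)
  for (s in minS:min(maxS, n)) {
    for (cmb in asplit(utils::combn(n, s), 2)) {
      cmb <- as.integer(cmb)
      if (!connected(cmb)) next
      o <- oracleObjective(scores[cmb], cr[cmb], penalty)
      if (o > best) { best <- o; bestSet <- cmb }
    }
  }
  list(objective = best, set = bestSet)
}

## restrict a fixture to its largest connected component
largestComponentFixture <- function(x) {
  g <- networkGraph(x$rn)
  comp <- igraph::components(g)
  keep <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
  pos <- match(keep, igraph::V(g)$name)
  g2 <- igraph::induced_subgraph(g, keep)
  list(rn = reactionNetwork(g2), A = x$A[pos, pos, drop = FALSE],
       scores = x$scores[keep], cr = x$cr[keep])
}

## small two-group experiment with arbitrary (non-lipid) row names
syntheticExperiment <- function(L, nCase, nControl) {
  groups <- stats::setNames(rep(c("D", "C"), c(nCase, nControl)),
                            colnames(L))
  lipidomicsExperiment(L, groups, case = "D", control = "C",
                       parseNames = FALSE)
}

speciesReactionFixture <- function(subs, prods, cr = "CRX",
                                   heuristic = FALSE) {
  new("SpeciesReaction",
      id = paste0(cr, "|", paste(sort(subs), collapse = "+"), ">",
                  paste(sort(prods), collapse = "+")),
      classReaction = cr, category = "fa_addition_removal",
      substrates = sort(subs), products = sort(prods),
      transferredAcyls = character(0), heuristic = heuristic)
}
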