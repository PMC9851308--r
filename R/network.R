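#' Expand a measured lipidome to molecular candidates
#'
#' Molecular species map to themselves; sum species are expanded through
#' [enumerateMolecularSpecies()] against the class acyl pool. Sum species
#' with no valid expansion are flagged `excluded`: they stay in the dataset
#' (and in the network as nodes) but cannot support class-reaction edges.
#'
#' @param lipids character vector of lipid names, or a list of
#'   [LipidSpecies-class].
#' @param pool a [FattyAcylPool-class].
#' @param registry a [ClassRegistry-class].
#' @return list with `candidates` (per lipid, a list of acyl-multiset
#'   character vectors), `keys` (per lipid, the canonical multiset keys) and
#'   `report` (data.frame: `lipid`, `lipidClass`, `level`, `nCandidates`,
#'   `excluded`).
#' @examples
#' pool <- fattyAcylPool(c("14:0", "16:0", "16:1", "18:0", "18:1", "20:1"))
#' expandDataset("DG(34:1)", pool)$report
#' @export
expandDataset <- function(lipids, pool = defaultAcylPool(),
                          registry = defaultClassRegistry()) {
  species <- asSpeciesList(lipids, registry)
  candidates <- vector("list", length(species))
  names(candidates) <- names(species)
  for (nm in names(species)) {
    sp <- species[[nm]]
    candidates[[nm]] <- if (sp@level == "molecular") {
      list(sp@acyls)
    } else {
      lapply(enumerateMolecularSpecies(sp, pool, registry), acylChains)
    }
  }
  keys <- lapply(candidates, function(sets)
    vapply(sets, function(s) paste(s, collapse = "_"), ""))
  nCand <- vapply(candidates, length, 1L)
  report <- data.frame(
    lipid = names(species),
    lipidClass = vapply(species, lipidClass, ""),
    level = vapply(species, speciesLevel, ""),
    nCandidates = nCand,
    excluded = nCand == 0L,
    stringsAsFactors = FALSE, row.names = NULL)
  list(candidates = candidates, keys = keys, report = report,
       species = species)
}

asSpeciesList <- function(lipids, registry) {
  if (is.character(lipids))
    lipids <- lapply(lipids, parseLipidName, registry = registry)
  if (is(lipids, "LipidSpecies")) lipids <- list(lipids)
  nm <- vapply(lipids, speciesName, "")
  lipids <- lipids[!duplicated(nm)]
  names(lipids) <- nm[!duplicated(nm)]
  lipids
}

#' Build the dataset-specific lipid species network
#'
#' Extends curated class reactions and heuristic fatty-acid rules to the
#' measured lipidome. Rules are evaluated on molecular candidates (sum
#' species via their pool expansion) and mapped back onto the measured
#' nodes; a pair of measured species is connected iff at least one candidate
#' pair supports the rule:
#'
#' * headgroup modification / addition-removal: identical acyl multisets;
#' * fatty-acid addition/removal: the smaller species' multiset is contained
#'   in the larger's, the single-acyl difference is the transferred acyl;
#' * lipid merging: the two substrates' multisets union to the product's
#'   (all participants must be measured);
#' * fatty-acid rule heuristic: same class, multisets differ by one rule
#'   application (elongation +2C, desaturation +1DB, hydroxylation +1OH) on
#'   exactly one chain;
#' * ether conversion heuristic (optional): same class and sum composition,
#'   different ether bond.
#'
#' @param lipids lipid names or [LipidSpecies-class] list (>= 2 lipids).
#' @param reactions list of [ClassReaction-class]
#'   (default [defaultClassReactions()]).
#' @param faRules data.frame from [faReactionRules()]; pass a zero-row frame
#'   to disable fatty-acid heuristics.
#' @param pool a [FattyAcylPool-class].
#' @param registry a [ClassRegistry-class].
#' @param allowEtherHeuristic include ether-conversion edges.
#' @return a [LipidNetwork-class]. Emits an `emptyNetworkWarning` when no
#'   edge can be generated.
#' @examples
#' net <- buildSpeciesNetwork(c("LPC(18:0)", "LPC(18:1)", "PC(34:1)"),
#'                            pool = defaultAcylPool())
#' net
#' @export
buildSpeciesNetwork <- function(lipids, reactions = defaultClassReactions(),
                                faRules = faReactionRules(),
                                pool = defaultAcylPool(),
                                registry = defaultClassRegistry(),
                                allowEtherHeuristic = TRUE) {
  ex <- expandDataset(lipids, pool, registry)
  species <- ex$species
  if (length(species) < 2L)
    stop(schemaError("need at least 2 distinct lipid species"))
  keys <- ex$keys
  candidates <- ex$candidates
  byClass <- split(names(species), vapply(species, lipidClass, ""))
  byClass <- lapply(byClass, sort)

  reg <- new.env(parent = emptyenv())
  reg$reactions <- list()
  addReaction <- function(crId, category, subs, prods, transferred,
                          heuristic) {
    subs <- sort(subs); prods <- sort(prods)
    id <- paste0(crId, "|", paste(subs, collapse = "+"), ">",
                 paste(prods, collapse = "+"))
    cur <- reg$reactions[[id]]
    if (is.null(cur)) {
      reg$reactions[[id]] <- new("SpeciesReaction", id = id,
                                 classReaction = crId, category = category,
                                 substrates = subs, products = prods,
                                 transferredAcyls = sortAcyls(unique(transferred)),
                                 heuristic = heuristic)
    } else if (length(transferred)) {
      cur@transferredAcyls <- sortAcyls(unique(c(cur@transferredAcyls,
                                                 transferred)))
      reg$reactions[[id]] <- cur
    }
    id
  }

  ## per-lipid removal tables for fatty-acid addition/removal: every way of
  ## taking one chain out of a candidate multiset
  removalTable <- function(nm) {
    sets <- candidates[[nm]]
    out <- list(key = character(0), acyl = character(0))
    for (s in sets) {
      for (j in seq_along(s)) {
        if (j > 1L && s[j] == s[j - 1L]) next   # duplicate chain, same removal
        out$key <- c(out$key, paste(s[-j], collapse = "_"))
        out$acyl <- c(out$acyl, s[j])
      }
    }
    out
  }

  for (cr in reactions) {
    cat <- cr@category
    if (cat %in% c("headgroup_modification", "headgroup_addition_removal")) {
      xs <- byClass[[cr@substrateClasses]]; ys <- byClass[[cr@productClasses]]
      for (x in xs) for (y in ys) {
        if (x == y) next
        if (length(intersect(keys[[x]], keys[[y]])))
          addReaction(cr@reactionId, cat, x, y, character(0), FALSE)
      }
    } else if (cat == "fa_addition_removal") {
      nsub <- nAcylPositions(registry, cr@substrateClasses)
      nprod <- nAcylPositions(registry, cr@productClasses)
      if (abs(nsub - nprod) != 1L) {
        warning(lipidnetWarning(sprintf(
          "reaction %s: class positions differ by %d, expected 1; skipped",
          cr@reactionId, abs(nsub - nprod)), "reactionSkippedWarning"))
        next
      }
      xs <- byClass[[cr@substrateClasses]]; ys <- byClass[[cr@productClasses]]
      largerIsProduct <- nprod > nsub
      for (x in xs) for (y in ys) {
        small <- if (largerIsProduct) x else y
        large <- if (largerIsProduct) y else x
        rem <- removalTable(large)
        hit <- rem$key %in% keys[[small]]
        if (any(hit))
          addReaction(cr@reactionId, cat, x, y, rem$acyl[hit], FALSE)
      }
    } else if (cat == "lipid_merging") {
      c1 <- cr@substrateClasses[1]; c2 <- cr@substrateClasses[2]
      xs <- byClass[[c1]]; ys <- byClass[[c2]]
      zs <- byClass[[cr@productClasses]]
      for (x in xs) for (y in ys) {
        if (x == y) next
        if (c1 == c2 && x > y) next             # unordered pair, once
        unions <- character(0)
        for (sa in candidates[[x]]) for (sb in candidates[[y]])
          unions <- c(unions, acylKey(c(sa, sb)))
        unions <- unique(unions)
        for (z in zs) {
          if (length(intersect(unions, keys[[z]])))
            addReaction(cr@reactionId, cat, c(x, y), z, character(0), FALSE)
        }
      }
    }
  }

  ## fatty-acid rule heuristics within each class
  banned <- attr(faRules, "bannedPairs")
  if (is.null(banned)) banned <- character(0)
  if (nrow(faRules)) {
    for (ri in seq_len(nrow(faRules))) {
      rule <- faRules$rule[ri]
      crId <- paste0("FA:", rule)
      for (cls in names(byClass)) {
        members <- byClass[[cls]]
        if (length(members) < 2L) next
        shifted <- lapply(members, function(nm) {
          out <- list(key = character(0))
          for (s in candidates[[nm]]) {
            for (j in seq_along(s)) {
              if (j > 1L && s[j] == s[j - 1L]) next
              newAcyl <- shiftAcyl(s[j], faRules$dC[ri], faRules$dDB[ri],
                                   faRules$dOH[ri])
              if (is.na(newAcyl)) next
              if (paste0(s[j], ">", newAcyl) %in% banned) next
              out$key <- c(out$key, acylKey(c(s[-j], newAcyl)))
            }
          }
          unique(out$key)
        })
        names(shifted) <- members
        for (x in members) for (y in members) {
          if (x == y) next
          if (length(intersect(shifted[[x]], keys[[y]])))
            addReaction(crId, rule, x, y, character(0), TRUE)
        }
      }
    }
  }

  ## ether conversion heuristic: same class and sum composition, different
  ## ether bond type
  if (allowEtherHeuristic) {
    for (cls in names(byClass)) {
      members <- byClass[[cls]]
      if (length(members) < 2L) next
      for (i in seq_along(members)) for (j in seq_along(members)) {
        if (i >= j) next
        a <- species[[members[i]]]; b <- species[[members[j]]]
        if (a@ether == b@ether) next
        if (a@sumC == b@sumC && a@sumDB == b@sumDB && a@sumOH == b@sumOH) {
          sub <- if (a@ether == "none") members[i] else members[j]
          prod <- setdiff(c(members[i], members[j]), sub)
          addReaction("ether_conversion", "ether_conversion", sub, prod,
                      character(0), TRUE)
        }
      }
    }
  }

  rxns <- reg$reactions
  if (length(rxns)) rxns <- rxns[order(names(rxns))]
  edges <- do.call(rbind, lapply(rxns, function(r) {
    grid <- expand.grid(from = r@substrates, to = r@products,
                        stringsAsFactors = FALSE)
    grid$reaction <- r@id; grid$category <- r@category
    grid$heuristic <- r@heuristic
    grid
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    warning(lipidnetWarning("no species reaction matched the dataset",
                            "emptyNetworkWarning"))
    edges <- data.frame(from = character(0), to = character(0),
                        reaction = character(0), category = character(0),
                        heuristic = logical(0))
  }
  vertices <- data.frame(
    name = names(species),
    lipidClass = vapply(species, lipidClass, ""),
    level = vapply(species, speciesLevel, ""),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  new("LipidNetwork", graph = g, reactions = rxns, species = species,
      expansion = ex$report)
}
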