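#' Load curated lipid-class reactions
#'
#' Reads a curated reaction table (TSV with columns `reaction_id`,
#' `category`, `substrates`, `products`, `db_refs`, `gene_refs`,
#' `organisms`; multi-valued fields are `+`- resp. `;`-separated) and
#' validates it against a class registry: every participating class must be
#' known and the participant arity must match the category
#' (`lipid_merging`: two substrate classes, one product; all other
#' categories: one and one).
#'
#' @param path path to the reaction TSV.
#' @param registry a [ClassRegistry-class].
#' @return named list of [ClassReaction-class] objects.
#' @examples
#' rxns <- defaultClassReactions()
#' rxns[["FAAR_LPI_PI"]]
#' @export
loadClassReactions <- function(path, registry = defaultClassRegistry()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = NULL)
  need <- c("reaction_id", "category", "substrates", "products",
            "db_refs", "gene_refs", "organisms")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop(schemaError(paste("reaction file lacks column(s):",
                           paste(miss, collapse = ", "))))
  if (anyDuplicated(tab$reaction_id))
    stop(schemaError("duplicated reaction_id in reaction table"))
  splitField <- function(x, sep) {
    if (is.na(x)) return(character(0))
    x <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
    x[nzchar(x)]
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    subs <- splitField(tab$substrates[i], "+")
    prods <- splitField(tab$products[i], "+")
    unknown <- setdiff(c(subs, prods), registry@table$abbreviation)
    if (length(unknown))
      stop(unknownClassError(sprintf(
        "reaction %s references unknown class(es): %s",
        tab$reaction_id[i], paste(unknown, collapse = ", "))))
    catg <- tab$category[i]
    if (!catg %in% reactionCategories)
      stop(schemaError(sprintf("reaction %s: unknown category '%s'",
                               tab$reaction_id[i], catg)))
    wantSub <- if (catg == "lipid_merging") 2L else 1L
    if (length(subs) != wantSub || length(prods) != 1L)
      stop(arityError(sprintf(
        "reaction %s: category %s requires %d substrate class(es) and 1 product class, got %d and %d",
        tab$reaction_id[i], catg, wantSub, length(subs), length(prods))))
    out[[i]] <- new("ClassReaction", reactionId = tab$reaction_id[i],
                    category = catg, substrateClasses = subs,
                    productClasses = prods,
                    dbRefs = splitField(tab$db_refs[i], ";"),
                    geneRefs = splitField(tab$gene_refs[i], ";"),
                    organisms = splitField(tab$organisms[i], ";"))
  }
  names(out) <- tab$reaction_id
  out
}

#' @rdname loadClassReactions
#' @details `defaultClassReactions()` returns the bundled curated fixture of
#'   class reactions spanning all four categories (headgroup modification,
#'   headgroup addition/removal, fatty-acid addition/removal, lipid
#'   merging), each with at least one database cross reference.
#' @export
defaultClassReactions <- function()
  loadClassReactions(system.file("extdata", "class_reactions.tsv",
                                 package = "lipidnet", mustWork = TRUE))

#' Write class reactions back to the TSV dialect
#'
#' Inverse of [loadClassReactions()] (the loader round-trips through it).
#'
#' @param reactions list of [ClassReaction-class].
#' @param path output file path.
#' @export
writeClassReactions <- function(reactions, path) {
  tab <- data.frame(
    reaction_id = vapply(reactions, reactionId, ""),
    category = vapply(reactions, function(r) r@category, ""),
    substrates = vapply(reactions, function(r)
      paste(r@substrateClasses, collapse = "+"), ""),
    products = vapply(reactions, function(r)
      paste(r@productClasses, collapse = "+"), ""),
    db_refs = vapply(reactions, function(r)
      paste(r@dbRefs, collapse = ";"), ""),
    gene_refs = vapply(reactions, function(r)
      paste(r@geneRefs, collapse = ";"), ""),
    organisms = vapply(reactions, function(r)
      paste(r@organisms, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter reactions by organism
#'
#' Keeps reactions whose organism set is empty (unrestricted) or contains
#' the given code (e.g. `"HSA"`, `"MMU"`).
#'
#' @param reactions list of [ClassReaction-class].
#' @param organism organism code.
#' @return the filtered list.
#' @export
filterByOrganism <- function(reactions, organism) {
  stopifnot(is.character(organism), length(organism) == 1L)
  keep <- vapply(reactions, function(r)
    length(r@organisms) == 0L || organism %in% r@organisms, TRUE)
  reactions[keep]
}

#' Fatty-acid reaction rules
#'
#' The heuristic fatty-acid reactions used to connect species of the same
#' class: elongation (+2 carbons), desaturation (+1 double bond) and
#' hydroxylation/oxidation (+1 hydroxylation). These transformations do not
#' occur directly on complex lipids (they act on activated fatty acids), so
#' the resulting network edges are flagged heuristic and score-penalized in
#' the enrichment.
#'
#' @param elongation,desaturation,hydroxylation enable flags.
#' @param bannedPairs character vector of banned conversions in the form
#'   `"from>to"` (e.g. `"16:0>16:1"`).
#' @return data.frame with one row per enabled rule (`rule`, `dC`, `dDB`,
#'   `dOH`) carrying `bannedPairs` as an attribute.
#' @export
faReactionRules <- function(elongation = TRUE, desaturation = TRUE,
                            hydroxylation = TRUE, bannedPairs = character(0)) {
  rules <- data.frame(
    rule = c("elongation", "desaturation", "hydroxylation"),
    dC = c(2L, 0L, 0L), dDB = c(0L, 1L, 0L), dOH = c(0L, 0L, 1L),
    stringsAsFactors = FALSE)
  rules <- rules[c(elongation, desaturation, hydroxylation), , drop = FALSE]
  attr(rules, "bannedPairs") <- bannedPairs
  rules
}
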