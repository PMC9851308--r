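#' Fatty acyl shorthand utilities
#'
#' Fatty acyls are the atomic unit of lipid species reasoning. They are held
#' in canonical shorthand text form `"C:D"` or `"C:D;O"` (carbons :
#' double bonds ; hydroxylations), with an optional `"O-"` (plasmanyl) or
#' `"P-"` (plasmenyl) ether prefix, e.g. `"16:0"`, `"20:4"`, `"18:1;1"`,
#' `"O-16:0"`.
#'
#' @param x character vector of acyl strings.
#' @return `parseAcyls()` returns a data.frame with one row per acyl and
#'   columns `carbons`, `doubleBonds`, `hydroxyls` (integer) and `ether`
#'   (one of `"none"`, `"plasmanyl"`, `"plasmenyl"`).
#' @examples
#' parseAcyls(c("16:0", "20:4", "18:1;1", "O-16:0"))
#' formatAcyls(c(16L, 20L), c(0L, 4L))
#' @export
parseAcyls <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^(O-|P-)?([0-9]+):([0-9]+)(;([0-9]+))?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop(malformedNameError(sprintf(
      "malformed fatty acyl token(s): %s",
      paste(sQuote(x[bad]), collapse = ", "))))
  }
  carbons <- vapply(m, function(g) as.integer(g[3L]), 1L)
  db <- vapply(m, function(g) as.integer(g[4L]), 1L)
  oh <- vapply(m, function(g) if (nzchar(g[6L])) as.integer(g[6L]) else 0L, 1L)
  pre <- vapply(m, function(g) g[2L], "")
  ether <- ifelse(pre == "O-", "plasmanyl",
                  ifelse(pre == "P-", "plasmenyl", "none"))
  invalid <- carbons < 1L | db < 0L | oh < 0L | db > carbons
  if (any(invalid)) {
    stop(malformedNameError(sprintf(
      "chemically invalid fatty acyl token(s): %s",
      paste(sQuote(x[invalid]), collapse = ", "))))
  }
  data.frame(carbons = carbons, doubleBonds = db, hydroxyls = oh,
             ether = ether, stringsAsFactors = FALSE)
}

#' @rdname parseAcyls
#' @param carbons,doubleBonds,hydroxyls integer vectors (recycled).
#' @param ether character vector of `"none"`, `"plasmanyl"` or `"plasmenyl"`.
#' @return `formatAcyls()` returns the canonical character form.
#' @export
formatAcyls <- function(carbons, doubleBonds, hydroxyls = 0L, ether = "none") {
  n <- max(length(carbons), length(doubleBonds), length(hydroxyls),
           length(ether))
  carbons <- rep_len(as.integer(carbons), n)
  doubleBonds <- rep_len(as.integer(doubleBonds), n)
  hydroxyls <- rep_len(as.integer(hydroxyls), n)
  ether <- rep_len(ether, n)
  pre <- ifelse(ether == "plasmanyl", "O-",
                ifelse(ether == "plasmenyl", "P-", ""))
  out <- paste0(pre, carbons, ":", doubleBonds)
  ifelse(hydroxyls > 0L, paste0(out, ";", hydroxyls), out)
}

## Canonical ordering of a multiset of acyl strings: ether chains first, then
## by carbons, double bonds and hydroxylations. Used everywhere a multiset is
## turned into a reproducible name or key.
sortAcyls <- function(x) {
  if (length(x) <= 1L) return(x)
  p <- parseAcyls(x)
  x[order(p$ether == "none", p$carbons, p$doubleBonds, p$hydroxyls, x)]
}

acylKey <- function(x) paste(sortAcyls(x), collapse = "_")

## Apply a fatty-acid reaction delta to a single acyl string; returns NA when
## the result is chemically invalid (e.g. more double bonds than carbons).
shiftAcyl <- function(acyl, dC, dDB, dOH) {
  p <- parseAcyls(acyl)
  c2 <- p$carbons + dC
  db2 <- p$doubleBonds + dDB
  oh2 <- p$hydroxyls + dOH
  ok <- c2 >= 1L & db2 >= 0L & oh2 >= 0L & db2 <= c2
  out <- rep(NA_character_, nrow(p))
  out[ok] <- formatAcyls(c2[ok], db2[ok], oh2[ok], p$ether[ok])
  out
}

## --- condition constructors -------------------------------------------------

lipidnetCondition <- function(msg, class, base = "error") {
  structure(
    class = c(class, paste0("lipidnet", toupper(substring(base, 1, 1)),
                            substring(base, 2)), base, "condition"),
    list(message = msg, call = sys.call(-1)))
}

unknownClassError <- function(msg) lipidnetCondition(msg, "unknownClassError")
malformedNameError <- function(msg) lipidnetCondition(msg, "malformedNameError")
schemaError <- function(msg) lipidnetCondition(msg, "schemaError")
arityError <- function(msg) lipidnetCondition(msg, "arityError")
missingLipidError <- function(msg) lipidnetCondition(msg, "missingLipidError")
nonPositiveAbundanceError <- function(msg)
  lipidnetCondition(msg, "nonPositiveAbundanceError")
degenerateControlError <- function(msg)
  lipidnetCondition(msg, "degenerateControlError")
noOverlapError <- function(msg) lipidnetCondition(msg, "noOverlapError")
specError <- function(msg) lipidnetCondition(msg, "specError")

lipidnetWarning <- function(msg, class) {
  structure(class = c(class, "lipidnetWarning", "warning", "condition"),
            list(message = msg, call = sys.call(-1)))
}
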