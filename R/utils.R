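# Internal helpers: error conditions, pair canonicalization, logging.

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("appia_format_error", "appia_error")))
}

abort_appia <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = "appia_error"))
}

#' Canonicalize unordered protein pairs
#'
#' A pair is stored with its two ids in lexicographic order so that (a, b)
#' and (b, a) refer to the same instance. Canonicalization is idempotent.
#'
#' @param a,b character vectors of protein ids (recycled to common length).
#' @return data.table with columns `idA`, `idB` (`idA < idB` element-wise).
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  idA <- ifelse(swap, b, a)
  idB <- ifelse(swap, a, b)
  data.table(idA = idA, idB = idB)
}

# Single string key for a canonical pair; used for joins and set ops.
pair_key <- function(idA, idB) paste(idA, idB, sep = "\t")

appia_log <- function(fmt, ..., verbose = getOption("appia.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-method score orientation. PP is a distance (smaller = stronger
# association); the other four grow with evidence strength.
METHODS <- c("PP", "GC", "GF", "MT", "I2H")

#' Score orientation of the five predictors
#'
#' @param method one of `"PP"`, `"GC"`, `"GF"`, `"MT"`, `"I2H"`.
#' @return `"asc"` if smaller scores are stronger (PP), else `"desc"`.
#' @export
method_orientation <- function(method) {
  method <- match.arg(method, METHODS)
  if (method == "PP") "asc" else "desc"
}

# Orient scores so that larger always means stronger.
orient_scores <- function(score, method) {
  if (method_orientation(method) == "asc") -score else score
}
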