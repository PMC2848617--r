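# Assembly of the 19-attribute instance representation:
#   5 method scores (PP, GC, GF, MT, I2H),
#   10 protein-centered rank attributes (min and max rank per method),
#   4 protein features (sequence length and ortholog count of each protein).
# Missing values stay NA throughout ("undetermined"); they are never
# replaced with flag values.

FEATURE_COLS <- c(
  "score_pp", "score_gc", "score_gf", "score_mt", "score_i2h",
  "rank_min_pp", "rank_max_pp", "rank_min_gc", "rank_max_gc",
  "rank_min_gf", "rank_max_gf", "rank_min_mt", "rank_max_mt",
  "rank_min_i2h", "rank_max_i2h",
  "len_a", "len_b", "n_orth_a", "n_orth_b")

#' Protein-centered prediction ranks
#'
#' Position of each pair involving `protein` in that protein's list of
#' predictions by one method, sorted strongest-first according to the
#' method's orientation (PP ascending, all others descending). Competition
#' ranking: tied scores share the smallest rank; output rows are ordered by
#' rank with ties broken by canonical pair id.
#'
#' @param protein protein id.
#' @param method one of the five method names.
#' @param all_scores pair-score `data.table` (`idA`, `idB`, `method`,
#'   `score`) holding at least that method's scores.
#' @return `data.table` (`idA`, `idB`, `rank`); empty when the protein has
#'   no scored pairs.
#' @export
protein_centered_rank <- function(protein, method, all_scores) {
  method <- match.arg(method, METHODS)
  sc <- as.data.table(all_scores)
  sc <- sc[method, on = "method"][idA == protein | idB == protein]
  if (!nrow(sc) || all(is.na(sc$score)))
    return(data.table(idA = character(), idB = character(), rank = integer()))
  sc <- sc[!is.na(score)]
  oriented <- orient_scores(sc$score, method)
  sc[, rank := data.table::frank(-oriented, ties.method = "min")]
  data.table::setorder(sc, rank, idA, idB)
  sc[, .(idA, idB, rank)]
}

#' Rank attributes of one pair for one method
#'
#' @param pair character vector of the two protein ids.
#' @param method method name.
#' @param ranks_a,ranks_b rank tables from [protein_centered_rank()] for the
#'   two proteins (may be `NULL` when the method gave the pair no score).
#' @return named numeric vector `c(rank_min, rank_max)`; both `NA` when the
#'   method score is missing for the pair.
#' @export
rank_attributes <- function(pair, method, ranks_a, ranks_b) {
  cp <- canonical_pair(pair[1L], pair[2L])
  get_rank <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return(NA_real_)
    hit <- as.data.table(tbl)[cp, on = c("idA", "idB"), nomatch = NULL]
    if (nrow(hit)) as.numeric(hit$rank[1L]) else NA_real_
  }
  ra <- get_rank(ranks_a); rb <- get_rank(ranks_b)
  if (is.na(ra) || is.na(rb))
    return(c(rank_min = NA_real_, rank_max = NA_real_))
  c(rank_min = min(ra, rb), rank_max = max(ra, rb))
}

# Bulk version: for one method's full score table, the rank of every pair in
# each of its two proteins' lists, by competition ranking.
rank_table <- function(scores, method) {
  sc <- as.data.table(scores)[!is.na(score)]
  if (!nrow(sc))
    return(data.table(idA = character(), idB = character(),
                      rank_min = numeric(), rank_max = numeric()))
  long <- data.table::rbindlist(list(
    sc[, .(protein = idA, idA, idB, score)],
    sc[, .(protein = idB, idA, idB, score)]))
  long[, oriented := orient_scores(score, method)]
  long[, rank := data.table::frank(-oriented, ties.method = "min"),
       by = protein]
  long[, .(rank_min = as.numeric(min(rank)), rank_max = as.numeric(max(rank))),
       by = .(idA, idB)]
}

#' Assemble 19-attribute feature vectors
#'
#' Joins method scores, protein-centered rank attributes and protein features
#' into one row per pair. Pairs without a single method score are excluded
#' (uninformative). A pair whose protein lacks a record in `records` is an
#' error. Absent values are `NA`, never flags.
#'
#' @param scores pair-score `data.table` (`idA`, `idB`, `method`, `score`)
#'   over all five methods (any subset of methods may be present).
#' @param records `data.frame`/`data.table` with columns `protein`, `length`
#'   (residues) and `n_orthologs`.
#' @param label optional pair label table (`idA`, `idB`, `label`); unlabeled
#'   pairs get `NA`.
#' @return `data.table` with `idA`, `idB`, the 19 attribute columns and
#'   `label`.
#' @export
assemble_features <- function(scores, records, label = NULL) {
  sc <- as.data.table(scores)[!is.na(score)]
  if (!nrow(sc)) abort_appia("assemble_features: no method scores at all")
  stopifnot(all(sc$method %in% METHODS))
  records <- as.data.table(records)
  if (anyDuplicated(records$protein))
    abort_appia("duplicate protein records")
  if (any(records$length < 1L)) abort_appia("protein record with length < 1")

  wide <- data.table::dcast(sc, idA + idB ~ method, value.var = "score")
  for (m in METHODS) {
    col <- tolower(m)
    if (m %in% names(wide)) data.table::setnames(wide, m, paste0("score_", col))
    else wide[, paste0("score_", col) := NA_real_]
  }
  for (m in METHODS) {
    rt <- rank_table(sc[method == m], m)
    cn <- paste0(c("rank_min_", "rank_max_"), tolower(m))
    if (nrow(rt)) {
      data.table::setnames(rt, c("rank_min", "rank_max"), cn)
      wide <- merge(wide, rt, by = c("idA", "idB"), all.x = TRUE)
    } else {
      wide[, (cn) := NA_real_]
    }
  }
  missing_rec <- setdiff(union(wide$idA, wide$idB), records$protein)
  if (length(missing_rec))
    abort_appia("no protein record for: %s",
                paste(utils::head(missing_rec, 5L), collapse = ", "))
  recA <- records[, .(idA = protein, len_a = as.numeric(length),
                      n_orth_a = as.numeric(n_orthologs))]
  recB <- records[, .(idB = protein, len_b = as.numeric(length),
                      n_orth_b = as.numeric(n_orthologs))]
  wide <- merge(wide, recA, by = "idA")
  wide <- merge(wide, recB, by = "idB")
  if (!is.null(label)) {
    lab <- as.data.table(label)[, .(idA, idB, label)]
    wide <- merge(wide, lab, by = c("idA", "idB"), all.x = TRUE)
  } else {
    wide[, label := NA_character_]
  }
  data.table::setcolorder(wide, c("idA", "idB", FEATURE_COLS, "label"))
  data.table::setkey(wide, idA, idB)
  wide[]
}

#' Rank-based noise filter
#'
#' Removes instances supported only by weak predictions of the noisy methods:
#' a vector is kept iff at least one of its PP/MT/I2H rank attributes is
#' present and `<= cutoff`, or it carries any GC or GF score. GC and GF
#' supply few, precise predictions and are never pruned.
#'
#' @param vectors feature table from [assemble_features()].
#' @param cutoff rank cutoff (default 100).
#' @param filter_methods methods whose ranks are examined by the filter.
#' @param keep_methods methods whose mere score presence keeps a vector.
#' @return filtered table; attribute `n_removed` counts dropped rows.
#' @export
rank_filter <- function(vectors, cutoff = 100L,
                        filter_methods = c("PP", "MT", "I2H"),
                        keep_methods = c("GC", "GF")) {
  v <- as.data.table(vectors)
  rank_cols <- as.vector(outer(c("rank_min_", "rank_max_"),
                               tolower(filter_methods), paste0))
  rank_cols <- intersect(rank_cols, names(v))
  score_cols <- intersect(paste0("score_", tolower(keep_methods)), names(v))
  keep_rank <- rep(FALSE, nrow(v))
  for (cc in rank_cols)
    keep_rank <- keep_rank | (!is.na(v[[cc]]) & v[[cc]] <= cutoff)
  keep_score <- rep(FALSE, nrow(v))
  for (cc in score_cols)
    keep_score <- keep_score | !is.na(v[[cc]])
  keep <- keep_rank | keep_score
  appia_log("rank_filter: removed %d of %d vectors", sum(!keep), nrow(v))
  out <- v[keep]
  data.table::setattr(out, "n_removed", sum(!keep))
  out[]
}

#' Write / read a feature matrix
#'
#' TSV with one row per pair: `idA`, `idB`, the 19 attribute columns and
#' `label`; missing values are encoded as empty fields.
#'
#' @param features feature table.
#' @param path TSV path.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(as.data.table(features), path, sep = "\t", na = "",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "",
                          colClasses = list(character = c("idA", "idB")))
  miss <- setdiff(c("idA", "idB", FEATURE_COLS), names(dt))
  if (length(miss))
    abort_format("feature matrix '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", "))
  if (!"label" %in% names(dt)) dt[, label := NA_character_]
  for (cc in FEATURE_COLS) data.table::set(dt, j = cc,
                                           value = as.numeric(dt[[cc]]))
  data.table::setkey(dt, idA, idB)
  dt[]
}
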