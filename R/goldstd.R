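# Gold-standard construction: positive pairs pooled from several source
# lists, negatives drawn from the non-positive pairs among the positive
# set's proteins (restricted to pairs the predictors scored), and the
# balanced 20%/80% train/test split.

#' Pool positive pairs from several source lists
#'
#' Union of the source pair lists with per-pair multi-source tags; homodimers
#' are dropped and duplicates merged.
#'
#' @param source_lists named list of pair tables (`idA`, `idB`, optionally
#'   `source`); names are used as source tags when a table has no `source`
#'   column.
#' @return `data.table` (`idA`, `idB`, `sources`) where `sources` is a
#'   comma-separated sorted tag list.
#' @export
build_positives <- function(source_lists) {
  if (!length(source_lists)) abort_appia("build_positives: no source lists")
  tagged <- lapply(seq_along(source_lists), function(k) {
    x <- as.data.table(source_lists[[k]])
    if (!nrow(x)) return(NULL)
    src <- if ("source" %in% names(x)) as.character(x$source)
           else names(source_lists)[k] %||% as.character(k)
    out <- canonical_pair(x$idA, x$idB)
    out[, source := src]
    out[idA != idB]
  })
  all <- data.table::rbindlist(Filter(Negate(is.null), tagged))
  if (is.null(all) || !nrow(all))
    abort_appia("build_positives: empty union of positive sources")
  pos <- all[, .(sources = paste(sort(unique(source)), collapse = ",")),
             by = .(idA, idB)]
  data.table::setkey(pos, idA, idB)
  pos[]
}

#' Pairs implied by shared transcriptional regulation
#'
#' From a regulator-to-targets map, emits (i) all unordered target pairs
#' within each regulon, pooled across regulons (co-regulated pairs), and
#' (ii) the regulator-target pairs themselves, as two separate lists.
#'
#' @param regulons named list: regulator id -> character vector of target
#'   ids, or a `data.table` with columns `regulator`, `target`.
#' @return list with `coregulated` and `regulator_target` pair tables.
#' @export
coregulated_from_regulons <- function(regulons) {
  if (is.data.frame(regulons)) {
    rt <- as.data.table(regulons)
    regulons <- split(rt$target, rt$regulator)
  }
  co <- list(); reg <- list()
  for (r in names(regulons)) {
    targets <- setdiff(unique(as.character(regulons[[r]])), r)
    if (length(targets) >= 2L) {
      cmb <- utils::combn(sort(targets), 2L)
      co[[r]] <- data.table(idA = cmb[1L, ], idB = cmb[2L, ])
    }
    if (length(targets) >= 1L)
      reg[[r]] <- canonical_pair(rep(r, length(targets)), targets)
  }
  mk <- function(lst, tag) {
    if (!length(lst))
      return(data.table(idA = character(), idB = character(),
                        source = character()))
    out <- unique(data.table::rbindlist(lst), by = c("idA", "idB"))
    out[, source := tag]
    data.table::setkey(out, idA, idB)
    out[]
  }
  list(coregulated = mk(co, "coregulated"),
       regulator_target = mk(reg, "regulator_regulated"))
}

#' Build the negative class
#'
#' Candidate negatives are the non-positive, non-homodimer pairs among the
#' proteins of the positive set; pairs for which no prediction method
#' produced a value are removed (uninformative). Since every usable negative
#' must carry at least one method value, candidates are enumerated from the
#' scored pairs.
#'
#' @param positives positive pair table (`idA`, `idB`).
#' @param scored_pairs table of pairs with at least one method value
#'   (`idA`, `idB`).
#' @return `data.table` (`idA`, `idB`) of negatives.
#' @export
build_negatives <- function(positives, scored_pairs) {
  pos <- canonical_pair(positives$idA, positives$idB)
  if (!nrow(pos)) abort_appia("build_negatives: empty positive set")
  universe <- union(pos$idA, pos$idB)
  neg <- unique(canonical_pair(scored_pairs$idA, scored_pairs$idB),
                by = c("idA", "idB"))
  neg <- neg[idA != idB & idA %in% universe & idB %in% universe]
  neg <- neg[!pos, on = c("idA", "idB")]
  data.table::setkey(neg, idA, idB)
  neg[]
}

#' Balanced train/test split
#'
#' Positives are shuffled by `seed`; the first 2/3 (floor) go to training and
#' the rest to test. Each set receives exactly 4 times as many negatives as
#' positives, sampled uniformly without replacement and disjoint between the
#' sets, so both sets are 20% positive / 80% negative. All positives are
#' used; surplus negatives are discarded.
#'
#' @param positives,negatives pair tables (`idA`, `idB`).
#' @param seed integer seed controlling the shuffle and the negative sample.
#' @param train_frac fraction of positives assigned to training.
#' @param neg_mult negatives per positive in each set.
#' @return list of class `appia_split`: `train` and `test` tables
#'   (`idA`, `idB`, `label`) plus the `seed`.
#' @export
make_split <- function(positives, negatives, seed, train_frac = 2 / 3,
                       neg_mult = 4L) {
  pos <- unique(canonical_pair(positives$idA, positives$idB),
                by = c("idA", "idB"))
  neg <- unique(canonical_pair(negatives$idA, negatives$idB),
                by = c("idA", "idB"))
  P <- nrow(pos); N <- nrow(neg)
  need <- neg_mult * P
  if (N < need)
    abort_appia("make_split: %d negatives required (%d positives x %d), found %d",
                need, P, neg_mult, N)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    list(pos_perm = sample.int(P), neg_perm = sample.int(N))
  })
  pos <- pos[rng$pos_perm]
  n_train_pos <- floor(train_frac * P)
  train_pos <- pos[seq_len(n_train_pos)]
  test_pos <- pos[setdiff(seq_len(P), seq_len(n_train_pos))]
  neg <- neg[rng$neg_perm]
  train_neg <- neg[seq_len(neg_mult * nrow(train_pos))]
  test_neg <- neg[neg_mult * nrow(train_pos) + seq_len(neg_mult * nrow(test_pos))]
  lab <- function(x, l) { x <- data.table::copy(x); x[, label := l]; x }
  split <- list(train = rbind(lab(train_pos, "positive"), lab(train_neg, "negative")),
                test = rbind(lab(test_pos, "positive"), lab(test_neg, "negative")),
                seed = seed)
  class(split) <- "appia_split"
  split
}

#' @export
print.appia_split <- function(x, ...) {
  cat(sprintf("<appia_split> train %d (%d pos) / test %d (%d pos), seed %d\n",
              nrow(x$train), sum(x$train$label == "positive"),
              nrow(x$test), sum(x$test$label == "positive"), x$seed))
  invisible(x)
}
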