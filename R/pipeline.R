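# End-to-end orchestration: score -> features -> gold standard -> train ->
# predict -> evaluate, from in-memory worlds or from a directory of input
# files, with a structured run log.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort_appia("stage '%s' failed: %s", name, conditionMessage(e)))
}

# Load pipeline inputs from a directory laid out like write_world().
read_world_dir <- function(dir) {
  gff <- list.files(file.path(dir, "gff"), pattern = "\\.gff3?$",
                    full.names = TRUE)
  aln_dir <- file.path(dir, "aln")
  alns <- if (dir.exists(aln_dir))
    list.files(aln_dir, pattern = "\\.(fa|fasta|afa)$", full.names = TRUE)
  else character(0)
  alignments <- lapply(alns, read_alignment)
  names(alignments) <- vapply(alignments, `[[`, character(1), "protein")
  pos_files <- list.files(file.path(dir, "positives"), pattern = "\\.tsv$",
                          full.names = TRUE)
  positives <- if (length(pos_files)) {
    lst <- lapply(pos_files, read_pair_list)
    pos <- build_positives(setNames(lst, sub("\\.tsv$", "",
                                             basename(pos_files))))
    data.table(idA = pos$idA, idB = pos$idB, source = pos$sources)
  } else data.table(idA = character(), idB = character(),
                    source = character())
  gf_path <- file.path(dir, "gf.tsv")
  list(table = read_ortholog_table(file.path(dir, "orthologs.tsv")),
       coords = if (length(gff)) read_gene_coordinates(gff)
                else data.table(genome = character(), gene = character(),
                                contig = character(), start = integer(),
                                end = integer(), strand = character()),
       alignments = alignments,
       gf = if (file.exists(gf_path)) read_pair_list(gf_path, source = "gf")
            else NULL,
       positives = positives,
       records = read_protein_records(file.path(dir, "records.tsv")))
}

#' Compute all method scores for a world
#'
#' @param world an `appia_world` or input list from a world directory.
#' @param methods subset of the five method names to run.
#' @param gc_threshold strict gene-context distance cutoff (bp).
#' @param min_common minimum common species for MT/I2H.
#' @param r_cut I2H correlation cutoff.
#' @return pair-score `data.table` (`idA`, `idB`, `method`, `score`).
#' @export
score_world <- function(world, methods = METHODS, gc_threshold = 300L,
                        min_common = 11L, r_cut = 0.5) {
  out <- list()
  if ("PP" %in% methods)
    out$pp <- stage("PP", score_pp_all(world$table))
  if ("GC" %in% methods)
    out$gc <- stage("GC", score_gc_all(world$table, world$coords,
                                       gc_threshold))
  if ("GF" %in% methods && !is.null(world$gf) && nrow(world$gf))
    out$gf <- stage("GF", ingest_gf(world$gf))
  co <- intersect(c("MT", "I2H"), methods)
  if (length(co) && length(world$alignments) >= 2L)
    out$co <- stage("MT/I2H", score_coevolution_pairs(
      world$alignments, world$table$genomes, min_common = min_common,
      r_cut = r_cut, methods = co))
  data.table::rbindlist(out, use.names = TRUE)
}

#' Run the full pipeline
#'
#' Scores every candidate pair with the enabled methods, assembles and
#' rank-filters the 19-attribute instances, builds the balanced gold
#' standard split, trains the discretizer and the AODE classifier, scores
#' all instances, and evaluates: test-set ROC/cost curve/MCC plus top-n
#' accuracy of the per-method and combined rankings on the extended test
#' (every scored pair not used in training). Deterministic given identical
#' inputs and `seed`.
#'
#' @param world an `appia_world`, or a directory path laid out like
#'   [write_world()].
#' @param seed integer seed for the gold-standard split.
#' @param out_dir optional output directory; when given, scores, features,
#'   model, predictions, curves and a JSON run log are written there.
#' @param methods methods to enable (disabled methods leave their attributes
#'   all-missing; the 19-attribute schema is unchanged).
#' @param gc_threshold,rank_cutoff,min_per_band,b_target,min_common,r_cut,
#'   train_frac,neg_mult method and dataset parameters (defaults are the
#'   production constants: 300 bp, rank 100, 50 per band, 2/3, 4x).
#' @param topn list depths for the accuracy curves.
#' @param threshold classification threshold on the positive-class
#'   probability.
#' @return list (class `appia_run`) with `scores`, `features`, `split`,
#'   `discretizer`, `model`, `predictions`, `evaluation` and `log`.
#' @export
run_all <- function(world, seed = 1L, out_dir = NULL, methods = METHODS,
                    gc_threshold = 300L, rank_cutoff = 100L,
                    min_per_band = 50L, b_target = 10L, min_common = 11L,
                    r_cut = 0.5, train_frac = 2 / 3, neg_mult = 4L,
                    topn = c(10L, 20L, 50L, 100L, 200L, 500L, 1000L, 2000L),
                    threshold = 0.5) {
  t0 <- Sys.time()
  if (is.character(world)) world <- stage("load", read_world_dir(world))
  log <- list(seed = seed, methods = methods,
              params = list(gc_threshold = gc_threshold,
                            rank_cutoff = rank_cutoff,
                            min_per_band = min_per_band,
                            min_common = min_common, r_cut = r_cut,
                            train_frac = train_frac, neg_mult = neg_mult))

  scores <- score_world(world, methods, gc_threshold, min_common, r_cut)
  if (!nrow(scores)) abort_appia("stage 'scores': no method produced scores")
  log$n_scores <- as.list(table(scores$method))

  features <- stage("features",
                    assemble_features(scores, world$records))
  n_pre <- nrow(features)
  features <- stage("rank_filter", rank_filter(features, rank_cutoff))
  log$n_features <- list(assembled = n_pre, kept = nrow(features),
                         removed = n_pre - nrow(features))

  positives <- stage("gold", {
    pos <- unique(canonical_pair(world$positives$idA, world$positives$idB))
    if (!nrow(pos)) abort_appia("no gold-standard positives")
    pos
  })
  pos_in <- features[positives, on = c("idA", "idB"),
                     nomatch = NULL][, .(idA, idB)]
  negatives <- stage("negatives", build_negatives(positives, features))
  log$n_gold <- list(positives = nrow(positives),
                     positives_with_features = nrow(pos_in),
                     negatives = nrow(negatives))
  split <- stage("split", make_split(pos_in, negatives, seed,
                                     train_frac, neg_mult))

  get_set <- function(s)
    merge(features[, !"label"], as.data.table(s), by = c("idA", "idB"))
  train <- get_set(split$train)
  test <- get_set(split$test)

  disc <- stage("discretize",
                fit_discretizer(train, min_per_band, b_target))
  model <- stage("train", fit_aode(train, train$label, discretizer = disc))

  predictions <- stage("predict", {
    p <- stats::predict(model, features)[, "positive"]
    data.table(idA = features$idA, idB = features$idB, appia = p)
  })

  evaluation <- stage("evaluate", {
    p_test <- predictions[test, on = c("idA", "idB")]$appia
    roc <- roc_points(p_test, test$label)
    curve <- lower_envelope(cost_lines(roc))
    trivial <- lower_envelope(data.table(intercept = c(0, 1),
                                         slope = c(1, -1)))
    pred_lab <- ifelse(p_test >= threshold, "positive", "negative")
    cm <- confusion_counts(pred_lab, test$label)
    train_pairs <- split$train[, .(idA, idB)]
    gold <- positives
    per_method <- list()
    for (m in intersect(METHODS, unique(scores$method))) {
      sm <- scores[method == m][!train_pairs, on = c("idA", "idB")]
      sm[, oriented := orient_scores(score, m)]
      data.table::setorder(sm, -oriented, idA, idB)
      per_method[[m]] <- topn_accuracy(sm, gold, topn)
    }
    ap <- predictions[!train_pairs, on = c("idA", "idB")]
    data.table::setorder(ap, -appia, idA, idB)
    per_method[["APPIA"]] <- topn_accuracy(ap, gold, topn)
    list(roc = roc, cost_curve = curve, trivial = trivial,
         confusion = cm, mcc = mcc(cm), topn = per_method)
  })
  log$mcc <- evaluation$mcc
  log$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  run <- structure(list(scores = scores, features = features, split = split,
                        discretizer = disc, model = model,
                        predictions = predictions, evaluation = evaluation,
                        log = log),
                   class = "appia_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.appia_run <- function(x, ...) {
  cat(sprintf(paste0("<appia_run> %d scored pairs, %d instances, ",
                     "test MCC %.3f\n"),
              nrow(x$scores), nrow(x$features), x$evaluation$mcc))
  invisible(x)
}

# Write the run artifacts (TSV curves + JSON log) into a directory.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(run$scores, file.path(out_dir, "scores.tsv"), sep = "\t")
  write_features(run$features, file.path(out_dir, "features.tsv"))
  save_model(run$model, file.path(out_dir, "model.json"))
  data.table::fwrite(run$predictions, file.path(out_dir, "predictions.tsv"),
                     sep = "\t")
  ev <- run$evaluation
  data.table::fwrite(ev$roc, file.path(out_dir, "roc.tsv"), sep = "\t")
  data.table::fwrite(ev$cost_curve, file.path(out_dir, "costcurve.tsv"),
                     sep = "\t")
  for (m in names(ev$topn))
    data.table::fwrite(ev$topn[[m]],
                       file.path(out_dir, sprintf("topn_%s.tsv", m)),
                       sep = "\t")
  jsonlite::write_json(run$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
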