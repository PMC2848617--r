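# ROC points, cost-line duality, lower envelopes, top-n accuracy, MCC and
# external-list ranking.

test_that("roc_points spans the trivial endpoints and orders by threshold", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  labels <- c("positive", "positive", "positive", "negative", "negative",
              "negative")
  roc <- roc_points(scores, labels)
  expect_identical(roc$fpr[1], 0); expect_identical(roc$tpr[1], 0)
  expect_identical(roc$fpr[nrow(roc)], 1)
  expect_identical(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation

  tied <- roc_points(rep(1, 6), labels)
  expect_identical(nrow(tied), 2L)               # (0,0) and (1,1) only
  # reversed scorer reflects through (0.5, 0.5)
  fwd <- roc_points(scores, labels)
  rev <- roc_points(-scores, labels)
  expect_equal(sort(1 - rev$fpr), sort(fwd$fpr))
  expect_equal(sort(1 - rev$tpr), sort(fwd$tpr))
  expect_error(roc_points(scores, rep("positive", 6)), class = "appia_error")
})

test_that("cost lines realize NE(0) = fpr and NE(1) = 1 - tpr", {
  roc <- data.table::data.table(fpr = c(0, 0, 1, 0.2), tpr = c(1, 0, 1, 0.6))
  cl <- cost_lines(roc)
  ne <- function(k, pc) cl$intercept[k] + cl$slope[k] * pc
  expect_identical(ne(1, 0), 0); expect_identical(ne(1, 1), 0)   # perfect
  expect_identical(ne(2, 0.3), 0.3)                              # NE = PC
  expect_identical(ne(3, 0.3), 0.7)                              # NE = 1-PC
  expect_equal(ne(4, 0), 0.2); expect_equal(ne(4, 1), 0.4)
})

test_that("ROC/cost-curve duality holds for every point", {
  run <- small_run(1)
  roc <- run$evaluation$roc
  cl <- cost_lines(roc)
  expect_equal(cl$intercept, roc$fpr)
  expect_equal(cl$intercept + cl$slope, 1 - roc$tpr)
})

test_that("trivial classifiers give the min(PC, 1-PC) envelope", {
  env <- lower_envelope(data.table::data.table(intercept = c(0, 1),
                                               slope = c(1, -1)))
  expect_equal(env$pc, c(0, 0.5, 1))
  expect_equal(env$ne, c(0, 0.5, 0))
  expect_equal(eval_costcurve(env, c(0.2, 0.5, 0.9)), c(0.2, 0.5, 0.1))
})

test_that("dominated lines never appear in the envelope", {
  lines <- data.table::data.table(intercept = c(0, 1, 0.6),
                                  slope = c(1, -1, 0))  # 0.6 flat dominated
  env <- lower_envelope(lines)
  expect_equal(max(env$ne), 0.5)
  pc <- seq(0, 1, length.out = 101)
  expect_equal(eval_costcurve(env, pc), pmin(pc, 1 - pc), tolerance = 1e-12)
})

test_that("envelope equals the dense-grid minimum on random line sets", {
  set.seed(123)
  pc <- seq(0, 1, length.out = 2001)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    fpr <- runif(n); tpr <- runif(n)
    cl <- cost_lines(data.table::data.table(fpr = fpr, tpr = tpr))
    env <- lower_envelope(cl)
    expect_true(all(diff(env$pc) > 0))
    got <- eval_costcurve(env, pc)
    ref <- oracle_envelope_grid(cl$intercept, cl$slope, pc)
    expect_lt(max(abs(got - ref)), 1e-9)
    # concavity and domination by every line
    mid <- (got[-1] + got[-length(got)]) / 2
    expect_true(all(got <= ref + 1e-12))
  }
})

test_that("envelope_difference measures vertical distances", {
  triv <- lower_envelope(data.table::data.table(intercept = c(0, 1),
                                                slope = c(1, -1)))
  expect_identical(envelope_difference(triv, triv)$max_abs, 0)
  perfect <- lower_envelope(data.table::data.table(intercept = 0, slope = 0))
  d <- envelope_difference(perfect, triv)
  expect_equal(d$max_abs, 0.5)             # difference min(PC, 1-PC)
  expect_equal(d$min_diff, -0.5)
  expect_equal(d$mean_signed, -0.25)       # integral of -min(PC,1-PC)
  expect_equal(d$frac_a_below, 1)
  # vertex-exact extremes dominate (and stay close to) a dense grid scan
  set.seed(9)
  pc <- seq(0, 1, length.out = 4001)
  for (rep in 1:5) {
    mk <- function() lower_envelope(cost_lines(data.table::data.table(
      fpr = runif(8), tpr = runif(8))))
    a <- mk(); b <- mk()
    d <- envelope_difference(a, b)
    ref <- eval_costcurve(a, pc) - eval_costcurve(b, pc)
    expect_gte(d$max_diff, max(ref) - 1e-12)   # grid can only undershoot
    expect_lte(d$min_diff, min(ref) + 1e-12)
    expect_lt(abs(d$max_diff - max(ref)), 5e-4)  # grid resolution bound
    expect_lt(abs(d$min_diff - min(ref)), 5e-4)
    # at the vertices themselves the difference is exact
    expect_equal(d$points$diff,
                 eval_costcurve(a, d$points$pc) - eval_costcurve(b, d$points$pc),
                 tolerance = 1e-12)
  }
})

test_that("topn_accuracy is the cumulative positive fraction", {
  ranked <- data.table::data.table(idA = sprintf("a%03d", 1:200),
                                   idB = sprintf("b%03d", 1:200))
  gold <- ranked[1:100]                      # first 100 all positive
  expect_identical(topn_accuracy(ranked, gold, 100)$accuracy, 1)
  set.seed(2)
  gold2 <- ranked[c(1:68, sample(101:200, 20))]
  expect_identical(topn_accuracy(ranked, gold2, 100)$accuracy, 0.68)
  # identity with the cumulative mean of the indicator
  hit <- paste(ranked$idA, ranked$idB) %in% paste(gold2$idA, gold2$idB)
  expect_equal(topn_accuracy(ranked, gold2)$accuracy,
               cumsum(hit) / seq_along(hit))
  # monotone score transforms do not change the ranking-based curve
  truncated <- topn_accuracy(ranked, gold2, c(50, 500))
  expect_identical(truncated$n, 50L)
})

test_that("mcc follows the confusion-matrix formula", {
  expect_identical(mcc(tp = 10, tn = 20, fp = 0, fn = 0), 1)
  expect_identical(mcc(tp = 25, tn = 25, fp = 25, fn = 25), 0)
  expect_equal(mcc(tp = 50, tn = 30, fp = 10, fn = 10),
               (50 * 30 - 10 * 10) / sqrt(60 * 60 * 40 * 40))
  expect_identical(mcc(tp = 0, tn = 50, fp = 0, fn = 0), 0)  # zero factor
  # symmetry under simultaneous class swap
  set.seed(4)
  for (rep in 1:20) {
    cc <- as.list(sample(0:30, 4, replace = TRUE))
    names(cc) <- c("tp", "tn", "fp", "fn")
    expect_equal(mcc(cc), mcc(list(tp = cc$tn, tn = cc$tp,
                                   fp = cc$fn, fn = cc$fp)))
  }
  expect_equal(mcc(confusion_counts(c("positive", "negative"),
                                    c("positive", "negative"))), 1)
})

test_that("rank_external sorts by probability with flagged leftovers", {
  run <- small_run(1)
  w <- small_world(1)
  ext <- rbind(w$planted[1:5],
               data.table::data.table(idA = "zz1", idB = "zz2"))
  ranked <- rank_external(ext, run$model, run$features)
  expect_identical(nrow(ranked), 6L)
  expect_false(ranked$has_features[6])
  expect_identical(ranked[has_features == TRUE,
                          order(-score, idA, idB)], 1:5)
  expect_identical(nrow(rank_external(w$planted[0], run$model, run$features)),
                   0L)
})

test_that("rank_external concentrates planted positives at the top", {
  run <- small_run(2)
  w <- small_world(2)
  # external list: planted pairs diluted in random pairs
  set.seed(42)
  noise <- canonical_pair(sample(w$proteins, 300, replace = TRUE),
                          sample(w$proteins, 300, replace = TRUE))
  noise <- unique(noise[idA != idB])
  ext <- unique(rbind(w$planted, noise))
  ranked <- rank_external(ext, run$model, run$features)
  top <- ranked[1:20]
  base_rate <- nrow(w$planted) / nrow(ext)
  top_rate <- mean(paste(top$idA, top$idB) %in%
                     paste(w$planted$idA, w$planted$idB))
  expect_gt(top_rate, base_rate)
})
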