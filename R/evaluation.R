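# Classifier assessment: ROC points, their dual cost lines, the cost-curve
# lower envelope, vertical distances between envelopes, top-n accuracy of
# ranked prediction lists, and the Matthews correlation coefficient.
#
# Cost curves plot normalized expected cost NE against the probability cost
# PC (the positive-class fraction under equal misclassification costs):
# every ROC point (fpr, tpr) maps to the line NE(PC) = (1-tpr) PC +
# fpr (1-PC), and the classifier's cost curve is the lower envelope of its
# lines. The always-negative / always-positive trivial classifiers give the
# reference envelope min(PC, 1-PC).

#' ROC operating points
#'
#' One point per distinct score threshold (ties grouped), predicting positive
#' when `score >= threshold`, plus the trivial endpoints (0,0) and (1,1).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels class labels.
#' @param positive label of the positive class.
#' @return `data.table` (`threshold`, `fpr`, `tpr`), sorted by decreasing
#'   threshold so `fpr` and `tpr` are nondecreasing.
#' @export
roc_points <- function(scores, labels, positive = "positive") {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  y <- labels == positive
  P <- sum(y); N <- sum(!y)
  if (P == 0L || N == 0L)
    abort_appia("roc_points: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  last <- which(diff(s) != 0)            # end of each tie group
  idx <- c(last, length(s))
  data.table(threshold = c(Inf, s[idx]),
             fpr = c(0, cumsum(!y)[idx] / N),
             tpr = c(0, cumsum(y)[idx] / P))
}

#' Cost lines dual to ROC points
#'
#' Each ROC point `(fpr, tpr)` becomes the line
#' `NE(PC) = (1 - tpr) * PC + fpr * (1 - PC)`, i.e. intercept `fpr` at
#' `PC = 0` and value `1 - tpr` at `PC = 1`. An optional cost ratio
#' (cost of a false negative over a false positive) rescales the x-axis
#' interpretation but not the line algebra.
#'
#' @param roc `data.table` from [roc_points()] (columns `fpr`, `tpr`).
#' @return `data.table` (`intercept`, `slope`, `fpr`, `tpr`) with
#'   `NE(pc) = intercept + slope * pc`.
#' @export
cost_lines <- function(roc) {
  roc <- as.data.table(roc)
  data.table(intercept = roc$fpr, slope = 1 - roc$tpr - roc$fpr,
             fpr = roc$fpr, tpr = roc$tpr)
}

#' Lower envelope of cost lines
#'
#' Exact pointwise minimum of the lines over `PC` in `[0, 1]`, computed by
#' the convex-hull scan (sort by slope, pop dominated lines at crossing
#' points), not by grid approximation. The result is concave and everywhere
#' at or below each generating line.
#'
#' @param lines `data.table` with `intercept` and `slope` columns.
#' @return an `appia_costcurve`: `data.table` (`pc`, `ne`) of envelope
#'   vertices from `pc = 0` to `pc = 1`.
#' @export
lower_envelope <- function(lines) {
  ln <- as.data.table(lines)[, .(intercept, slope)]
  if (!nrow(ln)) abort_appia("lower_envelope: need at least one line")
  # for equal slopes only the lowest line can touch the minimum
  ln <- ln[, .(intercept = min(intercept)), by = slope]
  data.table::setorder(ln, -slope)
  a <- ln$intercept; b <- ln$slope
  xat <- function(i, j) (a[j] - a[i]) / (b[i] - b[j])  # crossing point
  # convex-hull scan: slopes strictly decreasing, so the retained lines are
  # the full envelope over the real line, active left to right
  sel <- integer(0)
  for (k in seq_along(a)) {
    while (length(sel) >= 2L) {
      l1 <- sel[length(sel) - 1L]; l2 <- sel[length(sel)]
      if (xat(l1, k) <= xat(l1, l2)) sel <- sel[-length(sel)] else break
    }
    sel <- c(sel, k)
  }
  m <- length(sel)
  brk <- if (m > 1L) vapply(seq_len(m - 1L),
                            function(q) xat(sel[q], sel[q + 1L]), numeric(1))
         else numeric(0)
  # clip to [0, 1]: line q is active on [brk[q-1], brk[q]]
  lo <- c(-Inf, brk); hi <- c(brk, Inf)
  act <- which(lo < 1 & hi > 0)
  inner <- brk[brk > 0 & brk < 1]
  pcs <- c(0, inner, 1)
  segs <- sel[act]                        # one line per envelope segment
  stopifnot(length(segs) == length(pcs) - 1L)
  ne <- c(a[segs[1L]],                    # value at pc = 0
          a[segs] + b[segs] * pcs[-1L])   # each segment's right endpoint
  curve <- data.table(pc = pcs, ne = ne)
  class(curve) <- c("appia_costcurve", class(curve))
  curve
}

#' Evaluate a cost curve at given probability costs
#'
#' @param curve an `appia_costcurve`.
#' @param pc numeric vector in `[0, 1]`.
#' @return numeric vector of normalized expected costs.
#' @export
eval_costcurve <- function(curve, pc) {
  stats::approx(curve$pc, curve$ne, xout = pc, rule = 2)$y
}

#' Vertical distance between two cost curves
#'
#' Signed differences `A - B` evaluated exactly at the union of the two
#' envelopes' vertices (both curves are piecewise linear, so extremes occur
#' there); the mean is the integral average over `PC` in `[0, 1]`.
#'
#' @param curve_a,curve_b `appia_costcurve` objects.
#' @return list with `points` (`pc`, `ne_a`, `ne_b`, `diff`), `max_diff`,
#'   `min_diff`, `max_abs`, `mean_signed` and `frac_a_below` (fraction of
#'   the pc axis where A is strictly below B).
#' @export
envelope_difference <- function(curve_a, curve_b) {
  pc <- sort(unique(c(curve_a$pc, curve_b$pc)))
  na <- eval_costcurve(curve_a, pc)
  nb <- eval_costcurve(curve_b, pc)
  d <- na - nb
  mids <- (d[-1L] + d[-length(d)]) / 2
  w <- diff(pc)
  below <- mids < 0      # A below B on the segment's interior
  list(points = data.table(pc = pc, ne_a = na, ne_b = nb, diff = d),
       max_diff = max(d), min_diff = min(d), max_abs = max(abs(d)),
       mean_signed = sum(mids * w),
       frac_a_below = sum(w[below]))
}

#' Top-n accuracy of a ranked pair list
#'
#' For each n, the fraction of the first n ranked pairs that are gold
#' positives -- the cumulative mean of the positive indicator.
#'
#' @param ranked pair table (`idA`, `idB`) sorted strongest-first.
#' @param gold_positives pair table of gold positives.
#' @param n integer vector of list depths (default: every depth).
#' @return `data.table` (`n`, `accuracy`); depths beyond the list length are
#'   dropped.
#' @export
topn_accuracy <- function(ranked, gold_positives, n = NULL) {
  rk <- canonical_pair(ranked$idA, ranked$idB)
  gold <- unique(canonical_pair(gold_positives$idA, gold_positives$idB))
  hit <- !is.na(data.table::merge.data.table(
    rk[, .(idA, idB, ord = .I)], gold[, .(idA, idB, gold = TRUE)],
    by = c("idA", "idB"), all.x = TRUE, sort = FALSE)[order(ord), gold])
  acc <- cumsum(hit) / seq_along(hit)
  if (is.null(n)) n <- seq_along(hit)
  if (any(n > length(hit))) {
    appia_log("topn_accuracy: truncating %d depth(s) beyond list length %d",
              sum(n > length(hit)), length(hit))
    n <- n[n <= length(hit)]
  }
  data.table(n = as.integer(n), accuracy = acc[n])
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, with the
#' convention that a zero factor under the root yields 0.
#'
#' @param tp,tn,fp,fn confusion counts, or a list/vector with those names as
#'   the first argument.
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4L && !is.null(names(tp)))) {
    c0 <- as.list(tp)
    tp <- c0$tp; tn <- c0$tn; fp <- c0$fp; fn <- c0$fn
  }
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth label vectors.
#' @param positive positive-class label.
#' @return named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth, positive = "positive") {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == positive; t <- truth == positive
  list(tp = sum(p & t), tn = sum(!p & !t),
       fp = sum(p & !t), fn = sum(!p & t))
}

#' Rank an external pair list by model probability
#'
#' Scores every listed pair whose features are available with the model's
#' positive-class probability and sorts descending (ties broken by canonical
#' pair id); pairs with no computable features are flagged and placed last.
#'
#' @param pairs pair table (`idA`, `idB`) to rank.
#' @param model fitted `appia_aode` (or `appia_nb`) model.
#' @param features feature table covering the scorable pairs.
#' @param positive positive-class label.
#' @return `data.table` (`idA`, `idB`, `score`, `has_features`) in rank
#'   order; `score` is `NA` for feature-less pairs.
#' @export
rank_external <- function(pairs, model, features, positive = "positive") {
  pr <- unique(canonical_pair(pairs$idA, pairs$idB), by = c("idA", "idB"))
  if (!nrow(pr))
    return(data.table(idA = character(), idB = character(),
                      score = numeric(), has_features = logical()))
  fx <- as.data.table(features)
  hit <- fx[pr, on = c("idA", "idB"), nomatch = NULL]
  scored <- if (nrow(hit)) {
    p <- stats::predict(model, hit)[, positive]
    data.table(idA = hit$idA, idB = hit$idB, score = p, has_features = TRUE)
  } else {
    data.table(idA = character(), idB = character(), score = numeric(),
               has_features = logical())
  }
  rest <- pr[!scored, on = c("idA", "idB")]
  out <- rbind(scored[order(-score, idA, idB)],
               if (nrow(rest))
                 rest[order(idA, idB)][, `:=`(score = NA_real_,
                                              has_features = FALSE)])
  out[]
}
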