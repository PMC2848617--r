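# Equal-frequency discretization and the Averaged One-Dependence Estimators
# classifier, with a Naive Bayes baseline sharing the same smoothing and
# missing-data semantics.
#
# Missing values are first-class: they never form a band, contribute to no
# count involving their attribute, and at prediction time only the known
# values of an instance enter the product of probabilities.

#' Fit an equal-frequency discretizer
#'
#' Each attribute gets `B = max(1, min(b_target, floor(n/min_per_band)))`
#' bands (n = non-missing training values), with cut points at empirical
#' quantiles. Duplicate quantiles are merged and cuts are further dropped
#' until every band holds at least `min_per_band` training values (ties can
#' otherwise starve a band). Attributes with no non-missing values are
#' modeled as always-missing.
#'
#' @param x training feature table (numeric columns are discretized; id and
#'   label columns are ignored).
#' @param min_per_band minimum training instances per band.
#' @param b_target target band count before the occupancy floor.
#' @param cols columns to discretize (default: the 19 standard attributes
#'   present in `x`, else all numeric columns).
#' @return an `appia_discretizer`: cut points and band count per attribute.
#' @export
fit_discretizer <- function(x, min_per_band = 50L, b_target = 10L,
                            cols = NULL) {
  x <- as.data.table(x)
  if (is.null(cols)) {
    cols <- intersect(FEATURE_COLS, names(x))
    if (!length(cols)) cols <- names(x)[vapply(x, is.numeric, logical(1))]
  }
  cuts <- vector("list", length(cols))
  names(cuts) <- cols
  for (cc in cols) {
    v <- x[[cc]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      appia_log("fit_discretizer: attribute '%s' entirely missing", cc)
      cuts[[cc]] <- NULL
      next
    }
    B <- max(1L, min(b_target, n %/% min_per_band))
    # empirical-quantile cuts compatible with left-closed bands: cut k is
    # the order statistic one past the k-th band so band k keeps ~n/B values
    xs <- sort(v)
    cu <- if (B > 1L)
      sort(unique(xs[floor(seq_len(B - 1L) * n / B) + 1L]))
    else numeric(0)
    # enforce the occupancy floor under ties
    repeat {
      counts <- tabulate(findInterval(v, cu) + 1L, length(cu) + 1L)
      if (!length(cu) || all(counts >= min_per_band)) break
      worst <- which.min(counts)
      drop <- if (worst == 1L) 1L
              else if (worst == length(cu) + 1L) length(cu)
              else if (counts[worst - 1L] <= counts[worst + 1L]) worst - 1L
              else worst
      cu <- cu[-drop]
    }
    cuts[[cc]] <- cu
  }
  structure(list(attrs = cols, cuts = cuts,
                 nvals = setNames(vapply(cols, function(cc)
                   length(cuts[[cc]]) + 1L, integer(1)), cols),
                 min_per_band = as.integer(min_per_band),
                 b_target = as.integer(b_target)),
            class = "appia_discretizer")
}

#' Discretize feature values into nominal bands
#'
#' Values map to band indices via binary search with left-closed bands (a
#' value equal to a cut point falls in the right band); out-of-range values
#' clamp to the first/last band; missing stays missing. Attributes that were
#' entirely missing at fit time always map to missing.
#'
#' @param x feature table or numeric matrix.
#' @param model an `appia_discretizer`.
#' @return integer matrix of band indices (rows = instances, columns =
#'   `model$attrs`), `NA` for missing.
#' @export
discretize <- function(x, model) {
  stopifnot(inherits(model, "appia_discretizer"))
  x <- as.data.table(x)
  out <- matrix(NA_integer_, nrow = nrow(x), ncol = length(model$attrs),
                dimnames = list(NULL, model$attrs))
  for (cc in model$attrs) {
    if (!cc %in% names(x)) next
    cu <- model$cuts[[cc]]
    if (is.null(cu)) next    # fitted as always-missing: values stay missing
    v <- as.numeric(x[[cc]])
    band <- findInterval(v, cu) + 1L
    band[is.na(v)] <- NA_integer_
    out[, cc] <- band
  }
  out
}

#' @export
print.appia_discretizer <- function(x, ...) {
  cat(sprintf("<appia_discretizer> %d attributes, %d-%d bands (>=%d per band)\n",
              length(x$attrs), min(x$nvals), max(x$nvals), x$min_per_band))
  invisible(x)
}

# ---------------------------------------------------------------------------

check_training <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    abort_appia("training data contains a single class ('%s')", classes)
  list(X = X, y = y, classes = classes)
}

#' Fit an AODE classifier
#'
#' Averaged One-Dependence Estimators: classification averages over every
#' one-dependence model in which one attribute (the parent) is conditioned
#' on directly, relaxing Naive Bayes independence without structure search.
#' A single pass fills the class/attribute-value count tables `N(y, x_i)`
#' and `N(x_j, y, x_i)`; missing values contribute to no count involving
#' their attribute.
#'
#' @param X integer matrix of discretized attributes (from [discretize()]);
#'   `NA` marks missing.
#' @param y class labels (two or more classes must be present).
#' @param nvals integer vector: number of bands per attribute (defaults to
#'   the discretizer's counts when `discretizer` is given, else the maximum
#'   observed band).
#' @param m parent frequency threshold: attribute values seen fewer than `m`
#'   times in training do not anchor a one-dependence estimator.
#' @param discretizer optional `appia_discretizer` stored with the model so
#'   [predict.appia_aode()] can consume raw feature tables.
#' @return an `appia_aode` model.
#' @export
fit_aode <- function(X, y, nvals = NULL, m = 1L, discretizer = NULL) {
  if (!is.null(discretizer) && !is.matrix(X)) X <- discretize(X, discretizer)
  tr <- check_training(X, y)
  X <- tr$X; y <- tr$y; classes <- tr$classes
  A <- ncol(X)
  attrs <- colnames(X) %||% paste0("x", seq_len(A))
  if (is.null(nvals))
    nvals <- if (!is.null(discretizer)) as.integer(discretizer$nvals[attrs])
             else pmax(1L, apply(X, 2L, function(v) max(v, 0L, na.rm = TRUE)))
  stopifnot(length(nvals) == A)
  yf <- factor(y, levels = classes)
  joint <- vector("list", A)
  pair <- rep(list(vector("list", A)), A)
  n_known <- integer(A)
  for (i in seq_len(A)) {
    xi <- factor(X[, i], levels = seq_len(nvals[i]))
    n_known[i] <- sum(!is.na(X[, i]))
    joint[[i]] <- unclass(table(xi, yf))
    for (j in seq_len(A)) {
      if (j == i) next
      xj <- factor(X[, j], levels = seq_len(nvals[j]))
      pair[[i]][[j]] <- unclass(table(xj, yf, xi))
    }
  }
  structure(list(classes = classes, attrs = attrs, nvals = as.integer(nvals),
                 N = nrow(X),
                 n_class = as.vector(table(yf)),
                 n_known = n_known,
                 joint = joint, pair = pair,
                 m = as.integer(m),
                 discretizer = discretizer),
            class = "appia_aode")
}

#' Fit the Naive Bayes baseline
#'
#' Zero-dependence estimator sharing AODE's smoothing and missing-value
#' semantics: the class-conditional term of attribute `i` is estimated from
#' the same smoothed joint `P(y, x_i)` used by AODE, so a single known
#' attribute yields exactly the AODE posterior.
#'
#' @inheritParams fit_aode
#' @return an `appia_nb` model.
#' @export
fit_nb <- function(X, y, nvals = NULL, discretizer = NULL) {
  if (!is.null(discretizer) && !is.matrix(X)) X <- discretize(X, discretizer)
  tr <- check_training(X, y)
  X <- tr$X; y <- tr$y; classes <- tr$classes
  A <- ncol(X)
  attrs <- colnames(X) %||% paste0("x", seq_len(A))
  if (is.null(nvals))
    nvals <- if (!is.null(discretizer)) as.integer(discretizer$nvals[attrs])
             else pmax(1L, apply(X, 2L, function(v) max(v, 0L, na.rm = TRUE)))
  yf <- factor(y, levels = classes)
  joint <- vector("list", A)
  n_known <- integer(A)
  for (i in seq_len(A)) {
    xi <- factor(X[, i], levels = seq_len(nvals[i]))
    n_known[i] <- sum(!is.na(X[, i]))
    joint[[i]] <- unclass(table(xi, yf))
  }
  structure(list(classes = classes, attrs = attrs, nvals = as.integer(nvals),
                 N = nrow(X),
                 n_class = as.vector(table(yf)),
                 n_known = n_known,
                 joint = joint,
                 discretizer = discretizer),
            class = "appia_nb")
}

# Smoothed log joint log P(y, x_i) per attribute: (N(y,x_i)+1)/(N_i + k v_i).
smoothed_log_joint <- function(model) {
  k <- length(model$classes)
  lapply(seq_along(model$attrs), function(i)
    log((model$joint[[i]] + 1) / (model$n_known[i] + k * model$nvals[i])))
}

# Coerce prediction input to the band matrix the model expects.
as_band_matrix <- function(model, newdata) {
  if (is.matrix(newdata)) {
    X <- newdata
  } else if (!is.null(model$discretizer)) {
    X <- discretize(newdata, model$discretizer)
  } else {
    X <- as.matrix(as.data.table(newdata)[, model$attrs, with = FALSE])
  }
  storage.mode(X) <- "integer"
  if (!is.null(colnames(X))) {
    miss <- setdiff(model$attrs, colnames(X))
    if (length(miss))
      abort_appia("prediction data lacks attribute(s): %s",
                  paste(miss, collapse = ", "))
    X <- X[, model$attrs, drop = FALSE]
  } else stopifnot(ncol(X) == length(model$attrs))
  # clamp bands that exceed the model's range (robustness for hand-made data)
  for (i in seq_len(ncol(X))) {
    bad <- !is.na(X[, i]) & (X[, i] < 1L | X[, i] > model$nvals[i])
    if (any(bad)) X[bad, i] <- pmin(pmax(X[bad, i], 1L), model$nvals[i])
  }
  X
}

nb_log_scores <- function(model, X) {
  k <- length(model$classes)
  n <- nrow(X)
  logJ <- smoothed_log_joint(model)
  log_prior <- log((model$n_class + 1) / (model$N + k))
  S <- matrix(rep(log_prior, each = n), n, k)
  for (i in seq_along(model$attrs)) {
    xi <- X[, i]
    kn <- which(!is.na(xi))
    if (!length(kn)) next
    for (yy in seq_len(k))
      S[kn, yy] <- S[kn, yy] + logJ[[i]][cbind(xi[kn], yy)] - log_prior[yy]
  }
  colnames(S) <- model$classes
  S
}

aode_scores <- function(model, X) {
  k <- length(model$classes)
  A <- length(model$attrs)
  n <- nrow(X)
  logJ <- smoothed_log_joint(model)
  qualifies <- lapply(seq_len(A), function(i)
    rowSums(model$joint[[i]]) >= model$m)
  S <- matrix(0, n, k, dimnames = list(NULL, model$classes))
  any_parent <- rep(FALSE, n)
  for (i in seq_len(A)) {
    xi <- X[, i]
    rows <- which(!is.na(xi) & qualifies[[i]][xi])
    if (!length(rows)) next
    any_parent[rows] <- TRUE
    xir <- xi[rows]
    acc <- matrix(0, length(rows), k)
    for (yy in seq_len(k)) acc[, yy] <- logJ[[i]][cbind(xir, yy)]
    for (j in seq_len(A)) {
      if (j == i) next
      xj <- X[rows, j]
      kn <- which(!is.na(xj))
      if (!length(kn)) next
      # log P(x_j | y, x_i) = log (N(x_j,y,x_i)+1) - log (N(y,x_i)+v_j)
      tab <- model$pair[[i]][[j]]
      for (yy in seq_len(k)) {
        num <- tab[cbind(xj[kn], yy, xir[kn])] + 1
        den <- model$joint[[i]][cbind(xir[kn], yy)] + model$nvals[j]
        acc[kn, yy] <- acc[kn, yy] + log(num) - log(den)
      }
    }
    S[rows, ] <- S[rows, ] + exp(acc)
  }
  # instances with no qualifying parent fall back to Naive Bayes over the
  # known attributes (an instance with nothing known gets the class prior)
  if (!all(any_parent)) {
    nb <- model[c("classes", "attrs", "nvals", "N", "n_class", "n_known",
                  "joint")]
    fb <- which(!any_parent)
    S[fb, ] <- exp(nb_log_scores(nb, X[fb, , drop = FALSE]))
  }
  S
}

#' Posterior class probabilities
#'
#' For each instance, `score(y)` sums over every known attribute `i` whose
#' training frequency reaches the parent threshold `m` the product
#' `P(y, x_i) * prod_j P(x_j | y, x_i)` over the other known attributes `j`;
#' scores are normalized to probabilities. Instances with no qualifying
#' parent attribute fall back to Naive Bayes over their known values;
#' prediction never errors on missing values.
#'
#' @param object fitted `appia_aode` model.
#' @param newdata band matrix from [discretize()], or a raw feature table if
#'   the model carries its discretizer.
#' @param type `"prob"` for the class probability matrix, `"class"` for
#'   labels.
#' @param threshold positive-class probability threshold for
#'   `type = "class"`: the label is positive iff `P(positive) >= threshold`.
#' @param positive name of the positive class (for `type = "class"`).
#' @param ... unused.
#' @return probability matrix (rows sum to 1) or character labels.
#' @export
predict.appia_aode <- function(object, newdata, type = c("prob", "class"),
                               threshold = 0.5, positive = "positive", ...) {
  type <- match.arg(type)
  X <- as_band_matrix(object, newdata)
  S <- aode_scores(object, X)
  P <- S / rowSums(S)
  if (type == "prob") return(P)
  stopifnot(positive %in% object$classes)
  neg <- setdiff(object$classes, positive)[1L]
  ifelse(P[, positive] >= threshold, positive, neg)
}

#' @rdname predict.appia_aode
#' @export
predict.appia_nb <- function(object, newdata, type = c("prob", "class"),
                             threshold = 0.5, positive = "positive", ...) {
  type <- match.arg(type)
  X <- as_band_matrix(object, newdata)
  L <- nb_log_scores(object, X)
  L <- L - apply(L, 1L, max)
  P <- exp(L) / rowSums(exp(L))
  if (type == "prob") return(P)
  stopifnot(positive %in% object$classes)
  neg <- setdiff(object$classes, positive)[1L]
  ifelse(P[, positive] >= threshold, positive, neg)
}

#' @export
print.appia_aode <- function(x, ...) {
  cat(sprintf("<appia_aode> %d attributes, classes {%s}, N = %d, m = %d\n",
              length(x$attrs), paste(x$classes, collapse = ", "), x$N, x$m))
  invisible(x)
}

#' @export
print.appia_nb <- function(x, ...) {
  cat(sprintf("<appia_nb> %d attributes, classes {%s}, N = %d\n",
              length(x$attrs), paste(x$classes, collapse = ", "), x$N))
  invisible(x)
}
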