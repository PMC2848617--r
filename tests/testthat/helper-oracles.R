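# Independent oracle implementations: brute-force expansions written with
# plain loops and direct counting, sharing no code path with the package.

# Brute-force AODE posterior for one instance (vector with NA = missing).
# Materializes every one-dependence estimator explicitly.
oracle_aode <- function(X, y, inst, nvals, m = 1L) {
  classes <- sort(unique(y))
  k <- length(classes)
  A <- ncol(X)
  known <- which(!is.na(inst))
  score <- setNames(numeric(k), classes)
  for (cl in classes) {
    total <- 0
    for (i in known) {
      freq_xi <- sum(!is.na(X[, i]) & X[, i] == inst[i])
      if (freq_xi < m) next
      n_i <- sum(!is.na(X[, i]))
      n_y_xi <- sum(y == cl & !is.na(X[, i]) & X[, i] == inst[i])
      term <- (n_y_xi + 1) / (n_i + k * nvals[i])
      for (j in known) {
        if (j == i) next
        n_xj_y_xi <- sum(y == cl &
                           !is.na(X[, i]) & X[, i] == inst[i] &
                           !is.na(X[, j]) & X[, j] == inst[j])
        term <- term * (n_xj_y_xi + 1) / (n_y_xi + nvals[j])
      }
      total <- total + term
    }
    score[cl] <- total
  }
  if (all(score == 0)) score <- oracle_nb_scores(X, y, inst, nvals)
  score / sum(score)
}

# Brute-force NB scores with the same smoothed joint estimator:
# score(y) = P(y) * prod_i [ P(y, x_i) / P(y) ].
oracle_nb_scores <- function(X, y, inst, nvals) {
  classes <- sort(unique(y))
  k <- length(classes)
  known <- which(!is.na(inst))
  score <- setNames(numeric(k), classes)
  for (cl in classes) {
    prior <- (sum(y == cl) + 1) / (length(y) + k)
    s <- prior
    for (i in known) {
      n_i <- sum(!is.na(X[, i]))
      n_y_xi <- sum(y == cl & !is.na(X[, i]) & X[, i] == inst[i])
      s <- s * ((n_y_xi + 1) / (n_i + k * nvals[i])) / prior
    }
    score[cl] <- s
  }
  score
}

oracle_nb <- function(X, y, inst, nvals) {
  s <- oracle_nb_scores(X, y, inst, nvals)
  s / sum(s)
}

# Dense-grid lower envelope: pointwise min of lines over a pc grid.
oracle_envelope_grid <- function(intercept, slope, pc) {
  vapply(pc, function(x) min(intercept + slope * x), numeric(1))
}

# Genomic gap by integer enumeration: number of base positions strictly
# between the two 1-based inclusive intervals (0 when they touch/overlap).
oracle_gap <- function(a_start, a_end, b_start, b_end) {
  pos <- seq(min(a_start, b_start), max(a_end, b_end))
  covered <- (pos >= a_start & pos <= a_end) | (pos >= b_start & pos <= b_end)
  inner <- pos > min(a_end, b_end) & pos < max(a_start, b_start)
  if (any(pos >= a_start & pos <= a_end & pos >= b_start & pos <= b_end))
    return(0L)
  sum(inner & !covered)
}

# Brute-force I2H: enumerate all inter-protein column pairs with plain loops
# and stats::cor on McLachlan similarity vectors.
oracle_i2h <- function(aln_a, aln_b, r_cut = 0.5, min_common = 11L,
                       max_gap_frac = 0.5) {
  mcl <- mclachlan_matrix()
  split_rows <- function(aln)
    do.call(rbind, strsplit(toupper(aln$seqs), "", fixed = TRUE))
  ma <- split_rows(aln_a); rownames(ma) <- names(aln_a$seqs)
  mb <- split_rows(aln_b); rownames(mb) <- names(aln_b$seqs)
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) < min_common) return(NA_real_)
  # gap fraction relative to the alignment's own rows
  gap_a <- which(colMeans(matrix(!ma %in% rownames(mcl), nrow(ma))) <= max_gap_frac)
  gap_b <- which(colMeans(matrix(!mb %in% rownames(mcl), nrow(mb))) <= max_gap_frac)
  ma <- ma[common, , drop = FALSE]; mb <- mb[common, , drop = FALSE]
  n <- length(common)
  vals <- c(); defined <- 0L; hits <- 0L
  for (i in gap_a) {
    for (j in gap_b) {
      si <- c(); sj <- c()
      for (p in seq_len(n - 1L)) {
        for (q in (p + 1L):n) {
          ok <- all(c(ma[p, i], ma[q, i]) %in% rownames(mcl)) &&
                all(c(mb[p, j], mb[q, j]) %in% rownames(mcl))
          if (ok) {
            si <- c(si, mcl[ma[p, i], ma[q, i]])
            sj <- c(sj, mcl[mb[p, j], mb[q, j]])
          }
        }
      }
      # need at least 4 usable species rows, i.e. >= 6 species pairs
      if (length(si) < 6L) next
      if (stats::var(si) == 0 || stats::var(sj) == 0) next
      r <- stats::cor(si, sj)
      defined <- defined + 1L
      if (r >= r_cut) hits <- hits + 1L
    }
  }
  if (defined == 0L) return(NA_real_)
  hits / defined
}
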