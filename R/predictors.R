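# The five evolutionary association predictors.
#
# PP  phylogenetic profiles: Hamming distance between presence/absence
#     vectors over the genome panel (smaller = stronger).
# GC  gene-context conservation: number of genomes in which the two
#     orthologs lie closer than 300 bp on the same contig.
# GF  gene fusion: externally supplied z-scores, passed through.
# MT  mirror tree: Pearson correlation of the two proteins' ortholog
#     sequence distance matrices over their common species.
# I2H in silico two-hybrid: fraction of inter-protein alignment column
#     pairs whose McLachlan similarity patterns across species pairs
#     correlate at or above r_cut.

AA_ORDER <- c("A","C","D","E","F","G","H","I","K","L",
              "M","N","P","Q","R","S","T","V","W","Y")

.appia_cache <- new.env(parent = emptyenv())

#' McLachlan amino-acid similarity matrix
#'
#' The 20x20 integer similarity matrix of McLachlan (1972), shipped as a
#' plain-text data file. Used by the in silico two-hybrid predictor to turn
#' residue pairs into similarity values.
#'
#' @return numeric 20x20 matrix with residue dimnames.
#' @export
mclachlan_matrix <- function() {
  if (is.null(.appia_cache$mcl)) {
    path <- system.file("extdata", "mclachlan.tsv", package = "appia",
                        mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L])
    rownames(m) <- df[[1L]]
    stopifnot(identical(rownames(m), colnames(m)), isSymmetric(m))
    .appia_cache$mcl <- m[AA_ORDER, AA_ORDER]
  }
  .appia_cache$mcl
}

# Alignment -> integer residue matrix (rows = species, NA = gap/unknown).
aln_int_matrix <- function(aln) {
  stopifnot(inherits(aln, "appia_alignment"))
  chars <- do.call(rbind, strsplit(toupper(aln$seqs), "", fixed = TRUE))
  rownames(chars) <- names(aln$seqs)
  m <- match(chars, AA_ORDER)
  dim(m) <- dim(chars)
  dimnames(m) <- dimnames(chars)
  m
}

# ---------------------------------------------------------------------------
# Phylogenetic profiles

#' Build a phylogenetic profile
#'
#' Presence(1)/absence(0) of the protein's orthologs across the genome panel,
#' in the panel's genome order.
#'
#' @param protein protein id (must appear in the table, possibly with zero
#'   orthologs).
#' @param table an `appia_orthologs` object.
#' @return named integer 0/1 vector, one element per genome.
#' @export
build_profile <- function(protein, table) {
  stopifnot(inherits(table, "appia_orthologs"))
  if (!protein %in% table$proteins)
    abort_appia("protein '%s' not in ortholog table", protein)
  present <- table$entries[protein, genome, on = "protein", nomatch = NULL]
  setNames(as.integer(table$genomes %in% present), table$genomes)
}

#' Phylogenetic-profile (PP) score: Hamming distance
#'
#' Number of genomes in which exactly one of the two proteins has an
#' ortholog. Smaller values indicate stronger association.
#'
#' @param a,b profiles from [build_profile()] (equal length).
#' @return non-negative integer.
#' @export
pp_score <- function(a, b) {
  if (length(a) != length(b))
    abort_appia("profile length mismatch (%d vs %d)", length(a), length(b))
  sum(a != b)
}

# All-pairs Hamming distances from the presence matrix (proteins x genomes).
presence_matrix <- function(table) {
  X <- matrix(0L, nrow = length(table$proteins), ncol = length(table$genomes),
              dimnames = list(table$proteins, table$genomes))
  if (nrow(table$entries))
    X[cbind(table$entries$protein, table$entries$genome)] <- 1L
  X
}

#' All-pairs PP scores
#'
#' @param table an `appia_orthologs` object.
#' @return pair-score `data.table` (`idA`, `idB`, `method = "PP"`, `score`)
#'   over all unordered protein pairs in the table.
#' @export
score_pp_all <- function(table) {
  X <- presence_matrix(table)
  n <- nrow(X)
  if (n < 2L)
    return(data.table(idA = character(), idB = character(),
                      method = character(), score = numeric()))
  rs <- rowSums(X)
  H <- outer(rs, rs, "+") - 2 * tcrossprod(X)
  iu <- which(upper.tri(H), arr.ind = TRUE)
  ids <- rownames(X)
  cp <- canonical_pair(ids[iu[, 1L]], ids[iu[, 2L]])
  cp[, `:=`(method = "PP", score = as.numeric(H[iu]))]
  cp[]
}

# ---------------------------------------------------------------------------
# Gene context

#' Genomic distance between two gene locations
#'
#' 1-based inclusive intervals. Different genome or contig gives `NA`
#' (undefined); overlapping intervals give 0; otherwise the gap
#' `max(start) - min(end) - 1` in base pairs. Strand is ignored.
#'
#' @param la,lb single-row gene locations (lists or 1-row data.frames with
#'   `genome`, `contig`, `start`, `end`).
#' @return base pairs, or `NA` when the distance is undefined.
#' @export
neighborhood_distance <- function(la, lb) {
  if (la$genome != lb$genome || la$contig != lb$contig) return(NA_integer_)
  if (la$start > lb$end || lb$start > la$end)
    return(as.integer(max(la$start, lb$start) - min(la$end, lb$end) - 1L))
  0L
}

#' Gene-context (GC) score for one pair
#'
#' Number of genomes in which both proteins have orthologs with known
#' coordinates lying strictly closer than `threshold` base pairs on the same
#' contig. Larger values indicate stronger association.
#'
#' @param a,b protein ids.
#' @param table an `appia_orthologs` object.
#' @param coords coordinate table from [read_gene_coordinates()].
#' @param threshold strict upper bound on the genomic distance (bp).
#' @return non-negative integer count.
#' @export
gc_score <- function(a, b, table, coords, threshold = 300L) {
  ea <- table$entries[a, on = "protein", nomatch = NULL]
  eb <- table$entries[b, on = "protein", nomatch = NULL]
  shared <- intersect(ea$genome, eb$genome)
  count <- 0L
  for (g in shared) {
    la <- coords[.(g, ea[genome == g, gene]), on = c("genome", "gene"),
                 nomatch = NULL]
    lb <- coords[.(g, eb[genome == g, gene]), on = c("genome", "gene"),
                 nomatch = NULL]
    if (nrow(la) != 1L || nrow(lb) != 1L) next
    d <- neighborhood_distance(as.list(la), as.list(lb))
    if (!is.na(d) && d < threshold) count <- count + 1L
  }
  count
}

#' All-pairs GC scores
#'
#' Sweep over each genome's gene ladder (sorted by contig and start) and
#' collect ortholog pairs closer than `threshold` bp; a pair's score is the
#' number of genomes in which that happens. Pairs never observed near each
#' other are absent from the result (score semantics: only observed counts
#' are evidence; a zero count is not reported as a prediction).
#'
#' @inheritParams gc_score
#' @return pair-score `data.table` (`idA`, `idB`, `method = "GC"`, `score`).
#' @export
score_gc_all <- function(table, coords, threshold = 300L) {
  empty <- data.table(idA = character(), idB = character(),
                      method = character(), score = numeric())
  if (!nrow(table$entries) || !nrow(coords)) return(empty)
  genes <- merge(coords, table$entries,
                 by.x = c("genome", "gene"), by.y = c("genome", "gene"))
  if (!nrow(genes)) return(empty)
  data.table::setorder(genes, genome, contig, start, end)
  hits <- vector("list", 0L)
  for (gset in split(genes, by = c("genome", "contig"), drop = TRUE)) {
    n <- nrow(gset)
    if (n < 2L) next
    st <- gset$start; en <- gset$end; pr <- gset$protein
    out_a <- character(0); out_b <- character(0)
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n) {
        d <- if (st[j] <= en[i]) 0L else st[j] - en[i] - 1L
        if (d >= threshold) break   # starts sorted: gap only grows with j
        if (pr[i] != pr[j]) {
          out_a <- c(out_a, pr[i]); out_b <- c(out_b, pr[j])
        }
        j <- j + 1L
      }
    }
    if (length(out_a))
      hits[[length(hits) + 1L]] <-
        unique(cbind(canonical_pair(out_a, out_b),
                     genome = gset$genome[1L], contig = gset$contig[1L]))
  }
  if (!length(hits)) return(empty)
  all_hits <- unique(data.table::rbindlist(hits),
                     by = c("idA", "idB", "genome"))
  res <- all_hits[, .(score = as.numeric(.N)), by = .(idA, idB)]
  res[, method := "GC"]
  data.table::setcolorder(res, c("idA", "idB", "method", "score"))
  data.table::setkey(res, idA, idB)
  res[]
}

# ---------------------------------------------------------------------------
# Gene fusion

#' Ingest external gene-fusion (GF) z-scores
#'
#' GF evidence is consumed, not computed: the reader passes externally
#' collected z-scores through unchanged. Duplicate pairs keep the maximum
#' score. Larger values indicate stronger association.
#'
#' @param path TSV pair list with a numeric third column, or a `data.table`
#'   already carrying `idA`, `idB`, `score`.
#' @return pair-score `data.table` (`idA`, `idB`, `method = "GF"`, `score`).
#' @export
ingest_gf <- function(path) {
  pairs <- if (is.character(path)) read_pair_list(path, source = "gf")
           else as.data.table(path)
  if (nrow(pairs) == 0L)
    return(data.table(idA = character(), idB = character(),
                      method = character(), score = numeric()))
  if (!"score" %in% names(pairs))
    abort_format("gene-fusion input must carry a numeric score column")
  out <- canonical_pair(pairs$idA, pairs$idB)
  out[, score := as.numeric(pairs$score)]
  out <- out[idA != idB]
  out <- out[, .(score = max(score)), by = .(idA, idB)]
  out[, method := "GF"]
  data.table::setcolorder(out, c("idA", "idB", "method", "score"))
  data.table::setkey(out, idA, idB)
  out[]
}

# ---------------------------------------------------------------------------
# Mirror tree

#' Sequence distance matrix of an ortholog alignment
#'
#' Distance between two aligned rows is `1 - identity` over the columns where
#' neither row has a gap. A pair of rows with zero comparable columns is an
#' error.
#'
#' @param aln an `appia_alignment` with at least two rows.
#' @return symmetric numeric matrix in `[0, 1]` with species dimnames and
#'   zero diagonal.
#' @export
distance_matrix <- function(aln) {
  M <- aln_int_matrix(aln)
  n <- nrow(M)
  if (n < 2L) abort_appia("distance_matrix: need >= 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(M[i, ]) & !is.na(M[j, ])
      nc <- sum(ok)
      if (nc == 0L)
        abort_appia("distance_matrix: rows '%s' and '%s' share no ungapped columns",
                    rownames(M)[i], rownames(M)[j])
      d[i, j] <- d[j, i] <- 1 - sum(M[i, ok] == M[j, ok]) / nc
    }
  }
  d
}

#' Mirror-tree (MT) score
#'
#' Pearson correlation of the two distance matrices restricted to their
#' common species, computed over the strict upper triangles. Returns `NA`
#' (missing) when fewer than `min_common` species are shared or when either
#' triangle has zero variance. Larger values indicate stronger association.
#'
#' @param da,db distance matrices from [distance_matrix()].
#' @param min_common minimum number of common species for a defined score.
#' @return Pearson r in `[-1, 1]`, or `NA`.
#' @export
mt_score <- function(da, db, min_common = 11L) {
  common <- intersect(rownames(da), rownames(db))
  if (length(common) < min_common) return(NA_real_)
  ta <- da[common, common][upper.tri(diag(length(common)))]
  tb <- db[common, common][upper.tri(diag(length(common)))]
  if (stats::var(ta) == 0 || stats::var(tb) == 0) {
    appia_log("mt_score: zero variance in a distance triangle; missing")
    return(NA_real_)
  }
  stats::cor(ta, tb)
}

# ---------------------------------------------------------------------------
# In silico two-hybrid

#' McLachlan similarity correlation of two alignment columns
#'
#' For every unordered pair of the paired species rows carrying residues
#' (no gap) at both columns, the McLachlan similarity of the residues at
#' column `i` is correlated with the similarity at column `j`.
#'
#' @param col_i,col_j character vectors of residues, paired by species (same
#'   length and order; `"-"` marks a gap).
#' @param min_rows minimum number of usable species rows for a defined value.
#' @return Pearson r in `[-1, 1]`, or `NA` when fewer than `min_rows` rows
#'   are usable or either column's similarity pattern has zero variance.
#' @export
mclachlan_site_correlation <- function(col_i, col_j, min_rows = 4L) {
  stopifnot(length(col_i) == length(col_j))
  mcl <- mclachlan_matrix()
  ri <- match(toupper(col_i), AA_ORDER)
  rj <- match(toupper(col_j), AA_ORDER)
  ok <- !is.na(ri) & !is.na(rj)
  if (sum(ok) < min_rows) return(NA_real_)
  ri <- ri[ok]; rj <- rj[ok]
  pr <- which(upper.tri(diag(length(ri))), arr.ind = TRUE)
  si <- mcl[cbind(ri[pr[, 1L]], ri[pr[, 2L]])]
  sj <- mcl[cbind(rj[pr[, 1L]], rj[pr[, 2L]])]
  if (stats::var(si) == 0 || stats::var(sj) == 0) return(NA_real_)
  stats::cor(si, sj)
}

# Per-alignment I2H work matrix: for a fixed species vector, rows are the
# C(n,2) species pairs and columns the alignment columns that pass the gap
# filter; cell = McLachlan similarity of the two species' residues (NA when
# either is a gap or the species is absent from the alignment). Returned as
# the stacked [mask; sim; sim^2] block so that one cross-product against
# another stack yields all pairwise-complete correlation moments.
i2h_stack <- function(aln, species, max_gap_frac = 0.5) {
  mcl <- mclachlan_matrix()
  M <- aln_int_matrix(aln)
  L <- ncol(M)
  n <- length(species)
  R <- matrix(NA_integer_, n, L, dimnames = list(species, NULL))
  hit <- intersect(species, rownames(M))
  R[hit, ] <- M[hit, , drop = FALSE]
  gap_frac <- colMeans(is.na(M))           # alignment-own gap fraction
  keep <- which(gap_frac <= max_gap_frac)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  S <- matrix(NA_real_, nrow(pr), L)
  if (length(keep)) {
    Rk <- R[, keep, drop = FALSE]
    a <- Rk[pr[, 1L], , drop = FALSE]
    b <- Rk[pr[, 2L], , drop = FALSE]
    vals <- matrix(NA_real_, nrow(pr), length(keep))
    okk <- !is.na(a) & !is.na(b)
    vals[okk] <- mcl[cbind(a[okk], b[okk])]
    S[, keep] <- vals
  }
  G <- !is.na(S)
  S0 <- ifelse(G, S, 0)
  list(stack = cbind(G + 0, S0, S0 * S0), L = L,
       n_species = length(intersect(species, rownames(M))))
}

# Correlation matrix (columns of A x columns of B) from two stacks, using
# pairwise-complete moments; entries with fewer than 4 usable rows
# (6 species pairs) or zero variance are NA.
i2h_cor_from_stacks <- function(sa, sb, min_pairs = 6L) {
  La <- sa$L; Lb <- sb$L
  Z <- crossprod(sa$stack, sb$stack)
  ia <- seq_len(La); ib <- seq_len(Lb)
  n   <- Z[ia,        ib,        drop = FALSE]
  Sy  <- Z[ia,        Lb + ib,   drop = FALSE]
  Syy <- Z[ia,        2L * Lb + ib, drop = FALSE]
  Sx  <- Z[La + ia,   ib,        drop = FALSE]
  Sxy <- Z[La + ia,   Lb + ib,   drop = FALSE]
  Sxx <- Z[2L * La + ia, ib,     drop = FALSE]
  vx <- n * Sxx - Sx * Sx
  vy <- n * Syy - Sy * Sy
  r <- (n * Sxy - Sx * Sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  # similarity values are integers, so exact-zero variance is detectable
  r[n < min_pairs | vx < 0.5 | vy < 0.5] <- NA_real_
  r
}

#' In silico two-hybrid (I2H) score
#'
#' Fraction of defined inter-protein column pairs (column i of alignment A
#' against column j of alignment B, species paired across the two
#' alignments) whose McLachlan similarity correlation is at least `r_cut`.
#' Columns with more than `max_gap_frac` gaps in their own alignment are
#' excluded. Missing (`NA`) when the alignments share fewer than
#' `min_common` species or no column pair is defined. Larger values indicate
#' stronger association.
#'
#' @param aln_a,aln_b `appia_alignment` objects.
#' @param r_cut correlation cutoff declaring a co-varying column pair.
#' @param min_common minimum number of shared species.
#' @param max_gap_frac maximum per-column gap fraction.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
i2h_score <- function(aln_a, aln_b, r_cut = 0.5, min_common = 11L,
                      max_gap_frac = 0.5) {
  common <- intersect(names(aln_a$seqs), names(aln_b$seqs))
  if (length(common) < min_common) return(NA_real_)
  sa <- i2h_stack(aln_a, common, max_gap_frac)
  sb <- i2h_stack(aln_b, common, max_gap_frac)
  r <- i2h_cor_from_stacks(sa, sb)
  defined <- !is.na(r)
  if (!any(defined)) return(NA_real_)
  mean(r[defined] >= r_cut)
}

# ---------------------------------------------------------------------------
# Bulk MT / I2H over many alignment pairs (shared species panel)

# MT stack: distances indexed by panel species pairs, masked where a species
# is missing from the alignment.
mt_stack <- function(dmat, species) {
  n <- length(species)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  d <- rep(NA_real_, nrow(pr))
  hit <- match(species, rownames(dmat))
  i1 <- hit[pr[, 1L]]; i2 <- hit[pr[, 2L]]
  ok <- !is.na(i1) & !is.na(i2)
  d[ok] <- dmat[cbind(i1[ok], i2[ok])]
  g <- !is.na(d)
  d0 <- ifelse(g, d, 0)
  cbind(g = g + 0, d = d0, d2 = d0 * d0)
}

# Pairwise-complete Pearson r between two masked vectors from their stacks.
masked_cor <- function(sa, sb, min_n) {
  Z <- crossprod(sa, sb)
  n <- Z["g", "g"]
  if (n < min_n) return(NA_real_)
  vx <- n * Z["d2", "g"] - Z["d", "g"]^2
  vy <- n * Z["g", "d2"] - Z["g", "d"]^2
  if (vx <= 0 || vy <= 0) return(NA_real_)
  (n * Z["d", "d"] - Z["d", "g"] * Z["g", "d"]) / sqrt(vx * vy)
}

#' Bulk MT and I2H scores over candidate pairs
#'
#' Computes mirror-tree and in silico two-hybrid scores for every unordered
#' pair of the supplied alignments (or a given candidate pair set), sharing
#' per-alignment precomputation. Alignments must use species ids from
#' `genomes`.
#'
#' @param alignments named list of `appia_alignment` objects (names =
#'   protein ids).
#' @param genomes character vector: the genome/species panel.
#' @param pairs optional `data.table` (`idA`, `idB`) of candidate pairs;
#'   default all unordered pairs of aligned proteins.
#' @param min_common,r_cut,max_gap_frac as in [mt_score()] / [i2h_score()].
#' @param methods subset of `c("MT", "I2H")` to compute.
#' @return pair-score `data.table` (`idA`, `idB`, `method`, `score`), missing
#'   scores omitted.
#' @export
score_coevolution_pairs <- function(alignments, genomes, pairs = NULL,
                                    min_common = 11L, r_cut = 0.5,
                                    max_gap_frac = 0.5,
                                    methods = c("MT", "I2H")) {
  empty <- data.table(idA = character(), idB = character(),
                      method = character(), score = numeric())
  prot <- names(alignments)
  if (length(prot) < 2L) return(empty)
  if (is.null(pairs)) {
    iu <- utils::combn(sort(prot), 2L)
    pairs <- data.table(idA = iu[1L, ], idB = iu[2L, ])
  } else {
    pairs <- canonical_pair(pairs$idA, pairs$idB)
    pairs <- pairs[idA %in% prot & idB %in% prot & idA != idB]
    pairs <- unique(pairs, by = c("idA", "idB"))
  }
  if (!nrow(pairs)) return(empty)
  n_panel_pairs <- choose(length(genomes), 2L)
  do_mt <- "MT" %in% methods
  do_i2h <- "I2H" %in% methods
  used <- union(pairs$idA, pairs$idB)
  mt_stacks <- if (do_mt) setNames(vector("list", length(used)), used)
  i2h_stacks <- if (do_i2h) setNames(vector("list", length(used)), used)
  n_sp <- setNames(integer(length(used)), used)
  pres <- matrix(FALSE, length(used), length(genomes),
                 dimnames = list(used, genomes))
  for (p in used) {
    aln <- alignments[[p]]
    sp <- intersect(genomes, names(aln$seqs))
    n_sp[p] <- length(sp)
    pres[p, sp] <- TRUE
    if (do_mt) mt_stacks[[p]] <- mt_stack(distance_matrix(aln), genomes)
    if (do_i2h) i2h_stacks[[p]] <- i2h_stack(aln, genomes, max_gap_frac)
  }
  min_tri <- choose(min_common, 2L)
  res_mt <- rep(NA_real_, nrow(pairs))
  res_i2h <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$idA[k]; b <- pairs$idB[k]
    n_common <- sum(pres[a, ] & pres[b, ])
    if (n_common < min_common) next
    if (do_mt)
      res_mt[k] <- masked_cor(mt_stacks[[a]], mt_stacks[[b]], min_tri)
    if (do_i2h) {
      r <- i2h_cor_from_stacks(i2h_stacks[[a]], i2h_stacks[[b]])
      defined <- !is.na(r)
      if (any(defined)) res_i2h[k] <- mean(r[defined] >= r_cut)
    }
  }
  out <- list()
  if (do_mt && any(!is.na(res_mt)))
    out$mt <- data.table(idA = pairs$idA, idB = pairs$idB, method = "MT",
                         score = res_mt)[!is.na(score)]
  if (do_i2h && any(!is.na(res_i2h)))
    out$i2h <- data.table(idA = pairs$idA, idB = pairs$idB, method = "I2H",
                          score = res_i2h)[!is.na(score)]
  if (!length(out)) return(empty)
  data.table::rbindlist(out)
}
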