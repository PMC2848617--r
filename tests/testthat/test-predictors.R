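# The five method scores: worked examples, metric/symmetry properties, and
# agreement between the bulk scorers and the per-pair contract functions.

test_that("phylogenetic profiles follow the ortholog table", {
  tab <- mk_table(paste0("g", 1:4),
                  list(pA = c("g1", "g3"), pB = character(0),
                       pC = paste0("g", 1:4)))
  expect_identical(unname(build_profile("pA", tab)), c(1L, 0L, 1L, 0L))
  expect_identical(unname(build_profile("pB", tab)), rep(0L, 4))
  expect_identical(unname(build_profile("pC", tab)), rep(1L, 4))
  expect_error(build_profile("nope", tab), class = "appia_error")
})

test_that("pp_score is the Hamming distance", {
  expect_identical(pp_score(c(1L, 0L, 1L), c(1L, 0L, 1L)), 0L)
  expect_identical(pp_score(c(1,0,1,1,0), c(1,0,0,1,1)), 2L)
  a <- rep(c(1L, 0L), length.out = 118)
  expect_identical(pp_score(a, 1L - a), 118L)
  expect_error(pp_score(c(1L, 0L), c(1L, 0L, 1L)), class = "appia_error")
})

test_that("pp_score is a metric (property over random profiles)", {
  set.seed(11)
  for (rep in 1:50) {
    a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5); c <- rbinom(30, 1, 0.5)
    expect_identical(pp_score(a, b), pp_score(b, a))
    expect_identical(pp_score(a, b) == 0L, all(a == b))
    expect_lte(pp_score(a, b), pp_score(a, c) + pp_score(c, b))
  }
})

test_that("neighborhood_distance matches interval arithmetic", {
  loc <- function(s, e, genome = "g1", contig = "c1")
    list(genome = genome, contig = contig, start = s, end = e)
  expect_identical(neighborhood_distance(loc(100, 200), loc(350, 500)), 149L)
  expect_identical(oracle_gap(100, 200, 350, 500), 149L)
  expect_identical(neighborhood_distance(loc(100, 400), loc(300, 500)), 0L)
  expect_true(is.na(neighborhood_distance(loc(1, 10),
                                          loc(20, 30, contig = "c2"))))
  expect_true(is.na(neighborhood_distance(loc(1, 10),
                                          loc(20, 30, genome = "g2"))))
  # randomized agreement with the enumeration oracle
  set.seed(5)
  for (rep in 1:40) {
    s1 <- sample(1000, 1); e1 <- s1 + sample(0:500, 1)
    s2 <- sample(1000, 1); e2 <- s2 + sample(0:500, 1)
    expect_identical(neighborhood_distance(loc(s1, e1), loc(s2, e2)),
                     as.integer(oracle_gap(s1, e1, s2, e2)))
  }
})

test_that("gc_score counts genomes with distance strictly below 300", {
  tab <- mk_table(paste0("g", 1:3),
                  list(pA = c("g1", "g2", "g3"), pB = c("g1", "g2", "g3")))
  coords <- mk_coords(
    list("g1", "pA", "c1", 100, 200), list("g1", "pB", "c1", 301, 400),  # gap 100
    list("g2", "pA", "c1", 100, 200), list("g2", "pB", "c1", 451, 600),  # gap 250
    list("g3", "pA", "c1", 100, 200), list("g3", "pB", "c1", 501, 700))  # gap 300
  expect_identical(gc_score("pA", "pB", tab, coords), 2L)
  # never co-occurring orthologs
  tab2 <- mk_table(c("g1", "g2"), list(pA = "g1", pB = "g2"))
  expect_identical(gc_score("pA", "pB", tab2,
                            mk_coords(list("g1", "pA", "c1", 1, 10),
                                      list("g2", "pB", "c1", 1, 10))), 0L)
})

test_that("bulk GC scan agrees with the per-pair contract function", {
  w <- small_world(1)
  bulk <- score_gc_all(w$table, w$coords)
  expect_gt(nrow(bulk), 0L)
  set.seed(3)
  some <- bulk[sample(.N, min(15, .N))]
  for (k in seq_len(nrow(some)))
    expect_identical(gc_score(some$idA[k], some$idB[k], w$table, w$coords),
                     as.integer(some$score[k]))
  # pairs absent from the bulk result truly have no < 300 bp co-occurrence
  absent <- data.table::data.table(idA = "p0101", idB = "p0115")
  if (nrow(bulk[absent, on = c("idA", "idB"), nomatch = NULL]) == 0L)
    expect_identical(gc_score("p0101", "p0115", w$table, w$coords), 0L)
  # gc_score(pair) <= genomes containing orthologs of both proteins
  X <- with(w$table, {
    m <- matrix(0L, length(proteins), length(genomes),
                dimnames = list(proteins, genomes))
    m[cbind(entries$protein, entries$genome)] <- 1L
    m
  })
  expect_true(all(bulk$score <= rowSums(X[bulk$idA, , drop = FALSE] *
                                          X[bulk$idB, , drop = FALSE])))
})

test_that("distance_matrix implements gap-aware fractional identity", {
  aln <- ortholog_alignment("p", c(s1 = "AAAA", s2 = "AAAA"))
  expect_equal(unname(distance_matrix(aln)), matrix(0, 2, 2))
  aln2 <- ortholog_alignment("p", c(s1 = "AAAA", s2 = "AAAT"))
  expect_equal(distance_matrix(aln2)["s1", "s2"], 0.25)
  aln3 <- ortholog_alignment("p", c(s1 = "A-AA", s2 = "ATAA"))
  expect_equal(distance_matrix(aln3)["s1", "s2"], 0)
  aln4 <- ortholog_alignment("p", c(s1 = "A--", s2 = "-TT"))
  expect_error(distance_matrix(aln4), class = "appia_error")
})

test_that("mt_score behaves on identity, negation, overlap and variance", {
  set.seed(21)
  sp <- paste0("s", 1:12)
  d <- matrix(runif(144, 0, 0.9), 12, 12, dimnames = list(sp, sp))
  d <- (d + t(d)) / 2; diag(d) <- 0
  expect_equal(mt_score(d, d), 1.0)
  neg <- 1 - d; diag(neg) <- 0
  expect_equal(mt_score(d, neg), -1.0)
  expect_true(is.na(mt_score(d[1:5, 1:5], d[1:5, 1:5], min_common = 11)))
  flat <- matrix(0.5, 12, 12, dimnames = list(sp, sp)); diag(flat) <- 0
  # constant triangle: zero variance -> missing
  expect_true(is.na(suppressMessages(mt_score(flat, d))))
  # invariance under consistent species reordering
  perm <- sample(sp)
  expect_equal(mt_score(d[perm, perm], d), mt_score(d, d))
  d2 <- matrix(runif(144, 0, 0.9), 12, 12, dimnames = list(sp, sp))
  d2 <- (d2 + t(d2)) / 2; diag(d2) <- 0
  expect_equal(mt_score(d[perm, perm], d2[perm, perm]), mt_score(d, d2))
})

test_that("mclachlan_site_correlation matches a brute-force oracle", {
  expect_true(is.na(mclachlan_site_correlation(rep("A", 5), c("A","C","D","E","F"))))
  col <- c("A", "C", "D", "E", "F")
  expect_equal(mclachlan_site_correlation(col, col), 1.0)
  # 4-species toy: brute force over the 6 species pairs
  ci <- c("A", "C", "D", "E"); cj <- c("W", "W", "Y", "F")
  mcl <- mclachlan_matrix()
  si <- sj <- c()
  for (p in 1:3) for (q in (p + 1):4) {
    si <- c(si, mcl[ci[p], ci[q]]); sj <- c(sj, mcl[cj[p], cj[q]])
  }
  expect_equal(mclachlan_site_correlation(ci, cj), cor(si, sj))
  # gap rows excluded; fewer than 4 usable rows -> undefined
  expect_true(is.na(mclachlan_site_correlation(c("A", "C", "-", "E"),
                                               c("W", "W", "Y", "F"))))
})

test_that("i2h_score handles twin, invariant and toy alignments", {
  sp <- paste0("s", 1:12)
  set.seed(9)
  two_state <- sample(c("A", "W"), 12, replace = TRUE)
  two_state[1:2] <- c("A", "W")            # both states present
  other <- ifelse(two_state == "A", "C", "Y")
  aln <- ortholog_alignment("pA", setNames(paste0(two_state, other), sp))
  # twin columns co-vary perfectly: every defined pair at r = 1
  expect_equal(i2h_score(aln, aln, min_common = 11), 1.0)
  flat <- ortholog_alignment("pB", setNames(rep("AC", 12), sp))
  expect_true(is.na(i2h_score(flat, flat, min_common = 11)))
})

test_that("i2h_score equals brute-force enumeration on random alignments", {
  set.seed(31)
  sp <- paste0("s", 1:12)
  for (rep in 1:5) {
    mk <- function(protein, L) {
      m <- matrix(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
                         12 * L, replace = TRUE), 12, L)
      m[runif(12 * L) < 0.15] <- "-"
      ortholog_alignment(protein, setNames(apply(m, 1, paste, collapse = ""), sp))
    }
    a <- mk("pA", 6); b <- mk("pB", 5)
    expect_equal(i2h_score(a, b, min_common = 11),
                 oracle_i2h(a, b, min_common = 11))
  }
})

test_that("MT and I2H are symmetric in the pair and respect min_common", {
  set.seed(13)
  sp <- sprintf("g%03d", 1:20)
  pair <- generate_coupled_alignments(sp, coupling = 0.5, length = 30)
  expect_equal(mt_score(distance_matrix(pair$a), distance_matrix(pair$b)),
               mt_score(distance_matrix(pair$b), distance_matrix(pair$a)))
  expect_equal(i2h_score(pair$a, pair$b), i2h_score(pair$b, pair$a))
  few <- ortholog_alignment("pX", pair$a$seqs[1:5])
  expect_true(is.na(mt_score(distance_matrix(few), distance_matrix(pair$b))))
  expect_true(is.na(i2h_score(few, pair$b)))
})

test_that("bulk coevolution scorer agrees with per-pair contract functions", {
  w <- small_world(1)
  alns <- w$alignments[1:6]
  bulk <- score_coevolution_pairs(alns, w$table$genomes)
  prots <- names(alns)
  for (i in 1:(length(prots) - 1)) {
    for (j in (i + 1):length(prots)) {
      cp <- canonical_pair(prots[i], prots[j])
      mt_ref <- mt_score(distance_matrix(alns[[i]]), distance_matrix(alns[[j]]))
      i2h_ref <- i2h_score(alns[[i]], alns[[j]])
      got_mt <- bulk[cp, on = c("idA", "idB")][method == "MT", score]
      got_i2h <- bulk[cp, on = c("idA", "idB")][method == "I2H", score]
      if (is.na(mt_ref)) expect_length(got_mt, 0L)
      else expect_equal(got_mt, mt_ref, tolerance = 1e-12)
      if (is.na(i2h_ref)) expect_length(got_i2h, 0L)
      else expect_equal(got_i2h, i2h_ref, tolerance = 1e-12)
    }
  }
})

test_that("ingest_gf passes z-scores through and resolves duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t3.1", "b\ta\t2.0", "c\td\t-1"), path)
  gf <- ingest_gf(path)
  expect_identical(gf[idA == "a", score], 3.1)
  expect_identical(nrow(gf), 2L)
  expect_identical(unique(gf$method), "GF")
  writeLines(character(0), path)
  expect_identical(nrow(ingest_gf(path)), 0L)
  expect_error(ingest_gf(data.table::data.table(idA = "a", idB = "b")),
               class = "appia_format_error")
})
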