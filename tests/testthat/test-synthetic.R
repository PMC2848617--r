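# The synthetic world generator: determinism, file round-trips, and
# calibration of the plantable signals.

test_that("worlds are deterministic and files are byte-identical", {
  w1 <- generate_world(world_config(seed = 4))
  w2 <- generate_world(world_config(seed = 4))
  expect_equal(w1[setdiff(names(w1), "config")],
               w2[setdiff(names(w2), "config")])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, d1); write_world(w2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
})

test_that("every generated file parses through the io readers", {
  w <- small_world(1)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_no_warning({
    tab <- read_ortholog_table(file.path(dir, "orthologs.tsv"))
    coords <- read_gene_coordinates(
      list.files(file.path(dir, "gff"), full.names = TRUE))
    alns <- lapply(list.files(file.path(dir, "aln"), full.names = TRUE),
                   read_alignment)
    gf <- read_pair_list(file.path(dir, "gf.tsv"))
    pos <- lapply(list.files(file.path(dir, "positives"), full.names = TRUE),
                  read_pair_list)
    rec <- read_protein_records(file.path(dir, "records.tsv"))
  })
  expect_identical(tab$genomes, w$table$genomes)
  expect_length(alns, length(w$alignments))
  expect_identical(nrow(rec), length(w$proteins))
})

test_that("infeasible configurations are rejected", {
  expect_error(world_config(n_proteins = 10, n_positive_pairs = 6),
               class = "appia_error")
  expect_error(world_config(n_genomes = 8), class = "appia_error")
  expect_error(world_config(profile_correlation = 1.2),
               class = "appia_error")
})

test_that("generate_profile_pair hits its endpoints and expectation", {
  set.seed(10)
  ident <- generate_profile_pair(1, 118, p = 0.5)
  expect_identical(ident$a, ident$b)
  # rho = 0, p = 0.5, G = 118: expected Hamming distance 59
  dists <- replicate(1000, {
    pp <- generate_profile_pair(0, 118, p = 0.5)
    sum(pp$a != pp$b)
  })
  se <- sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - 59), 3 * se)
})

test_that("profile distance decreases with the correlation knob", {
  mean_dist <- function(rho, seed) {
    set.seed(seed)
    mean(replicate(200, {
      pp <- generate_profile_pair(rho, 118, p = 0.5)
      sum(pp$a != pp$b)
    }))
  }
  for (s in 1:10) {
    m0 <- mean_dist(0, s); m5 <- mean_dist(0.5, s); m9 <- mean_dist(0.9, s)
    expect_lt(m9, m5)
    expect_lt(m5, m0)
  }
})

test_that("fully coupled alignments give mirror-tree score exactly 1", {
  sp <- sprintf("g%03d", 1:20)
  for (s in 1:3) {
    set.seed(s)
    pair <- generate_coupled_alignments(sp, coupling = 1, length = 40)
    mt <- mt_score(distance_matrix(pair$a), distance_matrix(pair$b))
    expect_equal(mt, 1.0, tolerance = 1e-6)
  }
})

test_that("uncoupled alignments have mean mirror-tree score near zero", {
  sp <- sprintf("g%03d", 1:20)
  set.seed(100)
  mts <- replicate(50, {
    pair <- generate_coupled_alignments(sp, coupling = 0, length = 40)
    mt_score(distance_matrix(pair$a), distance_matrix(pair$b))
  })
  se <- sd(mts) / sqrt(length(mts))
  expect_lt(abs(mean(mts)), 3 * se)
})

test_that("mirror-tree signal is monotone in the coupling knob", {
  sp <- sprintf("g%03d", 1:20)
  mean_mt <- function(coupling, s) {
    set.seed(s)
    mean(replicate(8, {
      pair <- generate_coupled_alignments(sp, coupling, length = 40)
      mt_score(distance_matrix(pair$a), distance_matrix(pair$b))
    }))
  }
  wins <- 0L
  for (s in 1:10) {
    m <- c(mean_mt(0, s), mean_mt(0.5, s), mean_mt(1, s))
    if (m[1] < m[2] && m[2] < m[3]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("planted co-varying columns raise the I2H score", {
  sp <- sprintf("g%03d", 1:40)
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    pl <- generate_coupled_alignments(sp, coupling = 0.8, length = 50)
    pl <- plant_covarying_columns(pl$a, pl$b, n_cov = 15, flip = 0.05)
    nu <- generate_coupled_alignments(sp, coupling = 0, length = 50)
    if (isTRUE(i2h_score(pl$a, pl$b) > i2h_score(nu$a, nu$b)))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("forced adjacency makes gc_score equal the co-occurrence count", {
  cfg <- world_config(seed = 6, n_proteins = 60, n_positive_pairs = 10,
                      neighborhood_conservation = 1, n_align_extra = 0)
  w <- generate_world(cfg)
  gc <- score_gc_all(w$table, w$coords)
  X <- matrix(0L, length(w$proteins), length(w$genomes),
              dimnames = list(w$proteins, w$genomes))
  X[cbind(w$table$entries$protein, w$table$entries$genome)] <- 1L
  for (k in seq_len(nrow(w$planted))) {
    a <- w$planted$idA[k]; b <- w$planted$idB[k]
    expected <- sum(X[a, ] * X[b, ])
    got <- gc[data.table::data.table(idA = a, idB = b),
              on = c("idA", "idB")]$score
    expect_identical(as.integer(got), as.integer(expected))
  }
})

test_that("a zero-signal world leaves planted pairs indistinguishable", {
  ok <- 0L
  for (s in 1:10) {
    cfg <- world_config(seed = 100 + s, n_proteins = 80,
                        n_positive_pairs = 15,
                        profile_correlation = 0, neighborhood_conservation = 0,
                        coevolution_coupling = 0, column_covariation = 0,
                        gf_fraction = 0, n_align_extra = 15)
    w <- generate_world(cfg)
    pp <- score_pp_all(w$table)
    key <- paste(w$planted$idA, w$planted$idB)
    planted_pp <- pp[paste(idA, idB) %in% key, score]
    set.seed(s)
    null_pp <- pp[!paste(idA, idB) %in% key][sample(.N, 500), score]
    p1 <- stats::wilcox.test(planted_pp, null_pp, exact = FALSE)$p.value
    co <- score_coevolution_pairs(w$alignments, w$table$genomes,
                                  methods = "MT")
    planted_mt <- co[paste(idA, idB) %in% key, score]
    null_mt <- co[!paste(idA, idB) %in% key, score]
    p2 <- stats::wilcox.test(planted_mt, null_mt, exact = FALSE)$p.value
    if (p1 > 0.01 && p2 > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
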