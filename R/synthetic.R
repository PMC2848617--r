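# Synthetic fixture worlds with plantable signals.
#
# A world consists of a genome panel, an ortholog table, per-genome gene
# coordinates, per-protein ortholog alignments, an external gene-fusion
# score list, regulons and a gold standard. A configured set of planted
# positive pairs receives, with configurable strength, each predictor's
# signal: correlated presence/absence profiles (PP), conserved < 300 bp
# adjacency (GC), coupled per-branch substitution rates on a shared species
# tree (MT), co-varying alignment column pairs (I2H) and elevated external
# fusion z-scores (GF). Negative pairs receive independent draws.

#' Synthetic world configuration
#'
#' Defaults describe a small but realistic bacterial panel: a 40-genome
#' star phylogeny, ~60% ortholog presence, operon-like small intergenic
#' gaps for a quarter of adjacent gene pairs, and alignments only for
#' proteins with at least `min_aln_seqs` orthologs.
#'
#' @param seed integer seed; the whole world is deterministic given the
#'   configuration.
#' @param n_genomes genome panel size (>= 16 so alignments can reach the
#'   16-sequence floor).
#' @param n_proteins number of query proteins.
#' @param n_positive_pairs number of planted (signal-bearing) positive
#'   pairs; planted pairs are disjoint, so `2 * n_positive_pairs <=
#'   n_proteins` is required.
#' @param presence_prob marginal ortholog presence probability per genome.
#' @param profile_correlation PP signal: probability that a planted
#'   partner copies its mate's presence bit instead of drawing its own.
#' @param neighborhood_conservation GC signal: probability that, in a genome
#'   carrying both orthologs, the planted partners are placed < 300 bp
#'   apart.
#' @param coevolution_coupling MT signal: correlation of the two proteins'
#'   per-branch substitution-rate noise (1 = shared substitution events).
#' @param column_covariation I2H signal: fraction of alignment columns
#'   planted as perfectly co-varying (up to `covary_flip` noise) between the
#'   two partners.
#' @param alignment_length alignment columns.
#' @param gap_prob per-cell gap probability in alignments.
#' @param operon_rate probability that two unrelated adjacent genes lie
#'   < 300 bp apart (background gene-context noise).
#' @param n_align_extra unpaired proteins also given alignments, so MT/I2H
#'   score negative pairs too.
#' @param min_aln_seqs minimum ortholog count for an alignment to be built.
#' @param branch_rate expected substitutions per site per unit branch length.
#' @param rate_sd standard deviation of the log-normal per-branch rate noise.
#' @param covary_flip per-species state-flip noise in planted co-varying
#'   columns.
#' @param gf_fraction fraction of planted pairs with an external fusion
#'   z-score.
#' @param gf_background number of background (noise) fusion pairs.
#' @param n_regulons,regulon_size regulon count and targets per regulon
#'   (gold-standard positives without planted signal).
#' @return a validated `appia_world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_genomes = 40L,
                         n_proteins = 120L,
                         n_positive_pairs = 20L,
                         presence_prob = 0.6,
                         profile_correlation = 0.8,
                         neighborhood_conservation = 0.8,
                         coevolution_coupling = 0.8,
                         column_covariation = 0.3,
                         alignment_length = 50L,
                         gap_prob = 0.02,
                         operon_rate = 0.25,
                         n_align_extra = 10L,
                         min_aln_seqs = 16L,
                         branch_rate = 0.4,
                         rate_sd = 0.8,
                         covary_flip = 0.05,
                         gf_fraction = 0.4,
                         gf_background = 10L,
                         n_regulons = 2L,
                         regulon_size = 4L) {
  cfg <- as.list(environment())
  probs <- c("presence_prob", "profile_correlation",
             "neighborhood_conservation", "coevolution_coupling",
             "column_covariation", "gap_prob", "operon_rate", "covary_flip",
             "gf_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      abort_appia("world_config: '%s' must be in [0, 1]", p)
  if (cfg$n_genomes < 16L)
    abort_appia("world_config: n_genomes must be >= 16")
  if (2L * cfg$n_positive_pairs > cfg$n_proteins)
    abort_appia("world_config: %d planted pairs need %d proteins, have %d",
                cfg$n_positive_pairs, 2L * cfg$n_positive_pairs,
                cfg$n_proteins)
  structure(cfg, class = "appia_world_config")
}

#' Correlated presence/absence profile pair
#'
#' The first profile is Bernoulli(`p`) per genome; the second copies each
#' bit with probability `rho` and draws an independent Bernoulli(`p`)
#' otherwise, so `rho = 1` gives identical vectors and `rho = 0` independent
#' ones.
#'
#' @param rho copy probability in `[0, 1]`.
#' @param n_genomes profile length.
#' @param p marginal presence probability.
#' @return list of two integer 0/1 vectors `a`, `b`.
#' @export
generate_profile_pair <- function(rho, n_genomes, p = 0.5) {
  stopifnot(rho >= 0, rho <= 1)
  a <- stats::rbinom(n_genomes, 1L, p)
  copy <- stats::runif(n_genomes) < rho
  b <- ifelse(copy, a, stats::rbinom(n_genomes, 1L, p))
  list(a = as.integer(a), b = as.integer(b))
}

# --------------------------------------------------------------------------
# Sequence evolution: Poisson substitution events along a tree, residues
# advancing in a fixed 20-cycle so every event changes the residue.

# Edge list in parent-before-child order, with branch lengths.
tree_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(edge = tree$edge,
       len = tree$edge.length %||% rep(1, nrow(tree$edge)),
       n_tip = length(tree$tip.label),
       tips = tree$tip.label)
}

# Draw substitution events for every branch: list of (positions, advances).
draw_events <- function(n_edges, expected) {
  lapply(seq_len(n_edges), function(b) {
    k <- stats::rpois(1L, expected[b])
    list(pos = sample.int(attr(expected, "L"), k, replace = TRUE),
         adv = sample.int(19L, k, replace = TRUE))
  })
}

# Propagate a root sequence through the tree given per-branch events.
propagate <- function(root_seq, ed, events) {
  n_nodes <- max(ed$edge)
  seqs <- vector("list", n_nodes)
  root <- ed$n_tip + 1L
  seqs[[root]] <- root_seq
  for (b in seq_len(nrow(ed$edge))) {
    parent <- ed$edge[b, 1L]; child <- ed$edge[b, 2L]
    s <- seqs[[parent]]
    ev <- events[[b]]
    for (q in seq_along(ev$pos))
      s[ev$pos[q]] <- ((s[ev$pos[q]] - 1L + ev$adv[q]) %% 20L) + 1L
    seqs[[child]] <- s
  }
  tips <- seqs[seq_len(ed$n_tip)]
  names(tips) <- ed$tips
  tips
}

int_to_alignment <- function(protein, tips, gap_prob = 0) {
  seqs <- vapply(tips, function(s) {
    ch <- AA_ORDER[s]
    if (gap_prob > 0) {
      g <- stats::runif(length(ch)) < gap_prob
      ch[g] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  ortholog_alignment(protein, seqs)
}

#' Simulate a pair of alignments with coupled evolutionary rates
#'
#' Both proteins evolve on the same species tree (default: a star tree with
#' unit branches -- under a star, zero coupling gives a mean mirror-tree
#' correlation of zero). Each protein draws log-normal per-branch rate
#' multipliers; the second protein's log-rates correlate with the first's
#' at strength `coupling`. With `coupling = 1` the second protein reuses the
#' first's substitution events (different root sequence), so the two
#' distance matrices are identical and the mirror-tree score is exactly 1.
#'
#' @param species species/genome ids (used when `tree` is `NULL`).
#' @param coupling rate-noise correlation in `[0, 1]`.
#' @param length alignment columns.
#' @param tree optional `ape::phylo`; default star tree over `species`.
#' @param branch_rate expected substitutions per site per unit branch.
#' @param rate_sd sd of log-normal branch-rate noise.
#' @param proteins ids for the two alignments.
#' @param gap_prob per-cell gap probability.
#' @return list of two `appia_alignment` objects.
#' @export
generate_coupled_alignments <- function(species, coupling, length = 50L,
                                        tree = NULL, branch_rate = 0.4,
                                        rate_sd = 0.8,
                                        proteins = c("protA", "protB"),
                                        gap_prob = 0) {
  stopifnot(coupling >= 0, coupling <= 1)
  if (is.null(tree)) {
    tree <- ape::stree(length(species), type = "star")
    tree$tip.label <- species
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  ed <- tree_edges(tree)
  nE <- nrow(ed$edge)
  za <- stats::rnorm(nE)
  zb <- coupling * za + sqrt(1 - coupling^2) * stats::rnorm(nE)
  mk_expected <- function(z) {
    e <- length * branch_rate * ed$len * exp(rate_sd * z - rate_sd^2 / 2)
    attr(e, "L") <- as.integer(length)
    e
  }
  ev_a <- draw_events(nE, mk_expected(za))
  ev_b <- if (coupling == 1) ev_a else draw_events(nE, mk_expected(zb))
  root_a <- sample.int(20L, length, replace = TRUE)
  root_b <- sample.int(20L, length, replace = TRUE)
  tips_a <- propagate(root_a, ed, ev_a)
  tips_b <- propagate(root_b, ed, ev_b)
  list(a = int_to_alignment(proteins[1L], tips_a, gap_prob),
       b = int_to_alignment(proteins[2L], tips_b, gap_prob))
}

# Simulate one alignment (no coupling partner).
simulate_alignment <- function(species, length, protein, tree = NULL,
                               branch_rate = 0.4, rate_sd = 0.8,
                               gap_prob = 0) {
  generate_coupled_alignments(species, coupling = 0, length = length,
                              tree = tree, branch_rate = branch_rate,
                              rate_sd = rate_sd,
                              proteins = c(protein, ".drop"),
                              gap_prob = gap_prob)$a
}

#' Plant co-varying column pairs into two alignments
#'
#' Overwrites `n_cov` randomly chosen column pairs (one column in each
#' alignment) with a shared two-state pattern: species are split by a latent
#' binary state and both columns show the same two residues by state, so the
#' McLachlan similarity patterns correlate perfectly up to `flip` noise.
#'
#' @param aln_a,aln_b `appia_alignment` objects (gaps preserved).
#' @param n_cov number of column pairs to plant.
#' @param flip per-species probability of flipping the latent state in one
#'   alignment only.
#' @return list of the two modified alignments.
#' @export
plant_covarying_columns <- function(aln_a, aln_b, n_cov, flip = 0.05) {
  if (n_cov == 0L) return(list(a = aln_a, b = aln_b))
  ma <- do.call(rbind, strsplit(aln_a$seqs, "", fixed = TRUE))
  mb <- do.call(rbind, strsplit(aln_b$seqs, "", fixed = TRUE))
  rownames(ma) <- names(aln_a$seqs)
  rownames(mb) <- names(aln_b$seqs)
  La <- ncol(ma); Lb <- ncol(mb)
  n_cov <- min(n_cov, La, Lb)
  cols_a <- sample.int(La, n_cov)
  cols_b <- sample.int(Lb, n_cov)
  species <- union(rownames(ma), rownames(mb))
  for (t in seq_len(n_cov)) {
    res <- sample(AA_ORDER, 2L)
    state <- setNames(stats::rbinom(length(species), 1L, 0.5) + 1L, species)
    state_b <- state
    fl <- stats::runif(length(species)) < flip
    state_b[fl] <- 3L - state_b[fl]
    sa <- rownames(ma); sb <- rownames(mb)
    keep_a <- ma[, cols_a[t]] != "-"
    keep_b <- mb[, cols_b[t]] != "-"
    ma[keep_a, cols_a[t]] <- res[state[sa]][keep_a]
    mb[keep_b, cols_b[t]] <- res[state_b[sb]][keep_b]
  }
  list(a = ortholog_alignment(aln_a$protein,
                         setNames(apply(ma, 1L, paste, collapse = ""),
                                  names(aln_a$seqs))),
       b = ortholog_alignment(aln_b$protein,
                         setNames(apply(mb, 1L, paste, collapse = ""),
                                  names(aln_b$seqs))))
}

# --------------------------------------------------------------------------

#' Generate a synthetic world
#'
#' Deterministic under `config$seed`. See [world_config()] for the planted
#' signals. Gold-standard positives are the planted pairs plus
#' regulon-derived pairs (co-regulated and regulator-target), the latter
#' carrying no planted signal.
#'
#' @param config an `appia_world_config`.
#' @return an `appia_world`: list with `config`, `table`
#'   (`appia_orthologs`), `coords`, `alignments` (named list), `gf`
#'   (pair-score table), `regulons` (`regulator`, `target`), `positives`
#'   (`idA`, `idB`, `source`), `planted` and `records`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "appia_world_config"))
  set.seed(config$seed)
  G <- config$n_genomes
  genomes <- sprintf("g%03d", seq_len(G))
  proteins <- sprintf("p%04d", seq_len(config$n_proteins))
  K <- config$n_positive_pairs
  planted <- data.table(idA = proteins[2L * seq_len(K) - 1L],
                        idB = proteins[2L * seq_len(K)])

  ## presence profiles
  X <- matrix(0L, config$n_proteins, G, dimnames = list(proteins, genomes))
  for (k in seq_len(K)) {
    pp <- generate_profile_pair(config$profile_correlation, G,
                                config$presence_prob)
    X[2L * k - 1L, ] <- pp$a
    X[2L * k, ] <- pp$b
  }
  rest <- setdiff(seq_len(config$n_proteins), seq_len(2L * K))
  for (i in rest) X[i, ] <- stats::rbinom(G, 1L, config$presence_prob)

  hits <- which(X == 1L, arr.ind = TRUE)
  entries <- data.table(protein = proteins[hits[, 1L]],
                        genome = genomes[hits[, 2L]])
  entries[, gene := paste0(protein, "@", genome)]
  data.table::setkey(entries, protein, genome)
  table <- ortholog_table(genomes, proteins, entries)

  ## gene coordinates: one contig per genome; planted partners forced
  ## adjacent (< 300 bp) with probability neighborhood_conservation
  coords <- vector("list", G)
  partner <- setNames(rep(NA_character_, config$n_proteins), proteins)
  partner[planted$idA] <- planted$idB
  for (g in seq_len(G)) {
    present <- proteins[X[, g] == 1L]
    if (!length(present)) next
    ord <- sample(present)
    joined <- character(0)
    for (k in seq_len(K)) {
      a <- planted$idA[k]; b <- planted$idB[k]
      if (a %in% present && b %in% present &&
          stats::runif(1) < config$neighborhood_conservation)
        joined <- c(joined, a)
    }
    # place joined partners immediately after their mates
    if (length(joined)) {
      drop <- partner[joined]
      ord <- ord[!ord %in% drop]
      pos <- match(joined, ord)
      neword <- character(0)
      for (i in seq_along(ord)) {
        neword <- c(neword, ord[i])
        hitk <- which(pos == i)
        if (length(hitk)) neword <- c(neword, drop[hitk])
      }
      ord <- neword
    }
    n <- length(ord)
    glen <- sample(300:1500, n, replace = TRUE)
    after <- partner[ord]
    forced <- c(!is.na(after[-n]) & after[-n] == ord[-1L], FALSE)
    gap <- integer(n)
    small <- stats::runif(n) < config$operon_rate
    gap[small] <- sample(0:250, sum(small), replace = TRUE)
    gap[!small] <- sample(350:5000, sum(!small), replace = TRUE)
    gap[forced] <- sample(20:250, sum(forced), replace = TRUE)
    start <- cumsum(c(1L, glen[-n] + gap[-n] + 1L))
    coords[[g]] <- data.table(
      genome = genomes[g], gene = paste0(ord, "@", genomes[g]),
      contig = paste0(genomes[g], "_chr1"),
      start = start, end = start + glen - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE))
  }
  coords <- data.table::rbindlist(coords)
  data.table::setkey(coords, genome, gene)

  ## alignments (planted proteins plus extras), with MT/I2H signals
  aligned_extra <- if (length(rest) && config$n_align_extra > 0L)
    proteins[sample(rest, min(config$n_align_extra, length(rest)))]
  else character(0)
  alignments <- list()
  n_orth <- rowSums(X)
  for (k in seq_len(K)) {
    a <- planted$idA[k]; b <- planted$idB[k]
    pair <- generate_coupled_alignments(
      genomes, config$coevolution_coupling, config$alignment_length,
      branch_rate = config$branch_rate, rate_sd = config$rate_sd,
      proteins = c(a, b), gap_prob = config$gap_prob)
    n_cov <- round(config$column_covariation * config$alignment_length)
    pair <- plant_covarying_columns(pair$a, pair$b, n_cov,
                                    flip = config$covary_flip)
    for (p in c(a, b)) {
      if (n_orth[p] < config$min_aln_seqs) next
      aln <- if (p == a) pair$a else pair$b
      keep <- genomes[X[p, ] == 1L]
      alignments[[p]] <- ortholog_alignment(p, aln$seqs[keep])
    }
  }
  for (p in aligned_extra) {
    if (n_orth[p] < config$min_aln_seqs) next
    aln <- simulate_alignment(genomes, config$alignment_length, p,
                              branch_rate = config$branch_rate,
                              rate_sd = config$rate_sd,
                              gap_prob = config$gap_prob)
    alignments[[p]] <- ortholog_alignment(p, aln$seqs[genomes[X[p, ] == 1L]])
  }

  ## external gene-fusion z-scores
  n_gf <- stats::rbinom(1L, K, config$gf_fraction)
  gf_pos <- if (n_gf > 0L) {
    sel <- sample.int(K, n_gf)
    data.table(idA = planted$idA[sel], idB = planted$idB[sel],
               score = round(stats::rnorm(n_gf, 6, 1.5), 3))
  }
  gf_bg <- if (config$gf_background > 0L) {
    bg <- canonical_pair(sample(proteins, config$gf_background, replace = TRUE),
                         sample(proteins, config$gf_background, replace = TRUE))
    bg <- unique(bg[idA != idB])
    bg[, score := round(stats::rnorm(.N, 2, 1), 3)]
    bg
  }
  gf <- data.table::rbindlist(Filter(Negate(is.null), list(gf_pos, gf_bg)))
  if (nrow(gf)) gf <- gf[, .(score = max(score)), by = .(idA, idB)]

  ## regulons: gold positives without planted signal
  regulons <- if (config$n_regulons > 0L) {
    regs <- sample(proteins, config$n_regulons)
    data.table::rbindlist(lapply(regs, function(r)
      data.table(regulator = r,
                 target = sample(setdiff(proteins, r), config$regulon_size))))
  } else data.table(regulator = character(), target = character())

  reg_pairs <- coregulated_from_regulons(regulons)
  planted_src <- data.table::copy(planted)[, source := "planted"]
  positives <- build_positives(list(planted = planted_src,
                                    coregulated = reg_pairs$coregulated,
                                    regulator_regulated = reg_pairs$regulator_target))
  positives <- data.table(idA = positives$idA, idB = positives$idB,
                          source = positives$sources)

  records <- data.table(protein = proteins,
                        length = pmax(50L, round(stats::rlnorm(
                          config$n_proteins, log(300), 0.35))),
                        n_orthologs = as.integer(n_orth))

  structure(list(config = config, genomes = genomes, proteins = proteins,
                 table = table, coords = coords, alignments = alignments,
                 gf = gf, regulons = regulons, positives = positives,
                 planted = planted, records = records),
            class = "appia_world")
}

#' @export
print.appia_world <- function(x, ...) {
  cat(sprintf(paste0("<appia_world> seed %d: %d proteins x %d genomes, ",
                     "%d planted pairs, %d alignments, %d positives\n"),
              x$config$seed, length(x$proteins), length(x$genomes),
              nrow(x$planted), length(x$alignments), nrow(x$positives)))
  invisible(x)
}

#' Write a world's input files
#'
#' Materializes every input the pipeline consumes, in the external formats
#' of the I/O module: `orthologs.tsv`, `gff/<genome>.gff3`,
#' `aln/<protein>.fasta`, `gf.tsv`, `regulons.tsv`,
#' `positives/<source>.tsv` and `records.tsv`.
#'
#' @param world an `appia_world`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "appia_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ortholog_table(world$table, file.path(dir, "orthologs.tsv"))
  write_gene_coordinates(world$coords, file.path(dir, "gff"))
  aln_dir <- file.path(dir, "aln")
  dir.create(aln_dir, showWarnings = FALSE)
  for (p in names(world$alignments))
    write_alignment(world$alignments[[p]], file.path(aln_dir,
                                                     paste0(p, ".fasta")))
  write_pair_list(world$gf, file.path(dir, "gf.tsv"))
  data.table::fwrite(world$regulons, file.path(dir, "regulons.tsv"),
                     sep = "\t")
  pos_dir <- file.path(dir, "positives")
  dir.create(pos_dir, showWarnings = FALSE)
  for (src in unique(unlist(strsplit(world$positives$source, ","))))
    write_pair_list(world$positives[grepl(src, source, fixed = TRUE)],
                    file.path(pos_dir, paste0(src, ".tsv")))
  data.table::fwrite(world$records, file.path(dir, "records.tsv"), sep = "\t")
  invisible(dir)
}

#' Read protein records
#'
#' TSV with header `protein`, `length`, `n_orthologs`.
#'
#' @param path TSV path.
#' @return `data.table` with those columns.
#' @export
read_protein_records <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "protein"))
  need <- c("protein", "length", "n_orthologs")
  if (!all(need %in% names(dt)))
    abort_format("protein records '%s' need columns %s", path,
                 paste(need, collapse = ", "))
  dt[, .(protein, length = as.integer(length),
         n_orthologs = as.integer(n_orthologs))]
}
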