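# Shared fixtures. Expensive worlds are memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Default small world (120 proteins, 20 planted pairs), memoized by seed.
small_world <- function(seed = 1L) {
  cached(paste0("world_", seed),
         generate_world(world_config(seed = seed)))
}

small_run <- function(seed = 1L) {
  cached(paste0("run_", seed), run_all(small_world(seed), seed = seed))
}

# Tiny ortholog table: entries given as list(protein = c(genome, ...)).
mk_table <- function(genomes, presence) {
  entries <- data.table::rbindlist(lapply(names(presence), function(p)
    if (length(presence[[p]]))
      data.table::data.table(protein = p, genome = presence[[p]],
                             gene = paste0(p, "@", presence[[p]]))
    else NULL))
  if (is.null(entries) || !nrow(entries))
    entries <- data.table::data.table(protein = character(),
                                      genome = character(),
                                      gene = character())
  ortholog_table(genomes, names(presence), entries)
}

# Coordinate rows for genes named "<protein>@<genome>".
mk_coords <- function(...) {
  rows <- list(...)
  dt <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(genome = r[[1]], gene = paste0(r[[2]], "@", r[[1]]),
                           contig = r[[3]], start = as.integer(r[[4]]),
                           end = as.integer(r[[5]]),
                           strand = if (length(r) > 5) r[[6]] else "+")))
  data.table::setkey(dt, genome, gene)
  dt
}

# Pair-score table shorthand.
mk_scores <- function(idA, idB, method, score) {
  data.table::data.table(idA = idA, idB = idB, method = method,
                         score = as.numeric(score))
}

# Random discretized training data for classifier tests.
random_nominal_data <- function(seed, n = 30L, A = 3L, vmax = 3L,
                                classes = c("negative", "positive"),
                                miss = 0.2) {
  set.seed(seed)
  nv <- sample(2:vmax, A, replace = TRUE)
  X <- sapply(seq_len(A), function(i) sample.int(nv[i], n, replace = TRUE))
  X <- matrix(as.integer(X), n, A)
  if (miss > 0) X[matrix(runif(n * A) < miss, n, A)] <- NA_integer_
  y <- sample(classes, n, replace = TRUE)
  # guarantee both classes present
  y[1] <- classes[1]; y[2] <- classes[2]
  colnames(X) <- paste0("x", seq_len(A))
  list(X = X, y = y, nvals = nv)
}
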