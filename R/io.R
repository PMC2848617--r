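# Readers and writers for the external formats the pipeline touches:
# ortholog tables (TSV), gene coordinates (GFF3), ortholog alignments
# (aligned FASTA), pair lists (TSV) and model serialization (JSON).

#' Read an ortholog table
#'
#' Tab-separated file whose header row is `protein<TAB>genome1<TAB>genome2...`
#' and whose body holds one row per query protein, each cell carrying the
#' ortholog gene id detected in that genome (empty cell = no ortholog).
#'
#' @param path path to the TSV file.
#' @return An object of class `appia_orthologs`: a list with `genomes`
#'   (ordered character vector), `proteins` (ordered character vector) and
#'   `entries` (a `data.table` with columns `protein`, `genome`, `gene`; one
#'   row per detected ortholog).
#' @export
read_ortholog_table <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                      na.strings = NULL),
    error = function(e) abort_format("cannot parse ortholog table '%s': %s",
                                     path, conditionMessage(e)))
  if (ncol(dt) < 1L) abort_format("ortholog table '%s' has no columns", path)
  genomes <- names(dt)[-1L]
  if (anyDuplicated(genomes))
    abort_format("duplicate genome column(s): %s",
                 paste(unique(genomes[duplicated(genomes)]), collapse = ", "))
  proteins <- dt[[1L]]
  if (anyDuplicated(proteins))
    abort_format("duplicate protein row(s): %s",
                 paste(unique(proteins[duplicated(proteins)]), collapse = ", "))
  if (nrow(dt) == 0L || length(genomes) == 0L) {
    entries <- data.table(protein = character(), genome = character(),
                          gene = character())
  } else {
    long <- data.table::melt(dt, id.vars = names(dt)[1L],
                             variable.name = "genome", value.name = "gene",
                             variable.factor = FALSE)
    data.table::setnames(long, names(long)[1L], "protein")
    entries <- long[!is.na(gene) & gene != ""]
    data.table::setkey(entries, protein, genome)
  }
  ortholog_table(genomes, proteins, entries)
}

#' Construct an ortholog table
#'
#' Programmatic constructor with invariant checks (no duplicate genomes,
#' proteins or (protein, genome) keys), shared by [read_ortholog_table()]
#' and the synthetic world generator.
#'
#' @param genomes ordered genome ids.
#' @param proteins ordered query protein ids.
#' @param entries `data.frame`/`data.table` with columns `protein`, `genome`,
#'   `gene` (one row per detected ortholog).
#' @return an `appia_orthologs` object.
#' @export
ortholog_table <- function(genomes, proteins, entries) {
  genomes <- as.character(genomes)
  proteins <- as.character(proteins)
  entries <- as.data.table(entries)
  if (anyDuplicated(genomes)) abort_format("duplicate genome ids")
  if (anyDuplicated(proteins)) abort_format("duplicate protein ids")
  if (nrow(entries)) {
    if (anyDuplicated(entries, by = c("protein", "genome")))
      abort_format("(protein, genome) key appears more than once")
    bad <- setdiff(entries$genome, genomes)
    if (length(bad)) abort_format("entries reference unknown genome(s): %s",
                                  paste(bad, collapse = ", "))
  }
  structure(list(genomes = genomes, proteins = proteins, entries = entries),
            class = "appia_orthologs")
}

#' @export
print.appia_orthologs <- function(x, ...) {
  cat(sprintf("<appia_orthologs> %d proteins x %d genomes, %d orthologs\n",
              length(x$proteins), length(x$genomes), nrow(x$entries)))
  invisible(x)
}

#' Write an ortholog table
#'
#' Inverse of [read_ortholog_table()].
#'
#' @param table an `appia_orthologs` object.
#' @param path output TSV path.
#' @export
write_ortholog_table <- function(table, path) {
  stopifnot(inherits(table, "appia_orthologs"))
  wide <- matrix("", nrow = length(table$proteins), ncol = length(table$genomes),
                 dimnames = list(table$proteins, table$genomes))
  if (nrow(table$entries))
    wide[cbind(table$entries$protein, table$entries$genome)] <- table$entries$gene
  out <- data.table(protein = table$proteins)
  for (g in table$genomes) out[[g]] <- wide[, g]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read gene coordinates from GFF3
#'
#' Imports `gene`/`CDS` features from one GFF3 file per genome. Coordinates
#' are kept 1-based inclusive exactly as stored in GFF3; no BED-style
#' conversion is performed anywhere in the package. Features without an `ID`
#' attribute are skipped with a warning.
#'
#' @param paths character vector of GFF3 paths, one per genome.
#' @param genomes genome ids, parallel to `paths` (defaults to `names(paths)`,
#'   or the file base names without extension).
#' @param feature_types GFF3 `type` values to keep.
#' @return `data.table` keyed by (`genome`, `gene`) with columns `genome`,
#'   `gene`, `contig`, `start`, `end`, `strand`.
#' @export
read_gene_coordinates <- function(paths, genomes = NULL,
                                  feature_types = c("gene", "CDS")) {
  if (is.null(genomes)) {
    genomes <- names(paths)
    if (is.null(genomes))
      genomes <- sub("\\.(gff3?|GFF3?)$", "", basename(paths))
  }
  if (length(genomes) != length(paths))
    abort_format("'paths' and 'genomes' lengths differ")
  if (anyDuplicated(genomes)) abort_format("duplicate genome ids")
  res <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    gr <- tryCatch(rtracklayer::import(paths[k], format = "gff3"),
                   error = function(e)
                     abort_format("cannot parse GFF3 '%s': %s", paths[k],
                                  conditionMessage(e)))
    keep <- as.character(gr$type) %in% feature_types
    gr <- gr[keep]
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(!nzchar(ids))) {
      drop <- is.na(ids) | !nzchar(ids)
      warning(sprintf("%s: skipped %d feature(s) without an ID attribute",
                      paths[k], sum(drop)), call. = FALSE)
      gr <- gr[!drop]; ids <- ids[!drop]
    }
    res[[k]] <- data.table(
      genome = genomes[k], gene = ids,
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  }
  coords <- data.table::rbindlist(res)
  if (nrow(coords)) {
    if (any(coords$start > coords$end))
      abort_format("feature with start > end")
    if (any(coords$start < 1L)) abort_format("feature with start < 1")
    if (anyDuplicated(coords, by = c("genome", "gene")))
      abort_format("duplicate (genome, gene) coordinate records")
    data.table::setkey(coords, genome, gene)
  }
  coords[]
}

#' Write gene coordinates as GFF3
#'
#' One GFF3 file per genome, named `<genome>.gff3`, round-trippable through
#' [read_gene_coordinates()].
#'
#' @param coords coordinate `data.table` as returned by
#'   [read_gene_coordinates()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths (names = genome ids).
#' @export
write_gene_coordinates <- function(coords, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords <- as.data.table(coords)
  out <- character(0)
  for (g in unique(coords$genome)) {
    cc <- coords[genome == g]
    lines <- c("##gff-version 3",
               sprintf("%s\tappia\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       cc$contig, cc$start, cc$end, cc$strand, cc$gene))
    path <- file.path(dir, paste0(g, ".gff3"))
    writeLines(lines, path)
    out[g] <- path
  }
  out
}

#' Read one ortholog multiple sequence alignment
#'
#' Aligned FASTA; the species/genome id is the first whitespace-delimited
#' token of each header and must match genome ids used in the ortholog table.
#'
#' @param path aligned FASTA path.
#' @param protein protein id the alignment belongs to (defaults to the file
#'   base name without extension).
#' @return An `appia_alignment`: list with `protein` and `seqs` (named
#'   character vector of equal-length gapped sequences, names = species ids).
#' @export
read_alignment <- function(path, protein = NULL) {
  if (is.null(protein))
    protein <- sub("\\.(fa|fasta|afa|aln)$", "", basename(path))
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e)
                   abort_format("cannot parse FASTA '%s': %s", path,
                                conditionMessage(e)))
  if (length(aa) < 1L) abort_format("alignment '%s' has no sequences", path)
  species <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(species))
    abort_format("alignment '%s': duplicate species header(s): %s", path,
                 paste(unique(species[duplicated(species)]), collapse = ", "))
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1L)
    abort_format("alignment '%s' is ragged: row lengths %s", path,
                 paste(sort(unique(w)), collapse = ", "))
  ortholog_alignment(protein, setNames(as.character(aa), species))
}

#' Construct an ortholog alignment
#'
#' Programmatic constructor with invariant checks (equal row lengths, unique
#' species ids), shared by [read_alignment()] and the synthetic world
#' generator.
#'
#' @param protein protein id the alignment belongs to.
#' @param seqs named character vector of equal-length gapped sequences
#'   (names = species/genome ids).
#' @return an `appia_alignment` object.
#' @export
ortholog_alignment <- function(protein, seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) abort_format("ragged alignment rows")
  if (anyDuplicated(names(seqs))) abort_format("duplicate species ids")
  structure(list(protein = protein, seqs = seqs), class = "appia_alignment")
}

#' @export
print.appia_alignment <- function(x, ...) {
  cat(sprintf("<appia_alignment> protein %s: %d species x %d columns\n",
              x$protein, length(x$seqs), nchar(x$seqs[[1L]])))
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an `appia_alignment`.
#' @param path output FASTA path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "appia_alignment"))
  aa <- Biostrings::AAStringSet(aln$seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a protein pair list
#'
#' Tab-separated file with two (`idA`, `idB`) or three (`idA`, `idB`,
#' `score`) columns and no header. Pairs are canonicalized (lexicographic id
#' order); homodimer rows are dropped and counted; duplicate pairs are merged
#' (keeping the maximum score when scores are present).
#'
#' @param path TSV path.
#' @param source source tag recorded for every pair (defaults to the file
#'   base name without extension).
#' @return `data.table` with columns `idA`, `idB`, `source` and, when the
#'   file has a third column, `score`. Attribute `n_homodimers` counts the
#'   dropped homodimer rows.
#' @export
read_pair_list <- function(path, source = NULL) {
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  if (file.exists(path) && file.size(path) == 0) {
    out <- data.table(idA = character(), idB = character(),
                      source = character())
    data.table::setattr(out, "n_homodimers", 0L)
    return(out)
  }
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, fill = FALSE,
                      colClasses = list(character = 1:2)),
    error = function(e) abort_format("cannot parse pair list '%s': %s",
                                     path, conditionMessage(e)))
  if (nrow(dt) == 0L) {
    out <- data.table(idA = character(), idB = character(),
                      source = character())
    data.table::setattr(out, "n_homodimers", 0L)
    return(out)
  }
  if (!ncol(dt) %in% 2:3)
    abort_format("pair list '%s' must have 2 or 3 columns, found %d",
                 path, ncol(dt))
  has_score <- ncol(dt) == 3L
  if (has_score) {
    sc <- suppressWarnings(as.numeric(dt[[3L]]))
    bad <- which(is.na(sc) & !is.na(dt[[3L]]))
    if (length(bad))
      abort_format("pair list '%s': non-numeric score at line %d",
                   path, bad[1L])
  }
  out <- canonical_pair(dt[[1L]], dt[[2L]])
  if (has_score) out[, score := sc]
  homo <- out$idA == out$idB
  n_homo <- sum(homo)
  if (n_homo) {
    appia_log("%s: dropped %d homodimer row(s)", path, n_homo)
    out <- out[!homo]
  }
  if (has_score) {
    ndup <- nrow(out) - data.table::uniqueN(out, by = c("idA", "idB"))
    if (ndup > 0L)
      appia_log("%s: merged %d duplicate pair(s), keeping max score",
                path, ndup)
    out <- out[, .(score = max(score)), by = .(idA, idB)]
  } else {
    out <- unique(out, by = c("idA", "idB"))
  }
  out[, source := source]
  data.table::setkey(out, idA, idB)
  data.table::setattr(out, "n_homodimers", n_homo)
  out[]
}

#' Write a pair list
#'
#' @param pairs `data.table` with `idA`, `idB` and optionally `score`.
#' @param path output TSV path (no header, 2 or 3 columns).
#' @export
write_pair_list <- function(pairs, path) {
  cols <- intersect(c("idA", "idB", "score"), names(pairs))
  data.table::fwrite(as.data.table(pairs)[, ..cols], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Model serialization

MODEL_SCHEMA <- "appia-model/1"

#' Save / load a fitted model as JSON
#'
#' Serializes an AODE or Naive Bayes model (optionally with its attached
#' discretizer) with an explicit schema version. `load_model(save_model(m))`
#' predicts identically to `m` on any instance.
#'
#' @param model a fitted `appia_aode` or `appia_nb` model.
#' @param path JSON path.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("appia_aode", "appia_nb")))
    abort_appia("save_model: not a fitted appia model")
  if (length(model$classes) < 1L)
    abort_appia("save_model: model has no classes")
  obj <- unclass(model)
  obj$schema <- MODEL_SCHEMA
  obj$model_class <- class(model)[1L]
  # Flatten count tables column-major; rebuild_model_arrays() restores dims.
  obj$joint <- lapply(obj$joint, as.vector)
  if (!is.null(obj$pair))
    obj$pair <- lapply(obj$pair, function(row)
      lapply(row, function(x) if (is.null(x)) NULL else as.vector(x)))
  if (!is.null(obj$discretizer)) obj$discretizer <- unclass(obj$discretizer)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the model with its original class.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    abort_format("cannot parse model JSON '%s': %s", path,
                                 conditionMessage(e)))
  if (!identical(obj$schema, MODEL_SCHEMA))
    abort_format("model schema mismatch: found '%s', expected '%s'",
                 obj$schema %||% "<none>", MODEL_SCHEMA)
  cls <- obj$model_class
  obj$schema <- NULL
  obj$model_class <- NULL
  model <- rebuild_model_arrays(obj)
  class(model) <- cls
  model
}

# jsonlite round-trips matrices/arrays as nested lists of numbers; rebuild
# the count tables into the numeric arrays the predictors index into.
rebuild_model_arrays <- function(obj) {
  k <- length(obj$classes)
  A <- length(obj$attrs)
  obj$nvals <- as.integer(obj$nvals)
  obj$n_class <- as.numeric(obj$n_class)
  obj$n_known <- as.numeric(obj$n_known)
  obj$joint <- lapply(seq_len(A), function(i)
    matrix(as.numeric(unlist(obj$joint[[i]])), nrow = obj$nvals[i], ncol = k))
  if (!is.null(obj$pair)) {
    obj$pair <- lapply(seq_len(A), function(i) {
      lapply(seq_len(A), function(j) {
        x <- obj$pair[[i]][[j]]
        if (is.null(x) || length(unlist(x)) == 0L) return(NULL)
        array(as.numeric(unlist(x)), dim = c(obj$nvals[j], k, obj$nvals[i]))
      })
    })
  }
  if (!is.null(obj$discretizer)) {
    d <- obj$discretizer
    d$cuts <- lapply(d$cuts, function(x)
      if (is.null(x)) NULL else as.numeric(unlist(x)))
    d$nvals <- unlist(d$nvals)
    d$min_per_band <- as.integer(d$min_per_band)
    d$b_target <- as.integer(d$b_target)
    d$attrs <- as.character(unlist(d$attrs))
    class(d) <- "appia_discretizer"
    obj$discretizer <- d
  }
  obj
}
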