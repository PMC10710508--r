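# Readers and writers for every external format the pipeline touches.
# All readers validate strictly and report 1-based line numbers for
# malformed rows; write -> read round trips are the identity.

# read a TSV keeping track of original file line numbers; lines starting
# with '#' are provenance headers and are skipped
.readLines2 <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.splitFields <- function(lines, sep = "\t") strsplit(lines, sep, fixed = TRUE)

.asNumericStrict <- function(x, column, lineno, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stopf("%s: column '%s' not numeric at line(s) %s", path, column,
          paste(lineno[bad], collapse = ", "))
  }
  out
}

.asIntegerStrict <- function(x, column, lineno, path) {
  num <- .asNumericStrict(x, column, lineno, path)
  bad <- !is.na(num) & num != round(num)
  if (any(bad)) {
    stopf("%s: column '%s' not integer at line(s) %s", path, column,
          paste(lineno[bad], collapse = ", "))
  }
  as.integer(num)
}

.fieldMatrix <- function(path, n_min) {
  raw <- .readLines2(path)
  fields <- .splitFields(raw$lines)
  nf <- lengths(fields)
  bad <- nf < n_min
  if (any(bad)) {
    stopf("%s: expected >= %d tab-separated columns at line(s) %s", path,
          n_min, paste(raw$lineno[bad], collapse = ", "))
  }
  list(fields = fields, lineno = raw$lineno)
}

#' Default alignment-hit column order
#'
#' BLAST/DIAMOND tabular (outfmt 6) column order with two appended
#' columns, `query_coverage` and `subject_taxid`. Pass a reordered or
#' reduced character vector to [readAlignmentHits()] for other dialects;
#' it must contain the seven required column names.
#'
#' @return character vector of column names in file order.
#' @export
outfmt6Dialect <- function() {
  c("query_gene_id", "subject_id", "percent_identity", "alignment_length",
    "mismatches", "gap_openings", "q_start", "q_end", "s_start", "s_end",
    "evalue", "bitscore", "query_coverage", "subject_taxid")
}

.hitRequired <- c("query_gene_id", "subject_id", "percent_identity",
                  "evalue", "query_coverage", "bitscore", "subject_taxid")

#' Read protein-alignment hits
#'
#' Reads a headerless tab-separated hit table (BLAST outfmt-6-like).
#' Rows failing numeric validation or range invariants (identity and
#' query coverage in \[0,100\], e-value >= 0) are rejected with their
#' 1-based line numbers.
#'
#' @param path file path.
#' @param dialect character vector naming the file's columns in order;
#'   see [outfmt6Dialect()].
#' @return data.frame with the seven canonical hit columns.
#' @export
readAlignmentHits <- function(path, dialect = outfmt6Dialect()) {
  missing_cols <- setdiff(.hitRequired, dialect)
  if (length(missing_cols)) {
    stopf("dialect is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  fm <- .fieldMatrix(path, length(dialect))
  col <- function(nm) vapply(fm$fields, `[[`, character(1), match(nm, dialect))
  hits <- data.frame(
    query_gene_id = col("query_gene_id"),
    subject_id = col("subject_id"),
    percent_identity = .asNumericStrict(col("percent_identity"),
                                        "percent_identity", fm$lineno, path),
    evalue = .asNumericStrict(col("evalue"), "evalue", fm$lineno, path),
    query_coverage = .asNumericStrict(col("query_coverage"),
                                      "query_coverage", fm$lineno, path),
    bitscore = .asNumericStrict(col("bitscore"), "bitscore", fm$lineno, path),
    subject_taxid = .asIntegerStrict(col("subject_taxid"), "subject_taxid",
                                     fm$lineno, path),
    stringsAsFactors = FALSE
  )
  bad <- hits$percent_identity < 0 | hits$percent_identity > 100 |
    hits$query_coverage < 0 | hits$query_coverage > 100 | hits$evalue < 0
  if (any(bad)) {
    stopf("%s: hit invariant violated (identity/cover in [0,100], evalue >= 0) at line(s) %s",
          path, paste(fm$lineno[bad], collapse = ", "))
  }
  hits
}

#' @rdname readAlignmentHits
#' @param hits data.frame of hits as returned by `readAlignmentHits`.
#' @export
writeAlignmentHits <- function(hits, path, dialect = outfmt6Dialect()) {
  out <- as.data.frame(lapply(dialect, function(nm) {
    if (nm %in% names(hits)) hits[[nm]] else 0L
  }))
  names(out) <- dialect
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDGraph depth track
#'
#' Four-column BEDGraph (`genome start end depth`, 0-based half-open).
#' Intervals are sorted per genome; overlapping intervals are a
#' validation error. Contiguity gaps are allowed: positions without an
#' interval count as depth 0 once the genome length is known (see
#' [readGenomeManifest()]).
#'
#' @param path BEDGraph file path.
#' @param lengths optional named integer vector of genome lengths
#'   (genome manifest).
#' @return A [DepthTrackSet-class].
#' @export
readDepthTrack <- function(path, lengths = integer(0)) {
  fm <- .fieldMatrix(path, 4L)
  col <- function(i) vapply(fm$fields, `[[`, character(1), i)
  iv <- data.frame(
    genome_id = col(1L),
    start = .asIntegerStrict(col(2L), "start", fm$lineno, path),
    end = .asIntegerStrict(col(3L), "end", fm$lineno, path),
    depth = .asNumericStrict(col(4L), "depth", fm$lineno, path),
    stringsAsFactors = FALSE
  )
  bad <- iv$start >= iv$end | iv$start < 0 | iv$depth < 0
  if (any(bad)) {
    stopf("%s: invalid interval (start < end, start >= 0, depth >= 0) at line(s) %s",
          path, paste(fm$lineno[bad], collapse = ", "))
  }
  depthTrackSet(iv, lengths = lengths)
}

#' @rdname readDepthTrack
#' @param x a `DepthTrackSet`.
#' @export
writeDepthTrack <- function(x, path) {
  utils::write.table(depthIntervals(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a genome manifest
#'
#' Two-column TSV with header (`genome_id`, `length_bp`). The manifest
#' supplies genome lengths so that positions absent from a depth track
#' are counted as zero-depth in truncated-average-depth estimation.
#'
#' @param path file path.
#' @return named integer vector of genome lengths.
#' @export
readGenomeManifest <- function(path) {
  fm <- .fieldMatrix(path, 2L)
  header <- fm$fields[[1L]]
  if (!identical(header[1:2], c("genome_id", "length_bp"))) {
    stopf("%s: expected header 'genome_id\tlength_bp'", path)
  }
  rows <- fm$fields[-1L]
  lineno <- fm$lineno[-1L]
  len <- .asIntegerStrict(vapply(rows, `[[`, character(1), 2L), "length_bp",
                          lineno, path)
  if (any(len <= 0L)) {
    stopf("%s: non-positive genome length at line(s) %s", path,
          paste(lineno[len <= 0L], collapse = ", "))
  }
  stats::setNames(len, vapply(rows, `[[`, character(1), 1L))
}

#' @rdname readGenomeManifest
#' @param lengths named integer vector.
#' @export
writeGenomeManifest <- function(lengths, path) {
  utils::write.table(
    data.frame(genome_id = names(lengths), length_bp = as.integer(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read NCBI-style taxdump files
#'
#' Parses `nodes.dmp` (taxid, parent, rank) and `names.dmp` (scientific
#' names) in the pipe-delimited dmp dialect (`"\t|\t"` separators).
#' Every node must be reachable from the root; orphan nodes (parent
#' absent from the file) are an error listing the orphans.
#'
#' @param nodes_path path to `nodes.dmp`.
#' @param names_path path to `names.dmp`.
#' @return A [TaxonomyTree-class].
#' @export
readTaxdump <- function(nodes_path, names_path) {
  parseDmp <- function(path) {
    raw <- .readLines2(path)
    lines <- sub("\t\\|$", "", raw$lines)
    .splitFields(lines, sep = "\t|\t")
  }
  nodes <- parseDmp(nodes_path)
  taxid <- as.integer(vapply(nodes, `[[`, character(1), 1L))
  parent <- as.integer(vapply(nodes, `[[`, character(1), 2L))
  rank <- vapply(nodes, `[[`, character(1), 3L)
  orphan <- setdiff(parent, taxid)
  if (length(orphan)) {
    stopf("%s: orphan node(s), parent taxid(s) not in file: %s", nodes_path,
          paste(orphan, collapse = ", "))
  }
  nm <- rep(NA_character_, length(taxid))
  names_rows <- parseDmp(names_path)
  ntax <- as.integer(vapply(names_rows, `[[`, character(1), 1L))
  nname <- vapply(names_rows, `[[`, character(1), 2L)
  nclass <- vapply(names_rows, function(f) if (length(f) >= 4L) f[[4L]] else "scientific name",
                   character(1))
  sci <- nclass == "scientific name"
  idx <- match(taxid, ntax[sci])
  nm <- ifelse(is.na(idx), as.character(taxid), nname[sci][idx])
  taxonomyTree(taxid, parent, rank, nm)
}

#' @rdname readTaxdump
#' @param tree a `TaxonomyTree`.
#' @export
writeTaxdump <- function(tree, nodes_path, names_path) {
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tree@taxid, tree@parent, tree@rank)
  nms <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", tree@taxid, tree@name)
  writeLines(nodes, nodes_path)
  writeLines(nms, names_path)
  invisible(c(nodes_path, names_path))
}

#' Read / write gene annotation tables
#'
#' TSV with header: `gene_id`, `parent_id` (read or contig), `ordinal`
#' (0-based position index of the gene along its parent), `length_bp`,
#' `labels` (semicolon-joined functional tags: SC-RBP names, CAZyme
#' families such as `GH16_3`, `sulfatase`, `peptidase`, `susC`, `susD`,
#' `TBDT`, ...). Ordinals must be unique within a parent.
#'
#' @param path file path.
#' @return data.frame with the five annotation columns.
#' @export
readGeneAnnotation <- function(path) {
  fm <- .fieldMatrix(path, 5L)
  header <- fm$fields[[1L]]
  need <- c("gene_id", "parent_id", "ordinal", "length_bp", "labels")
  if (!identical(header[seq_along(need)], need)) {
    stopf("%s: expected header columns %s", path, paste(need, collapse = ", "))
  }
  rows <- fm$fields[-1L]
  lineno <- fm$lineno[-1L]
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), 1L),
    parent_id = vapply(rows, `[[`, character(1), 2L),
    ordinal = .asIntegerStrict(vapply(rows, `[[`, character(1), 3L),
                               "ordinal", lineno, path),
    length_bp = .asIntegerStrict(vapply(rows, `[[`, character(1), 4L),
                                 "length_bp", lineno, path),
    labels = vapply(rows, `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
  if (any(genes$length_bp <= 0L)) {
    stopf("%s: non-positive gene length at line(s) %s", path,
          paste(lineno[genes$length_bp <= 0L], collapse = ", "))
  }
  dup <- duplicated(genes[c("parent_id", "ordinal")])
  if (any(dup)) {
    stopf("%s: duplicate ordinal within parent at line(s) %s", path,
          paste(lineno[dup], collapse = ", "))
  }
  genes
}

#' @rdname readGeneAnnotation
#' @param genes annotation data.frame.
#' @export
writeGeneAnnotation <- function(genes, path) {
  utils::write.table(
    genes[c("gene_id", "parent_id", "ordinal", "length_bp", "labels")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-gene mapped transcript counts
#'
#' TSV with header (`gene_id`, `count`); counts are non-negative
#' integers of transcripts mapped to each predicted gene.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id` and `count`.
#' @export
readTranscriptCounts <- function(path) {
  fm <- .fieldMatrix(path, 2L)
  header <- fm$fields[[1L]]
  if (!identical(header[1:2], c("gene_id", "count"))) {
    stopf("%s: expected header 'gene_id\tcount'", path)
  }
  rows <- fm$fields[-1L]
  lineno <- fm$lineno[-1L]
  count <- .asIntegerStrict(vapply(rows, `[[`, character(1), 2L), "count",
                            lineno, path)
  if (any(count < 0L)) {
    stopf("%s: negative count at line(s) %s", path,
          paste(lineno[count < 0L], collapse = ", "))
  }
  data.frame(gene_id = vapply(rows, `[[`, character(1), 1L), count = count,
             stringsAsFactors = FALSE)
}

#' @rdname readTranscriptCounts
#' @param counts data.frame with `gene_id` and `count`.
#' @export
writeTranscriptCounts <- function(counts, path) {
  utils::write.table(counts[c("gene_id", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write microarray spot signals
#'
#' Long-format TSV with header: `sample_id`, `extraction`,
#' `antibody_id`, `replicate`, `signal` and optionally `is_control`
#' (standard-control spots; default `FALSE`).
#'
#' @param path file path.
#' @return A [MicroarraySignalSet-class] of raw (unnormalised) signals.
#' @export
readMicroarraySignals <- function(path) {
  fm <- .fieldMatrix(path, 5L)
  header <- fm$fields[[1L]]
  need <- c("sample_id", "extraction", "antibody_id", "replicate", "signal")
  if (!identical(header[seq_along(need)], need)) {
    stopf("%s: expected header columns %s", path, paste(need, collapse = ", "))
  }
  has_ctrl <- length(header) >= 6L && header[6L] == "is_control"
  rows <- fm$fields[-1L]
  lineno <- fm$lineno[-1L]
  sig <- data.frame(
    sample_id = vapply(rows, `[[`, character(1), 1L),
    extraction = vapply(rows, `[[`, character(1), 2L),
    antibody_id = vapply(rows, `[[`, character(1), 3L),
    replicate = .asIntegerStrict(vapply(rows, `[[`, character(1), 4L),
                                 "replicate", lineno, path),
    signal = .asNumericStrict(vapply(rows, `[[`, character(1), 5L),
                              "signal", lineno, path),
    is_control = if (has_ctrl) {
      vapply(rows, `[[`, character(1), 6L) %in% c("TRUE", "true", "1")
    } else FALSE,
    stringsAsFactors = FALSE
  )
  if (any(sig$signal < 0)) {
    stopf("%s: negative signal at line(s) %s", path,
          paste(lineno[sig$signal < 0], collapse = ", "))
  }
  microarraySignalSet(sig)
}

#' @rdname readMicroarraySignals
#' @param x a `MicroarraySignalSet`.
#' @export
writeMicroarraySignals <- function(x, path) {
  utils::write.table(x@signals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
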