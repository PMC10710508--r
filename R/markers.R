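# Single-copy ribosomal protein (SC-RBP) marker-gene bookkeeping:
# genome equivalents, species counts from identity clustering of four
# markers, and L6-cluster community composition.

#' The 16 single-copy ribosomal protein markers
#'
#' The canonical set of 16 universally single-copy ribosomal protein
#' genes used as genome proxies, and the four-marker subset (L3, L4,
#' L6, S8) used for species-level clustering.
#'
#' @return `scrbpMarkers()` returns the 16 marker labels;
#'   `speciesMarkers()` the four-marker subset.
#' @export
scrbpMarkers <- function() {
  c("L2", "L3", "L4", "L5", "L6", "L14", "L15", "L16", "L18", "L22",
    "L24", "S3", "S8", "S10", "S17", "S19")
}

#' @rdname scrbpMarkers
#' @export
speciesMarkers <- function() c("L3", "L4", "L6", "S8")

# count marker-labelled genes; one count per marker name
.markerCounts <- function(genes, markers, weights = NULL) {
  lab <- splitLabels(genes$labels)
  w <- weights %||% rep(1, nrow(genes))
  vapply(markers, function(m) {
    sum(w[vapply(lab, function(l) m %in% l, logical(1))])
  }, numeric(1))
}

#' Genome equivalents of a sample
#'
#' The average count of the 16 SC-RBP markers across a sample's genes:
#' a proxy for the number of microbial genomes sequenced, used as the
#' denominator of per-genome (PMG) normalisation. An optional weight
#' per gene (e.g. sequencing depth) supports depth-weighted counting.
#'
#' @param genes gene annotation data.frame; marker genes carry their
#'   SC-RBP name among their labels.
#' @param markers character vector of marker labels (default the 16).
#' @param weights optional numeric per-gene weights (default 1).
#' @return Mean marker count (positive real).
#' @export
genomeEquivalents <- function(genes, markers = scrbpMarkers(),
                              weights = NULL) {
  counts <- .markerCounts(genes, markers, weights)
  if (sum(counts) == 0) {
    stopf("no SC-RBP marker genes found; genome equivalents undefined")
  }
  mean(counts)
}

# percent identity of a global end-gap-free alignment (match +1,
# mismatch -1, linear gap -2): matches / alignment columns, with the
# denominator floored at the shorter sequence length so that a short
# spurious overlap between unrelated sequences cannot score as high
# identity
.pairIdentity <- function(query, centroids) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = centroids, subject = query, type = "overlap",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  ncol <- nchar(as.character(Biostrings::pattern(aln)))
  shorter <- pmin(Biostrings::width(centroids), length(query))
  100 * Biostrings::nmatch(aln) / pmax(ncol, shorter, 1L)
}

#' Greedy centroid clustering of marker-gene sequences
#'
#' Sequences are processed longest-first (ties broken by lexicographic
#' id); each sequence joins the first existing centroid whose
#' global end-gap-free alignment identity is at least `threshold`,
#' otherwise it founds a new cluster. Identity is the match count over
#' the alignment columns, with the denominator floored at the shorter
#' sequence's length so partial overlaps between unrelated sequences
#' cannot reach the threshold. This mirrors the usual semantics of
#' identity-threshold (ANI) gene clustering.
#'
#' @param sequences a [Biostrings::DNAStringSet] (or named character
#'   vector) of one marker's nucleotide sequences; names are gene ids.
#' @param threshold percent identity threshold in (0, 100\].
#' @return data.frame with columns `gene_id`, `cluster_id`,
#'   `centroid_gene_id`; empty input gives an empty frame.
#' @export
clusterMarkerGenes <- function(sequences, threshold = 99) {
  if (threshold <= 0 || threshold > 100) {
    stopf("threshold must be in (0, 100]")
  }
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  n <- length(sequences)
  empty <- data.frame(gene_id = character(0), cluster_id = character(0),
                      centroid_gene_id = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  if (is.null(names(sequences))) names(sequences) <- sprintf("seq%05d", seq_len(n))
  ord <- order(-Biostrings::width(sequences), names(sequences))
  sequences <- sequences[ord]
  centroid_idx <- integer(0)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    if (length(centroid_idx)) {
      ident <- .pairIdentity(sequences[[i]], sequences[centroid_idx])
      hit <- which(ident >= threshold)
    } else hit <- integer(0)
    if (length(hit)) {
      assignment[i] <- hit[1L]
    } else {
      centroid_idx <- c(centroid_idx, i)
      assignment[i] <- length(centroid_idx)
    }
  }
  data.frame(
    gene_id = names(sequences),
    cluster_id = sprintf("cluster_%03d", assignment),
    centroid_gene_id = names(sequences)[centroid_idx][assignment],
    stringsAsFactors = FALSE
  )
}

#' Species count from four-marker clustering
#'
#' Clusters each of the four species-resolution markers (L3, L4, L6,
#' S8) at its gene-specific identity threshold and returns the mean
#' cluster count: a proxy for the number of species captured.
#'
#' @param pools named list of sequence pools, one per marker in
#'   [speciesMarkers()].
#' @param thresholds named numeric vector of per-marker identity
#'   thresholds; default 99% for all four.
#' @return Mean number of clusters across the four markers.
#' @export
speciesCount <- function(pools, thresholds = NULL) {
  markers <- speciesMarkers()
  thresholds <- thresholds %||% stats::setNames(rep(99, 4), markers)
  missing_pool <- setdiff(markers, names(pools))
  if (length(missing_pool)) {
    stopf("missing sequence pool for marker(s): %s",
          paste(missing_pool, collapse = ", "))
  }
  n_clusters <- vapply(markers, function(m) {
    cl <- clusterMarkerGenes(pools[[m]], thresholds[[m]])
    length(unique(cl$cluster_id))
  }, numeric(1))
  mean(n_clusters)
}

#' Community composition from L6 marker clusters
#'
#' Aggregates per-gene weights (count 1 for metagenomes, TPM for
#' metatranscriptomes) over marker-gene clusters and expresses each
#' cluster's weight as a share of the total. When per-gene taxa and a
#' tree are supplied, each cluster is labelled by majority vote of its
#' member genes (ties resolved by LCA) and shares are aggregated per
#' taxon.
#'
#' @param clusters data.frame from [clusterMarkerGenes()].
#' @param weights named numeric vector of per-gene weights (names are
#'   gene ids; genes missing from `weights` get weight 1).
#' @param taxids optional named integer vector of per-gene taxa.
#' @param tree optional [TaxonomyTree-class] (required with `taxids`).
#' @return data.frame with columns `taxon` (cluster id or voted taxid),
#'   `weight` and `share`; shares sum to 1.
#' @export
compositionProfile <- function(clusters, weights = NULL, taxids = NULL,
                               tree = NULL) {
  w <- rep(1, nrow(clusters))
  if (!is.null(weights)) {
    idx <- match(clusters$gene_id, names(weights))
    w[!is.na(idx)] <- weights[idx[!is.na(idx)]]
  }
  total <- sum(w)
  if (total <= 0) stopf("total weight is zero; composition undefined")
  if (!is.null(taxids)) {
    if (is.null(tree)) stopf("a TaxonomyTree is required for majority voting")
    voted <- vapply(split(seq_len(nrow(clusters)), clusters$cluster_id),
                    function(i) {
                      t <- taxids[match(clusters$gene_id[i], names(taxids))]
                      majorityVote(tree, t[!is.na(t)])
                    }, integer(1))
    key <- as.character(voted[clusters$cluster_id])
  } else {
    key <- clusters$cluster_id
  }
  agg <- tapply(w, key, sum)
  out <- data.frame(taxon = names(agg), weight = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$share <- out$weight / total
  out[order(-out$weight), , drop = FALSE]
}
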