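#' @import methods
NULL

#' Rooted taxonomy with ranks
#'
#' A rooted tree of taxa in NCBI taxdump style: every node carries a
#' parent pointer, a rank label and a name. The root is the single node
#' whose parent is itself. All last-common-ancestor (LCA) operations run
#' on this class.
#'
#' @slot taxid integer vector of node identifiers (unique).
#' @slot parent integer vector, parallel to `taxid`; the root points to
#'   itself.
#' @slot rank character vector of rank labels (e.g. `"genus"`).
#' @slot name character vector of scientific names.
#'
#' @seealso [taxonomyTree()], [lca()], [readTaxdump()]
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
  representation(
    taxid = "integer",
    parent = "integer",
    rank = "character",
    name = "character"
  )
)

setValidity("TaxonomyTree", function(object) {
  n <- length(object@taxid)
  if (length(object@parent) != n || length(object@rank) != n ||
      length(object@name) != n) {
    return("taxid, parent, rank and name must have equal length")
  }
  if (n == 0L) return("tree must contain at least one node")
  if (anyDuplicated(object@taxid)) return("duplicate taxids")
  roots <- object@taxid[object@taxid == object@parent]
  if (length(roots) != 1L) {
    return(sprintf("exactly one root required, found %d", length(roots)))
  }
  orphan <- setdiff(object@parent, object@taxid)
  if (length(orphan)) {
    return(paste0("orphan nodes: parent taxid(s) absent from tree: ",
                  paste(orphan, collapse = ", ")))
  }
  # every chain must terminate at the root (no cycles)
  idx <- match(object@parent, object@taxid)
  depth <- integer(n)
  cur <- seq_len(n)
  for (step in seq_len(n + 1L)) {
    at_root <- object@parent[cur] == object@taxid[cur]
    if (all(at_root)) break
    cur <- ifelse(at_root, cur, idx[cur])
    if (step > n) return("cycle detected: ancestor chain does not reach root")
  }
  TRUE
})

#' Alignment-hit retention thresholds
#'
#' Thresholds applied to protein-alignment hits before LCA
#' classification. Comparisons are strict: identity must exceed
#' `minIdentity`, e-value must be below `maxEvalue` and query coverage
#' must exceed `minQueryCover`.
#'
#' @slot minIdentity percent identity threshold (default 65, strict >).
#' @slot maxEvalue e-value ceiling (default 1e-10, strict <).
#' @slot minQueryCover percent query-coverage threshold (default 50,
#'   strict >).
#'
#' @seealso [hitFilter()], [filterHits()]
#' @exportClass HitFilter
setClass("HitFilter",
  representation(
    minIdentity = "numeric",
    maxEvalue = "numeric",
    minQueryCover = "numeric"
  )
)

setValidity("HitFilter", function(object) {
  v <- c(object@minIdentity, object@maxEvalue, object@minQueryCover)
  if (length(v) != 3L || any(!is.finite(v))) return("thresholds must be finite scalars")
  if (object@minIdentity < 0 || object@minIdentity > 100) return("minIdentity outside [0,100]")
  if (object@minQueryCover < 0 || object@minQueryCover > 100) return("minQueryCover outside [0,100]")
  if (object@maxEvalue < 0) return("maxEvalue must be non-negative")
  TRUE
})

#' Per-base depth of genomes stored as intervals
#'
#' Run-length representation of per-base sequencing depth (BEDGraph
#' semantics: 0-based half-open intervals). Positions of a genome not
#' covered by any interval have depth 0; the genome length needed to
#' account for those zero runs comes from the `lengths` manifest (or,
#' when absent, the maximum interval end).
#'
#' @slot intervals data.frame with columns `genome_id`, `start`, `end`,
#'   `depth`.
#' @slot lengths named integer vector of genome lengths in bp (may be
#'   empty).
#'
#' @seealso [depthTrackSet()], [readDepthTrack()], [tad()]
#' @exportClass DepthTrackSet
setClass("DepthTrackSet",
  representation(
    intervals = "data.frame",
    lengths = "integer"
  )
)

setValidity("DepthTrackSet", function(object) {
  iv <- object@intervals
  need <- c("genome_id", "start", "end", "depth")
  if (!all(need %in% names(iv))) {
    return(paste0("intervals must have columns ", paste(need, collapse = ", ")))
  }
  if (nrow(iv)) {
    if (any(iv$start >= iv$end)) return("interval start must be < end")
    if (any(iv$start < 0)) return("negative interval start")
    if (any(iv$depth < 0)) return("negative depth")
    for (g in unique(iv$genome_id)) {
      sub <- iv[iv$genome_id == g, , drop = FALSE]
      ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      cov <- max(IRanges::coverage(ir))
      if (cov > 1L) return(sprintf("overlapping intervals for genome '%s'", g))
    }
  }
  if (length(object@lengths)) {
    if (is.null(names(object@lengths))) return("lengths must be named by genome_id")
    if (any(object@lengths <= 0L)) return("genome lengths must be positive")
  }
  TRUE
})

#' Per-gene transcript counts and TPM values of one sample
#'
#' Holds mapped transcript counts, gene lengths and derived TPM values.
#' The `in_universe` column marks the genes over which the TPM
#' denominator is computed; TPM of universe genes sums to 1e6 whenever
#' any universe count is positive.
#'
#' @slot sample_id sample identifier.
#' @slot genes data.frame with columns `gene_id`, `count`, `length_bp`,
#'   `in_universe`, `tpm`.
#'
#' @seealso [expressionTable()], [tpm()]
#' @exportClass ExpressionTable
setClass("ExpressionTable",
  representation(
    sample_id = "character",
    genes = "data.frame"
  )
)

setValidity("ExpressionTable", function(object) {
  g <- object@genes
  need <- c("gene_id", "count", "length_bp", "in_universe", "tpm")
  if (!all(need %in% names(g))) {
    return(paste0("genes must have columns ", paste(need, collapse = ", ")))
  }
  if (nrow(g)) {
    if (any(g$length_bp <= 0)) return("gene lengths must be positive")
    if (any(g$count < 0)) return("negative counts")
    total <- sum(g$tpm[g$in_universe])
    if (sum(g$count[g$in_universe]) > 0 &&
        abs(total - 1e6) > 1e-6 * 1e6) {
      return(sprintf("universe TPM sums to %g, expected 1e6", total))
    }
  }
  TRUE
})

#' Raw glycan microarray spot signals
#'
#' Long-format spot signals indexed by sample, extraction solvent,
#' antibody, and replicate (quadruplicate printing). Standard-control
#' spots are flagged: they participate in dataset-maximum normalisation
#' but are excluded from epitope abundance tables.
#'
#' @slot signals data.frame with columns `sample_id`, `extraction`,
#'   `antibody_id`, `replicate`, `signal`, `is_control`.
#' @slot normalized logical; `TRUE` after [normalizeToMax()] has scaled
#'   the dataset maximum to 100.
#'
#' @seealso [microarraySignalSet()], [normalizeToMax()]
#' @exportClass MicroarraySignalSet
setClass("MicroarraySignalSet",
  representation(
    signals = "data.frame",
    normalized = "logical"
  )
)

setValidity("MicroarraySignalSet", function(object) {
  s <- object@signals
  need <- c("sample_id", "extraction", "antibody_id", "replicate", "signal",
            "is_control")
  if (!all(need %in% names(s))) {
    return(paste0("signals must have columns ", paste(need, collapse = ", ")))
  }
  if (nrow(s)) {
    if (any(s$signal < 0)) return("negative raw signal")
    if (any(s$replicate < 1L | s$replicate > 4L)) {
      return("replicate index must be in 1..4 (quadruplicate printing)")
    }
  }
  if (length(object@normalized) != 1L) return("normalized must be a single flag")
  TRUE
})
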