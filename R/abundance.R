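# Truncated-average-depth (TAD) genome abundance, normalised to genome
# equivalents.

#' Construct a DepthTrackSet
#'
#' @param intervals data.frame with columns `genome_id`, `start`, `end`
#'   (0-based half-open) and `depth`.
#' @param lengths optional named integer vector of genome lengths; see
#'   [readGenomeManifest()].
#' @return A [DepthTrackSet-class]; intervals are sorted by genome and
#'   start.
#' @export
depthTrackSet <- function(intervals, lengths = integer(0)) {
  intervals <- intervals[order(intervals$genome_id, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  storage.mode(intervals$start) <- "integer"
  storage.mode(intervals$end) <- "integer"
  new("DepthTrackSet", intervals = intervals,
      lengths = stats::setNames(as.integer(lengths), names(lengths)))
}

#' @rdname depthTrackSet
#' @param x a `DepthTrackSet`.
#' @export
depthIntervals <- function(x) x@intervals

#' @rdname depthTrackSet
#' @export
genomeIds <- function(x) unique(x@intervals$genome_id)

#' @rdname depthTrackSet
#' @param genome_id single genome identifier.
#' @return `genomeLength` returns the manifest length when declared,
#'   otherwise the maximum interval end (full-coverage BEDGraph
#'   assumption).
#' @export
genomeLength <- function(x, genome_id) {
  if (genome_id %in% names(x@lengths)) {
    return(unname(x@lengths[[genome_id]]))
  }
  sub <- x@intervals[x@intervals$genome_id == genome_id, , drop = FALSE]
  if (!nrow(sub)) stopf("unknown genome '%s' (no intervals, no manifest entry)",
                        genome_id)
  max(sub$end)
}

setMethod("show", "DepthTrackSet", function(object) {
  cat(sprintf("DepthTrackSet: %d genomes, %d intervals%s\n",
              length(genomeIds(object)), nrow(object@intervals),
              if (length(object@lengths)) {
                sprintf(", %d manifest lengths", length(object@lengths))
              } else ""))
})

# truncated mean over run-length encoded depths without expansion:
# runs (depth, width), trim k positions off each tail of the sorted
# per-base multiset, weighted mean of the remainder
.tadRuns <- function(depths, widths, genome_length, central_fraction) {
  covered <- sum(widths)
  if (covered > genome_length) {
    stopf("intervals cover %d bp but genome length is %d", covered,
          genome_length)
  }
  if (covered < genome_length) {
    depths <- c(depths, 0)
    widths <- c(widths, genome_length - covered)
  }
  # epsilon guards the floor against float artefacts such as
  # 1 - 0.8 = 0.1999...96, which would under-trim lengths divisible by 10
  k <- floor(genome_length * (1 - central_fraction) / 2 + 1e-9)
  ord <- order(depths)
  depths <- depths[ord]
  widths <- widths[ord]
  upper <- genome_length - k
  pos_end <- cumsum(widths)
  pos_start <- pos_end - widths
  kept <- pmax(0, pmin(pos_end, upper) - pmax(pos_start, k))
  sum(depths * kept) / (genome_length - 2 * k)
}

#' Truncated average sequencing depth (TAD)
#'
#' The mean per-base depth after discarding the lowest and highest
#' `(1 - centralFraction) / 2` fraction of the sorted per-base depth
#' multiset (`floor` of each tail count); `centralFraction = 0.8` is
#' the TAD80 of genome-abundance estimation, `1` gives the plain mean.
#' Positions not covered by any interval count as depth 0, which is why
#' the genome length (manifest) matters for sparse tracks. The
#' computation runs on the run-length intervals without per-base
#' expansion and matches the per-base definition exactly.
#'
#' @param x a [DepthTrackSet-class].
#' @param genomes genome ids to evaluate (default all).
#' @param centralFraction central fraction retained, in (0, 1\].
#' @return Named numeric vector of TAD values.
#' @examples
#' dts <- depthTrackSet(data.frame(genome_id = "g", start = 0:9,
#'                                 end = 1:10, depth = 1:10))
#' tad(dts, centralFraction = 0.8) # mean of depths 2..9 = 5.5
#' @export
tad <- function(x, genomes = genomeIds(x), centralFraction = 0.8) {
  assertScalarNumber(centralFraction, "centralFraction")
  if (centralFraction <= 0 || centralFraction > 1) {
    stopf("centralFraction must be in (0, 1]")
  }
  iv <- x@intervals
  vapply(stats::setNames(genomes, genomes), function(g) {
    sub <- iv[iv$genome_id == g, , drop = FALSE]
    .tadRuns(sub$depth, sub$end - sub$start, genomeLength(x, g),
             centralFraction)
  }, numeric(1))
}

#' Relative abundance from TAD and genome equivalents
#'
#' The quotient between a genome's TAD value and the number of
#' microbial genomes captured in the sample (genome equivalents from
#' SC-RBP counts): the fraction of community genomes belonging to this
#' genome.
#'
#' @param tad_value TAD value(s).
#' @param genome_equiv positive genome-equivalents denominator.
#' @return `tad_value / genome_equiv`.
#' @export
relativeAbundance <- function(tad_value, genome_equiv) {
  assertScalarNumber(genome_equiv, "genome_equiv")
  if (genome_equiv <= 0) stopf("genome_equiv must be positive")
  tad_value / genome_equiv
}

#' Covered-fraction sanity report
#'
#' Flags genomes whose fraction of positions with non-zero depth falls
#' below `floorFraction`: their TAD estimates rest on few positions and
#' are advisory only. Read recruitment itself happens upstream; this is
#' a post-hoc reliability screen.
#'
#' @param x a [DepthTrackSet-class].
#' @param floorFraction minimum covered fraction (default 0.1).
#' @return data.frame with `genome_id`, `covered_fraction`, `flagged`.
#' @export
competitiveDepthSanity <- function(x, floorFraction = 0.1) {
  iv <- x@intervals
  ids <- genomeIds(x)
  covered <- vapply(ids, function(g) {
    sub <- iv[iv$genome_id == g & iv$depth > 0, , drop = FALSE]
    sum(sub$end - sub$start) / genomeLength(x, g)
  }, numeric(1))
  data.frame(genome_id = ids, covered_fraction = unname(covered),
             flagged = unname(covered) < floorFraction,
             stringsAsFactors = FALSE)
}
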