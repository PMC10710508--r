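# TPM conversion and MAG-level relative transcription metrics.

#' Transcripts per million
#'
#' Length-normalised transcript rates rescaled so that the genes of the
#' normalisation `universe` sum to one million:
#' `rate_g = count_g / length_g`, `tpm_g = 1e6 * rate_g / sum(rate_u)`.
#' Genes outside the universe still receive TPM values computed with
#' the universe denominator, which is how MAG genes are made
#' commensurable with whole-community values.
#'
#' @param count non-negative per-gene mapped transcript counts.
#' @param length_bp positive per-gene lengths (annotated nucleotide
#'   length of the predicted gene).
#' @param universe logical vector marking denominator genes (default
#'   all).
#' @return Numeric TPM vector, parallel to `count`.
#' @export
tpm <- function(count, length_bp, universe = NULL) {
  if (length(count) != length(length_bp)) {
    stopf("count and length_bp must have equal length")
  }
  if (any(length_bp <= 0)) stopf("gene lengths must be positive")
  if (any(count < 0)) stopf("counts must be non-negative")
  universe <- universe %||% rep(TRUE, length(count))
  rate <- count / length_bp
  denom <- sum(rate[universe])
  if (denom == 0) {
    warnf("all universe counts are zero; TPM set to 0")
    return(rep(0, length(count)))
  }
  1e6 * rate / denom
}

#' TPM of MAG genes on the community denominator
#'
#' Computes TPM for a MAG's genes using the total length-normalised
#' transcript rate of the whole metagenome's predicted genes as the
#' denominator, so MAG values sum to at most 1e6 and are directly
#' comparable with community values.
#'
#' @param mag_count,mag_length_bp counts and lengths of the MAG genes.
#' @param community_count,community_length_bp counts and lengths of all
#'   community genes (the denominator universe).
#' @return Numeric TPM vector for the MAG genes.
#' @export
magTpm <- function(mag_count, mag_length_bp, community_count,
                   community_length_bp) {
  n_mag <- length(mag_count)
  all_tpm <- tpm(c(mag_count, community_count),
                 c(mag_length_bp, community_length_bp),
                 universe = c(rep(FALSE, n_mag),
                              rep(TRUE, length(community_count))))
  all_tpm[seq_len(n_mag)]
}

#' Construct an ExpressionTable
#'
#' @param sample_id sample identifier.
#' @param gene_id,count,length_bp per-gene vectors.
#' @param universe logical vector of denominator genes (default all).
#' @return An [ExpressionTable-class] with TPM values filled in.
#' @export
expressionTable <- function(sample_id, gene_id, count, length_bp,
                            universe = NULL) {
  universe <- universe %||% rep(TRUE, length(gene_id))
  vals <- tpm(count, length_bp, universe)
  new("ExpressionTable", sample_id = as.character(sample_id),
      genes = data.frame(gene_id = as.character(gene_id),
                         count = as.numeric(count),
                         length_bp = as.integer(length_bp),
                         in_universe = universe, tpm = vals,
                         stringsAsFactors = FALSE))
}

#' @rdname expressionTable
#' @param x an `ExpressionTable`.
#' @return `tpms` returns a named numeric vector of per-gene TPM.
#' @export
tpms <- function(x) stats::setNames(x@genes$tpm, x@genes$gene_id)

setMethod("show", "ExpressionTable", function(object) {
  g <- object@genes
  cat(sprintf("ExpressionTable '%s': %d genes (%d in universe), %g mapped transcripts\n",
              object@sample_id, nrow(g), sum(g$in_universe), sum(g$count)))
})

#' MAG relative transcription
#'
#' The quotient of the mean TPM of a MAG's SC-RBP marker genes and the
#' mean TPM of the 16 SC-RBPs in the whole sample: the MAG's
#' proportional share of community genome activity. A MAG missing
#' markers is averaged over the markers it possesses, with at least
#' `minMarkers` required; fewer yields `NA` (flagged, no value
#' emitted).
#'
#' @param mag_scrbp_tpms TPM values of the MAG's SC-RBP genes (up to
#'   16).
#' @param sample_scrbp_tpms TPM values of the sample's 16 SC-RBPs.
#' @param minMarkers minimum marker count for a value (default 8).
#' @return `mean(mag) / mean(sample)`, or `NA` below the marker floor.
#' @export
magRelativeTranscription <- function(mag_scrbp_tpms, sample_scrbp_tpms,
                                     minMarkers = 8L) {
  mag <- mag_scrbp_tpms[!is.na(mag_scrbp_tpms)]
  smp <- sample_scrbp_tpms[!is.na(sample_scrbp_tpms)]
  if (!length(smp) || mean(smp) == 0) {
    stopf("sample SC-RBP mean TPM is zero; relative transcription undefined")
  }
  if (length(mag) < minMarkers) return(NA_real_)
  mean(mag) / mean(smp)
}

#' Per-MAG share of a CAZyme family's community transcription
#'
#' Given the total transcripts mapped to one CAZyme family at the
#' community level and the transcripts recruited to each MAG's genes of
#' that family, returns each MAG's share plus the unassigned remainder
#' ("other community members"). A family with zero community
#' transcripts is reported as absent (zero-row result flagged with
#' `attr(, "absent_family")`).
#'
#' @param community_total total family transcripts in the sample.
#' @param per_mag named numeric vector of per-MAG family transcripts.
#' @return data.frame with `mag_id`, `transcripts`, `share`; the last
#'   row is `other_community_members`.
#' @export
familyTranscriptionShare <- function(community_total, per_mag) {
  if (any(per_mag < 0) || community_total < 0) {
    stopf("transcript counts must be non-negative")
  }
  if (sum(per_mag) > community_total) {
    stopf("per-MAG transcripts (%g) exceed the community total (%g)",
          sum(per_mag), community_total)
  }
  if (community_total == 0) {
    out <- data.frame(mag_id = character(0), transcripts = numeric(0),
                      share = numeric(0), stringsAsFactors = FALSE)
    attr(out, "absent_family") <- TRUE
    return(out)
  }
  remainder <- community_total - sum(per_mag)
  data.frame(
    mag_id = c(names(per_mag), "other_community_members"),
    transcripts = c(unname(per_mag), remainder),
    share = c(unname(per_mag), remainder) / community_total,
    stringsAsFactors = FALSE
  )
}

#' Up-transcribed CAZyme families of a MAG
#'
#' Families whose summed TPM strictly exceeds the MAG's mean SC-RBP
#' TPM: transcription higher than the ribosomal protein baseline marks
#' a family as up-transcribed relative to the genome.
#'
#' @param family_tpms named numeric vector of per-family summed TPM.
#' @param scrbp_mean_tpm the MAG's mean SC-RBP TPM.
#' @return Character vector of up-transcribed family names.
#' @export
upTranscribedFamilies <- function(family_tpms, scrbp_mean_tpm) {
  names(family_tpms)[family_tpms > scrbp_mean_tpm]
}
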