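# Glycan microarray signal processing: dataset-maximum normalisation,
# antibody retention filtering, replicate averaging and extraction
# summing. Outputs stay per-antibody: probe avidities differ, so
# cross-antibody comparisons are never derived.

.validExtractions <- c("H2O", "EDTA", "NaOH")

#' Construct a MicroarraySignalSet
#'
#' @param signals data.frame with columns `sample_id`, `extraction`,
#'   `antibody_id`, `replicate` (1-4), `signal`, and optionally
#'   `is_control` (standard-control spots, default `FALSE`).
#' @param normalized whether signals are already on the 0-100 scale.
#' @return A [MicroarraySignalSet-class].
#' @export
microarraySignalSet <- function(signals, normalized = FALSE) {
  if (is.null(signals$is_control)) signals$is_control <- FALSE
  signals$replicate <- as.integer(signals$replicate)
  new("MicroarraySignalSet", signals = signals,
      normalized = isTRUE(normalized))
}

#' @rdname microarraySignalSet
#' @param x a `MicroarraySignalSet`.
#' @export
arraySignals <- function(x) x@signals

setMethod("show", "MicroarraySignalSet", function(object) {
  s <- object@signals
  cat(sprintf(
    "MicroarraySignalSet: %d spots, %d samples x %d antibodies x %d extractions%s\n",
    nrow(s), length(unique(s$sample_id)), length(unique(s$antibody_id)),
    length(unique(s$extraction)),
    if (object@normalized) " (normalized to max 100)" else " (raw)"))
})

#' Normalise signals to the dataset maximum
#'
#' Scales every spot signal by `100 / max(signal)` so the highest value
#' in the data set (by design a standard-control spot) becomes exactly
#' 100. Idempotent: normalising twice changes nothing.
#'
#' @param x a [MicroarraySignalSet-class].
#' @return The normalised set.
#' @export
normalizeToMax <- function(x) {
  s <- x@signals
  m <- max(s$signal)
  if (m <= 0) stopf("all signals are zero; normalisation undefined")
  s$signal <- s$signal * (100 / m)
  microarraySignalSet(s, normalized = TRUE)
}

#' Replicate means per (sample, extraction, antibody)
#'
#' Arithmetic mean of the (up to four) replicate spots of each
#' (sample, extraction, antibody) triple; standard-control spots are
#' excluded. The replicate count is reported.
#'
#' @param x a normalised [MicroarraySignalSet-class].
#' @return data.frame with `sample_id`, `extraction`, `antibody_id`,
#'   `mean_signal`, `n_replicates`.
#' @export
replicateMeans <- function(x) {
  s <- x@signals[!x@signals$is_control, , drop = FALSE]
  key <- interaction(s$sample_id, s$extraction, s$antibody_id, drop = TRUE)
  idx <- split(seq_len(nrow(s)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(sample_id = s$sample_id[i[1L]],
               extraction = s$extraction[i[1L]],
               antibody_id = s$antibody_id[i[1L]],
               mean_signal = mean(s$signal[i]),
               n_replicates = length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$antibody_id, out$extraction), , drop = FALSE]
}

#' Antibody retention filter
#'
#' Retains an antibody iff its best mean signal across samples and
#' extractions reaches `threshold` (non-strict, default 5 on the 0-100
#' normalised scale). Antibodies never reaching the threshold are
#' dropped from the table entirely.
#'
#' @param means data.frame from [replicateMeans()].
#' @param threshold retention threshold (default 5, `>=`).
#' @return The filtered means table; retained antibody ids in
#'   `attr(, "retained")`.
#' @export
filterAntibodies <- function(means, threshold = 5) {
  best <- tapply(means$mean_signal, means$antibody_id, max)
  retained <- names(best)[best >= threshold]
  out <- means[means$antibody_id %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained") <- retained
  out
}

#' Sum extraction means into epitope abundances
#'
#' Per (sample, antibody), sums the mean signals of the three
#' sequential extractions (H2O, EDTA, NaOH); a missing extraction
#' contributes 0. The result is the semi-quantitative epitope
#' abundance table; values are comparable within an antibody across
#' samples, never between antibodies.
#'
#' @param means filtered means table (see [filterAntibodies()]).
#' @return data.frame with `sample_id`, `antibody_id`,
#'   `summed_mean_signal`.
#' @export
sumExtractions <- function(means) {
  bad <- setdiff(unique(means$extraction), .validExtractions)
  if (length(bad)) {
    stopf("unknown extraction label(s): %s (expected %s)",
          paste(bad, collapse = ", "),
          paste(.validExtractions, collapse = ", "))
  }
  key <- interaction(means$sample_id, means$antibody_id, drop = TRUE)
  idx <- split(seq_len(nrow(means)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(sample_id = means$sample_id[i[1L]],
               antibody_id = means$antibody_id[i[1L]],
               summed_mean_signal = sum(means$mean_signal[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$antibody_id), , drop = FALSE]
}

#' Full microarray processing chain
#'
#' normalise to the dataset maximum -> replicate means -> antibody
#' retention filter -> extraction sums. By default the retention
#' decision is taken on replicate means (`filterOn = "mean"`); with
#' `filterOn = "spot"` an antibody is retained when any single
#' normalised spot reaches the threshold, for workflows that filter
#' before averaging.
#'
#' @param x a raw [MicroarraySignalSet-class].
#' @param threshold retention threshold (default 5).
#' @param filterOn `"mean"` (default) or `"spot"`.
#' @return Epitope abundance data.frame (see [sumExtractions()]) with
#'   retained antibodies in `attr(, "retained")`.
#' @export
epitopeAbundance <- function(x, threshold = 5,
                             filterOn = c("mean", "spot")) {
  filterOn <- match.arg(filterOn)
  normed <- normalizeToMax(x)
  means <- replicateMeans(normed)
  if (filterOn == "mean") {
    filtered <- filterAntibodies(means, threshold)
    retained <- attr(filtered, "retained")
  } else {
    s <- normed@signals[!normed@signals$is_control, , drop = FALSE]
    best <- tapply(s$signal, s$antibody_id, max)
    retained <- names(best)[best >= threshold]
    filtered <- means[means$antibody_id %in% retained, , drop = FALSE]
  }
  out <- sumExtractions(filtered)
  attr(out, "retained") <- retained
  out
}
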