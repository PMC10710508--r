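rawSet <- function(signal_df) {
  microarraySignalSet(signal_df)
}

exampleSignals <- function() {
  data.frame(
    sample_id = rep(c("S1", "S2"), each = 8),
    extraction = rep(c("H2O", "EDTA"), times = 8),
    antibody_id = rep(rep(c("ab1", "ab2"), each = 4), 2),
    replicate = rep(1:2, times = 8),
    signal = c(500, 500, 480, 520, 40, 60, 30, 10,
               200, 220, 180, 200, 2000, 1900, 2000, 1800),
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("normalisation sets the dataset maximum to exactly 100", {
  x <- rawSet(exampleSignals())
  n <- normalizeToMax(x)
  s <- arraySignals(n)
  expect_identical(max(s$signal), 100)
  # a spot at a quarter of the maximum lands at 25
  expect_equal(s$signal[arraySignals(x)$signal == 500][1], 25)
  # idempotent
  expect_equal(arraySignals(normalizeToMax(n)), s)
  zero <- exampleSignals()
  zero$signal <- 0
  expect_error(normalizeToMax(rawSet(zero)), "zero")
})

test_that("the chain is degree-1 before and degree-0 after normalisation", {
  x <- exampleSignals()
  x10 <- x
  x10$signal <- x10$signal * 10
  expect_equal(arraySignals(normalizeToMax(rawSet(x10))),
               arraySignals(normalizeToMax(rawSet(x))))
})

test_that("replicate means average the quadruplicate spots", {
  m <- replicateMeans(rawSet(exampleSignals()))
  expect_equal(m$mean_signal[m$sample_id == "S1" & m$antibody_id == "ab1" &
                               m$extraction == "H2O"], 490)
  expect_equal(m$mean_signal[m$sample_id == "S1" & m$antibody_id == "ab2" &
                               m$extraction == "EDTA"], 35)
  expect_identical(unique(m$n_replicates), 2L)
  # (0,0,0,40) -> 10
  one <- data.frame(sample_id = "S", extraction = "H2O", antibody_id = "a",
                    replicate = 1:4, signal = c(0, 0, 0, 40),
                    is_control = FALSE)
  expect_equal(replicateMeans(rawSet(one))$mean_signal, 10)
  # brute force over a random table
  set.seed(81)
  rnd <- data.frame(
    sample_id = sample(c("S1", "S2"), 200, replace = TRUE),
    extraction = sample(c("H2O", "EDTA", "NaOH"), 200, replace = TRUE),
    antibody_id = sample(c("a", "b", "c"), 200, replace = TRUE),
    replicate = sample(1:4, 200, replace = TRUE),
    signal = runif(200, 0, 50), is_control = FALSE)
  m <- replicateMeans(rawSet(rnd))
  for (j in sample(nrow(m), 10)) {
    sel <- rnd$sample_id == m$sample_id[j] &
      rnd$extraction == m$extraction[j] &
      rnd$antibody_id == m$antibody_id[j]
    expect_equal(m$mean_signal[j], mean(rnd$signal[sel]))
  }
})

test_that("antibody retention is non-strict at the threshold", {
  means <- data.frame(
    sample_id = "S1", extraction = "H2O",
    antibody_id = c("at", "above", "below"),
    mean_signal = c(5.0, 7.2, 4.999), n_replicates = 4L)
  kept <- filterAntibodies(means, threshold = 5)
  expect_setequal(attr(kept, "retained"), c("at", "above"))
  expect_false("below" %in% kept$antibody_id)
  # max over samples decides: one qualifying sample retains the antibody
  means2 <- rbind(means,
                  data.frame(sample_id = "S2", extraction = "NaOH",
                             antibody_id = "below", mean_signal = 6,
                             n_replicates = 4L))
  expect_true("below" %in% attr(filterAntibodies(means2, 5), "retained"))
})

test_that("extraction sums add the three solvent means", {
  means <- data.frame(
    sample_id = "S1", extraction = c("H2O", "EDTA", "NaOH"),
    antibody_id = "ab1", mean_signal = c(10, 5, 1), n_replicates = 4L)
  out <- sumExtractions(means)
  expect_equal(out$summed_mean_signal, 16)
  # a missing extraction contributes zero
  out1 <- sumExtractions(means[1, ])
  expect_equal(out1$summed_mean_signal, 10)
  bad <- means
  bad$extraction[1] <- "acetone"
  expect_error(sumExtractions(bad), "acetone")
})

test_that("control spots set the scale but never enter epitope tables", {
  sig <- exampleSignals()
  sig <- rbind(sig, data.frame(sample_id = "S1", extraction = "H2O",
                               antibody_id = "std", replicate = 1:2,
                               signal = c(4000, 3900), is_control = TRUE))
  out <- epitopeAbundance(rawSet(sig))
  expect_false("std" %in% out$antibody_id)
  n <- normalizeToMax(rawSet(sig))
  expect_equal(max(arraySignals(n)$signal), 100)
  # the epitope maximum is now scaled by the control, not by itself
  expect_lt(max(out$summed_mean_signal), 100)
})

test_that("the default chain order is normalise, mean, filter, sum", {
  sig <- exampleSignals()
  x <- rawSet(sig)
  manual <- sumExtractions(filterAntibodies(replicateMeans(normalizeToMax(x)),
                                            5))
  auto <- epitopeAbundance(x, 5)
  expect_equal(auto, manual, ignore_attr = TRUE)
  # spot-level filtering is available as the alternative order
  spot <- epitopeAbundance(x, 5, filterOn = "spot")
  expect_s3_class(spot, "data.frame")
})

test_that("retention decisions match planted truth at replicate CV 0.1", {
  ok <- 0L
  total <- 0L
  for (r in 1:25) {
    ma <- makeMicroarray(sprintf("S%d", 1:6), sprintf("ab%02d", 1:12),
                         replicate_cv = 0.1, seed = 8100 + r)
    out <- epitopeAbundance(ma$signals)
    retained <- attr(out, "retained")
    truth_present <- colnames(ma$truth)[colSums(ma$truth) > 0]
    decisions <- colnames(ma$truth)
    ok <- ok + sum((decisions %in% retained) == (decisions %in% truth_present))
    total <- total + length(decisions)
  }
  expect_gte(ok / total, 0.95)
})

test_that("zero replicate noise reproduces truth exactly", {
  ma <- makeMicroarray(sprintf("S%d", 1:4), sprintf("ab%02d", 1:10),
                       replicate_cv = 0, seed = 82)
  out <- epitopeAbundance(ma$signals)
  retained <- attr(out, "retained")
  truth_present <- colnames(ma$truth)[colSums(ma$truth) > 0]
  expect_setequal(retained, truth_present)
})
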