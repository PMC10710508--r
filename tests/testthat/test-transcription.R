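test_that("tpm follows its closed forms and sums to one million", {
  expect_equal(tpm(5, 1000), 1e6)
  v <- tpm(c(10, 10), c(100, 200))
  expect_equal(v, c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)
  expect_equal(sum(v), 1e6)
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(2:200, 1)
    v <- tpm(rpois(n, 20), sample(100:2000, n, replace = TRUE))
    expect_equal(sum(v), 1e6, tolerance = 1e-6)
  }
  expect_warning(z <- tpm(c(0, 0), c(100, 200)), "zero")
  expect_identical(z, c(0, 0))
  expect_error(tpm(1, 0), "positive")
  expect_error(tpm(-1, 10), "non-negative")
})

test_that("tpm is invariant to uniform count scaling", {
  set.seed(52)
  cnt <- rpois(50, 30)
  len <- sample(200:2000, 50, replace = TRUE)
  expect_equal(tpm(cnt * 7, len), tpm(cnt, len))
})

test_that("mag tpm uses the community denominator", {
  set.seed(53)
  comm_cnt <- rpois(100, 40)
  comm_len <- sample(300:1500, 100, replace = TRUE)
  mag_cnt <- rpois(10, 40)
  mag_len <- sample(300:1500, 10, replace = TRUE)
  got <- magTpm(mag_cnt, mag_len, comm_cnt, comm_len)
  # brute force: universe denominator from community rates only
  denom <- sum(comm_cnt / comm_len)
  expect_equal(got, 1e6 * (mag_cnt / mag_len) / denom)
  # a MAG gene with the same count/length as a community gene gets the
  # same tpm
  expect_equal(magTpm(comm_cnt[1], comm_len[1], comm_cnt, comm_len),
               tpm(comm_cnt, comm_len)[1])
  # the MAG subset can never exceed the community total
  expect_lte(sum(magTpm(comm_cnt[1:10], comm_len[1:10], comm_cnt, comm_len)),
             1e6)
})

test_that("expression tables validate the universe sum", {
  et <- expressionTable("S1", sprintf("g%d", 1:4), c(5, 0, 2, 8),
                        c(500L, 800L, 900L, 400L))
  expect_equal(sum(tpms(et)), 1e6)
  expect_s4_class(et, "ExpressionTable")
})

test_that("mag relative transcription is the SC-RBP mean quotient", {
  smp <- seq(10, 160, by = 10)
  expect_identical(magRelativeTranscription(smp, smp), 1)
  expect_identical(magRelativeTranscription(smp / 2, smp), 0.5)
  expect_error(magRelativeTranscription(smp, rep(0, 16)), "zero")
  # below the marker floor no value is emitted
  expect_true(is.na(magRelativeTranscription(smp[1:7], smp)))
  expect_false(is.na(magRelativeTranscription(smp[1:8], smp)))
})

test_that("relative transcription of a partitioned sample sums to one", {
  set.seed(54)
  # five MAGs partition the sample's SC-RBP expression
  mags <- lapply(1:5, function(i) matrix(rlnorm(16, 3, 1), nrow = 1))
  sample_tot <- Reduce(`+`, mags)
  vals <- vapply(mags, function(m) {
    magRelativeTranscription(as.numeric(m), as.numeric(sample_tot))
  }, numeric(1))
  expect_equal(sum(vals), 1, tolerance = 1e-9)
})

test_that("ratio recovery is unbiased at adequate marker counts", {
  # MAG SC-RBP expression generated as fraction p of the community's;
  # negative-binomial counts, mean marker count >= 50
  simRatio <- function(p, seed) {
    set.seed(seed)
    mu <- rlnorm(16, log(200), 0.5)
    len_mag <- sample(600:1200, 16, replace = TRUE)
    len_oth <- sample(600:1200, 16, replace = TRUE)
    cnt_mag <- rnbinom(16, mu = p * mu, size = 100)
    cnt_oth <- rnbinom(16, mu = (1 - p) * mu, size = 100)
    v <- tpm(c(cnt_mag, cnt_oth), c(len_mag, len_oth))
    magRelativeTranscription(v[1:16], v[1:16] + v[17:32])
  }
  for (p in c(0.2, 0.5)) {
    est <- vapply(1:100, function(r) simRatio(p, 5000 + r), numeric(1))
    expect_lte(abs(mean(est) - p), 0.02)
  }
})

test_that("family transcription shares include the community remainder", {
  sh <- familyTranscriptionShare(50, c(magA = 30, magB = 10))
  expect_equal(sh$share, c(0.6, 0.2, 0.2))
  expect_identical(sh$mag_id[3], "other_community_members")
  expect_equal(sum(sh$share), 1)
  one <- familyTranscriptionShare(20, c(magA = 20))
  expect_equal(one$share[1], 1)
  absent <- familyTranscriptionShare(0, c(magA = 0))
  expect_identical(nrow(absent), 0L)
  expect_true(attr(absent, "absent_family"))
  expect_error(familyTranscriptionShare(5, c(magA = 10)), "exceed")
})

test_that("up-transcribed families beat the SC-RBP baseline strictly", {
  fams <- c(GH16_3 = 10, GH29 = 20, PL7_5 = 40)
  expect_identical(upTranscribedFamilies(fams, 20), "PL7_5")
  expect_identical(upTranscribedFamilies(fams, 5),
                   c("GH16_3", "GH29", "PL7_5"))
  # brute-force threshold scan
  set.seed(55)
  v <- stats::setNames(runif(30, 0, 100), sprintf("f%02d", 1:30))
  thr <- 50
  expect_identical(upTranscribedFamilies(v, thr), names(v)[v > thr])
})
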