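test_that("roles derive from labels with configurable degradative set", {
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:6), parent_id = "c1", ordinal = 0:5,
    length_bp = 1000L,
    labels = c("GH16_3", "susD", "GT2", "CBM32", "susC;GH5", "PL7_5"),
    stringsAsFactors = FALSE)
  r <- assignRoles(genes)
  expect_identical(r$role,
                   c("degradative_cazyme", "susD", "other", "other", "susC",
                     "degradative_cazyme"))
  # a dual susC/CAZyme gene keeps susC role but still counts as CAZyme
  expect_true(r$is_susC[5] && r$is_cazyme[5])
  # CBMs count as degradative only when configured in
  r2 <- assignRoles(genes, degradativeClasses = c("GH", "PL", "CE", "CBM"))
  expect_identical(r2$role[4], "degradative_cazyme")
})

test_that("the two PUL clauses trigger as specified", {
  # susC/susD pair with two degradative CAZymes
  calls <- detectPuls(locusFromRoles(c("susC", "susD", "cazyme", "cazyme")))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$trigger_clause, "susCD_pair")
  # a pair with a single CAZyme is not enough
  expect_identical(
    nrow(detectPuls(locusFromRoles(c("susC", "susD", "cazyme")))), 0L)
  # three CAZymes six genes apart chain into a call ...
  roles6 <- c("cazyme", rep("other", 6), "cazyme", "cazyme")
  calls <- detectPuls(locusFromRoles(roles6))
  expect_identical(calls$trigger_clause, "cazyme_cluster")
  # ... but seven intervening genes break the chain
  roles7 <- c("cazyme", rep("other", 7), "cazyme", "cazyme")
  expect_identical(nrow(detectPuls(locusFromRoles(roles7))), 0L)
})

test_that("pul detection is symmetric under locus reversal", {
  set.seed(61)
  for (rep in 1:60) {
    roles <- sample(c("susC", "susD", "cazyme", "other"),
                    sample(4:14, 1), replace = TRUE)
    fwd <- detectPuls(locusFromRoles(roles))
    rev_calls <- detectPuls(locusFromRoles(rev(roles)))
    expect_identical(nrow(fwd), nrow(rev_calls))
    if (nrow(fwd)) {
      n <- length(roles)
      expect_setequal(
        paste(fwd$start_ordinal, fwd$end_ordinal),
        paste(n - 1L - rev(rev_calls$end_ordinal),
              n - 1L - rev(rev_calls$start_ordinal)))
    }
  }
})

test_that("detect_puls agrees with the brute-force checker on random loci", {
  set.seed(62)
  for (rep in 1:300) {
    roles <- sample(c("susC", "susD", "cazyme", "other"),
                    sample(1:12, 1), replace = TRUE)
    expectPulAgreement(roles)
  }
})

test_that("padding beyond the gap never creates a call", {
  # two CAZymes, then padding grows beyond maxGap before a third
  for (pad in 0:8) {
    roles <- c("cazyme", "cazyme", rep("other", pad), "cazyme")
    got <- nrow(detectPuls(locusFromRoles(roles)))
    expect_identical(got, if (pad <= 6) 1L else 0L)
  }
})

test_that("planted PULs are recovered exactly at zero noise", {
  archs <- rep(list(c("susC", "susD", "GH16_3", "GH29"),
                    c("GH5", "hypothetical", "GH13", "PL6"),
                    character(0)), length.out = 30)
  ml <- makeLoci(archs, n_filler = 12L, seed = 63)
  calls <- detectPuls(assignRoles(ml$genes))
  # exactly one call per planted architecture, none on filler contigs
  expect_identical(sort(calls$contig_id), sort(ml$truth$contig_id))
  idx <- match(calls$contig_id, ml$truth$contig_id)
  expect_identical(calls$start_ordinal, ml$truth$start_ordinal[idx])
  expect_identical(calls$end_ordinal, ml$truth$end_ordinal[idx])
})

test_that("every reported call re-validates against the rule checker", {
  set.seed(64)
  for (rep in 1:40) {
    roles <- sample(c("susC", "susD", "cazyme", "other"), 12, replace = TRUE)
    calls <- detectPuls(locusFromRoles(roles))
    oracle <- brutePulSpans(roles, 6L)
    if (nrow(calls)) {
      expect_false(is.null(oracle))
      for (j in seq_len(nrow(calls))) {
        expect_true(any(oracle[, 1] == calls$start_ordinal[j] + 1 &
                          oracle[, 2] == calls$end_ordinal[j] + 1))
      }
    }
  }
})

test_that("pul transcription sums and averages member TPM", {
  locus <- assignRoles(data.frame(
    gene_id = c("a", "b", "c", "d"), parent_id = "c1", ordinal = 0:3,
    length_bp = 1000L, labels = c("susC", "susD", "GH16_3", "GH29"),
    stringsAsFactors = FALSE))
  call <- detectPuls(locus)[1, ]
  tr <- pulTranscription(call, c(a = 10, b = 20, c = 30, d = 0))
  expect_equal(tr$sum, 60)
  expect_equal(tr$mean, 15)
  zero <- pulTranscription(call, c(a = 0, b = 0, c = 0, d = 0))
  expect_identical(c(zero$sum, zero$mean), c(0, 0))
  expect_error(pulTranscription(call, c(a = 1, b = 2, c = 3)), "d")
})

test_that("locus diagrams mark PUL spans", {
  locus <- assignRoles(data.frame(
    gene_id = c("a", "b", "c", "d", "e"), parent_id = "c1", ordinal = 0:4,
    length_bp = 1000L, labels = c("other", "susC", "susD", "GH16_3", "GH29"),
    stringsAsFactors = FALSE))
  lines <- locusDiagram(locus, detectPuls(locus))
  expect_identical(length(lines), 5L)
  expect_false(grepl("PUL", lines[1]))
  expect_true(all(grepl("PUL", lines[2:5])))
})
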