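markerGenes <- function(counts) {
  # counts: named vector marker -> number of genes carrying it
  labels <- rep(names(counts), counts)
  data.frame(gene_id = sprintf("g%04d", seq_along(labels)),
             parent_id = sprintf("r%04d", seq_along(labels)),
             ordinal = 0L, length_bp = 900L, labels = labels,
             stringsAsFactors = FALSE)
}

test_that("genome equivalents is the mean marker count", {
  even <- stats::setNames(rep(10L, 16), scrbpMarkers())
  expect_identical(genomeEquivalents(markerGenes(even)), 10)
  mixed <- stats::setNames(c(rep(10L, 8), rep(20L, 8)), scrbpMarkers())
  expect_identical(genomeEquivalents(markerGenes(mixed)), 15)
  # linear in counts
  expect_identical(genomeEquivalents(markerGenes(mixed * 2L)), 30)
  # no markers at all -> error
  none <- markerGenes(c(GH16_3 = 5L))
  expect_error(genomeEquivalents(none), "no SC-RBP")
})

test_that("a community of G genomes with one copy each gives G", {
  g <- 7L
  counts <- stats::setNames(rep(g, 16), scrbpMarkers())
  expect_identical(genomeEquivalents(markerGenes(counts)), as.numeric(g))
})

test_that("greedy clustering separates by identity threshold", {
  s <- paste(rep("ACGT", 75), collapse = "")
  expect_identical(
    length(unique(clusterMarkerGenes(c(a = s, b = s, c = s), 99)$cluster_id)),
    1L)
  set.seed(31)
  far <- MetaGlyco:::.mutateDna(s, 0.2)
  expect_identical(
    length(unique(clusterMarkerGenes(c(a = s, b = far), 99)$cluster_id)),
    2L)
  expect_identical(nrow(clusterMarkerGenes(character(0), 99)), 0L)
  expect_error(clusterMarkerGenes(c(a = s), 0), "threshold")
})

test_that("cluster count never increases when the threshold is relaxed", {
  set.seed(32)
  base <- MetaGlyco:::.randomDna(200)
  pool <- vapply(1:12, function(i) MetaGlyco:::.mutateDna(base, runif(1, 0, 0.1)),
                 character(1))
  names(pool) <- sprintf("s%02d", 1:12)
  n_at <- vapply(c(99, 97, 95, 90, 80), function(th) {
    length(unique(clusterMarkerGenes(pool, th)$cluster_id))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("marker pools recover the planted species count", {
  # species bases ~5% apart, within-species copies ~0.2% apart,
  # clustered at 99% identity
  ok <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    comm <- makeCommunity(n_species = 5, seed = 900 + r)
    set.seed(1900 + r)
    pool <- character(0)
    for (i in 1:5) {
      for (k in 1:3) {
        pool[sprintf("sp%d_c%d", i, k)] <-
          MetaGlyco:::.mutateDna(comm$marker_seq$L6[[i]], 0.001)
      }
    }
    cl <- clusterMarkerGenes(pool, 99)
    if (length(unique(cl$cluster_id)) == 5L) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("species count averages the four marker cluster counts", {
  s <- function(n, seed) {
    set.seed(seed)
    stats::setNames(vapply(seq_len(n), function(i) MetaGlyco:::.randomDna(150),
                           character(1)), sprintf("x%d_%d", seed, seq_len(n)))
  }
  pools <- list(L3 = s(8, 1), L4 = s(10, 2), L6 = s(12, 3), S8 = s(10, 4))
  # random sequences are ~75% divergent: every sequence is its own cluster
  expect_identical(speciesCount(pools), 10)
  expect_error(speciesCount(pools[c("L3", "L4", "L6")]), "S8")
  one <- lapply(pools, function(p) p[1])
  expect_identical(speciesCount(one), 1)
})

test_that("composition profiles are normalised shares", {
  clusters <- data.frame(gene_id = c("a", "b", "c", "d"),
                         cluster_id = c("c1", "c1", "c1", "c2"),
                         centroid_gene_id = c("a", "a", "a", "d"))
  prof <- compositionProfile(clusters)
  expect_equal(prof$share, c(0.75, 0.25))
  expect_equal(sum(prof$share), 1, tolerance = 1e-9)

  # metatranscriptome mode: TPM weights
  w <- c(a = 10, b = 0, c = 0, d = 30)
  prof <- compositionProfile(clusters, weights = w)
  expect_equal(stats::setNames(prof$share, prof$taxon),
               c(c2 = 0.75, c1 = 0.25))

  # permutation invariance
  perm <- sample(1:4)
  prof2 <- compositionProfile(clusters[perm, ], weights = w)
  expect_equal(prof2[order(prof2$taxon), ], prof[order(prof$taxon), ],
               ignore_attr = TRUE)
  expect_error(compositionProfile(clusters, weights = c(a = 0, b = 0, c = 0,
                                                        d = 0)),
               "zero")
})

test_that("majority vote picks the strict winner, LCA on ties", {
  tr <- taxonomyTree(1:6, c(1L, 1L, 2L, 2L, 1L, 5L),
                     c("root", "genus", "species", "species", "genus",
                       "species"))
  expect_identical(majorityVote(tr, c(3L, 3L, 4L)), 3L)
  expect_identical(majorityVote(tr, c(3L, 4L)), 2L)   # tie -> LCA
  expect_identical(majorityVote(tr, c(3L, 6L)), 1L)   # cross-genus tie
  set.seed(33)
  for (j in 1:25) {
    taxa <- sample(c(3L, 4L, 6L), sample(1:7, 1), replace = TRUE)
    tab <- table(taxa)
    top <- as.integer(names(tab)[tab == max(tab)])
    want <- if (length(top) == 1L) top else
      bruteLca(top, tr@taxid, tr@parent)
    expect_identical(majorityVote(tr, taxa), want)
  }
})
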