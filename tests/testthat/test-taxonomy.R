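smallTree <- function() {
  # root(1) -> genus P(2) -> species X(3), Y(4); genus Q(5) -> species Z(6)
  taxonomyTree(taxid = 1:6, parent = c(1L, 1L, 2L, 2L, 1L, 5L),
               rank = c("root", "genus", "species", "species", "genus",
                        "species"))
}

test_that("hit filtering applies strict thresholds and preserves order", {
  hits <- data.frame(
    query_gene_id = "g1", subject_id = letters[1:5],
    percent_identity = c(70, 65, 66, 90, 64),
    evalue = c(1e-20, 1e-20, 1e-10, 1e-11, 1e-30),
    query_coverage = c(60, 60, 51, 50, 80),
    bitscore = 100, subject_taxid = 1:5, stringsAsFactors = FALSE)
  kept <- filterHits(hits, hitFilter())
  # boundary identity 65 (b), boundary evalue 1e-10 (c), boundary
  # cover 50 (d) and identity 64 (e) are all rejected (strict
  # comparisons); only (a) survives
  expect_identical(kept$subject_id, "a")
  relaxed <- hits
  relaxed$query_coverage[4] <- 50.01
  expect_identical(filterHits(relaxed, hitFilter())$subject_id, c("a", "d"))

  set.seed(7)
  big <- data.frame(
    query_gene_id = "g", subject_id = as.character(1:1000),
    percent_identity = runif(1000, 0, 100),
    evalue = 10^runif(1000, -30, 0),
    query_coverage = runif(1000, 0, 100),
    bitscore = 1, subject_taxid = 1L, stringsAsFactors = FALSE)
  kept <- filterHits(big, hitFilter())
  manual <- big[big$percent_identity > 65 & big$evalue < 1e-10 &
                  big$query_coverage > 50, ]
  expect_identical(kept, manual)
})

test_that("lca returns the deepest shared ancestor", {
  tr <- smallTree()
  expect_identical(lca(tr, 3L), 3L)           # singleton
  expect_identical(lca(tr, c(3L, 4L)), 2L)    # siblings -> parent
  expect_identical(lca(tr, c(3L, 6L)), 1L)    # across genera -> root
  expect_identical(lca(tr, c(3L, 2L)), 2L)    # ancestor absorbs descendant
  expect_error(lca(tr, integer(0)), "non-empty")
  expect_error(lca(tr, 99L), "99")
})

test_that("lca matches the brute-force root-path oracle on random trees", {
  set.seed(11)
  for (rep in 1:40) {
    tx <- makeTaxonomy(n_species = sample(3:80, 1), seed = 500 + rep)
    tr <- tx$tree
    ids <- taxIds(tr)
    for (j in 1:10) {
      taxa <- sample(ids, sample(1:6, 1), replace = TRUE)
      expect_identical(lca(tr, taxa), bruteLca(taxa, tr@taxid, tr@parent))
    }
  }
})

test_that("lca is idempotent, order-invariant and monotone", {
  set.seed(12)
  tx <- makeTaxonomy(n_species = 30, seed = 77)
  tr <- tx$tree
  ids <- taxIds(tr)
  for (j in 1:30) {
    taxa <- sample(ids, sample(2:6, 1), replace = TRUE)
    a <- lca(tr, taxa)
    expect_identical(lca(tr, rev(taxa)), a)
    expect_identical(lca(tr, taxa[1]), taxa[1])
    # adding a taxon never yields a deeper (longer-lineage) result
    extra <- lca(tr, c(taxa, sample(ids, 1)))
    expect_lte(length(lineage(tr, extra)), length(lineage(tr, a)))
  }
})

test_that("gene classification uses filtered hits and flags unclassified", {
  tr <- smallTree()
  mk <- function(taxids, id = 65.1) data.frame(
    query_gene_id = "g1", subject_id = "s",
    percent_identity = id, evalue = 1e-20, query_coverage = 60,
    bitscore = 1, subject_taxid = taxids, stringsAsFactors = FALSE)
  expect_identical(classifyGene(mk(c(3L, 3L)), hitFilter(), tr)$taxid, 3L)
  expect_identical(classifyGene(mk(c(3L, 4L)), hitFilter(), tr)$taxid, 2L)
  # nothing survives the filter -> unclassified
  res <- classifyGene(mk(3L, id = 50), hitFilter(), tr)
  expect_true(is.na(res$taxid))
  expect_identical(res$n_hits_used, 0L)
  # mixed query ids are an error
  two <- rbind(mk(3L), mk(4L))
  two$query_gene_id <- c("g1", "g2")
  expect_error(classifyGene(two, hitFilter(), tr), "single gene")
})

test_that("read classification excludes unclassified genes", {
  tr <- smallTree()
  genes <- data.frame(gene_id = c("a", "b", "c"), parent_id = "r1",
                      ordinal = 0:2, length_bp = 900L, labels = "other")
  gc <- data.frame(gene_id = c("a", "b", "c"),
                   taxid = c(3L, 3L, NA), n_hits_used = c(2L, 1L, 0L))
  rc <- classifyReads(gc, genes, tr)
  expect_identical(rc$taxid, 3L)
  expect_identical(rc$n_genes_used, 2L)

  gc$taxid <- rep(NA_integer_, 3)
  rc <- classifyReads(gc, genes, tr)
  expect_true(is.na(rc$taxid))
  expect_identical(rc$n_genes_used, 0L)
})

test_that("read classification is invariant under gene order permutation", {
  tr <- smallTree()
  genes <- data.frame(gene_id = letters[1:4], parent_id = "r1",
                      ordinal = 0:3, length_bp = 900L, labels = "other")
  gc <- data.frame(gene_id = letters[1:4], taxid = c(3L, 4L, 3L, NA),
                   n_hits_used = 1L)
  ref <- classifyReads(gc, genes, tr)
  perm <- sample(1:4)
  expect_identical(classifyReads(gc[perm, ], genes, tr)$taxid, ref$taxid)
})

test_that("read taxonomy propagates to genes without losing classifications", {
  tr <- smallTree()
  genes <- data.frame(gene_id = letters[1:3], parent_id = "r1",
                      ordinal = 0:2, length_bp = 900L, labels = "other")
  gc <- data.frame(gene_id = letters[1:3], taxid = c(3L, NA, 4L),
                   n_hits_used = 1L)
  rc <- classifyReads(gc, genes, tr)
  prop <- propagateReadTaxonomy(rc, gc, genes)
  # classified read overrides gene calls for all its genes
  expect_identical(prop$taxid, rep(rc$taxid, 3))
  expect_identical(unique(prop$source), "read")

  # unclassified read keeps gene-level calls
  rc$taxid <- NA_integer_
  prop <- propagateReadTaxonomy(rc, gc, genes)
  expect_identical(prop$taxid, gc$taxid)
  expect_gte(sum(!is.na(prop$taxid)), sum(!is.na(gc$taxid)))
})

test_that("noise-free synthetic reads classify at or below their genus", {
  comm <- makeCommunity(n_species = 15, seed = 21)
  mh <- makeHits(comm, n_reads = 150, noise = 0, seed = 22)
  gc <- classifyGenes(mh$hits, hitFilter(), comm$tree)
  rc <- classifyReads(gc, mh$genes, comm$tree)
  asg <- rc$taxid[match(mh$truth$read_id, rc$read_id)]
  ok <- mapply(function(a, g) !is.na(a) && isDescendant(comm$tree, a, g),
               asg, mh$truth$genus_taxid)
  expect_identical(mean(ok), 1)
})
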