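# Seeded generators producing every input the pipeline consumes, with
# known ground truth. Every generator is a pure function of its
# arguments and seed: exported wrappers install the seed, internal
# `.make*` cores draw from the current RNG stream so that makeStudy()
# can compose them deterministically under one root seed.

.ranks <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

.makeTaxonomy <- function(n_species) {
  counts <- c(
    domain = max(1L, min(2L, n_species)),
    phylum = max(1L, ceiling(n_species / 10)),
    class = max(1L, ceiling(n_species / 8)),
    order = max(1L, ceiling(n_species / 6)),
    family = max(1L, ceiling(n_species / 4)),
    genus = max(1L, ceiling(n_species / 2)),
    species = n_species
  )
  taxid <- 1L
  parent <- 1L
  rank <- "root"
  name <- "root"
  prev_ids <- 1L
  next_id <- 2L
  for (r in .ranks) {
    k <- counts[[r]]
    ids <- seq.int(next_id, length.out = k)
    parent_ids <- if (length(prev_ids) == 1L) rep(prev_ids, k) else {
      prev_ids[sample.int(length(prev_ids), k, replace = TRUE)]
    }
    taxid <- c(taxid, ids)
    parent <- c(parent, parent_ids)
    rank <- c(rank, rep(r, k))
    name <- c(name, sprintf("%s_%02d", r, seq_len(k)))
    prev_ids <- ids
    next_id <- next_id + k
  }
  tree <- taxonomyTree(taxid, parent, rank, name)
  list(tree = tree, species_taxids = taxid[rank == "species"])
}

#' Generate a random rooted taxonomy
#'
#' Builds a random tree with ranks domain through species: each node's
#' parent is drawn uniformly from the rank above. Deterministic per
#' seed.
#'
#' @param n_species number of species leaves (>= 1).
#' @param seed integer seed.
#' @return list with `tree` (a [TaxonomyTree-class]) and
#'   `species_taxids`.
#' @export
makeTaxonomy <- function(n_species, seed) {
  stopifnot(n_species >= 1L)
  withSeed(seed, .makeTaxonomy(n_species))
}

# draw one element (safe for length-1 vectors, unlike sample())
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateDna <- function(seq, divergence) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < divergence)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.makeCommunity <- function(n_species, concentration, genome_length,
                           marker_seq_length = 300L) {
  taxo <- .makeTaxonomy(n_species)
  tree <- taxo$tree
  sp_tax <- taxo$species_taxids
  g <- stats::rgamma(n_species, shape = concentration, rate = 1)
  abundance <- g / sum(g)
  species <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n_species)),
    taxid = sp_tax,
    genus_taxid = vapply(sp_tax, function(t) ancestorAtRank(tree, t, "genus"),
                         integer(1)),
    family_taxid = vapply(sp_tax, function(t) ancestorAtRank(tree, t, "family"),
                          integer(1)),
    genome_length_bp = as.integer(genome_length),
    abundance = abundance,
    stringsAsFactors = FALSE
  )
  # per-species CAZyme roster: per-genome copy numbers over a fixed
  # family pool; half of the species carry Sus-type PUL machinery
  pool <- c("GH16_3", "GH16", "GH17", "GH29", "GH92", "GH33", "GH28",
            "GH23", "GH73", "GH103", "CE11", "PL7_5", "PL6", "PL17",
            "GH13", "CBM32")
  roster <- lapply(seq_len(n_species), function(i) {
    copies <- stats::rpois(length(pool), lambda = 1.2)
    names(copies) <- pool
    copies[c("GH23", "GH73", "CE11")] <- copies[c("GH23", "GH73", "CE11")] + 1L
    copies
  })
  names(roster) <- species$species_id
  has_pul <- seq_len(n_species) %% 2L == 1L
  # ancestral marker sequences; each species base diverges 2.5% from
  # the ancestor, so species pairs sit near 5% pairwise divergence
  markers <- speciesMarkers()
  ancestral <- stats::setNames(
    vapply(markers, function(m) .randomDna(marker_seq_length), character(1)),
    markers)
  marker_seq <- lapply(stats::setNames(markers, markers), function(m) {
    stats::setNames(
      vapply(seq_len(n_species), function(i) .mutateDna(ancestral[[m]], 0.025),
             character(1)),
      species$species_id)
  })
  list(tree = tree, species = species, roster = roster, has_pul = has_pul,
       marker_seq = marker_seq)
}

#' Generate a synthetic community specification
#'
#' A multi-species community with Dirichlet-distributed relative
#' abundances (symmetric concentration, default 3: a moderately uneven
#' community), a random taxonomy, per-species CAZyme rosters over a
#' fixed family pool, Sus-type PUL capability for half the species, and
#' per-species marker-gene sequences (ancestral sequence per marker
#' mutated per species so that species pairs diverge by ~5%;
#' within-species gene copies diverge pairwise by ~0.2%).
#'
#' @param n_species number of species (default 20).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration (default 3).
#' @param genome_length genome length in bp for every species.
#' @return list with `tree`, `species` (data.frame), `roster`,
#'   `has_pul`, `marker_seq`.
#' @export
makeCommunity <- function(n_species = 20L, seed = 1L, concentration = 3,
                          genome_length = 1e5) {
  withSeed(seed, .makeCommunity(n_species, concentration, genome_length))
}

# hits for a vector of genes with known source species.
# Informative hits target the true species (70%) or a same-genus
# species; spurious hits (a `noise` fraction of genes) emulate
# misassignment to close relatives: same family (95%) or anywhere (5%),
# with identity straddling the retention threshold.
.hitsForGenes <- function(community, gene_ids, gene_species,
                          noise = 0, identity_range = c(80, 100),
                          spurious_identity_range = c(50, 72),
                          spurious_same_family = 0.95) {
  sp <- community$species
  res <- vector("list", length(gene_ids))
  same_genus <- lapply(seq_len(nrow(sp)), function(i) {
    setdiff(which(sp$genus_taxid == sp$genus_taxid[i]), i)
  })
  same_family <- lapply(seq_len(nrow(sp)), function(i) {
    setdiff(which(sp$family_taxid == sp$family_taxid[i]), i)
  })
  for (g in seq_along(gene_ids)) {
    i <- match(gene_species[g], sp$species_id)
    k <- sample.int(5L, 1L)
    informative <- stats::runif(k) < 0.7
    subj <- integer(k)
    for (h in seq_len(k)) {
      subj[h] <- if (informative[h] || !length(same_genus[[i]])) {
        sp$taxid[i]
      } else {
        sp$taxid[.sample1(same_genus[[i]])]
      }
    }
    hit <- data.frame(
      query_gene_id = gene_ids[g],
      subject_id = sprintf("ref_%d_%d", i, seq_len(k)),
      percent_identity = stats::runif(k, identity_range[1], identity_range[2]),
      evalue = 10^stats::runif(k, -30, -15),
      query_coverage = stats::runif(k, 60, 100),
      bitscore = stats::runif(k, 200, 800),
      subject_taxid = subj,
      stringsAsFactors = FALSE
    )
    if (noise > 0 && stats::runif(1) < noise) {
      off <- if (stats::runif(1) < spurious_same_family &&
                 length(same_family[[i]])) {
        .sample1(same_family[[i]])
      } else {
        .sample1(setdiff(seq_len(nrow(sp)), i))
      }
      hit <- rbind(hit, data.frame(
        query_gene_id = gene_ids[g],
        subject_id = sprintf("ref_spur_%d", g),
        percent_identity = stats::runif(1, spurious_identity_range[1],
                                        spurious_identity_range[2]),
        evalue = 10^stats::runif(1, -20, -12),
        query_coverage = stats::runif(1, 55, 90),
        bitscore = stats::runif(1, 80, 300),
        subject_taxid = sp$taxid[off],
        stringsAsFactors = FALSE
      ))
    }
    res[[g]] <- hit
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.makeHits <- function(community, n_reads, genes_per_read, noise, ...) {
  sp <- community$species
  read_sp <- sample.int(nrow(sp), n_reads, replace = TRUE,
                        prob = sp$abundance)
  read_id <- sprintf("read%05d", seq_len(n_reads))
  genes <- data.frame(
    gene_id = sprintf("%s_g%d", rep(read_id, each = genes_per_read),
                      rep(seq_len(genes_per_read), n_reads)),
    parent_id = rep(read_id, each = genes_per_read),
    ordinal = rep(seq_len(genes_per_read) - 1L, n_reads),
    length_bp = sample(300:1500, n_reads * genes_per_read, replace = TRUE),
    labels = "other",
    stringsAsFactors = FALSE
  )
  gene_species <- rep(sp$species_id[read_sp], each = genes_per_read)
  hits <- .hitsForGenes(community, genes$gene_id, gene_species,
                        noise = noise, ...)
  truth <- data.frame(
    read_id = read_id,
    species_id = sp$species_id[read_sp],
    taxid = sp$taxid[read_sp],
    genus_taxid = sp$genus_taxid[read_sp],
    family_taxid = sp$family_taxid[read_sp],
    stringsAsFactors = FALSE
  )
  list(hits = hits, genes = genes, truth = truth)
}

#' Generate synthetic alignment hits with known source taxa
#'
#' Reads are drawn from the community's abundance vector; each read
#' carries `genes_per_read` genes, each gene 1-5 hits within the true
#' species' genus at identities above the retention thresholds. A
#' `noise` fraction of genes receives one extra spurious hit emulating
#' misassignment to a close relative (same family with probability
#' 0.95, otherwise any species) at identities straddling the 65%
#' threshold.
#'
#' @param community output of [makeCommunity()].
#' @param n_reads number of reads.
#' @param noise fraction of genes receiving a spurious hit.
#' @param seed integer seed.
#' @param genes_per_read genes per read (default 5).
#' @return list with `hits`, `genes` (annotation) and `truth` (per-read
#'   generating taxon).
#' @export
makeHits <- function(community, n_reads, noise = 0, seed = 1L,
                     genes_per_read = 5L) {
  withSeed(seed, .makeHits(community, n_reads, genes_per_read, noise))
}

.makeDepthTracks <- function(community, total_genome_equivalents,
                             poisson_noise) {
  sp <- community$species
  iv <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    len <- sp$genome_length_bp[i]
    lambda <- sp$abundance[i] * total_genome_equivalents
    if (poisson_noise) {
      d <- stats::rpois(len, lambda)
      r <- rle(d)
      end <- cumsum(r$lengths)
      iv[[i]] <- data.frame(genome_id = sp$species_id[i],
                            start = end - r$lengths, end = end,
                            depth = as.numeric(r$values),
                            stringsAsFactors = FALSE)
    } else {
      iv[[i]] <- data.frame(genome_id = sp$species_id[i], start = 0L,
                            end = len, depth = lambda,
                            stringsAsFactors = FALSE)
    }
  }
  lengths <- stats::setNames(sp$genome_length_bp, sp$species_id)
  list(
    depth = depthTrackSet(do.call(rbind, iv), lengths = lengths),
    truth = data.frame(genome_id = sp$species_id,
                       mean_depth = sp$abundance * total_genome_equivalents,
                       relative_abundance = sp$abundance,
                       stringsAsFactors = FALSE)
  )
}

#' Generate depth tracks with known relative abundances
#'
#' Per species, the mean depth is `abundance x total_genome_equivalents`;
#' per-base depths are Poisson around that mean (or constant when
#' `poisson_noise = FALSE`), run-length encoded into BEDGraph-style
#' intervals including zero runs.
#'
#' @param community output of [makeCommunity()].
#' @param total_genome_equivalents community genome equivalents.
#' @param poisson_noise draw per-base Poisson depths?
#' @param seed integer seed.
#' @return list with `depth` (a [DepthTrackSet-class]) and `truth`.
#' @export
makeDepthTracks <- function(community, total_genome_equivalents = 1000,
                            poisson_noise = TRUE, seed = 1L) {
  withSeed(seed, .makeDepthTracks(community, total_genome_equivalents,
                                  poisson_noise))
}

.makeTranscripts <- function(gene_lengths, rates, dispersion,
                             library_size) {
  p <- rates * gene_lengths / sum(rates * gene_lengths)
  counts <- stats::rnbinom(length(p), mu = library_size * p,
                           size = 1 / dispersion)
  list(
    counts = data.frame(gene_id = names(gene_lengths), count = counts,
                        stringsAsFactors = FALSE),
    truth_tpm = stats::setNames(1e6 * rates / sum(rates),
                                names(gene_lengths))
  )
}

#' Generate transcript counts with known truth TPM
#'
#' Counts are negative binomial with expectation proportional to
#' `rate x length` (rate = transcript abundance per gene); the truth
#' TPM follows analytically as `1e6 * rate / sum(rate)`. The default
#' dispersion (0.01) models the mild technical overdispersion of
#' counting transcripts from a single library; biological
#' between-replicate dispersion is larger but out of scope here.
#'
#' @param gene_lengths named positive integer vector.
#' @param rates per-gene expected transcription rates; default
#'   log-normal (sdlog 1.5, a wide dynamic range).
#' @param dispersion negative-binomial dispersion (> 0).
#' @param library_size expected total mapped transcripts.
#' @param seed integer seed.
#' @return list with `counts` (data.frame) and `truth_tpm`.
#' @export
makeTranscripts <- function(gene_lengths, rates = NULL, dispersion = 0.01,
                            library_size = 1e6, seed = 1L) {
  stopifnot(library_size > 0, dispersion > 0)
  withSeed(seed, {
    if (is.null(rates)) {
      rates <- stats::rlnorm(length(gene_lengths), meanlog = 0, sdlog = 1.5)
    }
    .makeTranscripts(gene_lengths, rates, dispersion, library_size)
  })
}

.makeLoci <- function(architectures, n_filler, contig_prefix) {
  contigs <- vector("list", length(architectures))
  truth <- vector("list", length(architectures))
  for (i in seq_along(architectures)) {
    arch <- architectures[[i]]
    labels <- rep("hypothetical", n_filler)
    insert_at <- if (n_filler > 0) sample.int(n_filler + 1L, 1L) - 1L else 0L
    all_labels <- append(labels, arch, after = insert_at)
    contig_id <- sprintf("%s%03d", contig_prefix, i)
    n <- length(all_labels)
    contigs[[i]] <- data.frame(
      gene_id = sprintf("%s_g%03d", contig_id, seq_len(n)),
      parent_id = contig_id,
      ordinal = seq_len(n) - 1L,
      length_bp = sample(600:2400, n, replace = TRUE),
      labels = all_labels,
      stringsAsFactors = FALSE
    )
    truth[[i]] <- if (length(arch)) {
      data.frame(contig_id = contig_id,
                 start_ordinal = insert_at,
                 end_ordinal = insert_at + length(arch) - 1L,
                 architecture = paste(arch, collapse = ";"),
                 stringsAsFactors = FALSE)
    } else NULL
  }
  list(genes = do.call(rbind, contigs), truth = do.call(rbind, truth))
}

#' Generate contigs with planted PUL architectures
#'
#' Each architecture (a vector of gene labels, e.g.
#' `c("susC", "susD", "GH16_3", "GH29")`) is embedded at a random
#' position among `n_filler` filler genes on its own contig; an empty
#' architecture yields a filler-only control contig. The truth table
#' records every planted span.
#'
#' @param architectures list of label vectors (possibly empty vectors).
#' @param n_filler filler genes per contig.
#' @param seed integer seed.
#' @param contig_prefix contig id prefix.
#' @return list with `genes` (annotation data.frame) and `truth`.
#' @export
makeLoci <- function(architectures, n_filler = 12L, seed = 1L,
                     contig_prefix = "contig") {
  withSeed(seed, .makeLoci(architectures, n_filler, contig_prefix))
}

.makeMicroarray <- function(samples, antibodies, presence, replicate_cv) {
  rows <- list()
  for (s in seq_along(samples)) {
    for (a in seq_along(antibodies)) {
      for (ext in .validExtractions) {
        base <- if (presence[s, a]) stats::runif(1, 15, 60) else
          stats::runif(1, 0.2, 2)
        noise <- if (replicate_cv > 0) {
          pmax(0, stats::rnorm(4L, mean = 1, sd = replicate_cv))
        } else rep(1, 4L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples[s], extraction = ext,
          antibody_id = antibodies[a], replicate = 1:4,
          signal = base * noise, is_control = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    # standard-control spots dominate the raw scale; the strongest one
    # defines the dataset maximum
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = samples[s], extraction = "H2O",
      antibody_id = "standard_control", replicate = 1:4,
      signal = stats::runif(4L, 200, 250), is_control = TRUE,
      stringsAsFactors = FALSE)
  }
  signals <- do.call(rbind, rows)
  microarraySignalSet(signals)
}

#' Generate microarray signals with known epitope presence
#'
#' Present epitopes draw per-extraction base signals well above the
#' retention threshold (after normalisation), absent epitopes below
#' it; replicate spots vary with coefficient of variation
#' `replicate_cv`. Standard-control spots provide the dataset maximum
#' and are flagged.
#'
#' @param samples character vector of sample ids.
#' @param antibodies character vector of antibody ids.
#' @param presence logical matrix (samples x antibodies); default
#'   random with probability 0.5.
#' @param replicate_cv replicate coefficient of variation (>= 0).
#' @param seed integer seed.
#' @return list with `signals` (a [MicroarraySignalSet-class]) and
#'   `truth` (the presence matrix).
#' @export
makeMicroarray <- function(samples, antibodies, presence = NULL,
                           replicate_cv = 0.1, seed = 1L) {
  stopifnot(replicate_cv >= 0)
  withSeed(seed, {
    if (is.null(presence)) {
      presence <- matrix(stats::runif(length(samples) * length(antibodies)) < 0.5,
                         nrow = length(samples),
                         dimnames = list(samples, antibodies))
    }
    list(signals = .makeMicroarray(samples, antibodies, presence,
                                   replicate_cv),
         truth = presence)
  })
}
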