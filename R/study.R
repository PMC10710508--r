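# makeStudy: compose all generators into one coherent synthetic study
# (8 samples across 4 stations x 2 depth layers), plus writeStudy to
# serialise every pipeline input with its ground truth.

.studyGeneTables <- function(community, abund, ge_target, sample_id) {
  sp <- community$species
  markers <- scrbpMarkers()
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    expect <- abund[i] * ge_target
    labels <- character(0)
    # SC-RBP markers: single-copy, so counts follow species depth
    for (m in markers) {
      labels <- c(labels, rep(m, stats::rpois(1L, expect)))
    }
    copies <- community$roster[[i]]
    for (f in names(copies)) {
      if (copies[[f]] > 0) {
        labels <- c(labels, rep(f, stats::rpois(1L, expect * copies[[f]])))
      }
    }
    labels <- c(labels,
                rep("peptidase", stats::rpois(1L, expect * 3)),
                rep("sulfatase", stats::rpois(1L, expect * 1.5)),
                rep("TBDT", stats::rpois(1L, expect * 2)))
    if (!length(labels)) next
    labels <- sample(labels)
    rows[[i]] <- data.frame(species_id = sp$species_id[i], labels = labels,
                            stringsAsFactors = FALSE)
  }
  gene_pool <- do.call(rbind, rows)
  n <- nrow(gene_pool)
  # bundle genes of one species into reads of up to 5 genes
  read_no <- 0L
  read_id <- character(n)
  ordinal <- integer(n)
  for (s in split(seq_len(n), gene_pool$species_id)) {
    chunks <- split(s, ceiling(seq_along(s) / 5))
    for (ch in chunks) {
      read_no <- read_no + 1L
      read_id[ch] <- sprintf("%s_read%05d", sample_id, read_no)
      ordinal[ch] <- seq_along(ch) - 1L
    }
  }
  data.frame(
    gene_id = sprintf("%s_gene%05d", sample_id, seq_len(n)),
    parent_id = read_id,
    ordinal = ordinal,
    length_bp = sample(300:1500, n, replace = TRUE),
    labels = gene_pool$labels,
    species_id = gene_pool$species_id,
    stringsAsFactors = FALSE
  )
}

.studyContigs <- function(community) {
  sp <- community$species
  genes <- list()
  truth <- list()
  for (i in seq_len(nrow(sp))) {
    sid <- sp$species_id[i]
    # one housekeeping contig per MAG carrying the 16 SC-RBPs
    hk <- data.frame(
      gene_id = sprintf("%s_hk_g%02d", sid, seq_along(scrbpMarkers())),
      parent_id = sprintf("%s_hk", sid),
      ordinal = seq_along(scrbpMarkers()) - 1L,
      length_bp = sample(600:1200, length(scrbpMarkers()), replace = TRUE),
      labels = scrbpMarkers(),
      stringsAsFactors = FALSE)
    hk$species_id <- sid
    genes[[length(genes) + 1L]] <- hk
    top_fams <- names(sort(community$roster[[i]], decreasing = TRUE))[1:3]
    archs <- if (community$has_pul[i]) {
      list(c("susC", "susD", top_fams[1], top_fams[2]),
           c(top_fams[1], "hypothetical", top_fams[2], top_fams[3]))
    } else {
      list(character(0))
    }
    loci <- .makeLoci(archs, n_filler = 10L,
                      contig_prefix = sprintf("%s_ctg", sid))
    loci$genes$species_id <- sid
    genes[[length(genes) + 1L]] <- loci$genes
    if (!is.null(loci$truth)) truth[[length(truth) + 1L]] <- loci$truth
  }
  list(genes = do.call(rbind, genes), truth = do.call(rbind, truth))
}

#' Generate a complete synthetic study
#'
#' Composes every generator into one coherent data set: a 20-species
#' community observed in 8 samples (4 stations x surface/bottom mixed
#' layer), with per-sample abundances drawn around the community base
#' composition, gene annotations bundled into reads, alignment hits
#' (5% spurious), marker-gene sequences, Poisson depth tracks,
#' negative-binomial transcript counts, MAG contigs with planted PULs,
#' and a glycan microarray. Genome lengths (5 kb), genome equivalents
#' (50) and library size (2e5) are kept small so a full study runs in
#' seconds; the quantities the pipeline estimates are unaffected by
#' this scaling.
#'
#' @param seed integer root seed; the whole study is a pure function of
#'   it.
#' @param n_species number of species (default 20).
#' @param n_samples number of samples (default 8, must be even).
#' @param genome_length per-species genome length (default 5000).
#' @param ge_target genome equivalents per sample (default 50).
#' @param library_size expected mapped transcripts per sample.
#' @param noise spurious-hit fraction (default 0.05).
#' @return A list with the community, per-sample tables, truth tables
#'   and generator parameters; see [writeStudy()].
#' @export
makeStudy <- function(seed = 1L, n_species = 20L, n_samples = 8L,
                      genome_length = 5000L, ge_target = 50,
                      library_size = 2e5, noise = 0.05) {
  stopifnot(n_samples %% 2L == 0L)
  withSeed(seed, {
    community <- .makeCommunity(n_species, concentration = 3,
                                genome_length = genome_length)
    stations <- sprintf("S%d", seq_len(n_samples / 2L))
    samples <- as.vector(outer(stations, c("SRF", "BML"), paste, sep = "_"))
    base <- community$species$abundance
    abund <- sapply(samples, function(s) {
      g <- stats::rgamma(length(base), shape = base * 50, rate = 1)
      g / sum(g)
    })
    rownames(abund) <- community$species$species_id

    contigs <- .studyContigs(community)

    genes <- list(); hits <- list(); depth <- list(); counts <- list()
    marker_seqs <- character(0)
    truth_tpm <- list()
    activity <- sapply(samples, function(s) {
      stats::rlnorm(n_species, meanlog = 0, sdlog = 0.8)
    })
    for (s in samples) {
      community_s <- community
      community_s$species$abundance <- abund[, s]
      g <- .studyGeneTables(community, abund[, s], ge_target, s)
      genes[[s]] <- g
      hits[[s]] <- .hitsForGenes(community, g$gene_id, g$species_id,
                                 noise = noise)
      depth[[s]] <- .makeDepthTracks(community_s, ge_target,
                                     poisson_noise = TRUE)$depth
      # species-resolution marker sequences (each copy 0.1% from the
      # species base, i.e. ~0.2% pairwise within-species divergence)
      for (m in speciesMarkers()) {
        lab <- splitLabels(g$labels)
        carry <- vapply(lab, function(l) m %in% l, logical(1))
        for (j in which(carry)) {
          marker_seqs[[g$gene_id[j]]] <-
            .mutateDna(community$marker_seq[[m]][[g$species_id[j]]], 0.001)
        }
      }
      # transcripts for community genes plus this sample's MAG genes
      act <- activity[match(g$species_id, community$species$species_id), s]
      act_ctg <- activity[match(contigs$genes$species_id,
                                community$species$species_id), s]
      all_len <- stats::setNames(c(g$length_bp, contigs$genes$length_bp),
                                 c(g$gene_id, contigs$genes$gene_id))
      rates <- c(act, act_ctg) * stats::rlnorm(length(all_len), 0, 1)
      tr <- .makeTranscripts(all_len, rates, dispersion = 0.01,
                             library_size = library_size)
      counts[[s]] <- tr$counts
      truth_tpm[[s]] <- tr$truth_tpm
    }

    antibodies <- c("FCSP_BAM1", "laminarin_BS400", "glucuronoxylan_LM28",
                    "xylan_LM10", "mannan_BS400_4", "arabinan_LM6",
                    "pectin_LM19", "alginate_BAM6", "ulvan_BS400_2",
                    "AGP_JIM13", "chitin_CBM3a", "starch_INCh1",
                    "fucoidan_BAM2", "carrageenan_BS400_3", "porphyran_INCh2",
                    "galactan_LM5", "xyloglucan_LM15", "rhamnogalacturonan_INRA")
    presence <- matrix(stats::runif(length(samples) * length(antibodies)) < 0.55,
                       nrow = length(samples),
                       dimnames = list(samples, antibodies))
    microarray <- .makeMicroarray(samples, antibodies, presence,
                                  replicate_cv = 0.1)

    list(
      community = community,
      samples = samples,
      genes = genes,
      hits = hits,
      depth = depth,
      counts = counts,
      marker_seqs = marker_seqs,
      contigs = contigs$genes,
      microarray = microarray,
      params = list(seed = seed, ge_target = ge_target,
                    genome_length = genome_length,
                    library_size = library_size, noise = noise),
      truth = list(abundance = abund, puls = contigs$truth,
                   presence = presence, tpm = truth_tpm,
                   species = community$species)
    )
  })
}

#' Write a synthetic study to disk
#'
#' Serialises every pipeline input of a [makeStudy()] result under
#' `dir`, together with a `truth/` directory and a ready-to-run
#' `config.yaml` for [runAll()].
#'
#' @param study a [makeStudy()] result.
#' @param dir output directory (created if absent).
#' @return The config file path, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  writeTaxdump(study$community$tree, file.path(dir, "nodes.dmp"),
               file.path(dir, "names.dmp"))
  writeGenomeManifest(
    stats::setNames(study$community$species$genome_length_bp,
                    study$community$species$species_id),
    file.path(dir, "manifest.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$marker_seqs),
    file.path(dir, "markers.fasta"))
  writeGeneAnnotation(study$contigs, file.path(dir, "contigs.tsv"))
  utils::write.table(
    data.frame(gene_id = study$contigs$gene_id,
               mag_id = study$contigs$species_id),
    file.path(dir, "contig_mags.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sample_cfg <- list()
  for (s in study$samples) {
    sdir <- file.path(dir, "samples", s)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    writeAlignmentHits(study$hits[[s]], file.path(sdir, "hits.tsv"))
    writeGeneAnnotation(study$genes[[s]], file.path(sdir, "genes.tsv"))
    writeDepthTrack(study$depth[[s]], file.path(sdir, "depth.bedgraph"))
    writeTranscriptCounts(study$counts[[s]], file.path(sdir, "counts.tsv"))
    sample_cfg[[s]] <- list(
      hits = file.path("samples", s, "hits.tsv"),
      genes = file.path("samples", s, "genes.tsv"),
      depth = file.path("samples", s, "depth.bedgraph"),
      counts = file.path("samples", s, "counts.tsv"))
  }
  writeMicroarraySignals(study$microarray, file.path(dir, "microarray.tsv"))
  # truth tables
  utils::write.table(
    data.frame(species_id = rownames(study$truth$abundance),
               study$truth$abundance, check.names = FALSE),
    file.path(dir, "truth", "abundance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(study$truth$puls, file.path(dir, "truth", "puls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(study$truth$presence),
               study$truth$presence, check.names = FALSE),
    file.path(dir, "truth", "presence.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(study$truth$species,
                     file.path(dir, "truth", "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  config <- list(
    base_dir = ".",
    seed = study$params$seed,
    inputs = list(
      nodes = "nodes.dmp", names = "names.dmp", manifest = "manifest.tsv",
      markers_fasta = "markers.fasta", contigs = "contigs.tsv",
      contig_mags = "contig_mags.tsv", microarray = "microarray.tsv",
      samples = sample_cfg),
    thresholds = list(
      min_identity = 65, max_evalue = 1e-10, min_query_cover = 50,
      ani = 99, tad_fraction = 0.8, pul_max_gap = 6,
      microarray_threshold = 5, min_markers = 8)
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
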