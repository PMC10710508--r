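# End-to-end pipeline: classify -> markers -> abundance ->
# transcription -> profiles -> pul -> microarray, driven by a single
# config (YAML or list). Every output file carries a provenance header
# (package version, config hash, seed) and a manifest JSON records
# checksums, so a re-run under the same config is byte-identical.

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

.provHeader <- function(version, config_md5, seed) {
  sprintf("# MetaGlyco %s; config_md5=%s; seed=%s", version, config_md5, seed)
}

.writeOutput <- function(df, path, header) {
  writeLines(header, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  path
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order on the inputs named in
#' `config`: taxonomic classification, marker-gene metrics (genome
#' equivalents, species count, L6 composition), TAD abundance, TPM and
#' MAG relative transcription, functional profiles, PUL detection, and
#' microarray processing. Missing input paths abort before any stage
#' runs; a stage failure aborts with the stage name, renaming that
#' stage's partial outputs with a `.partial` suffix. A
#' `manifest.json` lists every output with its MD5 checksum.
#'
#' @param config path to a YAML config (as written by [writeStudy()])
#'   or an equivalent list. Relative input paths resolve against the
#'   config file's directory joined with `base_dir`.
#' @param outdir output directory; default `<base_dir>/results`.
#' @return Invisibly, a list with `outdir`, `files` (named MD5 vector)
#'   and the parsed config.
#' @export
runAll <- function(config, outdir = NULL) {
  if (is.character(config)) {
    cfg_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    base <- normalizePath(file.path(cfg_dir, config$base_dir %||% "."))
  } else {
    base <- normalizePath(config$base_dir %||% ".")
  }
  inp <- config$inputs
  th <- config$thresholds %||% list()
  seed <- config$seed %||% 0L
  p <- function(x) file.path(base, x)
  outdir <- outdir %||% config$output_dir %||% file.path(base, "results")

  shared <- c(inp$nodes, inp$names, inp$manifest, inp$markers_fasta,
              inp$contigs, inp$microarray)
  per_sample <- unlist(inp$samples, use.names = FALSE)
  all_paths <- p(c(shared, per_sample))
  missing_paths <- all_paths[!file.exists(all_paths)]
  if (length(missing_paths)) {
    stopf("missing input path(s): %s", paste(missing_paths, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  version <- as.character(utils::packageVersion("MetaGlyco"))
  config_md5 <- .configHash(config)
  header <- .provHeader(version, config_md5, seed)
  files <- character(0)
  emit <- function(df, name) {
    path <- .writeOutput(df, file.path(outdir, name), header)
    files <<- c(files, path)
    path
  }
  stage_files_start <- 0L
  runStage <- function(stage, fun) {
    stage_files_start <<- length(files)
    tryCatch(fun(), error = function(e) {
      partial <- if (length(files) > stage_files_start) {
        files[(stage_files_start + 1L):length(files)]
      } else character(0)
      for (f in partial) file.rename(f, paste0(f, ".partial"))
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  tree <- readTaxdump(p(inp$nodes), p(inp$names))
  manifest_len <- readGenomeManifest(p(inp$manifest))
  filter <- hitFilter(th$min_identity %||% 65, th$max_evalue %||% 1e-10,
                      th$min_query_cover %||% 50)
  samples <- names(inp$samples)
  genes <- lapply(inp$samples, function(s) readGeneAnnotation(p(s$genes)))
  state <- new.env(parent = emptyenv())

  lineageOf <- local({
    cache <- new.env(parent = emptyenv())
    function(taxid) {
      if (is.na(taxid)) return("unclassified")
      key <- as.character(taxid)
      if (is.null(cache[[key]])) cache[[key]] <- lineageString(tree, taxid)
      cache[[key]]
    }
  })

  runStage("classify", function() {
    gene_rows <- list(); read_rows <- list()
    state$gene_tax <- list()
    for (s in samples) {
      hits <- readAlignmentHits(p(inp$samples[[s]]$hits))
      gc <- classifyGenes(hits, filter, tree)
      rc <- classifyReads(gc, genes[[s]], tree)
      prop <- propagateReadTaxonomy(rc, gc, genes[[s]])
      state$gene_tax[[s]] <- stats::setNames(prop$taxid, prop$gene_id)
      gene_rows[[s]] <- data.frame(sample_id = s, prop,
                                   lineage = vapply(prop$taxid, lineageOf,
                                                    character(1)))
      read_rows[[s]] <- data.frame(sample_id = s, rc,
                                   lineage = vapply(rc$taxid, lineageOf,
                                                    character(1)))
    }
    emit(do.call(rbind, gene_rows), "gene_classification.tsv")
    emit(do.call(rbind, read_rows), "read_classification.tsv")
  })

  runStage("markers", function() {
    ge <- vapply(samples, function(s) genomeEquivalents(genes[[s]]),
                 numeric(1))
    state$ge <- ge
    emit(data.frame(sample_id = samples, genome_equivalents = unname(ge)),
         "genome_equivalents.tsv")
    seqs <- Biostrings::readDNAStringSet(p(inp$markers_fasta))
    all_genes <- do.call(rbind, lapply(samples, function(s) {
      data.frame(sample_id = s, gene_id = genes[[s]]$gene_id,
                 labels = genes[[s]]$labels, stringsAsFactors = FALSE)
    }))
    lab <- splitLabels(all_genes$labels)
    ani <- th$ani %||% 99
    pools <- lapply(stats::setNames(speciesMarkers(), speciesMarkers()),
                    function(m) {
      ids <- all_genes$gene_id[vapply(lab, function(l) m %in% l, logical(1))]
      seqs[intersect(ids, names(seqs))]
    })
    n_clusters <- vapply(pools, function(pool) {
      length(unique(clusterMarkerGenes(pool, ani)$cluster_id))
    }, numeric(1))
    emit(data.frame(marker = names(n_clusters),
                    n_clusters = unname(n_clusters),
                    species_count = mean(n_clusters)),
         "species_count.tsv")
    # L6-cluster composition per sample, majority-vote taxonomy
    l6 <- clusterMarkerGenes(pools[["L6"]], ani)
    gene_tax_all <- unlist(unname(state$gene_tax))
    comp_rows <- list()
    for (s in samples) {
      sub <- l6[l6$gene_id %in% genes[[s]]$gene_id, , drop = FALSE]
      if (!nrow(sub)) next
      comp <- compositionProfile(sub, taxids = gene_tax_all, tree = tree)
      comp_rows[[s]] <- data.frame(
        sample_id = s, comp,
        name = vapply(as.integer(comp$taxon), function(t) taxName(tree, t),
                      character(1)))
    }
    emit(do.call(rbind, comp_rows), "composition.tsv")
  })

  runStage("abundance", function() {
    rows <- list()
    for (s in samples) {
      dts <- readDepthTrack(p(inp$samples[[s]]$depth), lengths = manifest_len)
      tads <- tad(dts, centralFraction = th$tad_fraction %||% 0.8)
      sanity <- competitiveDepthSanity(dts)
      rows[[s]] <- data.frame(
        sample_id = s, genome_id = names(tads), tad = unname(tads),
        relative_abundance = relativeAbundance(unname(tads), state$ge[[s]]),
        covered_fraction = sanity$covered_fraction[match(names(tads),
                                                         sanity$genome_id)],
        flagged = sanity$flagged[match(names(tads), sanity$genome_id)],
        stringsAsFactors = FALSE)
    }
    emit(do.call(rbind, rows), "abundance.tsv")
  })

  contigs <- readGeneAnnotation(p(inp$contigs))
  contig_mag <- if (!is.null(inp$contig_mags)) {
    m <- utils::read.delim(p(inp$contig_mags), stringsAsFactors = FALSE)
    stats::setNames(m$mag_id, m$gene_id)
  } else {
    stats::setNames(contigs$parent_id, contigs$gene_id)
  }

  runStage("transcription", function() {
    state$tpm <- list()
    tpm_rows <- list(); mag_rows <- list(); share_rows <- list()
    up_rows <- list()
    markers16 <- scrbpMarkers()
    ctg_lab <- splitLabels(contigs$labels)
    mags <- unique(contig_mag)
    for (s in samples) {
      counts <- readTranscriptCounts(p(inp$samples[[s]]$counts))
      g <- genes[[s]]
      ids <- c(g$gene_id, contigs$gene_id)
      len <- c(g$length_bp, contigs$length_bp)
      cnt <- counts$count[match(ids, counts$gene_id)]
      cnt[is.na(cnt)] <- 0
      in_universe <- c(rep(TRUE, nrow(g)), rep(FALSE, nrow(contigs)))
      vals <- tpm(cnt, len, in_universe)
      state$tpm[[s]] <- stats::setNames(vals, ids)
      tpm_rows[[s]] <- data.frame(sample_id = s, gene_id = ids, count = cnt,
                                  length_bp = len, in_universe = in_universe,
                                  tpm = vals, stringsAsFactors = FALSE)
      # sample-level SC-RBP TPM (summed per marker over community genes)
      g_lab <- splitLabels(g$labels)
      smp_scrbp <- vapply(markers16, function(m) {
        sum(vals[seq_len(nrow(g))][vapply(g_lab, function(l) m %in% l,
                                          logical(1))])
      }, numeric(1))
      ctg_tpm <- vals[-seq_len(nrow(g))]
      for (mag in mags) {
        mine <- contig_mag[contigs$gene_id] == mag
        mag_scrbp <- vapply(markers16, function(m) {
          v <- ctg_tpm[mine & vapply(ctg_lab, function(l) m %in% l,
                                     logical(1))]
          if (length(v)) sum(v) else NA_real_
        }, numeric(1))
        rel <- magRelativeTranscription(mag_scrbp, smp_scrbp,
                                        th$min_markers %||% 8L)
        mag_rows[[length(mag_rows) + 1L]] <- data.frame(
          sample_id = s, mag_id = mag,
          n_markers = sum(!is.na(mag_scrbp)),
          relative_transcription = rel, stringsAsFactors = FALSE)
        # up-transcribed CAZyme families relative to the SC-RBP mean
        fam_of <- vapply(ctg_lab, function(l) {
          caz <- l[isCazymeTag(l)]
          if (length(caz)) caz[1L] else NA_character_
        }, character(1))
        sel <- mine & !is.na(fam_of)
        if (any(sel)) {
          fam_tpm <- tapply(ctg_tpm[sel], fam_of[sel], sum)
          up <- upTranscribedFamilies(
            stats::setNames(as.numeric(fam_tpm), names(fam_tpm)),
            mean(mag_scrbp, na.rm = TRUE))
          up_rows[[length(up_rows) + 1L]] <- data.frame(
            sample_id = s, mag_id = mag,
            families = paste(up, collapse = ";"), stringsAsFactors = FALSE)
        }
      }
      # per-family transcription shares across MAGs; the family total
      # covers all transcripts of the family in the sample
      fam_comm <- vapply(g_lab, function(l) {
        caz <- l[isCazymeTag(l)]
        if (length(caz)) caz[1L] else NA_character_
      }, character(1))
      fam_ctg <- vapply(ctg_lab, function(l) {
        caz <- l[isCazymeTag(l)]
        if (length(caz)) caz[1L] else NA_character_
      }, character(1))
      cnt_comm <- cnt[seq_len(nrow(g))]
      cnt_ctg <- cnt[-seq_len(nrow(g))]
      for (f in sort(unique(stats::na.omit(c(fam_comm, fam_ctg))))) {
        total <- sum(cnt_comm[!is.na(fam_comm) & fam_comm == f]) +
          sum(cnt_ctg[!is.na(fam_ctg) & fam_ctg == f])
        sel <- !is.na(fam_ctg) & fam_ctg == f
        per_mag <- tapply(cnt_ctg[sel], contig_mag[contigs$gene_id][sel], sum)
        if (total == 0) next
        sh <- familyTranscriptionShare(total,
                                       stats::setNames(as.numeric(per_mag),
                                                       names(per_mag)))
        share_rows[[length(share_rows) + 1L]] <-
          data.frame(sample_id = s, family = f, sh, stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, tpm_rows), "tpm.tsv")
    emit(do.call(rbind, mag_rows), "mag_transcription.tsv")
    emit(do.call(rbind, share_rows), "family_transcription_shares.tsv")
    emit(do.call(rbind, up_rows), "up_transcribed_families.tsv")
  })

  runStage("profiles", function() {
    prof_rows <- list(); breakdown_rows <- list()
    for (s in samples) {
      g <- genes[[s]]
      g_lab <- splitLabels(g$labels)
      fam <- vapply(g_lab, function(l) {
        caz <- l[isCazymeTag(l)]
        if (length(caz)) caz[1L] else NA_character_
      }, character(1))
      sel <- !is.na(fam)
      counts <- table(fam[sel])
      counts <- stats::setNames(as.numeric(counts), names(counts))
      tpm_s <- state$tpm[[s]][g$gene_id]
      fam_tpm <- tapply(tpm_s[sel], fam[sel], sum)
      fam_tpm <- stats::setNames(as.numeric(fam_tpm), names(fam_tpm))
      pmg <- familyAbundancePmg(counts, state$ge[[s]])
      ab_share <- familyShares(counts)
      tr_share <- familyShares(fam_tpm)
      prof_rows[[s]] <- data.frame(
        sample_id = s, family = names(counts), count = unname(counts),
        abundance_pmg = unname(pmg), abundance_share = unname(ab_share),
        transcription_share = unname(tr_share[names(counts)]),
        stringsAsFactors = FALSE)
      taxv <- state$gene_tax[[s]][g$gene_id]
      for (f in names(counts)) {
        idx <- which(sel & fam == f)
        bd <- familyTaxonBreakdown(taxv[idx], tpm_s[idx], "genus", tree)
        bd$name <- ifelse(bd$taxon == "unresolved", "unresolved",
                          vapply(suppressWarnings(as.integer(bd$taxon)),
                                 function(t) if (is.na(t)) "unresolved" else
                                   taxName(tree, t), character(1)))
        breakdown_rows[[length(breakdown_rows) + 1L]] <-
          data.frame(sample_id = s, family = f, bd, stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, prof_rows), "family_profiles.tsv")
    emit(do.call(rbind, breakdown_rows), "family_taxon_breakdown.tsv")
    # per-MAG gene-group summaries, averaged TPM over samples
    group_rows <- list()
    for (mag in unique(contig_mag)) {
      sub <- contigs[contig_mag[contigs$gene_id] == mag, , drop = FALSE]
      size_mbp <- if (mag %in% names(manifest_len)) {
        manifest_len[[mag]] / 1e6
      } else sum(sub$length_bp) / 1e6
      for (s in samples) {
        gs <- geneGroupSummary(sub, state$tpm[[s]], size_mbp)
        group_rows[[length(group_rows) + 1L]] <- data.frame(
          sample_id = s, mag_id = mag, gs,
          peptidase_cazyme_ratio = attr(gs, "peptidase_cazyme_ratio"),
          stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, group_rows), "gene_groups.tsv")
  })

  runStage("pul", function() {
    roles <- assignRoles(contigs)
    calls <- detectPuls(roles, maxGap = th$pul_max_gap %||% 6L)
    emit(calls, "puls.tsv")
    rows <- list()
    if (nrow(calls)) {
      for (s in samples) {
        for (j in seq_len(nrow(calls))) {
          tr <- pulTranscription(calls[j, ], state$tpm[[s]])
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s, contig_id = calls$contig_id[j],
            start_ordinal = calls$start_ordinal[j],
            tpm_sum = tr$sum, tpm_mean = tr$mean, stringsAsFactors = FALSE)
        }
      }
    }
    emit(do.call(rbind, rows), "pul_transcription.tsv")
  })

  runStage("microarray", function() {
    sig <- readMicroarraySignals(p(inp$microarray))
    epi <- epitopeAbundance(sig, th$microarray_threshold %||% 5)
    emit(epi, "epitopes.tsv")
    wide <- stats::reshape(epi, idvar = "sample_id", timevar = "antibody_id",
                           direction = "wide")
    names(wide) <- sub("^summed_mean_signal\\.", "", names(wide))
    emit(wide, "epitopes_wide.tsv")
  })

  md5 <- tools::md5sum(files)
  names(md5) <- basename(files)
  manifest <- list(tool = "MetaGlyco", version = version,
                   config_md5 = unname(config_md5), seed = seed,
                   files = as.list(md5[order(names(md5))]))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(outdir = outdir, files = md5, config = config))
}
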