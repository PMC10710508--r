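# Rule-based detection of polysaccharide utilization loci (PULs) on
# ordered gene annotations. A PUL is called when either (1) an adjacent
# SusC/SusD gene pair has two or more degradative CAZymes nearby, or
# (2) at least three degradative CAZymes cluster with at most `maxGap`
# intervening genes between consecutive members.

#' Assign PUL roles to ordered genes
#'
#' Derives per-gene roles from functional labels. Degradative CAZymes
#' are those whose family class belongs to `degradativeClasses`
#' (default GH, PL, CE; CBMs bind rather than cleave and are excluded
#' by default, configurable). A gene labelled both `susC` and CAZyme
#' takes the susC role for the pair clause but still counts as a CAZyme
#' for the cluster clause.
#'
#' @param genes gene annotation data.frame of one or more contigs.
#' @param degradativeClasses CAZyme classes counted as degradative.
#' @return The input ordered by (`parent_id`, `ordinal`) with added
#'   columns `is_susC`, `is_susD`, `is_cazyme`, `families`, `role`.
#' @export
assignRoles <- function(genes, degradativeClasses = c("GH", "PL", "CE")) {
  lab <- splitLabels(genes$labels)
  is_susC <- vapply(lab, function(l) "susC" %in% l, logical(1))
  is_susD <- vapply(lab, function(l) "susD" %in% l, logical(1))
  fam <- vapply(lab, function(l) {
    caz <- l[isCazymeTag(l)]
    paste(caz[cazymeClass(caz) %in% degradativeClasses], collapse = ";")
  }, character(1))
  is_caz <- nzchar(fam)
  role <- ifelse(is_susC, "susC",
          ifelse(is_susD, "susD",
          ifelse(is_caz, "degradative_cazyme", "other")))
  out <- genes
  out$is_susC <- is_susC
  out$is_susD <- is_susD
  out$is_cazyme <- is_caz
  out$families <- fam
  out$role <- role
  out <- out[order(out$parent_id, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# core rule on positional logicals; returns matrix of (start, end,
# clause) with clause 1 = susCD_pair, 2 = cazyme_cluster
.pulSpans <- function(is_susC, is_susD, is_caz, maxGap) {
  n <- length(is_caz)
  starts <- integer(0); ends <- integer(0); clause <- integer(0)
  caz_pos <- which(is_caz)
  # clause 1: adjacent susC/susD pair (either order) with >= 2
  # degradative CAZymes within maxGap intervening genes of the pair
  if (n >= 2L) {
    pair_at <- which((is_susC[-n] & is_susD[-1L]) |
                     (is_susD[-n] & is_susC[-1L]))
    for (i in pair_at) {
      near <- caz_pos[(caz_pos >= i - maxGap - 1L & caz_pos < i) |
                      (caz_pos > i + 1L & caz_pos <= i + maxGap + 2L)]
      if (length(near) >= 2L) {
        starts <- c(starts, min(i, near))
        ends <- c(ends, max(i + 1L, near))
        clause <- c(clause, 1L)
      }
    }
  }
  # clause 2: maximal chains of >= 3 CAZymes, consecutive members
  # separated by <= maxGap intervening genes
  if (length(caz_pos) >= 3L) {
    gap_ok <- diff(caz_pos) <= maxGap + 1L
    run_id <- cumsum(c(TRUE, !gap_ok))
    for (r in split(caz_pos, run_id)) {
      if (length(r) >= 3L) {
        starts <- c(starts, r[1L])
        ends <- c(ends, r[length(r)])
        clause <- c(clause, 2L)
      }
    }
  }
  if (!length(starts)) return(NULL)
  # merge overlapping candidate spans (union); pair clause dominates
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]; clause <- clause[ord]
  m_start <- starts[1L]; m_end <- ends[1L]; m_clause <- clause[1L]
  out <- NULL
  for (j in seq_along(starts)[-1L]) {
    if (starts[j] <= m_end) {
      m_end <- max(m_end, ends[j])
      m_clause <- min(m_clause, clause[j])
    } else {
      out <- rbind(out, c(m_start, m_end, m_clause))
      m_start <- starts[j]; m_end <- ends[j]; m_clause <- clause[j]
    }
  }
  rbind(out, c(m_start, m_end, m_clause))
}

#' Detect polysaccharide utilization loci
#'
#' Applies the two-clause PUL rule to role-annotated genes (see
#' [assignRoles()]): (1) an adjacent SusC/SusD pair with at least two
#' degradative CAZymes within `maxGap` intervening genes of the pair,
#' or (2) at least three degradative CAZymes in which consecutive
#' members are separated by at most `maxGap` intervening genes.
#' Overlapping clause hits merge into a single call spanning their
#' union, so each gene belongs to at most one call. The rule is
#' symmetric under reversal of gene order.
#'
#' @param locus output of [assignRoles()] (one or more contigs).
#' @param maxGap maximum number of intervening genes (default 6).
#' @return data.frame with one row per call: `contig_id`,
#'   `start_ordinal`, `end_ordinal`, `n_genes`, `trigger_clause`
#'   (`"susCD_pair"` or `"cazyme_cluster"`), `member_gene_ids` and
#'   `cazyme_families` (semicolon-joined).
#' @export
detectPuls <- function(locus, maxGap = 6L) {
  res <- list()
  for (contig in unique(locus$parent_id)) {
    sub <- locus[locus$parent_id == contig, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    spans <- .pulSpans(sub$is_susC, sub$is_susD, sub$is_cazyme,
                       as.integer(maxGap))
    if (is.null(spans)) next
    for (j in seq_len(nrow(spans))) {
      idx <- spans[j, 1L]:spans[j, 2L]
      fams <- unlist(splitLabels(sub$families[idx]))
      res[[length(res) + 1L]] <- data.frame(
        contig_id = contig,
        start_ordinal = sub$ordinal[spans[j, 1L]],
        end_ordinal = sub$ordinal[spans[j, 2L]],
        n_genes = length(idx),
        trigger_clause = c("susCD_pair", "cazyme_cluster")[spans[j, 3L]],
        member_gene_ids = paste(sub$gene_id[idx], collapse = ";"),
        cazyme_families = paste(unique(fams[nzchar(fams)]), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(contig_id = character(0), start_ordinal = integer(0),
                      end_ordinal = integer(0), n_genes = integer(0),
                      trigger_clause = character(0),
                      member_gene_ids = character(0),
                      cazyme_families = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Transcription summary of a PUL call
#'
#' @param pul_call one row of the [detectPuls()] result.
#' @param gene_tpms named numeric vector of per-gene TPM.
#' @return list with `sum` and `mean` TPM over member genes.
#' @export
pulTranscription <- function(pul_call, gene_tpms) {
  members <- strsplit(pul_call$member_gene_ids, ";", fixed = TRUE)[[1L]]
  missing_tpm <- setdiff(members, names(gene_tpms))
  if (length(missing_tpm)) {
    stopf("no TPM value for gene(s): %s", paste(missing_tpm, collapse = ", "))
  }
  vals <- gene_tpms[members]
  list(sum = sum(vals), mean = mean(vals))
}

#' Plain-text locus diagram
#'
#' One line per gene showing ordinal, role and labels, with PUL spans
#' marked; a lightweight textual replacement for manual locus drawing.
#'
#' @param locus output of [assignRoles()] for a single contig.
#' @param calls optional [detectPuls()] result for the same contig.
#' @return Character vector of diagram lines (invisibly printed with
#'   `cat` when interactive use is intended).
#' @export
locusDiagram <- function(locus, calls = NULL) {
  sub <- locus[order(locus$ordinal), , drop = FALSE]
  glyph <- c(susC = "[C>", susD = "[D>", degradative_cazyme = "[E>",
             other = "---")
  in_pul <- rep(FALSE, nrow(sub))
  if (!is.null(calls) && nrow(calls)) {
    for (j in seq_len(nrow(calls))) {
      in_pul <- in_pul | (sub$ordinal >= calls$start_ordinal[j] &
                          sub$ordinal <= calls$end_ordinal[j])
    }
  }
  sprintf("%4d %s %s %s%s", sub$ordinal, glyph[sub$role],
          ifelse(in_pul, "PUL", "   "), sub$gene_id,
          ifelse(nzchar(sub$families), paste0(" (", sub$families, ")"), ""))
}
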