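# Community-level functional profiling: per-genome-normalised (PMG)
# family abundance, relative proportions, and per-family taxon
# attribution.

#' Per-microbial-genome (PMG) family abundance
#'
#' Divides per-family gene counts by the sample's genome equivalents,
#' giving the average copy number of each family per microbial genome.
#'
#' @param counts named numeric vector of per-family gene counts.
#' @param genome_equiv positive genome-equivalents denominator (see
#'   [genomeEquivalents()]).
#' @return Named numeric vector of PMG values.
#' @export
familyAbundancePmg <- function(counts, genome_equiv) {
  assertScalarNumber(genome_equiv, "genome_equiv")
  if (genome_equiv <= 0) stopf("genome_equiv must be positive")
  counts / genome_equiv
}

#' Relative proportions of family values
#'
#' @param values named non-negative vector (gene counts, PMG or TPM).
#' @return `values / sum(values)`; shares sum to 1.
#' @export
familyShares <- function(values) {
  total <- sum(values)
  if (total <= 0) stopf("total is zero; shares undefined")
  values / total
}

#' Per-taxon breakdown of one gene family
#'
#' Aggregates per-gene weights at a requested rank by walking each
#' gene's taxon up the tree; genes classified above the requested rank
#' pool into an `"unresolved"` bucket. Shares sum to 1.
#'
#' @param taxids integer vector of per-gene taxa (`NA` = unclassified).
#' @param weights per-gene weights (counts or TPM); default 1.
#' @param rank requested rank label (e.g. `"genus"`).
#' @param tree a [TaxonomyTree-class].
#' @return data.frame with `taxon` (taxid as character or
#'   `"unresolved"`), `weight`, `share`.
#' @export
familyTaxonBreakdown <- function(taxids, weights = NULL, rank, tree) {
  weights <- weights %||% rep(1, length(taxids))
  at_rank <- vapply(taxids, function(t) {
    if (is.na(t)) NA_integer_ else ancestorAtRank(tree, t, rank)
  }, integer(1))
  key <- ifelse(is.na(at_rank), "unresolved", as.character(at_rank))
  agg <- tapply(weights, key, sum)
  out <- data.frame(taxon = names(agg), weight = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$share <- out$weight / sum(out$weight)
  out[order(-out$weight), , drop = FALSE]
}

#' Gene-group summary of a MAG
#'
#' Sums gene counts and TPM within functional groups (CAZymes,
#' sulfatases, peptidases, TonB-dependent transporters), normalising
#' counts by MAG genome size in Mbp. Also reports the
#' peptidase:CAZyme count ratio, a proxy for protein- versus
#' carbohydrate-oriented substrate preference.
#'
#' @param genes annotation data.frame of the MAG's genes.
#' @param gene_tpms optional named numeric vector of per-gene TPM
#'   (default 0).
#' @param genome_size_mbp positive genome size in Mbp.
#' @return data.frame with `group`, `count`, `count_per_mbp`,
#'   `tpm_sum`; the peptidase:CAZyme ratio is attached as
#'   `attr(, "peptidase_cazyme_ratio")`.
#' @export
geneGroupSummary <- function(genes, gene_tpms = NULL,
                             genome_size_mbp) {
  assertScalarNumber(genome_size_mbp, "genome_size_mbp")
  if (genome_size_mbp <= 0) stopf("genome_size_mbp must be positive")
  lab <- splitLabels(genes$labels)
  member <- list(
    CAZyme = vapply(lab, function(l) any(isCazymeTag(l)), logical(1)),
    sulfatase = vapply(lab, function(l) "sulfatase" %in% l, logical(1)),
    peptidase = vapply(lab, function(l) "peptidase" %in% l, logical(1)),
    TBDT = vapply(lab, function(l) "TBDT" %in% l, logical(1))
  )
  tp <- rep(0, nrow(genes))
  if (!is.null(gene_tpms)) {
    idx <- match(genes$gene_id, names(gene_tpms))
    tp[!is.na(idx)] <- gene_tpms[idx[!is.na(idx)]]
  }
  out <- data.frame(
    group = names(member),
    count = vapply(member, sum, numeric(1)),
    count_per_mbp = vapply(member, sum, numeric(1)) / genome_size_mbp,
    tpm_sum = vapply(member, function(m) sum(tp[m]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  n_caz <- out$count[out$group == "CAZyme"]
  attr(out, "peptidase_cazyme_ratio") <-
    if (n_caz > 0) out$count[out$group == "peptidase"] / n_caz else NA_real_
  out
}

#' Aggregate CAZyme sub-families to their parent family
#'
#' Sub-family labels such as `GH16_3` are kept distinct by default
#' throughout the package; this helper collapses them (`GH16_3` ->
#' `GH16`) when parent-level reporting is wanted.
#'
#' @param values named vector keyed by (sub-)family label.
#' @return Named vector keyed by parent family, values summed.
#' @export
aggregateSubfamilies <- function(values) {
  parent <- sub("_.*$", "", names(values))
  agg <- tapply(values, parent, sum)
  stats::setNames(as.numeric(agg), names(agg))
}
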