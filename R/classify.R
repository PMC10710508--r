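# Two-stage LCA taxonomic classification: filtered protein hits are
# collapsed to one taxon per gene, then gene taxa are collapsed to one
# taxon per long read, which is propagated back to the read's genes.

#' Construct a hit filter
#'
#' Defaults follow the secondary filtering applied to DIAMOND output in
#' long-read community profiling: identity > 65%, e-value < 1e-10 and
#' query cover > 50%, all strict comparisons (boundary values are
#' rejected).
#'
#' @param minIdentity percent identity threshold (strict >).
#' @param maxEvalue e-value ceiling (strict <).
#' @param minQueryCover percent query-cover threshold (strict >).
#' @return A [HitFilter-class].
#' @export
hitFilter <- function(minIdentity = 65, maxEvalue = 1e-10,
                      minQueryCover = 50) {
  new("HitFilter", minIdentity = as.numeric(minIdentity),
      maxEvalue = as.numeric(maxEvalue),
      minQueryCover = as.numeric(minQueryCover))
}

setMethod("show", "HitFilter", function(object) {
  cat(sprintf("HitFilter: identity > %g%%, evalue < %g, query cover > %g%%\n",
              object@minIdentity, object@maxEvalue, object@minQueryCover))
})

#' Filter alignment hits
#'
#' Retains exactly the hits with `percent_identity > minIdentity`,
#' `evalue < maxEvalue` and `query_coverage > minQueryCover`; input
#' order is preserved and an empty result is permitted.
#'
#' @param hits data.frame of hits (see [readAlignmentHits()]).
#' @param filter a [HitFilter-class].
#' @return The retained subset of `hits`.
#' @export
filterHits <- function(hits, filter = hitFilter()) {
  stopifnot(is(filter, "HitFilter"))
  keep <- hits$percent_identity > filter@minIdentity &
    hits$evalue < filter@maxEvalue &
    hits$query_coverage > filter@minQueryCover
  hits[keep, , drop = FALSE]
}

#' Classify one gene from its alignment hits
#'
#' Applies the hit filter, then assigns the last common ancestor of the
#' surviving hits' subject taxa. A gene with no surviving hits is
#' unclassified (`NA` taxid).
#'
#' @param gene_hits hits sharing a single `query_gene_id`.
#' @param filter a [HitFilter-class].
#' @param tree a [TaxonomyTree-class].
#' @return list with `gene_id`, `taxid` (`NA` if unclassified) and
#'   `n_hits_used`.
#' @export
classifyGene <- function(gene_hits, filter, tree) {
  ids <- unique(gene_hits$query_gene_id)
  if (length(ids) != 1L) {
    stopf("classifyGene expects hits of a single gene, got %d query ids",
          length(ids))
  }
  surv <- filterHits(gene_hits, filter)
  if (nrow(surv) == 0L) {
    return(list(gene_id = ids, taxid = NA_integer_, n_hits_used = 0L))
  }
  list(gene_id = ids, taxid = lca(tree, surv$subject_taxid),
       n_hits_used = nrow(surv))
}

#' Classify all genes of a hit table
#'
#' @param hits full hit table (many genes).
#' @inheritParams classifyGene
#' @return data.frame with one row per gene: `gene_id`, `taxid`,
#'   `n_hits_used`.
#' @export
classifyGenes <- function(hits, filter, tree) {
  surv <- filterHits(hits, filter)
  all_ids <- unique(hits$query_gene_id)
  res <- data.frame(gene_id = all_ids, taxid = NA_integer_,
                    n_hits_used = 0L, stringsAsFactors = FALSE)
  if (nrow(surv)) {
    by_gene <- split(surv$subject_taxid, surv$query_gene_id)
    tax <- vapply(by_gene, function(t) lca(tree, t), integer(1))
    idx <- match(names(by_gene), res$gene_id)
    res$taxid[idx] <- tax
    res$n_hits_used[idx] <- lengths(by_gene)
  }
  res
}

#' Classify reads from their gene classifications
#'
#' The read taxon is the last common ancestor over the taxa of the
#' read's *classified* genes only; unclassified genes are excluded so
#' they cannot drag the read to the root. A read with no classified
#' gene is unclassified.
#'
#' @param gene_class data.frame from [classifyGenes()].
#' @param genes gene annotation data.frame (maps `gene_id` to its
#'   `parent_id` read).
#' @param tree a [TaxonomyTree-class].
#' @return data.frame with one row per read: `read_id`, `taxid`,
#'   `n_genes_used`.
#' @export
classifyReads <- function(gene_class, genes, tree) {
  read_of <- genes$parent_id[match(gene_class$gene_id, genes$gene_id)]
  if (anyNA(read_of)) {
    stopf("gene(s) absent from annotation: %s",
          paste(utils::head(gene_class$gene_id[is.na(read_of)], 5), collapse = ", "))
  }
  reads <- unique(genes$parent_id)
  res <- data.frame(read_id = reads, taxid = NA_integer_,
                    n_genes_used = 0L, stringsAsFactors = FALSE)
  cls <- !is.na(gene_class$taxid)
  if (any(cls)) {
    by_read <- split(gene_class$taxid[cls], read_of[cls])
    tax <- vapply(by_read, function(t) lca(tree, t), integer(1))
    idx <- match(names(by_read), res$read_id)
    res$taxid[idx] <- tax
    res$n_genes_used[idx] <- lengths(by_read)
  }
  res
}

#' Propagate read taxonomy to the read's genes
#'
#' When a read is classified, its taxon overrides the per-gene calls of
#' all genes it contains; genes of unclassified reads keep their own
#' gene-level classification. The count of classified genes never
#' decreases.
#'
#' @param read_class data.frame from [classifyReads()].
#' @param gene_class data.frame from [classifyGenes()].
#' @param genes gene annotation data.frame.
#' @return data.frame with one row per annotated gene: `gene_id`,
#'   `read_id`, `taxid`, `source` (`"read"` or `"gene"`).
#' @export
propagateReadTaxonomy <- function(read_class, gene_class, genes) {
  read_tax <- read_class$taxid[match(genes$parent_id, read_class$read_id)]
  gene_tax <- gene_class$taxid[match(genes$gene_id, gene_class$gene_id)]
  use_read <- !is.na(read_tax)
  data.frame(
    gene_id = genes$gene_id,
    read_id = genes$parent_id,
    taxid = ifelse(use_read, read_tax, gene_tax),
    source = ifelse(use_read, "read", "gene"),
    stringsAsFactors = FALSE
  )
}
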