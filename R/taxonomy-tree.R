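#' Construct a TaxonomyTree
#'
#' @param taxid integer vector of node identifiers.
#' @param parent integer vector of parent identifiers; the root points
#'   to itself.
#' @param rank character vector of rank labels.
#' @param name character vector of names; defaults to the taxid as text.
#'
#' @return A [TaxonomyTree-class] object.
#' @examples
#' tr <- taxonomyTree(taxid = 1:3, parent = c(1L, 1L, 2L),
#'                    rank = c("root", "genus", "species"))
#' lca(tr, c(2L, 3L))
#' @export
taxonomyTree <- function(taxid, parent, rank, name = as.character(taxid)) {
  new("TaxonomyTree",
      taxid = as.integer(taxid), parent = as.integer(parent),
      rank = as.character(rank), name = as.character(name))
}

#' @describeIn taxonomyTree Number of nodes in the tree.
#' @param x,object a `TaxonomyTree`.
#' @export
setMethod("length", "TaxonomyTree", function(x) length(x@taxid))

setMethod("show", "TaxonomyTree", function(object) {
  cat(sprintf("TaxonomyTree with %d nodes (root taxid %d)\n",
              length(object@taxid), rootTaxid(object)))
  rk <- table(object@rank)
  cat("  ranks:", paste(sprintf("%s (%d)", names(rk), rk), collapse = ", "),
      "\n")
})

#' Tree node accessors
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxids integer vector of node identifiers.
#' @return `taxIds` returns all node ids; `taxRank`, `taxName` and
#'   `taxParent` return the per-node attributes for `taxids`;
#'   `rootTaxid` returns the root node id.
#' @export
taxIds <- function(tree) tree@taxid

#' @rdname taxIds
#' @export
rootTaxid <- function(tree) tree@taxid[tree@taxid == tree@parent][1L]

.taxIndex <- function(tree, taxids) {
  idx <- match(as.integer(taxids), tree@taxid)
  if (anyNA(idx)) {
    stopf("unknown taxid(s): %s",
          paste(taxids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' @rdname taxIds
#' @export
taxRank <- function(tree, taxids) tree@rank[.taxIndex(tree, taxids)]

#' @rdname taxIds
#' @export
taxName <- function(tree, taxids) tree@name[.taxIndex(tree, taxids)]

#' @rdname taxIds
#' @export
taxParent <- function(tree, taxids) tree@parent[.taxIndex(tree, taxids)]

#' Root-to-node lineage
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxid single node identifier.
#' @return `lineage` returns the integer vector of taxids from the root
#'   down to `taxid` (inclusive); `lineageString` the corresponding
#'   names joined with `sep`.
#' @export
lineage <- function(tree, taxid) {
  i <- .taxIndex(tree, taxid)
  path <- integer(0)
  repeat {
    path <- c(tree@taxid[i], path)
    if (tree@parent[i] == tree@taxid[i]) break
    i <- match(tree@parent[i], tree@taxid)
  }
  path
}

#' @rdname lineage
#' @param sep separator between lineage fields.
#' @export
lineageString <- function(tree, taxid, sep = ";") {
  paste(taxName(tree, lineage(tree, taxid)), collapse = sep)
}

#' Walk up to the ancestor at a given rank
#'
#' @inheritParams lineage
#' @param rank requested rank label.
#' @return The taxid of the ancestor-or-self of `taxid` carrying `rank`,
#'   or `NA` when the node's classification sits above that rank.
#' @export
ancestorAtRank <- function(tree, taxid, rank) {
  i <- .taxIndex(tree, taxid)
  repeat {
    if (tree@rank[i] == rank) return(tree@taxid[i])
    if (tree@parent[i] == tree@taxid[i]) return(NA_integer_)
    i <- match(tree@parent[i], tree@taxid)
  }
}

#' Is `taxid` equal to or a descendant of `ancestor`?
#'
#' @inheritParams lineage
#' @param ancestor candidate ancestor taxid.
#' @return logical scalar.
#' @export
isDescendant <- function(tree, taxid, ancestor) {
  as.integer(ancestor) %in% lineage(tree, taxid)
}

#' Last common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every input
#' taxon: the last element shared by all root-to-node paths.
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxids non-empty integer vector of node identifiers (all
#'   present in the tree; duplicates allowed).
#' @return A single taxid.
#' @examples
#' tr <- taxonomyTree(taxid = 1:4, parent = c(1L, 1L, 2L, 2L),
#'                    rank = c("root", "genus", "species", "species"))
#' lca(tr, c(3L, 4L)) # the genus
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L || anyNA(taxids)) {
    stopf("lca requires a non-empty set of taxids")
  }
  common <- lineage(tree, taxids[1L])
  for (t in taxids[-1L]) {
    common <- intersect(common, lineage(tree, t))
  }
  # intersect preserves root-first order of the first path
  common[length(common)]
}

#' Majority-vote taxon of a set of classifications
#'
#' The strictly most frequent taxid wins; when several taxids tie for
#' the highest count, their last common ancestor is returned.
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxids non-empty vector of member taxids (a multiset).
#' @return A single taxid.
#' @export
majorityVote <- function(tree, taxids) {
  taxids <- as.integer(taxids)
  taxids <- taxids[!is.na(taxids)]
  if (!length(taxids)) stopf("majorityVote requires at least one classified member")
  tab <- table(taxids)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1L) top else lca(tree, top)
}
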