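#' Read a phylogenetic tree from Newick
#'
#' Loads a single (rooted or unrooted) Newick tree and validates it for
#' distance computation: all leaves must be named and unique, and every edge
#' must carry a branch length.
#'
#' @param path Path to a Newick file, or use `text` for an inline tree.
#' @param text Newick string (alternative to `path`).
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text)) abort("supply exactly one of `path` or `text`")
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) abort_format("malformed Newick: %s", conditionMessage(e))
  )
  if (is.null(tree)) abort_format("malformed Newick: no tree parsed")
  if (inherits(tree, "multiPhylo")) {
    abort_format("expected a single Newick tree, found %d", length(tree))
  }
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    abort_format("Newick tree has unnamed leaves")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort_format("Newick tree has duplicate leaf name: %s",
                 tree$tip.label[duplicated(tree$tip.label)][1])
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort_format("Newick tree is missing branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    abort_format("Newick tree has negative branch lengths")
  }
  tree
}
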