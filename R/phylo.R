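# Phylogenetic distances from each query species to the reference: patristic
# (path-length) distances from a supplied tree, or a JC69 estimate from the
# alignments themselves when no tree is available.

#' Patristic distances from the reference leaf
#'
#' Sums branch lengths along the unique tree path between the reference leaf
#' and each query species leaf.
#'
#' @param tree An [ape] `phylo` tree with branch lengths (see [read_newick()]).
#' @param ref_leaf Name of the reference species leaf.
#' @param species Character vector of query species; defaults to all other
#'   leaves.
#' @return A tibble with columns `species` and `distance`
#'   (substitutions/site), in the order of `species`. The reference itself
#'   has distance 0.
#' @export
#' @examples
#' tr <- read_newick(text = "((A:0.1,B:0.2):0.3,C:0.4);")
#' tree_distances(tr, "A")
tree_distances <- function(tree, ref_leaf, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ref_leaf %in% tree$tip.label) {
    abort(sprintf("reference leaf '%s' not in tree", ref_leaf))
  }
  species <- species %||% setdiff(tree$tip.label, ref_leaf)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("species not in tree: %s", paste(missing, collapse = ", ")))
  }
  D <- ape::cophenetic.phylo(tree)
  tibble(species = species, distance = unname(D[ref_leaf, species]))
}

#' Jukes-Cantor (JC69) distance from pairwise alignments
#'
#' Fallback distance estimator when no tree is supplied: pools all aligned
#' ungapped sites of one species' blocks (both bases unambiguous A/C/G/T),
#' takes the mismatch fraction p-hat, and applies the JC69 correction
#' d = -(3/4) log(1 - (4/3) p-hat). Saturated alignments (p-hat >= 0.75) have
#' no finite JC69 distance and raise an error.
#'
#' @param blocks Alignment-block tibble from [read_axt()]; may contain
#'   several species (one estimate per species).
#' @return A tibble with one row per species: `species`, `n_sites`, `p_hat`,
#'   `distance`, `se` (delta-method standard error of the distance).
#' @export
jc69_distance <- function(blocks) {
  if (nrow(blocks) == 0) abort("no alignment blocks supplied")
  per_species <- split(blocks, blocks$species)
  map_dfr(names(per_species), function(sp) {
    bl <- per_species[[sp]]
    n_sites <- 0L
    n_mismatch <- 0L
    for (b in seq_len(nrow(bl))) {
      rc <- seq_chars(bl$ref_aligned[b])
      qc <- seq_chars(bl$query_aligned[b])
      use <- rc %in% DNA_BASES & qc %in% DNA_BASES
      n_sites <- n_sites + sum(use)
      n_mismatch <- n_mismatch + sum(rc[use] != qc[use])
    }
    if (n_sites == 0) {
      abort(sprintf("species %s: no aligned ungapped sites", sp))
    }
    p_hat <- n_mismatch / n_sites
    if (p_hat >= 0.75) {
      abort(sprintf(
        "species %s: mismatch fraction %.3f >= 0.75, JC69 distance saturated",
        sp, p_hat))
    }
    d <- -0.75 * log(1 - 4 * p_hat / 3)
    # delta method: Var(d) = Var(p) / (1 - 4p/3)^2, Var(p) = p(1-p)/L
    se <- sqrt(p_hat * (1 - p_hat) / n_sites) / (1 - 4 * p_hat / 3)
    tibble(species = sp, n_sites = n_sites, p_hat = p_hat,
           distance = d, se = se)
  })
}
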