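#' Simulate a pure-birth chronogram
#'
#' Generates a rooted ultrametric tree under a pure-birth (Yule) process and
#' rescales it to the requested total height. Used as the synthetic stand-in
#' for a time-calibrated phylogeny; real analyses consume a supplied Newick
#' chronogram instead.
#'
#' @param n_species number of tips (>= 3).
#' @param height tree height in time units (default 1).
#' @param seed integer RNG seed.
#' @param tip_prefix tip labels are `paste0(tip_prefix, 1:n_species)`.
#' @param min_tip_frac minimum terminal branch length as a fraction of tree
#'   height (default 0.04). Pure-birth trees are redrawn until every
#'   terminal branch clears this floor, mimicking a chronogram of
#'   well-separated species: even the most recently diverged pair has had
#'   some few percent of the clade's history apart.
#' @return an [ape::phylo] object, ultrametric with the given height.
#' @export
simulate_chronogram <- function(n_species, height = 1, seed = 1L,
                                tip_prefix = "sp", min_tip_frac = 0.04) {
  stopifnot(n_species >= 3, height > 0, min_tip_frac >= 0, min_tip_frac < 0.5)
  set.seed(seed)
  for (i in seq_len(2000)) {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    depths <- ape::node.depth.edgelength(tree)
    tree$edge.length <- tree$edge.length / max(depths)
    term <- tree$edge.length[tree$edge[, 2] <= n_species]
    if (min(term) >= min_tip_frac) break
  }
  if (min(term) < min_tip_frac)
    stop("could not draw a tree clearing the terminal-branch floor",
         call. = FALSE)
  tree$edge.length <- tree$edge.length * height
  tree$tip.label <- paste0(tip_prefix, seq_len(n_species))
  tree
}

#' Simulate Brownian-motion trait values on a chronogram
#'
#' Draws one tip value per species from the multivariate normal implied by
#' Brownian motion on the tree: mean `root_state`, covariance
#' `sigma2 * C`, where `C[i, j]` is the shared root-to-tip path length of
#' tips i and j.
#'
#' @param tree ultrametric [ape::phylo] with positive branch lengths.
#' @param sigma2 trait variance accrued per unit branch length (>= 0).
#' @param root_state trait value at the root.
#' @param seed integer RNG seed.
#' @return named numeric vector of tip values (names = tip labels).
#' @export
simulate_bm_traits <- function(tree, sigma2, root_state = 0, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  C <- ape::vcv(tree)
  if (sigma2 == 0) {
    x <- rep(root_state, nrow(C))
    names(x) <- rownames(C)
    return(x)
  }
  L <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance matrix is not positive definite ",
         "(malformed tree)", call. = FALSE))
  set.seed(seed)
  z <- stats::rnorm(nrow(C))
  x <- root_state + sqrt(sigma2) * drop(crossprod(L, z))
  names(x) <- rownames(C)
  x
}
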