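#' Simulate correlated Brownian-motion traits on a tree
#'
#' Evolves two traits along the tree by correlated Brownian motion: on an
#' edge of length `L`, the bivariate increment is normal with covariance
#' `sigma^2 * L * [[1, rho], [rho, 1]]`. The root state is (0, 0). Trees
#' need not be ultrametric; zero-length branches are rejected because the
#' downstream contrast standardization divides by branch length.
#'
#' @param tree an `ape` phylo tree with positive branch lengths.
#' @param rho true correlation of the two traits' increments.
#' @param sigma per-unit-branch step standard deviation (`0` collapses
#'   every tip onto the root state).
#' @param seed integer seed.
#' @return data frame `species, trait1, trait2` with attribute
#'   `true_rho`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' simulate_bm_traits(tr, rho = 0.8, sigma = 1, seed = 1)
#' @export
simulate_bm_traits <- function(tree, rho, sigma, seed) {
  stopifnot(inherits(tree, "phylo"), abs(rho) <= 1, sigma >= 0)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) stop("zero-length branches rejected")
  set.seed(as.integer(seed))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  x <- matrix(NA_real_, n_node, 2)
  root <- n_tip + 1L
  x[root, ] <- c(0, 0)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    par <- edges[i, 1]; child <- edges[i, 2]
    s <- sigma * sqrt(el[i])
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    inc <- c(z1, rho * z1 + sqrt(1 - rho^2) * z2) * s
    x[child, ] <- x[par, ] + inc
  }
  out <- data.frame(species = tree$tip.label,
                    trait1 = x[seq_len(n_tip), 1],
                    trait2 = x[seq_len(n_tip), 2])
  attr(out, "true_rho") <- rho
  out
}

#' Simulate a random species tree
#'
#' A deterministic wrapper around [ape::rtree()] used by
#' [simulate_all()]; branch lengths are shifted away from zero.
#'
#' @param n_species number of tips.
#' @param seed integer seed.
#' @return an `ape` phylo tree with tips `sp01..`.
#' @export
simulate_species_tree <- function(n_species, seed) {
  set.seed(as.integer(seed))
  tr <- ape::rtree(n_species, tip.label = sprintf("sp%02d",
                                                  seq_len(n_species)))
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
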