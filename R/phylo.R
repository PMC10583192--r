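#' Brownian-motion covariance matrix of a tree
#'
#' Under Brownian motion the expected covariance between two tips is the
#' shared path length from the root to their most recent common ancestor;
#' the diagonal holds root-to-tip depths.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return Tip x tip covariance matrix, rows/columns in `tree$tip.label`
#'   order.
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop_linkmod("tree must be rooted")
  ape::vcv(tree)
}

#' Precompute phylogenetic whitening machinery
#'
#' Builds the BM covariance C and its symmetric inverse square root, used to
#' remove phylogenetic correlation from tip data. The symmetric (eigen)
#' square root is used rather than a Cholesky factor so the transform is
#' rotation-free and platform-stable.
#'
#' @param tree A rooted `ape::phylo`.
#' @return List with `tips`, `C`, `C_inv_sqrt`.
#' @export
phylo_context <- function(tree) {
  C <- bm_covariance(tree)
  list(tips = rownames(C), C = C, C_inv_sqrt = sym_inv_sqrt(C))
}

#' Phylogenetic whitening transform
#'
#' Computes `U = C^{-1/2} (X - 1 a')` with `a` the generalized least squares
#' phylogenetic mean `a = (1'C^-1 1)^-1 1'C^-1 X`. Under Brownian motion the
#' rows of U are uncorrelated with zero mean, so ordinary covariance of U is
#' the evolutionary (rate) covariance of the traits.
#'
#' @param X Specimen x trait matrix; row names must match the tree tips.
#' @param ctx A [phylo_context()] (or an `ape::phylo`, transformed on the
#'   fly).
#' @return U matrix (same shape as X) with attribute `phylo_mean` = `a`.
#' @export
phylo_transform <- function(X, ctx) {
  if (inherits(ctx, "phylo")) ctx <- phylo_context(ctx)
  X <- as.matrix(X)
  if (is.null(rownames(X)) || !identical(rownames(X), ctx$tips)) {
    stop_linkmod("rows of X must be named and ordered as the tree tips")
  }
  Cinv <- ctx$C_inv_sqrt %*% ctx$C_inv_sqrt
  one <- rep(1, nrow(X))
  a <- as.vector(crossprod(one, Cinv %*% X) /
                   as.numeric(crossprod(one, Cinv %*% one)))
  U <- ctx$C_inv_sqrt %*% sweep(X, 2, a)
  rownames(U) <- rownames(X)
  attr(U, "phylo_mean") <- a
  U
}

#' Evolutionary covariance of tip traits
#'
#' GLS evolutionary covariance `(X-1a')' C^-1 (X-1a') / (N-1)`, computed as
#' the cross-product of the whitened data (denominator N-1 by convention).
#'
#' @inheritParams phylo_transform
#' @return Trait x trait covariance matrix.
#' @export
evolutionary_covariance <- function(X, ctx) {
  U <- phylo_transform(X, ctx)
  crossprod(U) / (nrow(U) - 1)
}

#' Maximum-likelihood Brownian-motion ancestral states
#'
#' Estimates trait values at internal nodes by maximizing the BM likelihood,
#' equivalent to minimizing the branch-length-weighted sum of squared changes
#' along edges. The root estimate equals the GLS phylogenetic mean.
#'
#' @param X Specimen x trait matrix, row names = tip labels.
#' @param tree A rooted `ape::phylo`.
#' @return Internal-node x trait matrix; rows named by ape node numbers
#'   (`Ntip+1 ... Ntip+Nnode`), the first row being the root.
#' @export
ancestral_states <- function(X, tree) {
  validate_tree(tree)
  X <- as.matrix(X)
  if (is.null(rownames(X)) || !identical(rownames(X), tree$tip.label)) {
    stop_linkmod("rows of X must be named and ordered as the tree tips")
  }
  ntip <- ape::Ntip(tree); nnode <- tree$Nnode
  w <- 1 / tree$edge.length
  L <- matrix(0, nnode, nnode)        # internal-internal weights
  B <- matrix(0, nnode, ntip)         # internal-tip weights
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    L[pa, pa] <- L[pa, pa] + w[e]
    if (ch <= ntip) {
      B[pa, ch] <- B[pa, ch] + w[e]
    } else {
      ci <- ch - ntip
      L[ci, ci] <- L[ci, ci] + w[e]
      L[pa, ci] <- L[pa, ci] - w[e]
      L[ci, pa] <- L[ci, pa] - w[e]
    }
  }
  est <- solve(L, B %*% X)
  rownames(est) <- as.character(ntip + seq_len(nnode))
  colnames(est) <- colnames(X)
  est
}

#' Phylomorphospace projection
#'
#' Principal component analysis (covariance PCA on mean-centered vectorized
#' coordinates) of the tips only; maximum-likelihood BM ancestors are then
#' projected onto the same axes, giving the scores needed to draw the
#' phylogeny inside the morphospace.
#'
#' @param aligned An `aligned_shapes` object (or specimen x trait matrix with
#'   row names).
#' @param tree A rooted `ape::phylo` whose tips match the specimens.
#' @param n_axes Number of axes to return (defaults to full rank).
#' @return List of class `phylomorphospace_scores`: `scores` (tips x axes),
#'   `node_scores` (internal nodes x axes), `percent_variance`
#'   (non-increasing, sums to <= 100), `edges` (the tree edge matrix for
#'   plotting).
#' @export
phylomorphospace <- function(aligned, tree, n_axes = NULL) {
  X <- if (inherits(aligned, c("aligned_shapes", "configuration_set"))) {
    flatten_coords(aligned$coords)
  } else as.matrix(aligned)
  if (is.null(rownames(X)) || !setequal(rownames(X), tree$tip.label)) {
    stop_linkmod("specimens must match tree tips")
  }
  X <- X[tree$tip.label, , drop = FALSE]
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pos <- pca$sdev^2 > 1e-12 * pca$sdev[1]^2
  rank <- sum(pos)
  n_axes <- n_axes %||% rank
  if (n_axes > rank) {
    stop_linkmod("n_axes (", n_axes, ") exceeds available rank (", rank, ")")
  }
  pct <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  anc <- ancestral_states(X, tree)
  node_scores <- sweep(anc, 2, pca$center) %*% pca$rotation
  structure(
    list(scores = pca$x[, seq_len(n_axes), drop = FALSE],
         node_scores = node_scores[, seq_len(n_axes), drop = FALSE],
         percent_variance = pct[seq_len(n_axes)],
         edges = tree$edge),
    class = "phylomorphospace_scores"
  )
}
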