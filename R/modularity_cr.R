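#' Covariance ratio of a partitioned covariance matrix
#'
#' The covariance ratio (CR) compares the strength of between-module
#' covariation to within-module covariation. For modules i and j,
#' `CR_ij = sqrt( tr(S_ij S_ji) / sqrt(tr(S*_ii S*_ii) tr(S*_jj S*_jj)) )`
#' where `S*` zeroes the diagonal of a within-module block. Values below 1
#' indicate modular structure. For more than two modules the overall CR is
#' the mean of the pairwise values.
#'
#' @param S Symmetric trait covariance matrix.
#' @param partition List of disjoint trait-index vectors, each of length
#'   >= 2.
#' @return List with `cr` (overall scalar) and `pairwise` (symmetric
#'   module x module matrix, NA diagonal).
#' @export
covariance_ratio <- function(S, partition) {
  S <- as.matrix(S)
  if (any(lengths(partition) < 2L)) {
    stop_linkmod("each module needs at least 2 traits; ",
                 "within-module association is undefined otherwise")
  }
  if (anyDuplicated(unlist(partition))) {
    stop_linkmod("partition index sets overlap")
  }
  m <- length(partition)
  if (m < 2L) stop_linkmod("need at least 2 modules")
  ## tr(S_ij S_ji) is the sum of squared entries of the i,j block;
  ## tr(S*_ii^2) the same within block i with the diagonal removed.
  within_ss <- vapply(partition, function(ii) {
    sum(S[ii, ii]^2) - sum(diag(S)[ii]^2)
  }, 0)
  pw <- matrix(NA_real_, m, m,
               dimnames = list(names(partition), names(partition)))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      num <- sum(S[partition[[i]], partition[[j]]]^2)
      pw[i, j] <- pw[j, i] <- sqrt(num / sqrt(within_ss[i] * within_ss[j]))
    }
  }
  list(cr = mean(pw[upper.tri(pw)]), pairwise = pw)
}

## Resolve aligned input (aligned_shapes or matrix) to a tip-ordered
## specimen x trait matrix matching the tree.
.tip_matrix <- function(aligned, tree) {
  X <- if (inherits(aligned, c("aligned_shapes", "configuration_set"))) {
    flatten_coords(aligned$coords)
  } else as.matrix(aligned)
  if (is.null(rownames(X)) || !setequal(rownames(X), tree$tip.label)) {
    stop_linkmod("specimens must match tree tips")
  }
  X[tree$tip.label, , drop = FALSE]
}

.check_point_partition <- function(partition, p) {
  idx <- sort(unlist(partition))
  if (!identical(as.integer(idx), seq_len(p))) {
    stop_linkmod("partition must cover all ", p,
                 " points exactly once (got ", length(idx), " indices)")
  }
}

#' Phylogenetic covariance-ratio modularity test
#'
#' Computes the CR on the evolutionary covariance of phylogenetically
#' whitened landmark coordinates and calibrates it by permuting the
#' landmark-to-module labels. Landmarks move as whole (x,y,z) triplets, never
#' as single axes, so within-point covariance is preserved under the null.
#' Small CR means modular; the test is one-tailed for modularity
#' (`p = Pr(CR_perm <= CR_obs)`) and the effect size is the standardized
#' deviation `(CR_obs - mean(CR_perm)) / sd(CR_perm)` with the observed value
#' excluded from the null moments (strongly negative = strongly modular).
#'
#' @param aligned An `aligned_shapes` or `configuration_set` (or specimen x
#'   trait matrix) whose specimens match the tree tips.
#' @param tree A rooted `ape::phylo`.
#' @param partition List of disjoint 1-based point-index sets covering all
#'   landmarks (e.g. from [partition_points()]).
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed; mandatory, results are bit-reproducible given
#'   the seed.
#' @return An object of class `cr_result`.
#' @export
phylo_modularity <- function(aligned, tree, partition, n_perm = 999L, seed) {
  if (missing(seed) || is.null(seed)) stop_linkmod("seed is mandatory")
  if (n_perm < 99L) stop_linkmod("n_perm must be at least 99")
  X <- .tip_matrix(aligned, tree)
  p <- ncol(X) / 3
  .check_point_partition(partition, p)
  U <- phylo_transform(X, tree)
  S <- crossprod(U) / (nrow(U) - 1)
  trait_partition <- lapply(partition, coord_columns)
  obs <- covariance_ratio(S, trait_partition)
  sizes <- lengths(partition)
  perm_cr <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      relab <- split(sample.int(p), rep(seq_along(sizes), sizes))
      covariance_ratio(S, lapply(relab, coord_columns))$cr
    }, 0)
  })
  p_value <- (1 + sum(perm_cr <= obs$cr)) / (n_perm + 1)
  structure(
    list(cr_observed = obs$cr, pairwise_cr = obs$pairwise,
         p_value = p_value,
         effect_size = (obs$cr - mean(perm_cr)) / stats::sd(perm_cr),
         n_permutations = as.integer(n_perm), seed = as.integer(seed),
         perm_cr = perm_cr, specimen_ids = rownames(X),
         module_names = names(partition)),
    class = "cr_result"
  )
}

#' @export
print.cr_result <- function(x, ...) {
  cat(sprintf("CR = %.4f, p = %.4g, effect size Z = %.3f (%d permutations)\n",
              x$cr_observed, x$p_value, x$effect_size, x$n_permutations))
  invisible(x)
}

#' Compare covariance-ratio effect sizes across hypotheses
#'
#' Pairwise two-sample z statistics between effect sizes. Each effect size is
#' a permutation z-score (unit null standard deviation by construction), so
#' the difference of two is compared against a standard deviation of
#' `sqrt(2)`. The best-fitting hypothesis is the one with the lowest effect
#' size.
#'
#' @param results Named list of `cr_result` objects computed on the same
#'   specimens.
#' @return List with `effect_sizes`, `z` (pairwise matrix), `p` (two-sided
#'   normal p-values), `best` (name of the lowest effect size), and a tidy
#'   `table` ranking hypotheses by effect size.
#' @export
compare_cr <- function(results) {
  if (length(results) < 2L) stop_linkmod("need at least 2 results")
  ids <- lapply(results, `[[`, "specimen_ids")
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]]))) {
    stop_linkmod("results were not computed on the same specimens")
  }
  nm <- names(results) %||% paste0("R", seq_along(results))
  z_obs <- vapply(results, `[[`, 0, "effect_size")
  names(z_obs) <- nm
  k <- length(z_obs)
  zmat <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) zmat[i, j] <- (z_obs[i] - z_obs[j]) / sqrt(2)
  }
  pmat <- 2 * stats::pnorm(-abs(zmat))
  diag(pmat) <- NA_real_
  ord <- order(z_obs)
  list(effect_sizes = z_obs, z = zmat, p = pmat,
       best = nm[which.min(z_obs)],
       table = data.frame(hypothesis = nm[ord], effect_size = z_obs[ord],
                          p_value = vapply(results, `[[`, 0, "p_value")[ord],
                          row.names = NULL))
}
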