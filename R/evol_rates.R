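## Internal: whitened residual matrix U and bookkeeping for rate estimation.
.rate_setup <- function(aligned, tree) {
  X <- .tip_matrix(aligned, tree)
  ctx <- phylo_context(tree)
  U <- phylo_transform(X, ctx)
  list(X = X, U = U, ctx = ctx)
}

## sigma^2 per module from a whitened matrix: summed squared residuals over
## the module's coordinate columns divided by (N * landmark count). The
## landmark-count (not coordinate-count) denominator follows the multivariate
## rate convention, making rates comparable across modules of different
## sizes; it scales all rates by 3 relative to a per-coordinate definition.
.module_sigma <- function(U, partition) {
  n <- nrow(U)
  vapply(partition, function(idx) {
    sum(U[, coord_columns(idx)]^2) / (n * length(idx))
  }, 0)
}

#' Per-module Brownian-motion rates of shape evolution
#'
#' Estimates the multivariate net rate `sigma^2_mult` for each landmark
#' subset: the summed squared phylogenetically whitened residuals of the
#' module's coordinates divided by (number of specimens x number of
#' landmarks in the module). Units are squared Procrustes units per unit
#' branch length.
#'
#' @param aligned An `aligned_shapes` (or specimen x trait matrix) matching
#'   the tree tips.
#' @param tree A rooted `ape::phylo`.
#' @param partition Named list of point-index vectors (need not cover all
#'   points; empty modules are an error).
#' @return Named numeric vector of rates.
#' @export
module_rates <- function(aligned, tree, partition) {
  if (any(lengths(partition) == 0L)) stop_linkmod("empty module in partition")
  s <- .rate_setup(aligned, tree)
  .module_sigma(s$U, partition)
}

#' Rate-ratio test among landmark modules
#'
#' Compares per-module BM rates through the ratio of the highest to the
#' lowest rate. Significance is assessed by simulating multivariate BM on
#' the same tree under a common (pooled) rate with isotropic coordinate
#' covariance, recomputing the ratio for each simulation;
#' `p = Pr(ratio_sim >= ratio_obs)`.
#'
#' @inheritParams module_rates
#' @param n_sim Number of null simulations (>= 99).
#' @param seed Integer seed (mandatory; results reproducible given seed).
#' @return Object of class `rate_result`: `unit = "module"`, `rates`,
#'   `rate_ratio`, `pairwise_ratios`, `p_value`, `n_sim`, `seed`.
#' @export
rate_ratio_test <- function(aligned, tree, partition, n_sim = 999L, seed) {
  if (missing(seed) || is.null(seed)) stop_linkmod("seed is mandatory")
  if (length(partition) < 2L) stop_linkmod("need at least 2 modules")
  if (n_sim < 99L) stop_linkmod("n_sim must be at least 99")
  if (any(lengths(partition) == 0L)) stop_linkmod("empty module in partition")
  s <- .rate_setup(aligned, tree)
  rates <- .module_sigma(s$U, partition)
  obs_ratio <- max(rates) / min(rates)
  p_total <- sum(lengths(partition))
  cols <- coord_columns(unlist(partition))
  pooled <- sum(s$U[, cols]^2) / (nrow(s$U) * p_total)
  ## whitened null data are simulated directly: U_sim = C^{-1/2}(X - 1a')
  ## with X BM tip data; composing the two linear maps once keeps each
  ## simulation to a single matrix product.
  n <- nrow(s$U)
  ch <- chol(s$ctx$C)
  Cinv <- s$ctx$C_inv_sqrt %*% s$ctx$C_inv_sqrt
  one <- rep(1, n)
  g <- as.vector(Cinv %*% one) / as.numeric(crossprod(one, Cinv %*% one))
  proj <- diag(n) - tcrossprod(one, g)
  M <- s$ctx$C_inv_sqrt %*% proj %*% t(ch)
  sd_coord <- sqrt(pooled / 3)
  q <- 3 * p_total
  sim_ratio <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      Usim <- M %*% matrix(stats::rnorm(n * q, sd = sd_coord), n, q)
      colnames(Usim) <- NULL
      sim_part <- split(seq_len(p_total), rep(seq_along(partition),
                                              lengths(partition)))
      r <- .module_sigma(Usim, sim_part)
      max(r) / min(r)
    }, 0)
  })
  m <- length(rates)
  pr <- outer(rates, rates, `/`)
  structure(
    list(unit = "module", rates = rates, rate_ratio = obs_ratio,
         pairwise_ratios = pr,
         p_value = (1 + sum(sim_ratio >= obs_ratio)) / (n_sim + 1),
         sim_ratios = sim_ratio,
         n_sim = as.integer(n_sim), seed = as.integer(seed)),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%s rates (sigma^2_mult):\n", x$unit))
  print(signif(x$rates, 4))
  if (!is.null(x$rate_ratio)) {
    cat(sprintf("max/min ratio = %.3f", x$rate_ratio))
    if (!is.null(x$p_value)) cat(sprintf(", p = %.4g (%d simulations)",
                                         x$p_value, x$n_sim))
    cat("\n")
  }
  invisible(x)
}

#' Group-wise (clade) rates of shape evolution
#'
#' Estimates a BM rate per species group from group-restricted whitened
#' residual sums (normalized by group size and landmark count) and, when at
#' least two groups are present and `test = TRUE`, runs the same
#' common-rate simulation test as [rate_ratio_test()]. With
#' `prune_per_group = TRUE` each group's residuals are whitened on the tree
#' pruned to that group instead of the full tree.
#'
#' @inheritParams rate_ratio_test
#' @param groups Named character vector mapping every specimen to a group;
#'   each group needs >= 3 species.
#' @param test Run the ratio simulation test? Requesting a ratio with a
#'   single group is an error.
#' @param prune_per_group Whiten per pruned group tree rather than with the
#'   full tree.
#' @return Object of class `rate_result` with `unit = "group"`.
#' @export
group_rates <- function(aligned, tree, groups, n_sim = 999L, seed = NULL,
                        test = TRUE, prune_per_group = FALSE) {
  s <- .rate_setup(aligned, tree)
  tips <- rownames(s$X)
  if (!all(tips %in% names(groups))) {
    stop_linkmod("every specimen must be assigned to a group")
  }
  groups <- groups[tips]
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    stop_linkmod("each group needs at least 3 species: ",
                 paste(names(sizes)[sizes < 3], collapse = ", "))
  }
  p <- ncol(s$U) / 3
  rate_of_group <- function(gname) {
    members <- tips[groups == gname]
    if (prune_per_group) {
      sub <- ape::keep.tip(tree, members)
      Ug <- phylo_transform(s$X[sub$tip.label, , drop = FALSE], sub)
      sum(Ug^2) / (length(members) * p)
    } else {
      sum(s$U[members, ]^2) / (length(members) * p)
    }
  }
  gnames <- sort(unique(groups))
  rates <- stats::setNames(vapply(gnames, rate_of_group, 0), gnames)
  if (length(gnames) < 2L) {
    if (test) {
      stop_linkmod("only one group: a rate ratio requires at least two groups")
    }
    return(structure(list(unit = "group", rates = rates, rate_ratio = NULL,
                          p_value = NULL, n_sim = 0L, seed = seed),
                     class = "rate_result"))
  }
  obs_ratio <- max(rates) / min(rates)
  if (!test) {
    return(structure(list(unit = "group", rates = rates,
                          rate_ratio = obs_ratio,
                          pairwise_ratios = outer(rates, rates, `/`),
                          p_value = NULL, n_sim = 0L, seed = seed),
                     class = "rate_result"))
  }
  if (is.null(seed)) stop_linkmod("seed is mandatory for the simulation test")
  if (n_sim < 99L) stop_linkmod("n_sim must be at least 99")
  pooled <- sum(s$U^2) / (nrow(s$U) * p)
  n <- nrow(s$U)
  ch <- chol(s$ctx$C)
  Cinv <- s$ctx$C_inv_sqrt %*% s$ctx$C_inv_sqrt
  one <- rep(1, n)
  g <- as.vector(Cinv %*% one) / as.numeric(crossprod(one, Cinv %*% one))
  M <- s$ctx$C_inv_sqrt %*% (diag(n) - tcrossprod(one, g)) %*% t(ch)
  rownames(M) <- tips
  sd_coord <- sqrt(pooled / 3)
  sim_ratio <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      Usim <- M %*% matrix(stats::rnorm(n * 3 * p, sd = sd_coord), n, 3 * p)
      r <- vapply(gnames, function(gn) {
        sum(Usim[groups == gn, ]^2) / (sum(groups == gn) * p)
      }, 0)
      max(r) / min(r)
    }, 0)
  })
  structure(
    list(unit = "group", rates = rates, rate_ratio = obs_ratio,
         pairwise_ratios = outer(rates, rates, `/`),
         p_value = (1 + sum(sim_ratio >= obs_ratio)) / (n_sim + 1),
         sim_ratios = sim_ratio,
         n_sim = as.integer(n_sim), seed = as.integer(seed)),
    class = "rate_result"
  )
}
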