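#' Specification for simulating modular shape data
#'
#' Bundles the ground truth of a simulation: tree size, points per bone,
#' the true bone-to-module map, per-module rates (per-landmark
#' `sigma^2_mult`; coordinate variance is rate/3), within- and between-module
#' correlations, and the seed. The implied trait covariance must be positive
#' definite, checked at construction. For a "modular" scenario
#' `within_corr > between_corr`.
#'
#' @param n_tips Number of species (>= 3).
#' @param points_per_bone Points per bone element (see [make_scheme()]).
#' @param module_truth Named character vector bone -> module id; defaults to
#'   the two-module split of hypothesis H2 (linkage bones vs remainder).
#' @param rate_per_module Named numeric of per-landmark rates per module id
#'   (default 1 for all).
#' @param within_corr,between_corr Landmark correlations within/between true
#'   modules (defaults 0.7 / 0.1).
#' @param seed Integer seed.
#' @return Object of class `simulation_spec` (includes the `landmark_scheme`
#'   and the Cholesky factor of the trait covariance).
#' @export
simulation_spec <- function(n_tips = 64L, points_per_bone = 3L,
                            module_truth = NULL, rate_per_module = NULL,
                            within_corr = 0.7, between_corr = 0.1,
                            seed = 1L) {
  if (n_tips < 3L) stop_linkmod("n_tips must be at least 3")
  if (within_corr < 0 || within_corr >= 1 || between_corr < 0 ||
      between_corr >= 1) {
    stop_linkmod("correlations must lie in [0, 1)")
  }
  scheme <- make_scheme(points_per_bone)
  if (is.null(module_truth)) {
    h2 <- builtin_hypotheses()$H2
    module_truth <- stats::setNames(rep(NA_character_, 16), bone_elements())
    for (k in seq_along(h2$modules)) {
      module_truth[h2$modules[[k]]] <- paste0("M", k)
    }
  }
  module_truth <- stats::setNames(as.character(module_truth),
                                  canonical_bone(names(module_truth)))
  if (!all(unique(scheme$bone_of) %in% names(module_truth))) {
    stop_linkmod("module_truth must cover every bone in the scheme")
  }
  mods <- sort(unique(module_truth))
  if (is.null(rate_per_module)) {
    rate_per_module <- stats::setNames(rep(1, length(mods)), mods)
  }
  if (!all(mods %in% names(rate_per_module)) ||
      any(rate_per_module <= 0)) {
    stop_linkmod("rate_per_module must name every module with a positive rate")
  }
  ## per-landmark covariance: corr within_corr inside a true module,
  ## between_corr across, scaled by sqrt of the landmark rates
  lm_module <- module_truth[scheme$bone_of]
  p <- n_points(scheme)
  P <- matrix(between_corr, p, p)
  for (m in mods) {
    ii <- which(lm_module == m)
    P[ii, ii] <- within_corr
  }
  diag(P) <- 1
  sdv <- sqrt(rate_per_module[lm_module])
  sigma_landmark <- P * tcrossprod(sdv)
  ch <- tryCatch(chol(sigma_landmark), error = function(e) {
    stop_linkmod("trait covariance implied by (rates, within_corr, ",
                 "between_corr) is not positive definite")
  })
  structure(
    list(n_tips = as.integer(n_tips), scheme = scheme,
         module_truth = module_truth, rate_per_module = rate_per_module,
         within_corr = within_corr, between_corr = between_corr,
         seed = as.integer(seed), sigma_landmark = sigma_landmark,
         chol_landmark = ch, landmark_module = lm_module),
    class = "simulation_spec"
  )
}

#' True point-index partition of a simulation
#'
#' @param spec A `simulation_spec`.
#' @return Named list of point-index vectors, one per true module.
#' @export
true_partition <- function(spec) {
  mods <- sort(unique(spec$landmark_module))
  stats::setNames(lapply(mods, function(m) {
    which(spec$landmark_module == m)
  }), mods)
}

#' Simulate a pure-birth ultrametric tree of unit depth
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed; identical seeds give identical Newick strings.
#' @return A strictly bifurcating rooted ultrametric `ape::phylo` with all
#'   root-to-tip depths equal to 1.
#' @export
simulate_tree <- function(n_tips, seed) {
  if (n_tips < 3L) stop_linkmod("n_tips must be at least 3")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate modular shape data under multivariate Brownian motion
#'
#' Tip configurations evolve as `vec(X) ~ MVN(1 (x) mu, C (x) Sigma)` with C
#' the BM covariance of the tree and Sigma block-structured by the true
#' modules (per-landmark correlation `within_corr` inside and `between_corr`
#' across modules, per-landmark variance = module rate; the three coordinates
#' of a landmark are independent with variance rate/3). By default data are
#' produced directly in aligned tangent-space coordinates around a seeded
#' mean shape; `nuisance = TRUE` additionally applies a random rotation,
#' translation and scaling to every specimen so the full GPA path is
#' exercised.
#'
#' @param tree An `ape::phylo` (typically from [simulate_tree()]).
#' @param spec A `simulation_spec`.
#' @param nuisance Apply random similarity transforms per specimen?
#' @return A `configuration_set` (specimens in tip-label order) with
#'   attribute `truth` = list(partition, module_truth, spec).
#' @export
simulate_modular_shapes <- function(tree, spec, nuisance = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (ape::Ntip(tree) != spec$n_tips) {
    stop_linkmod("tree tip count does not match spec$n_tips")
  }
  p <- n_points(spec$scheme)
  n <- spec$n_tips
  C <- bm_covariance(tree)
  coords <- with_seed(spec$seed, {
    mu <- center_scale(matrix(stats::rnorm(p * 3), p, 3))$coords * sqrt(p)
    ## per-coordinate sampling: same landmark covariance on x, y, z,
    ## coordinates mutually independent, variance rate/3 per coordinate
    chL <- spec$chol_landmark / sqrt(3)
    chC <- chol(C)
    arr <- array(0, dim = c(p, 3, n))
    for (axis in 1:3) {
      Z <- matrix(stats::rnorm(n * p), n, p)
      X <- t(chC) %*% Z %*% chL           # n x p tip deviations
      arr[, axis, ] <- t(sweep(X, 2, mu[, axis], `+`))
    }
    if (nuisance) {
      for (i in seq_len(n)) {
        Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
        if (det(Q) < 0) Q[, 1] <- -Q[, 1]
        s <- stats::runif(1, 0.5, 2)
        tr <- stats::rnorm(3, sd = 2)
        arr[, , i] <- sweep(s * arr[, , i] %*% Q, 2, tr, `+`)
      }
    }
    arr
  })
  cs <- configuration_set(coords, rownames(C), spec$scheme)
  attr(cs, "truth") <- list(partition = true_partition(spec),
                            module_truth = spec$module_truth, spec = spec)
  cs
}

#' Simulate a batch of 4-bar linkage geometries
#'
#' Unit-square base joints (J1 = origin, J2 = (1,0,0), J3 = (1,1,0),
#' J4 = (0,1,h)) with the free joint lifted by `h` per system, plus optional
#' isotropic Gaussian jitter. Planarity decreases as `h` grows; with
#' `h = 0` and no noise every linkage is exactly planar (planarity 1), and
#' with `h = 1` and no noise planarity is `2 / (1 + sqrt(3))`.
#'
#' @param n Linkages per system.
#' @param h_per_system Named numeric vector of J4 lifts (h >= 0), one entry
#'   per system.
#' @param noise_sd Standard deviation of coordinate jitter (default 0).
#' @param seed Integer seed.
#' @return List of `linkage_joints`.
#' @export
simulate_linkage_batch <- function(n, h_per_system, noise_sd = 0, seed = 1L) {
  if (any(h_per_system < 0)) stop_linkmod("h must be non-negative")
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  with_seed(seed, {
    out <- list()
    for (sys in names(h_per_system)) {
      for (i in seq_len(n)) {
        J <- base
        J[4, 3] <- h_per_system[[sys]]
        if (noise_sd > 0) J <- J + matrix(stats::rnorm(12, sd = noise_sd),
                                          4, 3)
        out[[length(out) + 1L]] <- linkage_joints(
          J, system = sys, specimen = paste0(sys, "_", i))
      }
    }
    out
  })
}
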