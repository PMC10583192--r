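#' Center a configuration and scale it to unit centroid size
#'
#' Centroid size is the root summed squared distance of all points from their
#' centroid; dividing by it makes shapes of different specimens commensurate.
#'
#' @param block A p x 3 coordinate matrix.
#' @return List with `coords` (centered, unit-size p x 3 matrix) and
#'   `centroid_size` (the original size).
#' @export
center_scale <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) < 3L) stop_linkmod("need at least 3 points")
  centered <- sweep(block, 2, colMeans(block))
  cs <- sqrt(sum(centered^2))
  if (cs < 1e-12) stop_linkmod("degenerate configuration: all points coincident")
  list(coords = centered / cs, centroid_size = cs)
}

#' Optimal proper rotation of one configuration onto another
#'
#' Returns the rotation matrix R (determinant +1; reflections excluded, as is
#' standard for unilaterally digitised anatomical data) minimizing
#' `||A R - B||^2` for centered configurations A and B.
#'
#' @param A,B Centered p x 3 coordinate matrices with equal point counts.
#' @return A 3 x 3 proper rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop_linkmod("dimension mismatch between A and B")
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Procrustes (chord) distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, `b` is
#' optimally rotated onto `a`, and the square root of the summed squared
#' coordinate differences is returned.
#'
#' @param a,b p x 3 coordinate matrices.
#' @return Non-negative scalar; 0 iff the shapes are identical up to a
#'   similarity transform (without reflection).
#' @export
procrustes_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_linkmod("point count mismatch")
  a <- center_scale(a)$coords
  b <- center_scale(b)$coords
  b <- b %*% optimal_rotation(b, a)
  sqrt(sum((a - b)^2))
}

## Slide the semi-landmarks of one configuration toward a reference:
## each semi-landmark moves along its local curve tangent by the tangential
## component of (reference - current), which minimizes its squared chord
## distance to the reference along that direction. Fixed landmarks and the
## normal component are untouched.
.slide_block <- function(block, scheme, reference) {
  for (cv in scheme$curves) {
    if (length(cv) < 3) stop_linkmod("curve with fewer than 3 points")
    for (j in seq(2, length(cv) - 1L)) {
      k <- cv[j]
      if (!scheme$is_semilandmark[k]) next
      tangent <- block[cv[j + 1L], ] - block[cv[j - 1L], ]
      nt <- sqrt(sum(tangent^2))
      if (nt < 1e-12) next
      tangent <- tangent / nt
      block[k, ] <- block[k, ] +
        tangent * sum(tangent * (reference[k, ] - block[k, ]))
    }
  }
  block
}

#' Slide semi-landmarks toward a reference configuration
#'
#' Applies tangent-direction sliding (minimum Procrustes chord distance
#' criterion) to every specimen of an aligned set. Tangents are the
#' normalized chord between the two curve neighbours of each semi-landmark.
#' Sliding never increases a specimen's summed squared distance to the
#' reference.
#'
#' @param aligned An `aligned_shapes` object (or p x 3 x n array).
#' @param scheme A `landmark_scheme` with at least one curve.
#' @param reference Reference p x 3 configuration; defaults to the consensus.
#' @return p x 3 x n array of adjusted coordinates.
#' @export
slide_semilandmarks <- function(aligned, scheme, reference = NULL) {
  coords <- if (inherits(aligned, "aligned_shapes")) aligned$coords else aligned
  reference <- reference %||% aligned$consensus
  if (!length(scheme$curves)) stop_linkmod("scheme defines no curves")
  if (nrow(reference) != dim(coords)[1]) {
    stop_linkmod("reference point count mismatch")
  }
  for (i in seq_len(dim(coords)[3])) {
    coords[, , i] <- .slide_block(coords[, , i], scheme, reference)
  }
  coords
}

## Deterministic canonical orientation: rotate everything so the consensus
## lies along its principal axes, with eigenvector signs fixed by their
## largest-magnitude element and det +1 enforced. Makes GPA output invariant
## to a common rigid motion of the inputs.
.principal_axes <- function(consensus) {
  V <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  p <- nrow(consensus)
  ## sign convention must depend only on the projected coordinates (which a
  ## common pre-rotation of the inputs leaves unchanged), never on the
  ## eigenvector entries themselves
  for (j in 1:2) {
    proj <- as.vector(consensus %*% V[, j])
    a <- sum(seq_len(p) * proj)
    if (abs(a) < 1e-12) a <- sum(proj^3)
    if (a < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- .cross3(V[, 1], V[, 2])   # right-handed => proper rotation
  V
}

#' Generalized Procrustes Analysis
#'
#' Iteratively centers, scales to unit centroid size, and rotates all
#' configurations to their evolving consensus until the consensus stabilises;
#' optionally interleaves chord-distance semi-landmark sliding against the
#' current consensus. Sliding runs in a first phase at a coarser tolerance
#' (positions along a curve are a nearly neutral direction, so full-precision
#' convergence during sliding would stall); semi-landmarks are then frozen
#' and alignment iterates to `tol`. The final solution is rotated to the
#' consensus' principal axes, so the output is invariant to any common
#' similarity transform of the inputs and deterministic given specimen
#' order.
#'
#' @param config A `configuration_set` (>= 2 specimens).
#' @param slide Slide semi-landmarks along their curves? Requires a scheme
#'   with curves.
#' @param slide_once If `TRUE`, sliding is a single pass after the first
#'   alignment instead of being interleaved with every iteration.
#' @param tol Convergence tolerance on the change in consensus sum of
#'   squares.
#' @param max_iter Maximum number of alignment iterations; non-convergence
#'   gives a warning and `converged = FALSE`, not an error.
#' @return An `aligned_shapes` object: `coords` (p x 3 x n, each specimen
#'   centered at the origin with unit centroid size), `consensus` (their
#'   mean), `centroid_sizes`, `n_iterations`, `converged`.
#' @export
gpa <- function(config, slide = FALSE, slide_once = FALSE,
                tol = 1e-10, max_iter = 100L) {
  coords <- config$coords
  n <- dim(coords)[3]
  if (n < 2L) stop_linkmod("GPA needs at least 2 specimens")
  if (slide && (is.null(config$scheme) || !length(config$scheme$curves))) {
    stop_linkmod("slide = TRUE requires a scheme with curves")
  }
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- center_scale(coords[, , i])
    coords[, , i] <- cs$coords
    sizes[i] <- cs$centroid_size
  }
  ## initial consensus: everything rotated onto the first specimen
  ref <- coords[, , 1]
  for (i in seq_len(n)) {
    coords[, , i] <- coords[, , i] %*% optimal_rotation(coords[, , i], ref)
  }
  consensus <- center_scale(apply(coords, c(1, 2), mean))$coords
  ## Sliding runs in a first phase at a coarser tolerance: semi-landmark
  ## positions along a curve are a nearly neutral direction (the whole
  ## curve can drift in its own parametrization without changing fit), so
  ## demanding full tol during sliding would stall. Once the consensus is
  ## stable at slide_tol the semis are frozen and plain alignment iterates
  ## to tol.
  converged <- FALSE
  iter <- 0L
  slide_tol <- max(tol, 1e-8)
  sliding <- slide
  n_slide_passes <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (sliding) {
      for (i in seq_len(n)) {
        adj <- .slide_block(coords[, , i], config$scheme, consensus)
        coords[, , i] <- center_scale(adj)$coords
      }
      n_slide_passes <- n_slide_passes + 1L
      if (slide_once) sliding <- FALSE
    }
    for (i in seq_len(n)) {
      coords[, , i] <- coords[, , i] %*%
        optimal_rotation(coords[, , i], consensus)
    }
    new_consensus <- center_scale(apply(coords, c(1, 2), mean))$coords
    delta <- sum((new_consensus - consensus)^2)
    consensus <- new_consensus
    if (sliding && (delta < slide_tol || n_slide_passes >= 20L)) {
      sliding <- FALSE
      next
    }
    if (!sliding && delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("GPA did not converge in ", max_iter, " iterations")
  }
  V <- .principal_axes(consensus)
  for (i in seq_len(n)) coords[, , i] <- coords[, , i] %*% V
  ## reported consensus is the arithmetic mean of the aligned specimens
  ## (unit size is a property of the specimens, not of their mean)
  consensus <- apply(coords, c(1, 2), mean)
  dimnames(coords) <- dimnames(config$coords)
  dimnames(consensus) <- dimnames(config$coords)[1:2]
  structure(
    list(coords = coords, consensus = consensus, centroid_sizes = sizes,
         n_iterations = iter, converged = converged,
         specimen_ids = config$specimen_ids, scheme = config$scheme),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("aligned_shapes:", dim(x$coords)[3], "specimens x", dim(x$coords)[1],
      "points;", x$n_iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}
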