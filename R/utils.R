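#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_linkmod <- function(..., class = "linkmod_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

## Coordinates travel as p x 3 x n arrays (landmarks x dimensions x specimens).
assert_coord_array <- function(coords, what = "coords") {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop_linkmod(what, " must be a p x 3 x n array of 3D coordinates")
  }
  if (!all(is.finite(coords))) {
    stop_linkmod(what, " contains non-finite coordinates")
  }
  invisible(coords)
}

## Flatten p x 3 x n -> n x 3p (x1 y1 z1 x2 y2 z2 ...), one row per specimen.
flatten_coords <- function(coords) {
  p <- dim(coords)[1]; n <- dim(coords)[3]
  out <- matrix(aperm(coords, c(2, 1, 3)), nrow = n, ncol = 3 * p, byrow = TRUE)
  rownames(out) <- dimnames(coords)[[3]]
  out
}

## Inverse of flatten_coords.
unflatten_coords <- function(X, point_labels = NULL) {
  n <- nrow(X); p <- ncol(X) / 3
  if (p != round(p)) stop_linkmod("column count is not a multiple of 3")
  coords <- aperm(array(t(X), dim = c(3, p, n)), c(2, 1, 3))
  dimnames(coords) <- list(point_labels, c("x", "y", "z"), rownames(X))
  coords
}

## Column indices in the flattened matrix for a set of landmark indices.
coord_columns <- function(point_idx) {
  as.vector(rbind(3 * point_idx - 2, 3 * point_idx - 1, 3 * point_idx))
}

## Deterministic RNG scope: run expr under a local seed without disturbing
## the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Symmetric inverse square root; eigenvalues below tol * max are an error
## (rank-deficient phylogenetic covariance cannot be whitened).
sym_inv_sqrt <- function(M, tol = 1e-12) {
  eig <- eigen(M, symmetric = TRUE)
  if (any(eig$values < tol * max(eig$values))) {
    stop_linkmod("matrix is numerically singular; cannot form inverse square root")
  }
  eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
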