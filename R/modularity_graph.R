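#' Per-bone point partition of a scheme
#'
#' Splits the point indices of a scheme by bone element, in
#' [bone_elements()] order. This is the node set of the graphical-model
#' modularity analysis.
#'
#' @param scheme A `landmark_scheme`.
#' @return Named list of point-index vectors, one per bone present.
#' @export
bone_partition <- function(scheme) {
  bones <- intersect(bone_elements(), unique(scheme$bone_of))
  stats::setNames(lapply(bones, function(b) which(scheme$bone_of == b)), bones)
}

## Extract the p_b x 3 x n sub-array for one partition block.
.block_coords <- function(coords, idx) coords[idx, , , drop = FALSE]

#' Pairwise specimen distance matrices per shape partition
#'
#' For each block of the partition, computes a symmetric zero-diagonal
#' specimen x specimen distance matrix in one of two modes:
#' \describe{
#'   \item{shape_only}{each block is superimposed independently, so only the
#'     block's own shape contributes: pairwise Procrustes distances between
#'     block configurations.}
#'   \item{position_and_shape}{blocks are taken verbatim from the supplied
#'     (whole-configuration) alignment, so relative position and size of the
#'     block within the skull contribute: pairwise Euclidean distances.}
#' }
#' With `tree` supplied, distances are computed between rows of the
#' phylogenetically whitened block coordinates (the same `C^{-1/2}` transform
#' for every block; blocks are GPA-aligned first in `shape_only` mode), which
#' removes shared-ancestry correlation before the conditional-independence
#' analysis.
#'
#' @param data An `aligned_shapes` or `configuration_set`.
#' @param partition Named list of point-index vectors (blocks of >= 3
#'   points).
#' @param mode `"shape_only"` or `"position_and_shape"`.
#' @param tree Optional rooted `ape::phylo` for phylogenetic control.
#' @return Named list of n x n distance matrices.
#' @export
partition_distance_matrices <- function(data, partition,
                                        mode = c("position_and_shape",
                                                 "shape_only"),
                                        tree = NULL) {
  mode <- match.arg(mode)
  coords <- data$coords
  n <- dim(coords)[3]
  if (n < 3L) stop_linkmod("need at least 3 specimens")
  if (any(lengths(partition) < 3L)) {
    stop_linkmod("every partition block needs at least 3 points")
  }
  ids <- dimnames(coords)[[3]]
  ctx <- if (!is.null(tree)) phylo_context(tree)
  out <- lapply(partition, function(idx) {
    blk <- .block_coords(coords, idx)
    if (is.null(tree)) {
      if (mode == "shape_only") {
        D <- matrix(0, n, n, dimnames = list(ids, ids))
        for (i in seq_len(n - 1)) {
          for (j in seq(i + 1, n)) {
            D[i, j] <- D[j, i] <- procrustes_distance(blk[, , i], blk[, , j])
          }
        }
        D
      } else {
        as.matrix(stats::dist(flatten_coords(blk)))
      }
    } else {
      M <- if (mode == "shape_only") {
        flatten_coords(gpa(configuration_set(blk, ids))$coords)
      } else {
        flatten_coords(blk)
      }
      as.matrix(stats::dist(phylo_transform(M[ctx$tips, , drop = FALSE], ctx)))
    }
  })
  names(out) <- names(partition)
  out
}

#' Matrix correlation between two distance matrices
#'
#' Pearson correlation over the strictly lower triangles.
#'
#' @param D1,D2 Symmetric matrices of identical dimension.
#' @return Correlation in `[-1, 1]`.
#' @export
matrix_correlation <- function(D1, D2) {
  if (!all(dim(D1) == dim(D2))) stop_linkmod("distance matrices differ in size")
  a <- D1[lower.tri(D1)]
  b <- D2[lower.tri(D2)]
  if (stats::sd(a) < 1e-15 || stats::sd(b) < 1e-15) {
    stop_linkmod("constant distance matrix: correlation undefined")
  }
  stats::cor(a, b)
}

#' Correlation matrix among shape partitions
#'
#' Builds the partition x partition matrix of matrix correlations between
#' per-block specimen distance matrices; the input to the Gaussian
#' graphical-model fits.
#'
#' @inheritParams partition_distance_matrices
#' @return Object of class `partition_correlation` with `partitions`, `R`,
#'   `n_specimens`, `mode`.
#' @export
partition_correlation <- function(data, partition,
                                  mode = c("position_and_shape",
                                           "shape_only"),
                                  tree = NULL) {
  mode <- match.arg(mode)
  D <- partition_distance_matrices(data, partition, mode, tree)
  m <- length(D)
  R <- diag(1, m)
  dimnames(R) <- list(names(D), names(D))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      R[i, j] <- R[j, i] <- matrix_correlation(D[[i]], D[[j]])
    }
  }
  structure(
    list(partitions = names(D), R = R, n_specimens = dim(data$coords)[3],
         mode = mode),
    class = "partition_correlation"
  )
}

## Edge list (2-column character matrix) for a hypothesis: bones in the same
## module covary; no edges between modules.
hypothesis_graph <- function(hypothesis, nodes) {
  edges <- NULL
  for (m in hypothesis$modules) {
    m <- intersect(nodes, m)
    if (length(m) >= 2) {
      pairs <- utils::combn(m, 2)
      edges <- cbind(edges, pairs)
    }
  }
  if (is.null(edges)) {
    matrix(character(0), nrow = 2)
  } else edges
}

#' Fit a Gaussian graphical model by iterative proportional scaling
#'
#' Fits the covariance-selection model in which concentration-matrix entries
#' for missing edges are zero while fitted marginals match `R` on the cliques
#' of the graph. Deviance is `n (tr(R K) - log det(R K) - p)`; for the
#' saturated graph it is 0 with `K = R^-1`.
#'
#' @param R A `partition_correlation` (or a positive-definite correlation
#'   matrix).
#' @param edges 2 x k (or k x 2) matrix of node-name pairs allowed to covary;
#'   no row/column means the empty graph.
#' @param n Number of specimens (taken from `R` when it is a
#'   `partition_correlation`).
#' @param name Optional hypothesis name stored in the result.
#' @param tol Convergence tolerance on fitted clique marginals.
#' @param max_cycles Maximum IPS sweeps.
#' @return Object of class `graph_model_fit`: `name`, `edges`, `deviance`,
#'   `df` (missing-edge count), `ic` (deviance + 2 x free parameters),
#'   `fitted_concentration`.
#' @export
fit_graph_model <- function(R, edges, n = NULL, name = NULL,
                            tol = 1e-10, max_cycles = 200L) {
  if (inherits(R, "partition_correlation")) {
    n <- n %||% R$n_specimens
    S <- R$R
  } else {
    S <- as.matrix(R)
  }
  if (is.null(n)) stop_linkmod("specimen count n is required")
  p <- ncol(S)
  nodes <- colnames(S)
  if (is.null(nodes)) nodes <- colnames(S) <- rownames(S) <- paste0("V", 1:p)
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop_linkmod("correlation matrix is not positive definite; ",
                 "more specimens (or fewer partitions) are needed")
  }
  if (is.matrix(edges) && nrow(edges) != 2 && ncol(edges) == 2) {
    edges <- t(edges)
  }
  k_edges <- ncol(edges) %||% 0L
  bad <- setdiff(as.vector(edges), nodes)
  if (length(bad)) stop_linkmod("unknown graph nodes: ",
                                paste(bad, collapse = ", "))
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (k_edges) for (e in seq_len(k_edges)) {
    adj[edges[1, e], edges[2, e]] <- adj[edges[2, e], edges[1, e]] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  cliques <- lapply(cliques, function(cl) sort(as.integer(cl)))
  K <- diag(1 / diag(S), p)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    for (cl in cliques) {
      Sigma <- solve(K)
      K[cl, cl] <- K[cl, cl] + solve(S[cl, cl, drop = FALSE]) -
        solve(Sigma[cl, cl, drop = FALSE])
    }
    Sigma <- solve(K)
    err <- max(vapply(cliques, function(cl) {
      max(abs(Sigma[cl, cl] - S[cl, cl]))
    }, 0))
    if (err < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop_linkmod("graphical-model fit did not converge in ", max_cycles,
                 " cycles")
  }
  SK <- S %*% K
  deviance <- n * (sum(diag(SK)) - determinant(SK)$modulus[1] - p)
  deviance <- max(deviance, 0)
  n_missing <- p * (p - 1) / 2 - k_edges
  structure(
    list(name = name, edges = edges, deviance = as.numeric(deviance),
         df = as.integer(n_missing),
         ic = as.numeric(deviance) + 2 * (k_edges + p),
         fitted_concentration = K, n = n),
    class = "graph_model_fit"
  )
}

#' @export
print.graph_model_fit <- function(x, ...) {
  cat(sprintf("%s: deviance %.3f on %d df, IC %.3f\n",
              x$name %||% "graph model", x$deviance, x$df, x$ic))
  invisible(x)
}

#' Rank modularity hypotheses by graphical-model fit
#'
#' Each hypothesis is translated into a conditional-independence graph over
#' the partition nodes (edges between bones sharing a module, none across
#' modules), fitted against the partition correlation matrix, and ranked by
#' a deviance information criterion `IC = deviance + 2 (edges + nodes)`;
#' lower is better. Rankings, not absolute IC values, are the meaningful
#' output.
#'
#' @param pc A `partition_correlation` whose partitions are bone elements
#'   (see [bone_partition()]).
#' @param hypotheses List of `modularity_hypothesis` objects (defaults to the
#'   full H1-H13 registry).
#' @return List with `table` (data frame sorted ascending by `ic`, with a
#'   `non_identifiable` flag for saturated single-module hypotheses), `fits`
#'   (named list of `graph_model_fit`), `best`.
#' @export
rank_hypotheses <- function(pc, hypotheses = builtin_hypotheses()) {
  if (!inherits(pc, "partition_correlation")) {
    stop_linkmod("pc must be a partition_correlation")
  }
  nodes <- pc$partitions
  fits <- lapply(hypotheses, function(h) {
    missing <- setdiff(unlist(h$modules), c(nodes, setdiff(bone_elements(),
                                                           nodes)))
    fit_graph_model(pc, hypothesis_graph(h, nodes), name = h$name)
  })
  names(fits) <- vapply(hypotheses, `[[`, "", "name")
  tab <- data.frame(
    hypothesis = names(fits),
    n_modules = vapply(hypotheses, `[[`, 0L, "n_modules"),
    deviance = vapply(fits, `[[`, 0, "deviance"),
    df = vapply(fits, `[[`, 0L, "df"),
    ic = vapply(fits, `[[`, 0, "ic"),
    non_identifiable = vapply(hypotheses, function(h) h$n_modules == 1L, TRUE),
    row.names = NULL
  )
  tab <- tab[order(tab$ic), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits, best = tab$hypothesis[1])
}
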