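## Shared fixtures, all generated in code.

## tiny scheme: one point per bone (16 points, no curves)
toy_scheme <- function() make_scheme(1L)

## small random configuration set on a given scheme
random_config <- function(n = 4, scheme = toy_scheme(), seed = 1) {
  p <- n_points(scheme)
  coords <- linkmod:::with_seed(seed, {
    array(rnorm(p * 3 * n), dim = c(p, 3, n))
  })
  configuration_set(coords, paste0("sp", seq_len(n)), scheme)
}

## scheme with one sliding curve: 2 fixed endpoints + k semis + extra fixed
line_scheme <- function(k = 3) {
  p <- k + 3
  landmark_scheme(
    point_labels = paste0("pt", seq_len(p)),
    bone_of = rep("dentary", p),
    is_semilandmark = c(FALSE, FALSE, rep(TRUE, k), FALSE),
    curves = list(c(1L, 2L + seq_len(k), 2L))
  )
}

## apply a random similarity transform (proper rotation, scale, shift) to
## every specimen of a configuration set
apply_similarity <- function(config, seed = 1) {
  coords <- config$coords
  linkmod:::with_seed(seed, {
    for (i in seq_len(dim(coords)[3])) {
      Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      coords[, , i] <- sweep(runif(1, 0.5, 3) * coords[, , i] %*% Q, 2,
                             rnorm(3, sd = 5), `+`)
    }
    coords
  })
  configuration_set(coords, config$specimen_ids, config$scheme)
}

## common rigid motion applied to ALL specimens (same Q, s, t)
apply_common_similarity <- function(config, seed = 1) {
  coords <- config$coords
  linkmod:::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    s <- runif(1, 0.5, 3)
    tr <- rnorm(3, sd = 5)
    for (i in seq_len(dim(coords)[3])) {
      coords[, , i] <- sweep(s * coords[, , i] %*% Q, 2, tr, `+`)
    }
  })
  configuration_set(coords, config$specimen_ids, config$scheme)
}

## unit square joints, optionally with J4 lifted by h
square_joints <- function(h = 0) {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, h))
}

## independent naive CR implementation: elementwise double loops over the
## printed formula, no shared code with covariance_ratio()
naive_cr <- function(S, partition) {
  m <- length(partition)
  star <- function(ii) { B <- S[ii, ii]; diag(B) <- 0; B }
  pair <- function(i, j) {
    Sij <- S[partition[[i]], partition[[j]], drop = FALSE]
    num <- sum(diag(Sij %*% t(Sij)))
    di <- sum(diag(star(partition[[i]]) %*% star(partition[[i]])))
    dj <- sum(diag(star(partition[[j]]) %*% star(partition[[j]])))
    sqrt(num / sqrt(di * dj))
  }
  vals <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) vals <- c(vals, pair(i, j))
  mean(vals)
}
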