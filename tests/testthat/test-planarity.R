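random_rigid <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(Q = Q, t = rnorm(3, sd = 4))
}

test_that("align_to_plane canonicalises rigidly", {
  J <- square_joints(h = 0.4)
  al <- align_to_plane(J)$joints
  expect_equal(unname(al[1, ]), c(0, 0, 0))
  expect_equal(unname(al[2, c("y", "z")]), c(0, 0))
  expect_gt(al[2, "x"], 0)
  expect_equal(unname(al[3, "z"]), 0)
  expect_gt(al[3, "y"], 0)
  ## idempotence
  expect_equal(align_to_plane(al)$joints, al, tolerance = 1e-12)
  ## invariance to an arbitrary rigid pre-motion
  rg <- random_rigid(5)
  moved <- sweep(J %*% rg$Q, 2, rg$t, `+`)
  expect_equal(align_to_plane(moved)$joints, al, tolerance = 1e-9)
  ## rigidity: pairwise distances preserved
  expect_equal(as.matrix(dist(al)), as.matrix(dist(J)), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## collinear fixed-plane joints are degenerate
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 1))
  expect_error(align_to_plane(bad), "collinear")
})

test_that("quad_area_3d matches hand and numerical oracles", {
  sq <- square_joints()
  expect_equal(quad_area_3d(sq[1, ], sq[2, ], sq[3, ], sq[4, ]), 1)
  lifted <- square_joints(h = 1)
  a <- quad_area_3d(lifted[1, ], lifted[2, ], lifted[3, ], lifted[4, ])
  expect_equal(a, (1 + sqrt(3)) / 2, tolerance = 1e-12)
  ## numerical oracle: fine barycentric triangulation of the two triangles
  subdiv_area <- function(p, q, r, m = 64) {
    tot <- 0
    for (i in seq_len(m)) for (j in seq_len(m - i + 1)) {
      f <- function(ii, jj) p + (q - p) * ii / m + (r - p) * jj / m
      v1 <- f(i - 1, j - 1); v2 <- f(i, j - 1); v3 <- f(i - 1, j)
      tot <- tot + sqrt(sum(linkmod:::.cross3(v2 - v1, v3 - v1)^2)) / 2
      if (j <= m - i) {
        v4 <- f(i, j)
        tot <- tot + sqrt(sum(linkmod:::.cross3(v2 - v4, v3 - v4)^2)) / 2
      }
    }
    tot
  }
  num <- subdiv_area(lifted[1, ], lifted[2, ], lifted[3, ]) +
    subdiv_area(lifted[1, ], lifted[3, ], lifted[4, ])
  expect_equal(a, num, tolerance = 1e-8)
  ## rigid invariance
  rg <- random_rigid(9)
  moved <- sweep(lifted %*% rg$Q, 2, rg$t, `+`)
  expect_equal(quad_area_3d(moved[1, ], moved[2, ], moved[3, ], moved[4, ]),
               a, tolerance = 1e-10)
  expect_error(quad_area_3d(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
               "degenerate")
})

test_that("planarity has its closed-form values and bounds", {
  expect_equal(planarity(square_joints())$planarity, 1.0)
  res <- planarity(square_joints(h = 1))
  expect_equal(res$planarity, 2 / (1 + sqrt(3)), tolerance = 1e-12)
  expect_equal(res$area_3d, (1 + sqrt(3)) / 2, tolerance = 1e-12)
  expect_equal(res$area_projected, 1, tolerance = 1e-12)
  expect_equal(res$z_offset_of_J4, 1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lte(res$area_projected, res$area_3d)
})

test_that("planarity is invariant to rigid motion and scale", {
  set.seed(31)
  for (rep in 1:20) {
    J <- matrix(rnorm(12), 4, 3)
    pl <- tryCatch(planarity(J)$planarity, error = function(e) NA)
    if (is.na(pl)) next
    rg <- random_rigid(rep)
    moved <- sweep((2.5 * J) %*% rg$Q, 2, rg$t, `+`)
    expect_equal(planarity(moved)$planarity, pl, tolerance = 1e-10)
    expect_lte(pl, 1)
    expect_gt(pl, 0)
  }
})

test_that("planarity equals 1 exactly when J4 is in plane", {
  set.seed(17)
  ## coplanar: planarity 1 and |z| tiny; both directions
  for (rep in 1:10) {
    plane2d <- matrix(rnorm(8), 4, 2)
    J <- cbind(plane2d, 0)
    rg <- random_rigid(rep + 50)
    moved <- sweep(J %*% rg$Q, 2, rg$t, `+`)
    res <- tryCatch(planarity(moved), error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(res$planarity, 1, tolerance = 1e-9)
    expect_lt(abs(res$z_offset_of_J4), 1e-9)
  }
  ## off-plane J4 forces planarity < 1
  res2 <- planarity(square_joints(h = 1e-3))
  expect_lt(res2$planarity, 1)
})

test_that("planarity decreases monotonically with the lift", {
  hgrid <- seq(0, 3, by = 0.25)
  pl <- vapply(hgrid, function(h) planarity(square_joints(h))$planarity, 0)
  expect_true(all(diff(pl) < 0))
})

test_that("linkage extraction and batch summaries work end to end", {
  batch0 <- simulate_linkage_batch(5, c(anterior_jaw = 0, opercular = 0,
                                        hyoid = 0), noise_sd = 0, seed = 2)
  pl0 <- vapply(batch0, function(j) planarity(j)$planarity, 0)
  expect_equal(pl0, rep(1, 15), tolerance = 1e-12)

  batch1 <- simulate_linkage_batch(5, c(hyoid = 1), noise_sd = 0, seed = 2)
  expect_equal(vapply(batch1, function(j) planarity(j)$planarity, 0),
               rep(2 / (1 + sqrt(3)), 5), tolerance = 1e-12)

  ## extraction from a configuration set
  sch <- make_scheme(2L)
  cs <- random_config(n = 6, scheme = sch, seed = 12)
  jm <- list(anterior_jaw = c("palatine_p1", "maxilla_p1", "dentary_p1",
                              "angular_p1"),
             hyoid = c("hyomandibula_p1", "ceratohyal_p1", "urohyal_p1",
                       "pectoral_girdle_p1"))
  res <- extract_linkage_joints(cs, jm)
  expect_equal(nrow(res$per_specimen), 12L)
  expect_setequal(res$summary$system, c("anterior_jaw", "hyoid"))
  expect_true(all(res$per_specimen$planarity > 0 &
                    res$per_specimen$planarity <= 1))
  expect_error(extract_linkage_joints(cs, list()), "empty")
  expect_error(extract_linkage_joints(cs, list(x = c("nope", "maxilla_p1",
                                                     "dentary_p1",
                                                     "angular_p1"))),
               "missing")

  ## systematic lift in one system pushes its mean planarity lowest
  mixed <- simulate_linkage_batch(30, c(anterior_jaw = 0.1, opercular = 0.1,
                                        hyoid = 0.6), noise_sd = 0.02,
                                  seed = 3)
  df <- do.call(rbind, lapply(mixed, function(j) {
    data.frame(system = j$system, planarity = planarity(j)$planarity)
  }))
  means <- tapply(df$planarity, df$system, mean)
  expect_lt(means["hyoid"], min(means[c("anterior_jaw", "opercular")]))
})

test_that("gape QC flags open-jawed specimens and scales correctly", {
  sch <- make_scheme(2L)
  p <- n_points(sch)
  arr <- array(0, c(p, 3, 2))
  ## skull length 10 between the two neurocranium points
  arr[, , 1] <- matrix(rnorm(p * 3, sd = 0.01), p, 3)
  arr[, , 2] <- arr[, , 1]
  labels <- sch$point_labels
  iskull <- match(c("neurocranium_p1", "neurocranium_p2"), labels)
  igape <- match(c("premaxilla_p1", "dentary_p1"), labels)
  for (i in 1:2) {
    arr[iskull[1], , i] <- c(0, 0, 0)
    arr[iskull[2], , i] <- c(10, 0, 0)
  }
  ## specimen 1 closed (gape 0), specimen 2 just over 10%
  arr[igape[1], , 1] <- c(1, 1, 0); arr[igape[2], , 1] <- c(1, 1, 0)
  arr[igape[1], , 2] <- c(1, 1, 0); arr[igape[2], , 2] <- c(1, 2.01, 0)
  cs <- configuration_set(arr, c("closed", "open"), sch)
  qc <- gape_ratio(cs, c("premaxilla_p1", "dentary_p1"),
                   c("neurocranium_p1", "neurocranium_p2"))
  expect_equal(qc$ratio[1], 0)
  expect_false(qc$flagged[1])
  expect_true(qc$flagged[2])
  ## scale invariance of the proportion
  cs5 <- configuration_set(arr * 5, c("closed", "open"), sch)
  qc5 <- gape_ratio(cs5, c("premaxilla_p1", "dentary_p1"),
                    c("neurocranium_p1", "neurocranium_p2"))
  expect_equal(qc5$ratio, qc$ratio, tolerance = 1e-12)
  expect_error(gape_ratio(cs, c("premaxilla_p1", "nope"),
                          c("neurocranium_p1", "neurocranium_p2")),
               "missing")
})
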