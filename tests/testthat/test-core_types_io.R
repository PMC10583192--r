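test_that("default scheme has the expected structure", {
  s <- default_scheme()
  expect_equal(n_points(s), 200L)
  expect_equal(sum(!s$is_semilandmark), 83L)
  expect_equal(sum(s$is_semilandmark), 117L)
  expect_setequal(unique(s$bone_of), bone_elements())
  ## every semi-landmark in exactly one curve, endpoints fixed
  interior <- unlist(lapply(s$curves, function(cv) cv[-c(1, length(cv))]))
  expect_setequal(interior, which(s$is_semilandmark))
  expect_equal(anyDuplicated(interior), 0L)
  for (cv in s$curves) {
    expect_false(any(s$is_semilandmark[cv[c(1, length(cv))]]))
  }
})

test_that("scheme validation rejects malformed inputs", {
  expect_error(landmark_scheme(c("a", "b"), c("dentary", "quadrate"),
                               c(FALSE, FALSE)), "unknown bone")
  expect_error(landmark_scheme(c("a", "a"), c("dentary", "dentary"),
                               c(FALSE, FALSE)), "duplicate")
  ## semi-landmark outside any curve
  expect_error(landmark_scheme(c("a", "b", "c"), rep("dentary", 3),
                               c(FALSE, TRUE, FALSE)), "exactly one curve")
})

test_that("landmark round trips are coordinate-exact in every dialect", {
  cs <- random_config(n = 3, seed = 11)
  for (dialect in c("csv_wide", "csv_long", "tps", "morphologika")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(cs, f, dialect)
    back <- read_landmarks(f, dialect, scheme = cs$scheme)
    expect_equal(back$specimen_ids, cs$specimen_ids, info = dialect)
    expect_equal(unname(back$coords), unname(cs$coords),
                 tolerance = 0, info = dialect)
  }
})

test_that("dialects agree on identical data and report malformed input", {
  cs <- random_config(n = 2, scheme = make_scheme(2L), seed = 3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".tps")
  write_landmarks(cs, f1, "csv_wide")
  write_landmarks(cs, f2, "tps")
  a <- read_landmarks(f1, "csv_wide")
  b <- read_landmarks(f2, "tps")
  expect_equal(unname(a$coords), unname(b$coords))

  ## specimen with a missing point is named in the error
  lines <- readLines(f2)
  bad <- lines[-3]                         # drop one coordinate row of sp1
  bad[1] <- "LM3=32"                       # keep header honest about intent
  f3 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=31", bad[-1]), f3)
  expect_error(read_landmarks(f3, "tps"), "sp1|mismatch|non-numeric")

  f4 <- withr::local_tempfile(fileext = ".csv")
  txt <- readLines(f1)
  txt[2] <- sub(",[-0-9.]+,", ",oops,", txt[2])
  writeLines(txt, f4)
  expect_error(read_landmarks(f4, "csv_wide"), "line")
})

test_that("read_tree validates lengths and labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_tree(f)
  expect_equal(ape::Ntip(tr), 3L)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(2, 3))

  big <- simulate_tree(410, seed = 2)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(big, f2)
  expect_equal(ape::Ntip(read_tree(f2)), 410L)

  f3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", f3)
  expect_error(read_tree(f3), "branch length")
  f4 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:1):1,C:2);", f4)
  expect_error(read_tree(f4), "duplicate")
})

test_that("hypothesis registry matches the published table structure", {
  hs <- builtin_hypotheses()
  expect_length(hs, 13L)
  expect_named(hs, paste0("H", 1:13))
  for (h in hs) {
    expect_setequal(unlist(h$modules), bone_elements())
    expect_equal(anyDuplicated(unlist(h$modules)), 0L)
    expect_equal(h$n_modules, length(h$modules))
  }
  ## H1 control: one bone per module, printed count recorded separately
  expect_equal(hs$H1$n_modules, 16L)
  expect_equal(hs$H1$printed_n_modules, 14L)
  ## H4: anterior jaw + premaxilla, hyoid, opercular, remainder
  expect_equal(hs$H4$n_modules, 4L)
  expect_setequal(hs$H4$modules[[1]],
                  c("angular", "dentary", "palatine", "maxilla", "premaxilla"))
  expect_setequal(hs$H4$modules[[2]],
                  c("ceratohyal", "hypohyal", "urohyal", "pectoral girdle"))
  expect_setequal(hs$H4$modules[[3]],
                  c("opercular series", "suspensorium", "hyomandibula"))
  expect_setequal(hs$H4$modules[[4]],
                  c("nasals", "neurocranium", "upper pharyngeal jaw",
                    "lower pharyngeal jaw"))
  ## H2 and H3 differ only in premaxilla placement
  expect_equal(hs$H2$n_modules, 2L)
  expect_setequal(setdiff(hs$H2$modules[[1]], hs$H3$modules[[1]]),
                  "premaxilla")
  expect_setequal(setdiff(hs$H3$modules[[2]], hs$H2$modules[[2]]),
                  "premaxilla")
})

test_that("partition_points maps bones to point indices", {
  hs <- builtin_hypotheses()
  toy <- toy_scheme()
  pp <- partition_points(toy, hs$H2)
  expect_setequal(lengths(pp), c(12L, 4L))
  expect_setequal(unlist(pp), seq_len(16))
  pp1 <- partition_points(toy, hs$H1)
  expect_equal(lengths(pp1), setNames(rep(1L, 16),
                                      names(pp1)), ignore_attr = TRUE)
  bad <- structure(list(name = "X", modules = list("quadrate"),
                        n_modules = 1L), class = "modularity_hypothesis")
  expect_error(partition_points(toy, bad), "absent")
})

test_that("hypothesis files round-trip through YAML and JSON", {
  h2 <- builtin_hypotheses()$H2
  flat <- list()
  for (k in seq_along(h2$modules)) {
    for (b in h2$modules[[k]]) flat[[b]] <- paste0("m", k)
  }
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(flat, fy)
  hy <- read_hypothesis(fy, name = "H2")
  expect_equal(hy$n_modules, 2L)
  expect_setequal(vapply(hy$modules, function(m) paste(sort(m), collapse = "|"),
                         ""),
                  vapply(h2$modules, function(m) paste(sort(m), collapse = "|"),
                         ""))
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(flat, fj, auto_unbox = TRUE)
  expect_equal(read_hypothesis(fj)$n_modules, 2L)
  ## unknown bones are errors, never dropped
  flat$quadrate <- "m1"
  yaml::write_yaml(flat, fy)
  expect_error(read_hypothesis(fy), "unknown bone")
})

test_that("pruning preserves patristic distances among kept tips", {
  for (sd in 1:5) {
    tr <- simulate_tree(12, seed = sd)
    cs <- random_config(n = 12, scheme = toy_scheme(), seed = sd)
    cs$specimen_ids <- tr$tip.label
    dimnames(cs$coords)[[3]] <- tr$tip.label
    keep <- sort(sample(tr$tip.label, 5))
    sub <- subset_by_clade(cs, tr, keep)
    expect_setequal(sub$tree$tip.label, keep)
    expect_equal(sub$config$specimen_ids, sub$tree$tip.label)
    full_d <- ape::cophenetic.phylo(tr)[keep, keep]
    sub_d <- ape::cophenetic.phylo(sub$tree)[keep, keep]
    expect_equal(sub_d, full_d, tolerance = 1e-10)
  }
  tr <- simulate_tree(5, seed = 1)
  cs <- random_config(n = 5, scheme = toy_scheme(), seed = 1)
  cs$specimen_ids <- tr$tip.label
  dimnames(cs$coords)[[3]] <- tr$tip.label
  all_kept <- subset_by_clade(cs, tr, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(all_kept$tree),
               ape::cophenetic.phylo(tr)[all_kept$tree$tip.label,
                                         all_kept$tree$tip.label])
  expect_error(subset_by_clade(cs, tr, tr$tip.label[1]), "at least 2")
  expect_error(subset_by_clade(cs, tr, c(tr$tip.label[1], "nope")), "nope")
})
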