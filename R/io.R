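#' Read 3D landmark configurations
#'
#' Supported dialects:
#' \describe{
#'   \item{csv_wide}{one row per specimen; first column `specimen`, then
#'     `x1,y1,z1,x2,y2,z2,...`}
#'   \item{csv_long}{columns `specimen,point,x,y,z`; specimen order is order
#'     of first appearance}
#'   \item{tps}{`LM3=p` blocks of `x y z` rows followed by `ID=name`}
#'   \item{morphologika}{`[individuals]`, `[landmarks]`, `[dimensions]`,
#'     `[names]`, `[rawpoints]` sections}
#' }
#' Point indexing in all dialects is 1-based; internally indices are the
#' usual R 1-based vectors so no shift is applied beyond label bookkeeping.
#'
#' @param path File path.
#' @param dialect One of `"csv_wide"`, `"csv_long"`, `"tps"`,
#'   `"morphologika"`.
#' @param scheme Optional `landmark_scheme` to attach (point counts must
#'   agree).
#' @return A `configuration_set`; specimen order preserved from the file.
#' @export
read_landmarks <- function(path,
                           dialect = c("csv_wide", "csv_long", "tps",
                                       "morphologika"),
                           scheme = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_linkmod("no such file: ", path)
  parsed <- switch(dialect,
    csv_wide = .read_csv_wide(path),
    csv_long = .read_csv_long(path),
    tps = .read_tps(path),
    morphologika = .read_morphologika(path)
  )
  configuration_set(parsed$blocks, parsed$ids, scheme)
}

.as_num <- function(x, path, line) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    stop_linkmod("non-numeric coordinate in ", path, " at line ", line)
  }
  out
}

.read_csv_wide <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  p <- (ncol(df) - 1L) / 3
  if (p != round(p)) {
    stop_linkmod("csv_wide: coordinate column count not a multiple of 3")
  }
  blocks <- lapply(seq_len(nrow(df)), function(i) {
    vals <- .as_num(unlist(df[i, -1]), path, i + 1L)
    matrix(vals, ncol = 3, byrow = TRUE)
  })
  list(ids = ids, blocks = blocks)
}

.read_csv_long <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("specimen", "point", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_linkmod("csv_long: expected columns ", paste(need, collapse = ","))
  }
  ids <- unique(df$specimen)
  counts <- table(df$specimen)
  if (length(unique(counts)) != 1L) {
    bad <- names(counts)[counts != stats::median(counts)][1]
    stop_linkmod("dimensional mismatch: specimen '", bad,
                 "' has a different point count")
  }
  blocks <- lapply(ids, function(id) {
    rows <- which(df$specimen == id)
    rows <- rows[order(as.integer(df$point[rows]))]
    cbind(.as_num(df$x[rows], path, rows + 1L),
          .as_num(df$y[rows], path, rows + 1L),
          .as_num(df$z[rows], path, rows + 1L))
  })
  list(ids = ids, blocks = blocks)
}

.read_tps <- function(path) {
  lines <- readLines(path)
  lm_at <- grep("^LM3?=", lines)
  if (!length(lm_at)) stop_linkmod("tps: no LM3= records found")
  ids <- character(0); blocks <- list()
  for (k in seq_along(lm_at)) {
    start <- lm_at[k]
    p <- as.integer(sub("^LM3?=", "", lines[start]))
    coord_lines <- lines[start + seq_len(p)]
    vals <- lapply(seq_len(p), function(j) {
      .as_num(strsplit(trimws(coord_lines[j]), "[ \t]+")[[1]], path, start + j)
    })
    dims <- unique(lengths(vals))
    if (!identical(dims, 3L)) stop_linkmod("tps: expected 3 coordinates per row")
    end <- if (k < length(lm_at)) lm_at[k + 1] - 1L else length(lines)
    id_line <- grep("^ID=", lines[(start + p):end], value = TRUE)
    ids <- c(ids, if (length(id_line)) sub("^ID=", "", id_line[1]) else
      paste0("specimen_", k))
    blocks[[k]] <- do.call(rbind, vals)
  }
  pcounts <- vapply(blocks, nrow, 1L)
  if (length(unique(pcounts)) != 1L) {
    bad <- ids[which(pcounts != stats::median(pcounts))[1]]
    stop_linkmod("dimensional mismatch: specimen '", bad,
                 "' has a different point count")
  }
  list(ids = ids, blocks = blocks)
}

.read_morphologika <- function(path) {
  lines <- trimws(readLines(path))
  sec <- function(tag) {
    i <- grep(paste0("^\\[", tag, "\\]$"), lines, ignore.case = TRUE)
    if (!length(i)) stop_linkmod("morphologika: missing [", tag, "] section")
    i[1]
  }
  n <- as.integer(lines[sec("individuals") + 1L])
  p <- as.integer(lines[sec("landmarks") + 1L])
  d <- as.integer(lines[sec("dimensions") + 1L])
  if (d != 3L) stop_linkmod("morphologika: only 3D data supported")
  ids <- lines[sec("names") + seq_len(n)]
  at <- sec("rawpoints")
  body <- lines[(at + 1L):length(lines)]
  body <- body[nzchar(body)]
  blocks <- list()
  pos <- 1L
  for (k in seq_len(n)) {
    if (!startsWith(body[pos], "'")) {
      stop_linkmod("morphologika: expected specimen header at rawpoints entry ", k)
    }
    rows <- body[pos + seq_len(p)]
    vals <- lapply(seq_len(p), function(j) {
      .as_num(strsplit(rows[j], "[ \t]+")[[1]], path, at + pos + j)
    })
    blocks[[k]] <- do.call(rbind, vals)
    pos <- pos + p + 1L
  }
  list(ids = ids, blocks = blocks)
}

#' Write landmark configurations
#'
#' Writes a `configuration_set` in any dialect supported by
#' [read_landmarks()]; read-write-read round trips are coordinate-exact.
#'
#' @param config A `configuration_set`.
#' @param path Output file path.
#' @param dialect Output dialect.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(config, path,
                            dialect = c("csv_wide", "csv_long", "tps",
                                        "morphologika")) {
  dialect <- match.arg(dialect)
  coords <- config$coords
  p <- dim(coords)[1]; n <- dim(coords)[3]
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  switch(dialect,
    csv_wide = {
      header <- c("specimen",
                  as.vector(t(outer(seq_len(p), c("x", "y", "z"),
                                    function(i, a) paste0(a, i)))))
      rows <- vapply(seq_len(n), function(i) {
        paste(c(config$specimen_ids[i], fmt(as.vector(t(coords[, , i])))),
              collapse = ",")
      }, "")
      writeLines(c(paste(header, collapse = ","), rows), path)
    },
    csv_long = {
      rows <- unlist(lapply(seq_len(n), function(i) {
        vapply(seq_len(p), function(j) {
          paste(c(config$specimen_ids[i], j, fmt(coords[j, , i])),
                collapse = ",")
        }, "")
      }))
      writeLines(c("specimen,point,x,y,z", rows), path)
    },
    tps = {
      out <- unlist(lapply(seq_len(n), function(i) {
        c(paste0("LM3=", p),
          vapply(seq_len(p), function(j) paste(fmt(coords[j, , i]),
                                               collapse = " "), ""),
          paste0("ID=", config$specimen_ids[i]))
      }))
      writeLines(out, path)
    },
    morphologika = {
      out <- c("[individuals]", n, "[landmarks]", p, "[dimensions]", 3,
               "[names]", config$specimen_ids, "[rawpoints]")
      for (i in seq_len(n)) {
        out <- c(out, paste0("' ", config$specimen_ids[i]),
                 vapply(seq_len(p), function(j) paste(fmt(coords[j, , i]),
                                                      collapse = " "), ""))
      }
      writeLines(out, path)
    }
  )
  invisible(path)
}

#' Read a time-calibrated phylogeny
#'
#' Accepts Newick or Nexus; validates that every edge carries a strictly
#' positive branch length and tip labels are unique.
#'
#' @param path File path.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_linkmod("no such file: ", path)
  first <- toupper(trimws(readLines(path, n = 1L)))
  tree <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree)) stop_linkmod("could not parse tree in ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_linkmod("not a phylogenetic tree")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop_linkmod("tree is missing branch lengths")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0)) {
    stop_linkmod("tree has non-positive or missing branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop_linkmod("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", "))
  }
  tree
}

#' Subset data and tree to a common set of tips
#'
#' Prunes the tree to `tip_names` (suppressing degree-2 nodes, summing branch
#' lengths, so patristic distances among kept tips are unchanged) and subsets
#' the configurations to the same species in the pruned tree's tip order.
#'
#' @param config A `configuration_set`.
#' @param tree An `ape::phylo`.
#' @param tip_names Species to keep (at least 2).
#' @return List with elements `config` and `tree`.
#' @export
subset_by_clade <- function(config, tree, tip_names) {
  if (length(tip_names) < 2L) {
    stop_linkmod("at least 2 tips are required for comparative analysis")
  }
  miss_tree <- setdiff(tip_names, tree$tip.label)
  miss_data <- setdiff(tip_names, config$specimen_ids)
  if (length(miss_tree) || length(miss_data)) {
    stop_linkmod("names missing from ",
                 if (length(miss_tree)) paste0("tree: ",
                   paste(miss_tree, collapse = ", ")) else "",
                 if (length(miss_tree) && length(miss_data)) "; " else "",
                 if (length(miss_data)) paste0("data: ",
                   paste(miss_data, collapse = ", ")) else "")
  }
  pruned <- ape::keep.tip(tree, tip_names)
  idx <- match(pruned$tip.label, config$specimen_ids)
  sub <- configuration_set(config$coords[, , idx, drop = FALSE],
                           config$specimen_ids[idx], config$scheme)
  list(config = sub, tree = pruned)
}
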