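#' Controlled vocabulary of skull bone elements
#'
#' The sixteen bone elements used by the modularity hypothesis registry.
#' Landmark schemes must assign every point to one of these names (the
#' articular is canonicalised to "angular").
#'
#' @return Character vector of 16 bone-element names.
#' @export
bone_elements <- function() {
  c("premaxilla", "maxilla", "dentary", "angular", "palatine",
    "neurocranium", "nasals", "upper pharyngeal jaw", "lower pharyngeal jaw",
    "ceratohyal", "hypohyal", "urohyal", "hyomandibula",
    "opercular series", "suspensorium", "pectoral girdle")
}

canonical_bone <- function(x) {
  x <- tolower(trimws(x))
  x[x == "articular"] <- "angular"
  x
}

#' Construct a landmark scheme
#'
#' A landmark scheme names every point of a configuration, assigns each to a
#' bone element, marks semi-landmarks, and groups semi-landmarks into sliding
#' curves. Curves are ordered index sequences whose interior points are
#' semi-landmarks and whose endpoints are fixed landmarks.
#'
#' @param point_labels Character vector of unique point names.
#' @param bone_of Character vector (same length) assigning each point to a
#'   bone element from [bone_elements()].
#' @param is_semilandmark Logical vector marking sliding points.
#' @param curves List of integer vectors (1-based point indices) defining the
#'   sliding curves.
#' @return An object of class `landmark_scheme`.
#' @export
landmark_scheme <- function(point_labels, bone_of, is_semilandmark,
                            curves = list()) {
  p <- length(point_labels)
  if (anyDuplicated(point_labels)) stop_linkmod("duplicate point labels")
  if (length(bone_of) != p || length(is_semilandmark) != p) {
    stop_linkmod("bone_of and is_semilandmark must match point_labels in length")
  }
  bone_of <- canonical_bone(bone_of)
  unknown <- setdiff(unique(bone_of), bone_elements())
  if (length(unknown)) {
    stop_linkmod("unknown bone element(s): ", paste(unknown, collapse = ", "))
  }
  seen <- integer(p)
  for (cv in curves) {
    if (length(cv) < 3) stop_linkmod("curves need at least 3 points")
    if (any(cv < 1 | cv > p)) stop_linkmod("curve index out of range")
    interior <- cv[-c(1, length(cv))]
    if (any(!is_semilandmark[interior])) {
      stop_linkmod("curve interior points must be semi-landmarks")
    }
    if (any(is_semilandmark[cv[c(1, length(cv))]])) {
      stop_linkmod("curve endpoints must be fixed landmarks")
    }
    seen[interior] <- seen[interior] + 1L
  }
  if (any(seen[is_semilandmark] != 1L)) {
    stop_linkmod("every semi-landmark must lie in exactly one curve")
  }
  if (any(seen[!is_semilandmark] > 0L)) {
    ## endpoints may appear in several curves; only interiors were counted
  }
  structure(
    list(point_labels = point_labels, bone_of = bone_of,
         is_semilandmark = as.logical(is_semilandmark), curves = curves),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("landmark_scheme:", length(x$point_labels), "points (",
      sum(!x$is_semilandmark), "fixed,", sum(x$is_semilandmark),
      "semi-landmarks in", length(x$curves), "curves ) over",
      length(unique(x$bone_of)), "bone elements\n")
  invisible(x)
}

#' Number of points in a scheme
#' @param scheme A `landmark_scheme`.
#' @return Integer point count.
#' @export
n_points <- function(scheme) length(scheme$point_labels)

## Per-bone point allocation of the packaged default scheme: 83 fixed and
## 117 semi-landmark points over the 16 bone elements.  Point-level
## anatomical definitions must come from a real digitisation protocol; the
## packaged scheme fixes only the counts, bone assignments and curve
## topology so analyses and simulations are well-defined.
default_scheme_table <- function() {
  data.frame(
    bone = c("premaxilla", "maxilla", "dentary", "angular", "palatine",
             "neurocranium", "nasals", "upper pharyngeal jaw",
             "lower pharyngeal jaw", "ceratohyal", "hypohyal", "urohyal",
             "hyomandibula", "opercular series", "suspensorium",
             "pectoral girdle"),
    n_fixed = c(6, 6, 6, 4, 4, 10, 4, 5, 5, 5, 4, 4, 5, 6, 5, 4),
    n_semi  = c(10, 10, 8, 5, 5, 16, 4, 7, 7, 8, 4, 5, 6, 10, 8, 4),
    stringsAsFactors = FALSE
  )
}

#' The packaged 200-point skull landmark scheme
#'
#' A default scheme with 83 fixed landmarks and 117 semi-landmarks spread over
#' the 16 bone elements, one sliding curve per bone (two for the
#' neurocranium), curve endpoints anchored on that bone's first two fixed
#' landmarks. Intended for simulation and as a template; studies with real
#' data should encode their own digitisation protocol.
#'
#' @return A `landmark_scheme` with 200 points.
#' @export
default_scheme <- function() {
  tab <- default_scheme_table()
  labels <- character(0); bones <- character(0); semi <- logical(0)
  curves <- list()
  offset <- 0L
  for (i in seq_len(nrow(tab))) {
    b <- tab$bone[i]; nf <- tab$n_fixed[i]; ns <- tab$n_semi[i]
    slug <- gsub(" ", "_", b)
    labels <- c(labels, paste0(slug, "_f", seq_len(nf)),
                if (ns > 0) paste0(slug, "_s", seq_len(ns)))
    bones <- c(bones, rep(b, nf + ns))
    semi <- c(semi, rep(FALSE, nf), rep(TRUE, ns))
    if (ns > 0) {
      semi_idx <- offset + nf + seq_len(ns)
      ends <- offset + c(1L, 2L)
      if (b == "neurocranium") {
        half <- ns %/% 2
        curves <- c(curves,
                    list(c(offset + 1L, semi_idx[seq_len(half)], offset + 2L)),
                    list(c(offset + 3L, semi_idx[(half + 1):ns], offset + 4L)))
      } else {
        curves <- c(curves, list(c(ends[1], semi_idx, ends[2])))
      }
    }
    offset <- offset + nf + ns
  }
  landmark_scheme(labels, bones, semi, curves)
}

#' Build a simple synthetic landmark scheme
#'
#' Allocates `points_per_bone` fixed landmarks to each named bone element, in
#' order, with no sliding curves. Used by the simulators and in tests where
#' curve structure is irrelevant.
#'
#' @param points_per_bone Named integer vector (names from [bone_elements()]),
#'   or a single unnamed count applied to all 16 elements.
#' @return A `landmark_scheme`.
#' @export
make_scheme <- function(points_per_bone = 3L) {
  if (is.null(names(points_per_bone))) {
    stopifnot(length(points_per_bone) == 1L)
    points_per_bone <- stats::setNames(
      rep(as.integer(points_per_bone), 16L), bone_elements())
  }
  bones <- canonical_bone(names(points_per_bone))
  labels <- character(0); assign <- character(0)
  for (i in seq_along(bones)) {
    k <- points_per_bone[i]
    labels <- c(labels, paste0(gsub(" ", "_", bones[i]), "_p", seq_len(k)))
    assign <- c(assign, rep(bones[i], k))
  }
  landmark_scheme(labels, assign, rep(FALSE, length(labels)))
}

#' Bundle specimens' coordinates with a scheme
#'
#' @param coords A p x 3 x n array (landmarks x dimensions x specimens) or a
#'   list of p x 3 matrices.
#' @param specimen_ids Character vector of species/specimen names.
#' @param scheme A `landmark_scheme` (its point count must equal p), or
#'   `NULL` for raw coordinate data not yet tied to a scheme.
#' @return An object of class `configuration_set`.
#' @export
configuration_set <- function(coords, specimen_ids, scheme = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    pcounts <- vapply(coords, nrow, 1L)
    if (length(unique(pcounts)) != 1L) {
      bad <- specimen_ids[which(pcounts != stats::median(pcounts))[1]]
      stop_linkmod("dimensional mismatch: specimen '", bad,
                   "' has a different point count")
    }
    coords <- array(unlist(coords), dim = c(pcounts[1], 3, length(coords)))
  }
  assert_coord_array(coords)
  if (length(specimen_ids) != dim(coords)[3]) {
    stop_linkmod("specimen_ids length must equal the number of specimens")
  }
  if (anyDuplicated(specimen_ids)) stop_linkmod("duplicate specimen ids")
  if (!is.null(scheme)) {
    if (dim(coords)[1] != n_points(scheme)) {
      stop_linkmod("coordinate blocks have ", dim(coords)[1],
                   " points but the scheme defines ", n_points(scheme))
    }
    dimnames(coords)[[1]] <- scheme$point_labels
  } else if (is.null(dimnames(coords)[[1]])) {
    dimnames(coords)[[1]] <- paste0("p", seq_len(dim(coords)[1]))
  }
  dimnames(coords)[[2]] <- c("x", "y", "z")
  dimnames(coords)[[3]] <- specimen_ids
  structure(list(coords = coords, specimen_ids = specimen_ids, scheme = scheme),
            class = "configuration_set")
}

#' @export
print.configuration_set <- function(x, ...) {
  cat("configuration_set:", dim(x$coords)[3], "specimens x",
      dim(x$coords)[1], "3D points\n")
  invisible(x)
}
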