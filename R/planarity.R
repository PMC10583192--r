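#' Four rotational joints of a 4-bar linkage
#'
#' J1 and J2 are the two joints of the fixed link, J3 the designated mobile
#' joint that together with the fixed link defines the reference plane, and
#' J4 the free joint whose out-of-plane displacement the planarity metric
#' measures. Which mobile joint plays the role of J3 changes the metric, so
#' it is an explicit labelling, not a convention buried in code.
#'
#' @param joints 4 x 3 numeric matrix of 3D joint positions, rows J1..J4.
#' @param system Linkage system name (`"anterior_jaw"`, `"opercular"`,
#'   `"hyoid"`, or any label).
#' @param specimen Optional source specimen id.
#' @return Object of class `linkage_joints`.
#' @export
linkage_joints <- function(joints, system = "linkage", specimen = NULL) {
  joints <- as.matrix(joints)
  if (!all(dim(joints) == c(4, 3)) || !all(is.finite(joints))) {
    stop_linkmod("joints must be a finite 4 x 3 matrix")
  }
  if (anyDuplicated(round(joints, 12))) {
    stop_linkmod("joints must be four distinct points")
  }
  if (sqrt(sum((joints[1, ] - joints[2, ])^2)) < 1e-12) {
    stop_linkmod("fixed link has zero length (J1 == J2)")
  }
  rownames(joints) <- c("J1", "J2", "J3", "J4")
  colnames(joints) <- c("x", "y", "z")
  structure(list(joints = joints, system = system, specimen = specimen),
            class = "linkage_joints")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Align linkage joints to the fixed-link plane
#'
#' Applies the rigid motion placing J1 at the origin, J2 on the positive X
#' axis, and J3 in the Z = 0 plane with positive Y; J4 carries its full 3D
#' position through the same motion, so its Z coordinate afterwards is its
#' out-of-plane offset. All pairwise distances are preserved.
#'
#' @param joints A `linkage_joints` (or 4 x 3 matrix).
#' @return A `linkage_joints` with transformed coordinates.
#' @export
align_to_plane <- function(joints) {
  lj <- if (inherits(joints, "linkage_joints")) joints else
    linkage_joints(joints)
  P <- sweep(lj$joints, 2, lj$joints[1, ])
  e1 <- P[2, ] / sqrt(sum(P[2, ]^2))
  v3 <- P[3, ]
  nrm <- .cross3(e1, v3)
  if (sqrt(sum(nrm^2)) < 1e-12 * sqrt(sum(v3^2))) {
    stop_linkmod("degenerate plane: J1, J2, J3 are collinear")
  }
  e3 <- nrm / sqrt(sum(nrm^2))
  e2 <- .cross3(e3, e1)
  out <- P %*% cbind(e1, e2, e3)
  dimnames(out) <- dimnames(lj$joints)
  linkage_joints(out, lj$system, lj$specimen)
}

.tri_area <- function(a, b, c) {
  sqrt(sum(.cross3(b - a, c - a)^2)) / 2
}

#' 3D area of a quadrilateral
#'
#' Sum of the two triangle areas obtained by splitting along the J1-J3
#' diagonal (fixed-link joint to designated mobile joint); each triangle
#' area is half the cross-product norm. The diagonal choice is a fixed
#' convention: for non-planar quadrilaterals the two diagonals give
#' different areas.
#'
#' @param p1,p2,p3,p4 3D points (vertices in J1, J2, J3, J4 order).
#' @return Positive area; degenerate (zero-area) triangles are an error.
#' @export
quad_area_3d <- function(p1, p2, p3, p4) {
  a1 <- .tri_area(p1, p2, p3)
  a2 <- .tri_area(p1, p3, p4)
  if (a1 < 1e-14 || a2 < 1e-14) {
    stop_linkmod("degenerate quadrilateral: a triangle has zero area")
  }
  a1 + a2
}

#' Planarity of a 4-bar linkage
#'
#' Aligns the joints to the fixed-link plane, computes the 3D quadrilateral
#' area, projects J4 onto the plane (Z set to 0), recomputes the projected
#' area, and returns their ratio. The ratio lies in (0, 1]; it equals 1
#' exactly when the four joints are coplanar, and is invariant to rigid
#' motion and uniform scaling of the input.
#'
#' @param joints A `linkage_joints` (or 4 x 3 matrix).
#' @return Object of class `planarity_result`: `planarity`, `area_3d`,
#'   `area_projected`, `z_offset_of_J4` (signed), `system`, `specimen`.
#' @export
planarity <- function(joints) {
  al <- align_to_plane(joints)
  P <- al$joints
  area3 <- quad_area_3d(P[1, ], P[2, ], P[3, ], P[4, ])
  Pflat <- P
  Pflat[4, 3] <- 0
  areap <- quad_area_3d(Pflat[1, ], Pflat[2, ], Pflat[3, ], Pflat[4, ])
  structure(
    list(planarity = areap / area3, area_3d = area3, area_projected = areap,
         z_offset_of_J4 = P[4, 3], system = al$system,
         specimen = al$specimen),
    class = "planarity_result"
  )
}

#' @export
print.planarity_result <- function(x, ...) {
  cat(sprintf("planarity %.4f (3D area %.4g, projected %.4g, J4 z %.4g)\n",
              x$planarity, x$area_3d, x$area_projected, x$z_offset_of_J4))
  invisible(x)
}

#' Extract linkage joints from landmark configurations and measure planarity
#'
#' @param config A `configuration_set` (or `aligned_shapes`).
#' @param joint_map Named list mapping each linkage system to the four point
#'   labels of its joints, in J1, J2, J3, J4 order. The labels must exist in
#'   the configuration's point labels.
#' @return List with `joints` (list of `linkage_joints`, one per specimen x
#'   system), `per_specimen` (data frame: specimen, system, planarity,
#'   area_3d, area_projected, z_offset), `summary` (per-system mean, min,
#'   max planarity).
#' @export
extract_linkage_joints <- function(config, joint_map) {
  if (!length(joint_map)) stop_linkmod("joint_map is empty")
  coords <- config$coords
  labels <- dimnames(coords)[[1]]
  ids <- dimnames(coords)[[3]]
  rows <- list(); joints <- list()
  for (sys in names(joint_map)) {
    lab <- joint_map[[sys]]
    if (length(lab) != 4L) {
      stop_linkmod("system '", sys, "' must name exactly 4 joints")
    }
    miss <- setdiff(lab, labels)
    if (length(miss)) {
      stop_linkmod("joint labels missing from configuration: ",
                   paste(miss, collapse = ", "))
    }
    idx <- match(lab, labels)
    for (i in seq_along(ids)) {
      lj <- linkage_joints(coords[idx, , i], system = sys,
                           specimen = ids[i])
      pr <- planarity(lj)
      joints[[length(joints) + 1L]] <- lj
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = ids[i], system = sys, planarity = pr$planarity,
        area_3d = pr$area_3d, area_projected = pr$area_projected,
        z_offset = pr$z_offset_of_J4)
    }
  }
  per_specimen <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_specimen, per_specimen$system),
    function(d) data.frame(system = d$system[1],
                           mean = mean(d$planarity),
                           min = min(d$planarity),
                           max = max(d$planarity))))
  rownames(summary) <- NULL
  list(joints = joints, per_specimen = per_specimen, summary = summary)
}

#' Jaw gape quality-control ratio
#'
#' Computes jaw gape as a proportion of skull length for every specimen and
#' flags specimens whose jaws were likely open when preserved (ratio above
#' the threshold). Which landmarks define the gape and the skull length is
#' study configuration, not code.
#'
#' @param config A `configuration_set`.
#' @param gape_labels Two point labels whose distance is the gape (e.g.
#'   premaxilla tip and dentary tip).
#' @param skull_length_labels Two point labels whose distance is skull
#'   length (e.g. anteriormost and posteriormost neurocranium points).
#' @param threshold Flagging threshold on the proportion (default 0.10).
#' @return Data frame: specimen, gape, skull_length, ratio, flagged.
#' @export
gape_ratio <- function(config, gape_labels, skull_length_labels,
                       threshold = 0.10) {
  coords <- config$coords
  labels <- dimnames(coords)[[1]]
  miss <- setdiff(c(gape_labels, skull_length_labels), labels)
  if (length(miss)) {
    stop_linkmod("labels missing from configuration: ",
                 paste(miss, collapse = ", "))
  }
  gi <- match(gape_labels, labels)
  si <- match(skull_length_labels, labels)
  n <- dim(coords)[3]
  gape <- vapply(seq_len(n), function(i) {
    sqrt(sum((coords[gi[1], , i] - coords[gi[2], , i])^2))
  }, 0)
  skull <- vapply(seq_len(n), function(i) {
    sqrt(sum((coords[si[1], , i] - coords[si[2], , i])^2))
  }, 0)
  if (any(skull < 1e-12)) stop_linkmod("zero skull length")
  data.frame(specimen = dimnames(coords)[[3]], gape = gape,
             skull_length = skull, ratio = gape / skull,
             flagged = gape / skull > threshold)
}
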