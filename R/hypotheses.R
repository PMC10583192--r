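#' Construct a modularity hypothesis
#'
#' A hypothesis is a named partition of the 16 bone elements into disjoint
#' modules covering the full vocabulary.
#'
#' @param name Hypothesis name (e.g. "H4").
#' @param modules List of character vectors of bone-element names.
#' @param printed_n_modules Optional integer recording an externally printed
#'   module count when it disagrees with the encoded structure.
#' @return An object of class `modularity_hypothesis`.
#' @export
modularity_hypothesis <- function(name, modules, printed_n_modules = NULL) {
  modules <- lapply(modules, canonical_bone)
  all_bones <- unlist(modules)
  if (anyDuplicated(all_bones)) {
    stop_linkmod("hypothesis '", name, "': modules are not disjoint")
  }
  unknown <- setdiff(all_bones, bone_elements())
  if (length(unknown)) {
    stop_linkmod("hypothesis '", name, "': unknown bone element(s): ",
                 paste(unknown, collapse = ", "))
  }
  missing <- setdiff(bone_elements(), all_bones)
  if (length(missing)) {
    stop_linkmod("hypothesis '", name, "': bone element(s) not covered: ",
                 paste(missing, collapse = ", "))
  }
  structure(
    list(name = name, modules = modules, n_modules = length(modules),
         printed_n_modules = printed_n_modules),
    class = "modularity_hypothesis"
  )
}

#' @export
print.modularity_hypothesis <- function(x, ...) {
  cat(x$name, ": ", x$n_modules, " modules\n", sep = "")
  for (m in x$modules) cat("  (", paste(m, collapse = " * "), ")\n", sep = "")
  invisible(x)
}

## Bone groups shared by several hypotheses.
.anterior_jaw <- c("angular", "dentary", "palatine", "maxilla")
.hyoid <- c("ceratohyal", "hypohyal", "urohyal", "pectoral girdle")
.opercular <- c("opercular series", "suspensorium", "hyomandibula")
.remainder <- c("nasals", "neurocranium",
                "upper pharyngeal jaw", "lower pharyngeal jaw")
.neuro_nasal <- c("nasals", "neurocranium")
.pharyngeal <- c("upper pharyngeal jaw", "lower pharyngeal jaw")

#' The thirteen linkage-based modularity hypotheses
#'
#' The registry of hypotheses H1-H13 partitioning the 16 bone elements by
#' their membership in the anterior-jaw, opercular, and hyoid 4-bar linkage
#' systems. H1 is the each-bone-separate control; even-numbered structure
#' pairs differ in whether the premaxilla travels with the anterior jaw
#' linkage or with the remainder of the skull. Where a published table prints
#' a module count that differs from the listed structure (H1, H6, H7) the
#' structure is encoded and the printed count kept in `printed_n_modules`.
#'
#' @return Named list of 13 [modularity_hypothesis()] objects, "H1".."H13".
#' @export
builtin_hypotheses <- function() {
  link12 <- c(.anterior_jaw, .hyoid, .opercular, "premaxilla")
  link11 <- c(.anterior_jaw, .hyoid, .opercular)
  singles <- function(bones) as.list(bones)
  hs <- list(
    modularity_hypothesis("H1", singles(bone_elements()),
                          printed_n_modules = 14L),
    modularity_hypothesis("H2", list(link12, .remainder)),
    modularity_hypothesis("H3", list(link11, c("premaxilla", .remainder))),
    modularity_hypothesis("H4", list(c(.anterior_jaw, "premaxilla"), .hyoid,
                                     .opercular, .remainder)),
    modularity_hypothesis("H5", list(.anterior_jaw, .hyoid, .opercular,
                                     c("premaxilla", .remainder))),
    modularity_hypothesis("H6", c(list(link12), singles(.remainder)),
                          printed_n_modules = 4L),
    modularity_hypothesis("H7", c(list(link11), list("premaxilla"),
                                  singles(.remainder)),
                          printed_n_modules = 5L),
    modularity_hypothesis("H8", c(list(c(.anterior_jaw, "premaxilla")),
                                  list(.hyoid), list(.opercular),
                                  singles(.remainder))),
    modularity_hypothesis("H9", c(list(.anterior_jaw), list(.hyoid),
                                  list(.opercular), list("premaxilla"),
                                  singles(.remainder))),
    modularity_hypothesis("H10", list(link12, .neuro_nasal, .pharyngeal)),
    modularity_hypothesis("H11", list(link11, "premaxilla",
                                      .neuro_nasal, .pharyngeal)),
    modularity_hypothesis("H12", list(c(.anterior_jaw, "premaxilla"), .hyoid,
                                      .opercular, .neuro_nasal, .pharyngeal)),
    modularity_hypothesis("H13", list(.anterior_jaw, .hyoid, .opercular,
                                      "premaxilla", .neuro_nasal, .pharyngeal))
  )
  stats::setNames(hs, vapply(hs, `[[`, "", "name"))
}

#' Map a hypothesis onto point indices of a scheme
#'
#' @param scheme A `landmark_scheme`.
#' @param hypothesis A `modularity_hypothesis`.
#' @return Named list of disjoint 1-based point-index vectors, one per
#'   module, jointly covering all points of the scheme.
#' @export
partition_points <- function(scheme, hypothesis) {
  missing <- setdiff(unlist(hypothesis$modules), unique(scheme$bone_of))
  if (length(missing)) {
    stop_linkmod("bones in hypothesis absent from scheme: ",
                 paste(missing, collapse = ", "))
  }
  parts <- lapply(hypothesis$modules, function(m) {
    which(scheme$bone_of %in% m)
  })
  if (any(lengths(parts) == 0L)) {
    stop_linkmod("hypothesis '", hypothesis$name,
                 "' produces an empty module on this scheme")
  }
  names(parts) <- vapply(hypothesis$modules, function(m) {
    paste(m, collapse = "+")
  }, "")
  parts
}

#' Read a modularity hypothesis from YAML or JSON
#'
#' The file holds a flat mapping from bone-element name to module identifier;
#' bones sharing an identifier form one module. Unknown bones are an error.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @param name Hypothesis name; defaults to the file name.
#' @return A `modularity_hypothesis`.
#' @export
read_hypothesis <- function(path, name = NULL) {
  if (!file.exists(path)) stop_linkmod("no such file: ", path)
  mapping <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mapping <- unlist(mapping)
  modules <- split(canonical_bone(names(mapping)), as.character(mapping))
  modularity_hypothesis(
    name %||% sub("\\.[^.]+$", "", basename(path)),
    unname(modules)
  )
}
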