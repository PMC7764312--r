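#' 3D intensity volume
#'
#' A `volume3d` is a 3D scalar grid with voxel spacing (mm) and a 4x4
#' grid-to-world affine. Voxel indices are 0-based in world-coordinate
#' computations: the world position of voxel `(i,j,k)` is
#' `affine %*% c(i,j,k,1)`.
#'
#' @param data 3D numeric array (a 4D array with a trailing singleton axis
#'   is squeezed).
#' @param spacing Numeric length-3, voxel spacing in mm, all > 0.
#' @param affine 4x4 grid-to-world transform; the upper-left 3x3 block must
#'   be non-singular. Default: diagonal of `spacing` (axis-aligned).
#' @return An object of class `volume3d` with elements `data`, `spacing`,
#'   `affine`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array with 3 axes")
  if (length(d) == 4 && d[4] == 1) {
    data <- array(data, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3) stop("data must have exactly 3 axes")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive lengths (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine upper-left 3x3 block is singular")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Integer label volume
#'
#' A `label_volume` is a 3D non-negative integer grid aligned to a
#' [volume3d()] grid and governed by a [label_schema()]; label id 0 is
#' background. Every label value present in the grid must appear in the
#' schema.
#'
#' @param data 3D array of non-negative integers.
#' @param schema A [label_schema()].
#' @param spacing,affine As in [volume3d()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, schema, spacing = c(1, 1, 1), affine = NULL) {
  v <- volume3d(data, spacing, affine)
  data <- v$data
  if (any(data < 0) || any(data != round(data)))
    stop("label data must be non-negative integers")
  storage.mode(data) <- "integer"
  stopifnot(inherits(schema, "label_schema"))
  present <- sort(unique(as.vector(data)))
  if (!all(present %in% schema$entries$id))
    stop("label values not present in schema: ",
         paste(setdiff(present, schema$entries$id), collapse = ", "))
  structure(list(data = data, schema = schema, spacing = v$spacing,
                 affine = v$affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d, %d schema labels, %d present\n",
              d[1], d[2], d[3], nrow(x$schema$entries),
              length(unique(as.vector(x$data)))))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

#' Label schema
#'
#' An ordered table of `(id, name, laterality)` entries. Ids must be unique
#' and contiguous from 0, and id 0 must be named `"background"`.
#'
#' @param ids Integer vector of label ids, contiguous from 0.
#' @param names Character vector of structure names.
#' @param laterality Character vector, each `"left"`, `"right"` or `"none"`.
#' @return An object of class `label_schema` with a data.frame element
#'   `entries`.
#' @export
label_schema <- function(ids, names, laterality = NULL) {
  ids <- as.integer(ids)
  if (is.null(laterality)) laterality <- rep("none", length(ids))
  if (length(names) != length(ids) || length(laterality) != length(ids))
    stop("ids, names and laterality must have equal length")
  if (anyDuplicated(ids)) stop("label ids must be unique")
  if (!identical(sort(ids), seq_len(length(ids)) - 1L))
    stop("label ids must be contiguous from 0")
  if (names[ids == 0L] != "background") stop("id 0 must be named 'background'")
  if (!all(laterality %in% c("left", "right", "none")))
    stop("laterality must be 'left', 'right' or 'none'")
  o <- order(ids)
  structure(list(entries = data.frame(id = ids[o], name = names[o],
                                      laterality = laterality[o],
                                      stringsAsFactors = FALSE)),
            class = "label_schema")
}

#' @export
print.label_schema <- function(x, ...) {
  cat(sprintf("<label_schema> %d entries\n", nrow(x$entries)))
  print(utils::head(x$entries, 12))
  if (nrow(x$entries) > 12) cat("  ...\n")
  invisible(x)
}

#' Number of classes in a schema (including background)
#' @param schema A [label_schema()].
#' @return Integer count of entries.
#' @export
n_classes <- function(schema) nrow(schema$entries)

#' Reference whole-brain label schema
#'
#' The default 34-class whole-brain schema: id 0 is background, ids 1-18
#' are the nine bilateral structures reported in whole-brain volumetry
#' (cerebral white matter, lateral ventricle, caudate, accumbens, putamen,
#' amygdala, hippocampus, pallidum, thalamus; left then right), and ids
#' 19-33 are named placeholders (`"structure_19"` ...) for the remaining
#' structures of the 33-label whole-brain protocol, which callers may
#' rename or replace.
#'
#' @return A [label_schema()] with 34 entries.
#' @export
default_schema <- function() {
  bilateral <- c("cerebral_wm", "lateral_ventricle", "caudate", "accumbens",
                 "putamen", "amygdala", "hippocampus", "pallidum", "thalamus")
  nm <- c("background",
          as.vector(t(outer(bilateral, c("left", "right"), paste, sep = "_"))),
          paste0("structure_", 19:33))
  lat <- c("none", rep(c("left", "right"), times = 9), rep("none", 15))
  label_schema(0:33, nm, lat)
}

#' Restrict a schema to a subset of label ids
#'
#' Evaluation against other tools commonly uses a subset of structures
#' (e.g. 22 of the 33 labels); that subset is expressed as a filter over
#' the full schema rather than a new schema.
#'
#' @param schema A [label_schema()].
#' @param ids Ids to keep (background 0 is always kept).
#' @return A data.frame of the retained entries (not a new schema: ids keep
#'   their original values and need not be contiguous).
#' @export
schema_subset <- function(schema, ids) {
  ids <- union(0L, as.integer(ids))
  if (!all(ids %in% schema$entries$id)) stop("unknown ids in subset")
  schema$entries[schema$entries$id %in% ids, , drop = FALSE]
}

#' Write / read a schema sidecar table
#'
#' The sidecar is a TSV with columns `id`, `name`, `laterality`.
#'
#' @param schema A [label_schema()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  utils::write.table(schema$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  label_schema(df$id, df$name, df$laterality)
}
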