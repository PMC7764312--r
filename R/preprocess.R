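#' Rigid (Euler) transform
#'
#' A world-space rigid transform parameterized by three rotation angles
#' (degrees, applied as Rz Ry Rx about `center`) and a translation in mm:
#' `w' = R (w - c) + c + t`.
#'
#' @param angles Length-3 rotation angles in degrees (about x, y, z axes).
#' @param translation Length-3 translation in mm.
#' @param center Length-3 rotation center in world mm (default origin).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# 4x4 homogeneous world-to-world matrix of a rigid_transform.
rigid_matrix <- function(t) {
  R <- rotation_matrix(t$angles)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$center + t$translation - R %*% t$center
  M
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()] represented via its matrix; the
#'   result is a plain 4x4 matrix wrapper of class `rigid_matrix` accepted
#'   wherever a transform is consumed.
#' @export
invert_rigid <- function(t) {
  structure(list(M = solve(as_rigid_matrix(t))), class = "rigid_matrix")
}

as_rigid_matrix <- function(t) {
  if (inherits(t, "rigid_transform")) rigid_matrix(t)
  else if (inherits(t, "rigid_matrix")) t$M
  else if (is.matrix(t) && all(dim(t) == c(4, 4))) t
  else stop("not a rigid transform")
}

#' Resample a volume under a rigid world transform
#'
#' Produces the moving volume rendered on `grid` (default: its own grid)
#' such that output voxel `v` takes the intensity of the moving volume at
#' world position `T^{-1} A_out v` (pull-back resampling of the forward
#' transform `T`).
#'
#' @param v A [volume3d()] or [label_volume()].
#' @param t A [rigid_transform()] (forward, moving to fixed).
#' @param grid Target grid: a [volume3d()] supplying dim/spacing/affine, or
#'   `NULL` to reuse `v`'s grid.
#' @param method `"trilinear"` or `"nearest"`; label volumes always use
#'   nearest-neighbor.
#' @param fill Fill value outside the moving volume.
#' @return Resampled object of the same class as `v`.
#' @export
apply_rigid <- function(v, t, grid = NULL, method = c("trilinear", "nearest"),
                        fill = 0) {
  method <- match.arg(method)
  is_lab <- inherits(v, "label_volume")
  if (is_lab) method <- "nearest"
  out_affine <- if (is.null(grid)) v$affine else grid$affine
  out_dim <- if (is.null(grid)) dim(v$data) else dim(grid$data)
  out_spacing <- if (is.null(grid)) v$spacing else grid$spacing
  Tm <- as_rigid_matrix(t)
  # output voxel -> world -> inverse transform -> moving voxel
  M <- solve(v$affine) %*% solve(Tm) %*% out_affine
  res <- cpp_resample_affine(array(as.double(v$data), dim(v$data)), M,
                             as.integer(out_dim),
                             if (method == "trilinear") 1L else 0L, fill)
  if (is_lab) {
    label_volume(array(as.integer(round(res)), out_dim), v$schema,
                 out_spacing, out_affine)
  } else {
    volume3d(res, out_spacing, out_affine)
  }
}

#' Register a volume to a template grid
#'
#' Rigid registration is a pluggable backend contract: this package renders
#' a moving volume onto the template grid under a transform supplied by the
#' backend, it does not implement a registration optimizer. Backends:
#'
#' * `"identity"` — for pre-registered or synthetic inputs; the volume is
#'   resampled onto the template grid under the identity world transform
#'   (a pure grid change; a passthrough when the grids already agree).
#' * a `rigid_transform` — an externally estimated (or oracle) transform.
#' * a function `(moving, template) -> rigid_transform` — an external
#'   engine adapter.
#'
#' The returned transform is retained so the segmentation can be mapped
#' back to native space afterwards.
#'
#' @param moving A [volume3d()].
#' @param template A [volume3d()] defining the target grid.
#' @param backend `"identity"`, a [rigid_transform()], or a function.
#' @return List with `volume` (resampled onto the template grid) and
#'   `transform` (the forward [rigid_transform()] used).
#' @export
register_to_template <- function(moving, template, backend = "identity") {
  tr <- if (identical(backend, "identity")) {
    rigid_transform()
  } else if (inherits(backend, "rigid_transform")) {
    backend
  } else if (is.function(backend)) {
    out <- tryCatch(backend(moving, template), error = function(e) {
      stop("registration backend failed: ", conditionMessage(e))
    })
    if (!inherits(out, "rigid_transform"))
      stop("registration backend must return a rigid_transform")
    out
  } else {
    stop("unknown registration backend")
  }
  resampled <- apply_rigid(moving, tr, grid = template, method = "trilinear")
  list(volume = resampled, transform = tr)
}

#' Zero-pad a volume symmetrically
#'
#' Adds `pad` zero voxels on every face of each axis and shifts the affine
#' so that world coordinates of the original voxels are unchanged.
#'
#' @param v A [volume3d()] or [label_volume()].
#' @param pad Length-3 (or scalar) non-negative integer padding per face.
#' @return Padded object of the same class.
#' @export
pad_volume <- function(v, pad) {
  pad <- rep_len(as.integer(pad), 3)
  stopifnot(all(pad >= 0))
  d <- dim(v$data)
  nd <- d + 2L * pad
  out <- array(if (inherits(v, "label_volume")) 0L else 0, nd)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3])] <- v$data
  affine <- v$affine
  affine[1:3, 4] <- affine[1:3, 4] - affine[1:3, 1:3] %*% pad
  if (inherits(v, "label_volume")) {
    label_volume(out, v$schema, v$spacing, affine)
  } else {
    volume3d(out, v$spacing, affine)
  }
}

#' Crop the symmetric padding added by [pad_volume()]
#' @param v Padded volume.
#' @param pad The padding that was applied.
#' @return The unpadded object (inverse of [pad_volume()]).
#' @export
crop_volume <- function(v, pad) {
  pad <- rep_len(as.integer(pad), 3)
  d <- dim(v$data) - 2L * pad
  stopifnot(all(d >= 1))
  out <- v$data[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
                pad[3] + seq_len(d[3]), drop = FALSE]
  affine <- v$affine
  affine[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% pad
  if (inherits(v, "label_volume")) {
    label_volume(out, v$schema, v$spacing, affine)
  } else {
    volume3d(out, v$spacing, affine)
  }
}

#' Learn histogram standardization landmarks
#'
#' Landmark-based intensity standardization (Nyul-Udupa style): for each
#' training volume the foreground (intensity > 0) percentiles at
#' `percentiles` are computed and mapped linearly so that the volume's
#' `[p_min, p_max]` spans `standard_range`; the standard-scale value of
#' each percentile is the mean of these mapped values over volumes.
#'
#' @param volumes List of [volume3d()] (at least one).
#' @param percentiles Strictly increasing percentiles in (0, 100); default
#'   deciles plus 1 and 99.
#' @param standard_range Length-2 target range for `[p_min, p_max]`.
#' @return An object of class `histogram_landmarks` with fields
#'   `percentiles`, `standard`, `floor`, `ceiling`.
#' @export
learn_landmarks <- function(volumes,
                            percentiles = c(1, seq(10, 90, 10), 99),
                            standard_range = c(0, 1)) {
  if (inherits(volumes, "volume3d")) volumes <- list(volumes)
  stopifnot(length(volumes) >= 1)
  percentiles <- as.numeric(percentiles)
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) ||
      any(percentiles >= 100))
    stop("percentiles must be strictly increasing within (0, 100)")
  mapped <- vapply(volumes, function(v) {
    fg <- v$data[v$data > 0]
    if (!length(fg)) stop("empty foreground (no voxels > 0)")
    q <- stats::quantile(fg, percentiles / 100, names = FALSE, type = 7)
    if (q[length(q)] <= q[1]) stop("degenerate foreground histogram")
    standard_range[1] + (q - q[1]) / (q[length(q)] - q[1]) *
      diff(standard_range)
  }, numeric(length(percentiles)))
  mapped <- matrix(mapped, nrow = length(percentiles))
  std <- rowMeans(mapped)
  structure(list(percentiles = percentiles, standard = std,
                 floor = standard_range[1], ceiling = standard_range[2]),
            class = "histogram_landmarks")
}

#' Standardize a volume's intensities to learned landmarks
#'
#' Applies the monotone piecewise-linear map sending the volume's own
#' foreground percentiles to the learned standard-scale values, with linear
#' extrapolation clipped to `[floor, ceiling]` outside the landmark range.
#' Background voxels (intensity <= 0) are left untouched.
#'
#' @param v A [volume3d()].
#' @param lm A `histogram_landmarks` object from [learn_landmarks()].
#' @return Standardized [volume3d()].
#' @export
standardize_intensity <- function(v, lm) {
  stopifnot(inherits(lm, "histogram_landmarks"))
  fg <- v$data > 0
  vals <- v$data[fg]
  if (!length(vals)) stop("empty foreground (no voxels > 0)")
  q <- stats::quantile(vals, lm$percentiles / 100, names = FALSE, type = 7)
  if (q[length(q)] <= q[1]) stop("degenerate (constant) foreground")
  # collapse any ties in the source knots to keep approx() happy
  keep <- c(TRUE, diff(q) > 0)
  mapped <- stats::approx(q[keep], lm$standard[keep], xout = vals,
                          rule = 2)$y
  mapped <- pmin(pmax(mapped, lm$floor), lm$ceiling)
  out <- v$data
  out[fg] <- mapped
  volume3d(out, v$spacing, v$affine)
}

#' Serialize / load landmarks as JSON
#' @param lm A `histogram_landmarks` object.
#' @param path JSON file path.
#' @return `path` invisibly; `read_landmarks()` returns the object.
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(unclass(lm), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(percentiles = as.numeric(x$percentiles),
                 standard = as.numeric(x$standard),
                 floor = as.numeric(x$floor),
                 ceiling = as.numeric(x$ceiling)),
            class = "histogram_landmarks")
}
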