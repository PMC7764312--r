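#' Augmentation configuration
#'
#' The four stochastic training-time transforms with their published
#' default parameter ranges: additive Gaussian noise with sd drawn from
#' `[0, 0.2]` (intensities are assumed standardized to a roughly \[0, 1\]
#' scale), a multiplicative bias field with polynomial coefficients uniform
#' in `[-0.5, 0.5]`, a random affine with scale in `[0.9, 1.1]` and
#' rotations in `[-10, 10]` degrees (no shear or translation), and an
#' elastic deformation driven by a 7x7x7 control-point grid.
#'
#' Unstated knobs fixed here: maximum elastic control-point displacement
#' defaults to 2 voxels, each transform is applied independently with
#' probability 0.5, and the composition order is noise, bias, affine,
#' elastic.
#'
#' @param noise_sd_range Range the per-call noise sd is drawn from.
#' @param bias_range Range of the bias polynomial coefficients.
#' @param scale_range Range of the isotropic scale factor.
#' @param rotation_range Rotation range in degrees (each axis).
#' @param elastic_control_points Control points per axis (>= 2).
#' @param elastic_max_disp Maximum control-point displacement in voxels.
#' @param p Per-transform application probability.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(noise_sd_range = c(0, 0.2),
                           bias_range = c(-0.5, 0.5),
                           scale_range = c(0.9, 1.1),
                           rotation_range = c(-10, 10),
                           elastic_control_points = 7L,
                           elastic_max_disp = 2,
                           p = 0.5) {
  stopifnot(noise_sd_range[1] <= noise_sd_range[2],
            bias_range[1] <= bias_range[2],
            scale_range[1] <= scale_range[2],
            rotation_range[1] <= rotation_range[2],
            elastic_control_points >= 2, p >= 0, p <= 1)
  structure(list(noise_sd_range = noise_sd_range, bias_range = bias_range,
                 scale_range = scale_range, rotation_range = rotation_range,
                 elastic_control_points = as.integer(elastic_control_points),
                 elastic_max_disp = elastic_max_disp, p = p),
            class = "augment_config")
}

as_vol_data <- function(v) if (inherits(v, "volume3d")) v$data else v
rewrap <- function(v, data) {
  if (inherits(v, "volume3d")) volume3d(data, v$spacing, v$affine) else data
}

#' Additive Gaussian noise
#'
#' @param v A [volume3d()] or plain 3D array.
#' @param sd Noise standard deviation (>= 0); draws use the current RNG
#'   state.
#' @return Same type as `v`.
#' @export
gaussian_noise <- function(v, sd) {
  stopifnot(sd >= 0)
  x <- as_vol_data(v)
  if (sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
  rewrap(v, x)
}

#' Multiplicative polynomial bias field
#'
#' Multiplies the volume voxelwise by `exp(P(x))`, `P` a 3rd-order
#' polynomial over normalized coordinates with the given coefficients
#' (20 coefficients for total degree <= 3, in the column-major order of
#' `expand.grid(i = 0:3, j = 0:3, k = 0:3)` filtered to `i+j+k <= 3`).
#' The field is strictly positive.
#'
#' @param v A [volume3d()] or 3D array.
#' @param coefficients Polynomial coefficients; when `NULL`, drawn
#'   uniformly from `amplitude_range`.
#' @param amplitude_range Range for random coefficients.
#' @return Same type as `v`.
#' @export
bias_field <- function(v, coefficients = NULL,
                       amplitude_range = c(-0.5, 0.5)) {
  x <- as_vol_data(v)
  if (is.null(coefficients)) {
    coefficients <- stats::runif(n_bias_coeffs(), amplitude_range[1],
                                 amplitude_range[2])
  }
  field <- bias_field_grid(dim(x), NA, coeffs = coefficients)
  rewrap(v, x * field)
}

n_bias_coeffs <- function() {
  pw <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  sum(pw$i + pw$j + pw$k <= 3)
}

# Voxel-space matrix mapping output voxel -> input voxel for a rotation +
# isotropic scale about the grid center (no shear, no translation).
affine_voxel_matrix <- function(d, scale, angles_deg) {
  ctr <- (d - 1) / 2
  R <- rotation_matrix(angles_deg)
  M <- diag(4)
  M[1:3, 1:3] <- solve(R * scale) # inverse map for pull-back resampling
  M[1:3, 4] <- ctr - M[1:3, 1:3] %*% ctr
  M
}

#' Random affine transform (scale + rotation)
#'
#' Resamples the image with trilinear interpolation and the paired labels
#' (if any) with nearest-neighbor under the same transform. Shearing and
#' translation are not applied.
#'
#' @param v A [volume3d()] or 3D array.
#' @param lv Optional paired [label_volume()] or integer 3D array.
#' @param scale Isotropic scale factor.
#' @param angles Length-3 rotation angles in degrees.
#' @return `list(volume =, labels =)` with `labels = NULL` when `lv` is
#'   `NULL`.
#' @export
random_affine <- function(v, lv = NULL, scale = 1, angles = c(0, 0, 0)) {
  x <- as_vol_data(v)
  M <- affine_voxel_matrix(dim(x), scale, angles)
  xi <- cpp_resample_affine(array(as.double(x), dim(x)), M,
                            as.integer(dim(x)), 1L, 0)
  out_l <- NULL
  if (!is.null(lv)) {
    l <- if (inherits(lv, "label_volume")) lv$data else lv
    li <- cpp_resample_affine(array(as.double(l), dim(l)), M,
                              as.integer(dim(l)), 0L, 0)
    li <- array(as.integer(round(li)), dim(l))
    out_l <- if (inherits(lv, "label_volume")) {
      label_volume(li, lv$schema, lv$spacing, lv$affine)
    } else li
  }
  list(volume = rewrap(v, xi), labels = out_l)
}

# Dense displacement field (X,Y,Z,3) interpolated trilinearly from a
# control-point grid of random vectors.
elastic_field <- function(d, control_points, max_disp) {
  cp <- control_points
  disp <- array(stats::runif(cp^3 * 3, -max_disp, max_disp), c(cp, cp, cp, 3))
  out <- array(0, c(d, 3))
  # map full-grid voxel coords onto the control grid (align corners)
  M <- diag(4)
  for (ax in 1:3) M[ax, ax] <- (cp - 1) / max(d[ax] - 1, 1)
  for (comp in 1:3) {
    out[, , , comp] <- cpp_resample_affine(
      array(disp[, , , comp], c(cp, cp, cp)), M, as.integer(d), 1L, 0)
  }
  out
}

#' Elastic deformation
#'
#' A smooth random displacement field is interpolated from a cubic grid of
#' control points (default 7 per axis) with displacement vectors bounded by
#' `max_disp` voxels. The image is resampled with trilinear interpolation
#' and paired labels with nearest-neighbor under the same field.
#'
#' @param v A [volume3d()] or 3D array.
#' @param lv Optional paired labels.
#' @param control_points Control points per axis.
#' @param max_disp Maximum displacement in voxels.
#' @param field Optionally a precomputed `(X,Y,Z,3)` displacement field.
#' @return `list(volume =, labels =)`.
#' @export
elastic <- function(v, lv = NULL, control_points = 7L, max_disp = 2,
                    field = NULL) {
  x <- as_vol_data(v)
  if (is.null(field)) {
    if (max_disp == 0) {
      field <- array(0, c(dim(x), 3))
    } else {
      field <- elastic_field(dim(x), control_points, max_disp)
    }
  }
  xi <- cpp_resample_disp(array(as.double(x), dim(x)), field, 1L, 0)
  out_l <- NULL
  if (!is.null(lv)) {
    l <- if (inherits(lv, "label_volume")) lv$data else lv
    li <- cpp_resample_disp(array(as.double(l), dim(l)), field, 0L, 0)
    li <- array(as.integer(round(li)), dim(l))
    out_l <- if (inherits(lv, "label_volume")) {
      label_volume(li, lv$schema, lv$spacing, lv$affine)
    } else li
  }
  list(volume = rewrap(v, xi), labels = out_l)
}

#' Sample augmentation parameters
#'
#' Draws one set of per-call parameters uniformly from the configured
#' ranges, plus Bernoulli application flags.
#'
#' @param cfg An [augment_config()].
#' @return Named list of sampled parameters.
#' @export
sample_augment_params <- function(cfg) {
  list(
    apply = stats::runif(4) < cfg$p,
    noise_sd = stats::runif(1, cfg$noise_sd_range[1], cfg$noise_sd_range[2]),
    bias_coeffs = stats::runif(n_bias_coeffs(), cfg$bias_range[1],
                               cfg$bias_range[2]),
    scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
    angles = stats::runif(3, cfg$rotation_range[1], cfg$rotation_range[2]),
    elastic_max_disp = cfg$elastic_max_disp
  )
}

#' Apply the composed augmentation
#'
#' Applies (with the sampled per-transform flags) noise, bias field, random
#' affine and elastic deformation, in that fixed order; geometric
#' transforms are applied jointly to image and labels.
#'
#' @param cfg An [augment_config()].
#' @param v Image ([volume3d()] or array).
#' @param lv Paired labels (or `NULL`).
#' @param params Optional pre-sampled parameters from
#'   [sample_augment_params()]; drawn fresh when `NULL`.
#' @return `list(volume =, labels =, params =)`.
#' @export
apply_augment <- function(cfg, v, lv = NULL, params = NULL) {
  if (is.null(params)) params <- sample_augment_params(cfg)
  if (params$apply[1]) v <- gaussian_noise(v, params$noise_sd)
  if (params$apply[2]) v <- bias_field(v, params$bias_coeffs)
  if (params$apply[3]) {
    out <- random_affine(v, lv, params$scale, params$angles)
    v <- out$volume
    if (!is.null(lv)) lv <- out$labels
  }
  if (params$apply[4]) {
    out <- elastic(v, lv, cfg$elastic_control_points,
                   params$elastic_max_disp)
    v <- out$volume
    if (!is.null(lv)) lv <- out$labels
  }
  list(volume = v, labels = lv, params = params)
}
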