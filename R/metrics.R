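#' Extract the binary mask of one structure
#'
#' @param lv A [label_volume()] (or integer array).
#' @param id Label id.
#' @param spacing Spacing override when `lv` is a plain array.
#' @return An object of class `structure_mask`: logical 3D `mask` plus
#'   `spacing` in mm.
#' @export
structure_mask <- function(lv, id, spacing = NULL) {
  if (inherits(lv, "label_volume")) {
    m <- lv$data == id
    sp <- lv$spacing
  } else {
    m <- lv == id
    sp <- if (is.null(spacing)) c(1, 1, 1) else spacing
  }
  structure(list(mask = m, spacing = as.numeric(sp)),
            class = "structure_mask")
}

as_mask <- function(a, spacing = c(1, 1, 1)) {
  if (inherits(a, "structure_mask")) a else
    structure(list(mask = as.array(a) != 0, spacing = as.numeric(spacing)),
              class = "structure_mask")
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` over voxel sets; 1 when both masks
#' are empty (perfect agreement on absence).
#'
#' @param a,b `structure_mask` objects (or logical arrays) on the same
#'   grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a$mask) == dim(b$mask))) stop("grid mismatch")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0) return(1)
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Boundary voxels of a mask
#'
#' Mask voxels with at least one face-adjacent (6-connected) neighbor
#' outside the mask; voxels on the array edge count as boundary. A single
#' voxel is its own boundary.
#'
#' @param m A `structure_mask` (or logical array).
#' @return Integer matrix of 0-based voxel coordinates (one row per
#'   boundary voxel).
#' @export
boundary <- function(m) {
  m <- as_mask(m)
  msk <- m$mask
  if (!any(msk)) stop("boundary of an empty mask is undefined")
  d <- dim(msk)
  interior <- array(TRUE, d)
  # neighbor presence along each axis; edges are boundary
  shift_and <- function(acc, ax) {
    nb_lo <- array(FALSE, d); nb_hi <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    lo <- idx; lo[[ax]] <- seq_len(d[ax] - 1)
    hi <- idx; hi[[ax]] <- 2:d[ax]
    nb_hi[lo[[1]], lo[[2]], lo[[3]]] <- msk[hi[[1]], hi[[2]], hi[[3]]]
    nb_lo[hi[[1]], hi[[2]], hi[[3]]] <- msk[lo[[1]], lo[[2]], lo[[3]]]
    acc & nb_lo & nb_hi
  }
  for (ax in 1:3) interior <- shift_and(interior, ax)
  b <- msk & !interior
  which(b, arr.ind = TRUE) - 1L
}

#' Average symmetric surface distance (mm)
#'
#' The symmetric mean of Euclidean distances between the two masks'
#' boundary voxel sets: `(sum_x d(x, B_b) + sum_y d(y, B_a)) /
#' (|B_a| + |B_b|)`, with distances between voxel centers in physical mm.
#' Undefined (error) when either mask is empty.
#'
#' @param a,b `structure_mask` objects on the same grid and spacing.
#' @return Non-negative distance in mm; symmetric in its arguments.
#' @export
assd <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a$mask) == dim(b$mask))) stop("grid mismatch")
  if (!isTRUE(all.equal(a$spacing, b$spacing))) stop("spacing mismatch")
  if (!any(a$mask) || !any(b$mask))
    stop("ASSD is undefined for an empty mask")
  ba <- boundary(a)
  bb <- boundary(b)
  sp <- a$spacing
  pa <- sweep(ba, 2, sp, "*")
  pb <- sweep(bb, 2, sp, "*")
  da <- cpp_min_dists(pa, pb)
  db <- cpp_min_dists(pb, pa)
  (sum(da) + sum(db)) / (nrow(pa) + nrow(pb))
}

#' Structure volume in cubic centimeters
#'
#' Voxel count times the voxel volume (product of spacings in mm),
#' divided by 1000.
#'
#' @param m A `structure_mask`.
#' @return Volume in cc.
#' @export
volume_cc <- function(m) {
  m <- as_mask(m)
  sum(m$mask) * prod(m$spacing) / 1000
}

#' Average intra-session coefficient of variation (percent)
#'
#' For paired test-retest measurements: per pair the population standard
#' deviation over the two sessions `sigma_s = sqrt(sum_i (x_i - mu_s)^2 /
#' 2)` is divided by the pair mean, and the ratios are averaged over pairs
#' and expressed in percent.
#'
#' @param pairs An n x 2 matrix (or data.frame) of per-pair volume
#'   estimates.
#' @return CVs_avg in percent.
#' @export
cv_intra_session <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("each pair must have exactly 2 measurements")
  mu <- rowMeans(pairs)
  if (any(mu <= 0)) stop("pair mean must be positive")
  sigma <- sqrt(rowSums((pairs - mu)^2) / 2)
  mean(sigma / mu) * 100
}

#' Total coefficient of variation over a scan series (percent)
#'
#' Population standard deviation over the n scans of one subject divided
#' by the series mean, in percent.
#'
#' @param series Numeric vector of n >= 2 volume estimates.
#' @return CVt in percent.
#' @export
cv_total <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2) stop("need at least 2 scans")
  mu <- mean(series)
  if (mu <= 0) stop("series mean must be positive")
  sigma <- sqrt(sum((series - mu)^2) / length(series))
  sigma / mu * 100
}

#' Per-structure evaluation report
#'
#' One row per requested structure with Dice, ASSD and the two volumes,
#' plus an unweighted mean/sd summary across structures. A structure
#' absent from both volumes scores Dice 1 with ASSD skipped; absent from
#' exactly one, Dice 0 with ASSD skipped (flagged).
#'
#' @param pred,truth [label_volume()] on a shared grid and schema.
#' @param ids Structure ids to evaluate (default: all foreground ids of
#'   the schema).
#' @return Data.frame with columns `id`, `name`, `dice`, `assd_mm`,
#'   `volume_pred_cc`, `volume_truth_cc`, `flag`; the summary is attached
#'   as attribute `"summary"` (named vector with `dice_mean`, `dice_sd`,
#'   `assd_mean`, `assd_sd`).
#' @export
evaluate_report <- function(pred, truth, ids = NULL) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!all(dim(pred$data) == dim(truth$data))) stop("grid mismatch")
  if (is.null(ids)) ids <- setdiff(truth$schema$entries$id, 0L)
  names_of <- truth$schema$entries$name[match(ids, truth$schema$entries$id)]
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    mp <- structure_mask(pred, id)
    mt <- structure_mask(truth, id)
    ep <- !any(mp$mask); et <- !any(mt$mask)
    if (ep && et) {
      data.frame(id = id, name = names_of[i], dice = 1, assd_mm = NA_real_,
                 volume_pred_cc = 0, volume_truth_cc = 0,
                 flag = "absent_both")
    } else if (ep || et) {
      data.frame(id = id, name = names_of[i], dice = 0, assd_mm = NA_real_,
                 volume_pred_cc = volume_cc(mp), volume_truth_cc = volume_cc(mt),
                 flag = "absent_one")
    } else {
      data.frame(id = id, name = names_of[i], dice = dice(mp, mt),
                 assd_mm = assd(mp, mt), volume_pred_cc = volume_cc(mp),
                 volume_truth_cc = volume_cc(mt), flag = "")
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    dice_mean = mean(out$dice),
    dice_sd = stats::sd(out$dice),
    assd_mean = mean(out$assd_mm, na.rm = TRUE),
    assd_sd = stats::sd(out$assd_mm, na.rm = TRUE))
  out
}
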