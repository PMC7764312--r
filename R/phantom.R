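#' Phantom specification
#'
#' Describes a deterministic T1-like synthetic volume: painted ellipsoidal
#' tissue compartments (later entries overwrite earlier ones, which is how
#' nested compartments and bilateral structures are expressed), per-tissue
#' mean intensity and intensity spread, additive Gaussian noise, and a
#' smooth multiplicative bias field.
#'
#' @param grid Integer length-3 grid size in voxels.
#' @param tissues A data.frame with one row per painted ellipsoid and
#'   columns `label` (positive id), `cx`, `cy`, `cz` (center, 0-based voxel
#'   coords), `ax`, `ay`, `az` (semi-axes in voxels), `mean` (tissue mean
#'   intensity) and `sd` (within-tissue intensity spread).
#' @param noise_sd Global additive Gaussian noise standard deviation.
#' @param bias_amplitude Bias field coefficient amplitude; the field is
#'   `exp(P(x))` with `P` a 3rd-order polynomial in normalized coordinates
#'   whose coefficients are drawn uniformly in `±bias_amplitude`.
#' @param schema A [label_schema()] covering every `label` used.
#' @param seed Integer seed; identical specs produce bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, tissues, noise_sd = 0.05,
                         bias_amplitude = 0.2, schema = NULL, seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 4))
  need <- c("label", "cx", "cy", "cz", "ax", "ay", "az", "mean", "sd")
  if (!all(need %in% names(tissues))) {
    stop("tissues must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tissues$label <= 0)) stop("tissue labels must be positive ids")
  # ellipsoids must lie inside the grid
  lo <- cbind(tissues$cx - tissues$ax, tissues$cy - tissues$ay,
              tissues$cz - tissues$az)
  hi <- cbind(tissues$cx + tissues$ax, tissues$cy + tissues$ay,
              tissues$cz + tissues$az)
  if (any(lo < -0.5) || any(hi > rep(grid, each = nrow(tissues)) - 0.5)) {
    stop("an ellipsoid extends outside the grid")
  }
  if (is.null(schema)) {
    ids <- sort(unique(tissues$label))
    if (!identical(as.integer(ids), seq_along(ids))) {
      stop("tissue labels must be 1..K when no schema is given")
    }
    schema <- label_schema(c(0L, ids),
                           c("background", paste0("tissue_", ids)))
  }
  if (!all(tissues$label %in% schema$entries$id)) {
    stop("tissue labels missing from schema")
  }
  structure(list(grid = grid, tissues = tissues, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, schema = schema,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default desk-scale phantom specification
#'
#' A 64-voxel cube with four bilateral structure pairs (8 foreground
#' labels) embedded in two large hemispheric compartments, emulating a
#' pair of white-matter shells containing ventricle-, thalamus- and
#' hippocampus-like structures. Mean intensities are on a roughly
#' standardized \[0, 1\] scale and differ between homologous left/right
#' structures so that a patch-scale network without whole-volume context
#' can resolve laterality.
#'
#' @param grid Grid size (default 64 cubed).
#' @param noise_sd,bias_amplitude,seed Passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(grid = c(64, 64, 64), noise_sd = 0.05,
                                 bias_amplitude = 0.2, seed = 1L) {
  g <- grid
  cx <- (g[1] - 1) / 2; cy <- (g[2] - 1) / 2; cz <- (g[3] - 1) / 2
  lx <- cx - g[1] * 0.21; rx <- cx + g[1] * 0.21
  s <- g[1] / 64 # scale structure sizes with the grid
  tissues <- rbind(
    # hemispheric white-matter-like shells (painted first, nested inside)
    data.frame(label = 1, cx = lx, cy = cy, cz = cz, ax = 12 * s, ay = 22 * s,
               az = 22 * s, mean = 0.80, sd = 0.02),
    data.frame(label = 2, cx = rx, cy = cy, cz = cz, ax = 12 * s, ay = 22 * s,
               az = 22 * s, mean = 0.70, sd = 0.02),
    # ventricle-like dark structures
    data.frame(label = 3, cx = lx, cy = cy - 6 * s, cz = cz, ax = 5 * s,
               ay = 9 * s, az = 7 * s, mean = 0.12, sd = 0.02),
    data.frame(label = 4, cx = rx, cy = cy - 6 * s, cz = cz, ax = 5 * s,
               ay = 9 * s, az = 7 * s, mean = 0.22, sd = 0.02),
    # thalamus-like structures
    data.frame(label = 5, cx = lx, cy = cy + 8 * s, cz = cz - 5 * s,
               ax = 6 * s, ay = 7 * s, az = 6 * s, mean = 0.50, sd = 0.02),
    data.frame(label = 6, cx = rx, cy = cy + 8 * s, cz = cz - 5 * s,
               ax = 6 * s, ay = 7 * s, az = 6 * s, mean = 0.60, sd = 0.02),
    # hippocampus-like structures
    data.frame(label = 7, cx = lx, cy = cy + 6 * s, cz = cz + 9 * s,
               ax = 5 * s, ay = 6 * s, az = 6 * s, mean = 0.35, sd = 0.02),
    data.frame(label = 8, cx = rx, cy = cy + 6 * s, cz = cz + 9 * s,
               ax = 5 * s, ay = 6 * s, az = 6 * s, mean = 0.44, sd = 0.02)
  )
  schema <- label_schema(
    0:8,
    c("background",
      "wm_left", "wm_right", "ventricle_left", "ventricle_right",
      "thalamus_left", "thalamus_right", "hippocampus_left",
      "hippocampus_right"),
    c("none", rep(c("left", "right"), 4)))
  phantom_spec(grid, tissues, noise_sd, bias_amplitude, schema, seed)
}

# Evaluate exp(P(x)) for a random 3rd-order polynomial P over normalized
# coordinates in [-1, 1]; coefficients uniform in +-amplitude.
bias_field_grid <- function(grid, amplitude, coeffs = NULL) {
  xs <- seq(-1, 1, length.out = grid[1])
  ys <- seq(-1, 1, length.out = grid[2])
  zs <- seq(-1, 1, length.out = grid[3])
  pw <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  pw <- pw[pw$i + pw$j + pw$k <= 3, , drop = FALSE]
  if (is.null(coeffs)) {
    coeffs <- stats::runif(nrow(pw), -amplitude, amplitude)
  }
  stopifnot(length(coeffs) == nrow(pw))
  P <- array(0, grid)
  xi <- outer(xs, 0:3, "^") # grid[1] x 4
  yj <- outer(ys, 0:3, "^")
  zk <- outer(zs, 0:3, "^")
  for (t in seq_len(nrow(pw))) {
    if (coeffs[t] == 0) next
    P <- P + coeffs[t] * (xi[, pw$i[t] + 1] %o% yj[, pw$j[t] + 1] %o%
                            zk[, pw$k[t] + 1])
  }
  exp(P)
}

paint_labels <- function(spec) {
  g <- spec$grid
  lab <- array(0L, g)
  xs <- seq_len(g[1]) - 1; ys <- seq_len(g[2]) - 1; zs <- seq_len(g[3]) - 1
  for (t in seq_len(nrow(spec$tissues))) {
    tt <- spec$tissues[t, ]
    dx2 <- ((xs - tt$cx) / tt$ax)^2
    dy2 <- ((ys - tt$cy) / tt$ay)^2
    dz2 <- ((zs - tt$cz) / tt$az)^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    lab[inside] <- as.integer(tt$label)
  }
  lab
}

#' Generate a phantom volume and its ground-truth labels
#'
#' The label grid paints the spec's ellipsoids in order (later entries
#' overwrite earlier ones). The intensity grid assigns each tissue its mean
#' plus per-tissue Gaussian spread, adds global Gaussian noise, and
#' multiplies by a smooth positive bias field.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([volume3d()]) and `labels`
#'   ([label_volume()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    lab <- paint_labels(spec)
    img <- array(0, spec$grid)
    for (t in seq_len(nrow(spec$tissues))) {
      tt <- spec$tissues[t, ]
      idx <- which(lab == tt$label)
      if (length(idx)) {
        img[idx] <- tt$mean +
          if (tt$sd > 0) stats::rnorm(length(idx), 0, tt$sd) else 0
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    }
    if (spec$bias_amplitude > 0) {
      img <- img * bias_field_grid(spec$grid, spec$bias_amplitude)
    }
    list(volume = volume3d(img),
         labels = label_volume(lab, spec$schema))
  })
}

# Evaluate a block with a private RNG state so generation is reproducible
# and does not disturb the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Degradation specification for auxiliary labels
#'
#' Auxiliary labels emulate automatically generated segmentations whose
#' boundaries systematically disagree with the ground truth: each foreground
#' label is morphologically dilated (positive radius) or eroded (negative
#' radius) and boundary voxels are then randomly flipped to a neighboring
#' label.
#'
#' @param dilate_radius Either a single integer radius applied to every
#'   foreground label or a named vector mapping label id to radius
#'   (negative = erosion).
#' @param flip_prob Probability in \[0, 1\] that a boundary voxel is
#'   reassigned to the label of a random 6-neighbor.
#' @param seed Integer seed.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(dilate_radius = 1L, flip_prob = 0.2, seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob <= 1)
  structure(list(dilate_radius = dilate_radius, flip_prob = flip_prob,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

# 6-connected binary dilation by repeated unit steps (radius in voxels).
dilate6 <- function(mask, radius) {
  for (r in seq_len(abs(radius))) {
    m <- mask
    d <- dim(mask)
    m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
    m[, , -1] <- m[, , -1] | mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
    mask <- m
  }
  mask
}

erode6 <- function(mask, radius) !dilate6(!mask, radius)

# Voxels of `lab` with at least one 6-neighbor carrying a different label.
boundary_mask <- function(lab) {
  d <- dim(lab)
  b <- array(FALSE, d)
  b[-1, , ] <- b[-1, , ] | (lab[-1, , ] != lab[-d[1], , ])
  b[-d[1], , ] <- b[-d[1], , ] | (lab[-d[1], , ] != lab[-1, , ])
  b[, -1, ] <- b[, -1, ] | (lab[, -1, ] != lab[, -d[2], ])
  b[, -d[2], ] <- b[, -d[2], ] | (lab[, -d[2], ] != lab[, -1, ])
  b[, , -1] <- b[, , -1] | (lab[, , -1] != lab[, , -d[3]])
  b[, , -d[3]] <- b[, , -d[3]] | (lab[, , -d[3]] != lab[, , -1])
  b
}

#' Corrupt a label volume into auxiliary labels
#'
#' Applies per-label dilation/erosion followed by random boundary flips,
#' per the degradation spec. No new label ids are introduced.
#'
#' @param lv A [label_volume()] of ground-truth labels.
#' @param d A [degradation_spec()].
#' @return A degraded [label_volume()] on the same grid and schema.
#' @export
degrade_labels <- function(lv, d) {
  stopifnot(inherits(lv, "label_volume"), inherits(d, "degradation_spec"))
  with_seed(d$seed, {
    lab <- lv$data
    fg_ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    radius_of <- function(id) {
      r <- d$dilate_radius
      if (!is.null(names(r))) {
        if (as.character(id) %in% names(r)) r[[as.character(id)]] else 0L
      } else {
        r
      }
    }
    for (id in fg_ids) {
      r <- as.integer(radius_of(id))
      if (r == 0L) next
      m <- lab == id
      m2 <- if (r > 0) dilate6(m, r) else erode6(m, -r)
      grow <- m2 & !m & (if (r > 0) lab == 0L else FALSE)
      lab[m & !m2] <- 0L
      lab[grow] <- id
    }
    if (d$flip_prob > 0) {
      bidx <- which(boundary_mask(lab))
      flip <- bidx[stats::runif(length(bidx)) < d$flip_prob]
      if (length(flip)) {
        dm <- dim(lab)
        strides <- c(1L, dm[1], dm[1] * dm[2])
        offs <- c(-strides, strides)
        pick <- sample(6L, length(flip), replace = TRUE)
        src <- flip + offs[pick]
        ok <- src >= 1L & src <= length(lab)
        lab[flip[ok]] <- lab[src[ok]]
      }
    }
    label_volume(lab, lv$schema, lv$spacing, lv$affine)
  })
}

#' Generate paired test-retest phantom scans
#'
#' Each pair shares identical label geometry but has independent noise and
#' bias draws and a small rigid jitter, emulating a subject scanned twice
#' in one session. Suitable for intra-session coefficient-of-variation
#' experiments.
#'
#' @param spec A [phantom_spec()].
#' @param n_pairs Number of scan pairs (each pair is one "subject").
#' @param jitter_deg,jitter_mm Maximum absolute rotation (degrees) and
#'   translation (mm) of the rigid jitter applied to the second scan of a
#'   pair; 0 disables jitter.
#' @return A list of `n_pairs` elements, each a list with `scan1`, `scan2`
#'   ([volume3d()]) and `labels` (the shared ground truth,
#'   [label_volume()]).
#' @export
make_paired_set <- function(spec, n_pairs, jitter_deg = 1, jitter_mm = 1) {
  stopifnot(n_pairs >= 1)
  lapply(seq_len(n_pairs), function(p) {
    s1 <- spec; s1$seed <- spec$seed + 1000L * p
    s2 <- spec; s2$seed <- spec$seed + 1000L * p + 1L
    ph1 <- make_phantom(s1)
    ph2 <- make_phantom(s2)
    scan2 <- ph2$volume
    if (jitter_deg > 0 || jitter_mm > 0) {
      tr <- with_seed(spec$seed + 1000L * p + 2L, rigid_transform(
        angles = stats::runif(3, -jitter_deg, jitter_deg),
        translation = stats::runif(3, -jitter_mm, jitter_mm),
        center = (dim(scan2) - 1) / 2 * scan2$spacing))
      scan2 <- apply_rigid(scan2, tr, method = "trilinear")
      attr(scan2, "jitter") <- tr
    }
    list(scan1 = ph1$volume, scan2 = scan2, labels = ph1$labels)
  })
}

#' Generate a multi-center phantom scan set
#'
#' One subject's anatomy rendered under per-site global intensity
#' transforms (scale and offset) and per-site noise levels, emulating the
#' same subject scanned at several imaging centers. Label geometry is
#' identical across sites.
#'
#' @param spec A [phantom_spec()].
#' @param n_sites Number of sites (>= 2).
#' @param scales,offsets,noise_sds Per-site intensity scale, offset and
#'   noise sd; recycled to `n_sites`.
#' @return A list with `scans` (list of [volume3d()]) and `labels`.
#' @export
make_multicenter_set <- function(spec, n_sites = 12,
                                 scales = seq(0.8, 1.2, length.out = n_sites),
                                 offsets = 0, noise_sds = spec$noise_sd) {
  stopifnot(n_sites >= 2)
  scales <- rep_len(scales, n_sites)
  offsets <- rep_len(offsets, n_sites)
  noise_sds <- rep_len(noise_sds, n_sites)
  base <- spec
  base$noise_sd <- 0 # site noise is added per scan below
  ph <- make_phantom(base)
  scans <- lapply(seq_len(n_sites), function(s) {
    with_seed(spec$seed + 77L * s, {
      img <- ph$volume$data * scales[s] + offsets[s]
      if (noise_sds[s] > 0) {
        img <- img + stats::rnorm(length(img), 0, noise_sds[s])
      }
      volume3d(img, ph$volume$spacing, ph$volume$affine)
    })
  })
  list(scans = scans, labels = ph$labels)
}
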