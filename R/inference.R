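#' Plan patches covering a volume
#'
#' Grid mode tiles the volume with stride `patch - overlap`, clamping the
#' last origin of each axis to the boundary. Random mode draws
#' `n_patches` origins uniformly (the published inference setting uses 128
#' random patches) and then repairs coverage by appending grid origins
#' that still cover unseen voxels, because random origins alone do not
#' guarantee that every voxel is inside at least one patch. Coverage is
#' verified exhaustively before the plan is returned.
#'
#' @param vol_dim Length-3 volume dimensions.
#' @param patch_size Cubic patch edge (or length-3); default 96.
#' @param overlap Target overlap between adjacent grid patches (default
#'   12).
#' @param mode `"grid"` or `"random"`.
#' @param n_patches Random-mode patch count (default 128).
#' @param seed Random-mode seed.
#' @return An object of class `patch_plan` with `origins` (n x 3 matrix of
#'   0-based origins), `patch_size`, `mode`, `vol_dim`.
#' @export
plan_patches <- function(vol_dim, patch_size = 96L, overlap = 12L,
                         mode = c("grid", "random"), n_patches = 128L,
                         seed = 1L) {
  mode <- match.arg(mode)
  vol_dim <- as.integer(vol_dim)
  patch_size <- rep_len(as.integer(patch_size), 3)
  overlap <- rep_len(as.integer(overlap), 3)
  if (any(patch_size > vol_dim))
    stop("patch larger than volume: coverage impossible")
  stride <- pmax(patch_size - overlap, 1L)
  axis_origins <- lapply(1:3, function(ax) {
    o <- seq.int(0L, vol_dim[ax] - patch_size[ax], by = stride[ax])
    unique(c(o, vol_dim[ax] - patch_size[ax]))
  })
  grid_origins <- as.matrix(expand.grid(axis_origins[[1]], axis_origins[[2]],
                                        axis_origins[[3]]))
  dimnames(grid_origins) <- NULL
  if (mode == "grid") {
    origins <- grid_origins
  } else {
    origins <- with_seed(seed, {
      vapply(1:3, function(ax) {
        sample.int(vol_dim[ax] - patch_size[ax] + 1L, n_patches,
                   replace = TRUE) - 1L
      }, integer(n_patches))
    })
    origins <- matrix(origins, ncol = 3)
    # coverage repair: append grid origins still contributing new voxels
    cov <- coverage_counts(vol_dim, origins, patch_size)
    for (i in seq_len(nrow(grid_origins))) {
      if (all(cov > 0)) break
      o <- grid_origins[i, ]
      ix <- lapply(1:3, function(ax) o[ax] + seq_len(patch_size[ax]))
      if (any(cov[ix[[1]], ix[[2]], ix[[3]]] == 0)) {
        origins <- rbind(origins, o)
        cov[ix[[1]], ix[[2]], ix[[3]]] <- cov[ix[[1]], ix[[2]], ix[[3]]] + 1L
      }
    }
  }
  plan <- structure(list(origins = unname(origins), patch_size = patch_size,
                         overlap = overlap, mode = mode, vol_dim = vol_dim,
                         n_random = if (mode == "random") n_patches else 0L,
                         seed = as.integer(seed)),
                    class = "patch_plan")
  if (!plan_covers(plan)) stop("internal error: plan does not cover volume")
  plan
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("<patch_plan> %s mode, %d patches of %s over %s\n",
              x$mode, nrow(x$origins),
              paste(x$patch_size, collapse = "x"),
              paste(x$vol_dim, collapse = "x")))
  invisible(x)
}

# Per-voxel count of covering patches, via a 3D difference array and three
# axis-wise cumulative sums.
coverage_counts <- function(vol_dim, origins, patch_size) {
  d <- vol_dim + 1L
  a <- array(0L, d)
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ] + 1L
    e <- o + patch_size
    a[o[1], o[2], o[3]] <- a[o[1], o[2], o[3]] + 1L
    a[e[1], o[2], o[3]] <- a[e[1], o[2], o[3]] - 1L
    a[o[1], e[2], o[3]] <- a[o[1], e[2], o[3]] - 1L
    a[o[1], o[2], e[3]] <- a[o[1], o[2], e[3]] - 1L
    a[e[1], e[2], o[3]] <- a[e[1], e[2], o[3]] + 1L
    a[e[1], o[2], e[3]] <- a[e[1], o[2], e[3]] + 1L
    a[o[1], e[2], e[3]] <- a[o[1], e[2], e[3]] + 1L
    a[e[1], e[2], e[3]] <- a[e[1], e[2], e[3]] - 1L
  }
  a <- apply(a, c(2, 3), cumsum)
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  a <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  a[seq_len(vol_dim[1]), seq_len(vol_dim[2]), seq_len(vol_dim[3]),
    drop = FALSE]
}

#' Does a plan cover every voxel?
#' @param plan A [plan_patches()] result.
#' @return TRUE iff every voxel lies inside at least one patch.
#' @export
plan_covers <- function(plan) {
  all(coverage_counts(plan$vol_dim, plan$origins, plan$patch_size) > 0)
}

#' Predict class probabilities for every planned patch
#'
#' One N-channel probability grid per origin; nothing is predicted outside
#' patch bounds. Deterministic given the checkpoint and input.
#'
#' @param ckpt `sau_weights` or `sau_checkpoint`.
#' @param v A [volume3d()] (standardized and padded as in training).
#' @param plan A [plan_patches()] result.
#' @return List of `(s,s,s,N)` probability arrays, parallel to
#'   `plan$origins`.
#' @export
predict_patches <- function(ckpt, v, plan) {
  w <- if (inherits(ckpt, "sau_checkpoint")) ckpt$weights else ckpt
  x <- as_vol_data(v)
  if (!all(dim(x) == plan$vol_dim)) stop("plan does not match volume shape")
  s <- plan$patch_size
  lapply(seq_len(nrow(plan$origins)), function(i) {
    o <- plan$origins[i, ]
    patch <- x[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
               o[3] + seq_len(s[3]), drop = FALSE]
    sau_forward(w, array(patch, s))
  })
}

#' OR-logical label fusion of overlapping patch predictions
#'
#' Per voxel: the argmax labels of all covering patches are collected. If
#' every covering patch votes background the voxel is background; any
#' non-background claim overrides background ("OR" semantics, the exact
#' logical OR in the binary case); a single non-background label wins
#' outright; conflicting non-background labels are resolved by the largest
#' probability summed across all covering patches, ties broken by the
#' smallest label id. Voxels covered by a single patch reduce to naive
#' concatenation. Every voxel must be covered.
#'
#' @param patches List of `(s,s,s,N)` probability arrays from
#'   [predict_patches()].
#' @param plan The matching [plan_patches()].
#' @param schema [label_schema()] for the output.
#' @param spacing,affine Grid geometry of the output volume.
#' @return A [label_volume()] on the plan's grid.
#' @export
fuse_or_logical <- function(patches, plan, schema, spacing = c(1, 1, 1),
                            affine = NULL) {
  D <- plan$vol_dim
  s <- plan$patch_size
  nvox <- prod(D)
  N <- dim(patches[[1]])[4]
  sN <- prod(s)
  probsum <- matrix(0, nvox, N)
  claim <- rep.int(-1L, nvox)   # -1 none, 0 background-only, >0 label
  conflict <- rep.int(FALSE, nvox)
  ncov <- rep.int(0L, nvox)
  for (i in seq_along(patches)) {
    o <- plan$origins[i, ]
    ix <- as.vector(outer(outer(o[1] + seq_len(s[1]),
                                (o[2] + seq_len(s[2]) - 1L) * D[1], "+"),
                          (o[3] + seq_len(s[3]) - 1L) * D[1] * D[2], "+"))
    pm <- matrix(patches[[i]], sN, N)
    probsum[ix, ] <- probsum[ix, ] + pm
    ncov[ix] <- ncov[ix] + 1L
    am <- max.col(pm, ties.method = "first") - 1L # 0-based labels
    cl <- claim[ix]
    new_claim <- cl
    new_claim[cl == -1L] <- ifelse(am[cl == -1L] > 0L, am[cl == -1L], 0L)
    upgrade <- cl == 0L & am > 0L
    new_claim[upgrade] <- am[upgrade]
    clash <- cl > 0L & am > 0L & am != cl
    conflict[ix][clash] <- TRUE
    claim[ix] <- new_claim
  }
  if (any(ncov == 0L)) stop("fusion error: uncovered voxel(s)")
  out <- claim
  out[claim <= 0L] <- 0L
  cidx <- which(conflict)
  if (length(cidx)) {
    pm <- probsum[cidx, -1L, drop = FALSE]
    out[cidx] <- max.col(pm, ties.method = "first")
  }
  label_volume(array(as.integer(out), D), schema, spacing, affine)
}

#' Map a template-space segmentation back to native space
#'
#' Resamples labels to the native grid with nearest-neighbor interpolation
#' under the inverse of the stored forward registration transform. No new
#' label ids are introduced.
#'
#' @param lv Template-space [label_volume()].
#' @param t The forward [rigid_transform()] from [register_to_template()].
#' @param native_grid A [volume3d()] defining the native grid.
#' @return Native-space [label_volume()].
#' @export
to_native_space <- function(lv, t, native_grid) {
  if (is.null(t)) stop("missing registration transform")
  apply_rigid(lv, invert_rigid(t), grid = native_grid, method = "nearest")
}

#' Pipeline configuration for [segment_volume()]
#'
#' @param template Template [volume3d()] or `NULL` to segment on the
#'   native grid.
#' @param backend Registration backend (see [register_to_template()]).
#' @param pad Test-time padding per face (default 24; training uses 16).
#' @param landmarks `histogram_landmarks` or `NULL` to learn them from the
#'   input volume itself.
#' @param patch_size,overlap,mode,n_patches,seed Passed to
#'   [plan_patches()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(template = NULL, backend = "identity",
                            pad = 24L, landmarks = NULL, patch_size = 96L,
                            overlap = 12L, mode = "grid", n_patches = 128L,
                            seed = 1L) {
  structure(list(template = template, backend = backend,
                 pad = as.integer(pad), landmarks = landmarks,
                 patch_size = as.integer(patch_size),
                 overlap = as.integer(overlap), mode = mode,
                 n_patches = as.integer(n_patches), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Segment a whole volume
#'
#' The end-to-end path: register to the template, zero-pad, standardize
#' intensities, plan patches, predict per patch, fuse with OR-logical
#' label fusion, crop the padding, and map back to native space.
#' Deterministic given the checkpoint and configuration.
#'
#' @param ckpt `sau_weights` or `sau_checkpoint`.
#' @param raw Native-space [volume3d()].
#' @param schema [label_schema()] matching the checkpoint's class count.
#' @param opts A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return Native-space [label_volume()].
#' @export
segment_volume <- function(ckpt, raw, schema, opts = pipeline_config(),
                           verbose = FALSE) {
  w <- if (inherits(ckpt, "sau_checkpoint")) ckpt$weights else ckpt
  if (n_classes(schema) != w$cfg$n_classes)
    stop("schema class count does not match checkpoint")
  say <- function(...) if (verbose) message(sprintf(...))
  template <- if (is.null(opts$template)) raw else opts$template
  say("registering to template (%s backend)", class(opts$backend)[1])
  reg <- register_to_template(raw, template, opts$backend)
  say("padding by %d", opts$pad)
  padded <- pad_volume(reg$volume, opts$pad)
  lm <- if (is.null(opts$landmarks)) learn_landmarks(list(reg$volume)) else
    opts$landmarks
  padded <- standardize_intensity(padded, lm)
  plan <- plan_patches(dim(padded), opts$patch_size, opts$overlap,
                       opts$mode, opts$n_patches, opts$seed)
  say("predicting %d patches", nrow(plan$origins))
  preds <- predict_patches(w, padded, plan)
  fused <- fuse_or_logical(preds, plan, schema, padded$spacing,
                           padded$affine)
  say("fusing + back-registration")
  fused <- crop_volume(fused, opts$pad)
  to_native_space(fused, reg$transform, raw)
}
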