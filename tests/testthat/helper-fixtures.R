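# Shared fixtures: everything is generated in code at test time.

# A tiny two-tissue phantom spec on a small grid (fast, deterministic).
tiny_phantom_spec <- function(grid = 24L, noise_sd = 0, bias = 0, seed = 1L,
                              sd_tissue = 0) {
  g <- rep_len(grid, 3)
  ctr <- (g - 1) / 2
  tissues <- rbind(
    data.frame(label = 1, cx = ctr[1], cy = ctr[2], cz = ctr[3],
               ax = g[1] * 0.35, ay = g[2] * 0.35, az = g[3] * 0.35,
               mean = 0.8, sd = sd_tissue),
    data.frame(label = 2, cx = ctr[1], cy = ctr[2], cz = ctr[3],
               ax = g[1] * 0.15, ay = g[2] * 0.15, az = g[3] * 0.15,
               mean = 0.3, sd = sd_tissue))
  phantom_spec(g, tissues, noise_sd = noise_sd, bias_amplitude = bias,
               seed = seed)
}

# A small network configuration cheap enough for per-test forward passes.
tiny_net_config <- function(n_classes = 3L) {
  network_config(levels = 2L, base_channels = 4L, norm_groups = 2L,
                 n_classes = n_classes, conv_units = 1L)
}

# Solid sphere mask in a cubic grid (logical array).
sphere_mask <- function(n, radius, center = (n - 1) / 2) {
  idx <- seq_len(n) - 1
  d2 <- outer(outer((idx - center)^2, (idx - center)^2, "+"),
              (idx - center)^2, "+")
  d2 <= radius^2
}

# Direct R re-implementation of ASSD from its definition (explicit
# 6-neighbor boundary scan, full all-pairs distance matrix), used as the
# independent oracle against the compiled distance kernel.
assd_oracle <- function(ma, mb, spacing = c(1, 1, 1)) {
  bnd <- function(m) {
    d <- dim(m)
    keep <- matrix(NA_integer_, 0, 3)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!m[i, j, k]) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else FALSE,
        if (i < d[1]) m[i + 1, j, k] else FALSE,
        if (j > 1) m[i, j - 1, k] else FALSE,
        if (j < d[2]) m[i, j + 1, k] else FALSE,
        if (k > 1) m[i, j, k - 1] else FALSE,
        if (k < d[3]) m[i, j, k + 1] else FALSE)
      if (!all(nb)) keep <- rbind(keep, c(i, j, k) - 1L)
    }
    keep
  }
  ba <- sweep(bnd(ma), 2, spacing, "*")
  bb <- sweep(bnd(mb), 2, spacing, "*")
  dmat <- sqrt(outer(ba[, 1], bb[, 1], "-")^2 +
                 outer(ba[, 2], bb[, 2], "-")^2 +
                 outer(ba[, 3], bb[, 3], "-")^2)
  (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) /
    (nrow(ba) + nrow(bb))
}
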