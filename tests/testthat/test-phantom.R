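test_that("noise-free single-tissue phantom is exactly the tissue mean", {
  g <- c(20, 20, 20)
  tis <- data.frame(label = 1, cx = 9.5, cy = 9.5, cz = 9.5, ax = 6, ay = 6,
                    az = 6, mean = 100, sd = 0)
  ph <- make_phantom(phantom_spec(g, tis, noise_sd = 0, bias_amplitude = 0))
  fg <- ph$labels$data == 1L
  expect_true(all(ph$volume$data[fg] == 100))
  expect_true(all(ph$volume$data[!fg] == 0))
})

test_that("phantom generation is bit-identical under the same spec", {
  spec <- default_phantom_spec(grid = c(32, 32, 32), seed = 7)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  # a different seed changes noise but not label geometry
  spec2 <- spec; spec2$seed <- 8L
  c2 <- make_phantom(spec2)
  expect_identical(c2$labels$data, a$labels$data)
  expect_false(identical(c2$volume$data, a$volume$data))
})

test_that("painted label counts match a brute-force ellipsoid oracle", {
  spec <- default_phantom_spec(grid = c(64, 64, 64), seed = 3)
  lab <- make_phantom(spec)$labels$data
  # independent voxel-wise membership test, honoring paint order
  g <- spec$grid
  co <- as.matrix(expand.grid(x = 0:(g[1] - 1), y = 0:(g[2] - 1),
                              z = 0:(g[3] - 1)))
  expected <- integer(nrow(co))
  for (t in seq_len(nrow(spec$tissues))) {
    tt <- spec$tissues[t, ]
    inside <- ((co[, 1] - tt$cx) / tt$ax)^2 + ((co[, 2] - tt$cy) / tt$ay)^2 +
      ((co[, 3] - tt$cz) / tt$az)^2 <= 1
    expected[inside] <- tt$label
  }
  expect_identical(as.vector(lab), as.integer(expected))
})

test_that("ground-truth volumes agree with analytic ellipsoid volumes", {
  g <- c(48, 48, 48)
  tis <- data.frame(label = 1, cx = 23.5, cy = 23.5, cz = 23.5,
                    ax = 8, ay = 10, az = 6, mean = 1, sd = 0)
  ph <- make_phantom(phantom_spec(g, tis, noise_sd = 0, bias_amplitude = 0))
  vox <- sum(ph$labels$data == 1L)
  analytic <- 4 / 3 * pi * 8 * 10 * 6
  expect_lt(abs(vox - analytic) / analytic, 0.05)
})

test_that("degrade_labels with zero radius and zero flips is the identity", {
  ph <- make_phantom(tiny_phantom_spec())
  d <- degradation_spec(dilate_radius = 0L, flip_prob = 0)
  expect_identical(degrade_labels(ph$labels, d)$data, ph$labels$data)
})

test_that("flips only touch boundary voxels and preserve the label set", {
  ph <- make_phantom(tiny_phantom_spec(grid = 32L))
  lab <- ph$labels$data
  d <- degradation_spec(dilate_radius = 0L, flip_prob = 1, seed = 5)
  out <- degrade_labels(ph$labels, d)$data
  changed <- out != lab
  bnd <- sauseg:::boundary_mask(lab)
  expect_true(all(changed[!bnd] == FALSE)) # interior untouched
  expect_true(all(unique(as.vector(out)) %in% unique(as.vector(lab))))
})

test_that("dilation radius 1 Dice matches an independent voxel count", {
  n <- 48
  m <- sphere_mask(n, 20)
  sc <- label_schema(0:1, c("background", "s"))
  lv <- label_volume(array(as.integer(m), dim(m)), sc)
  out <- degrade_labels(lv, degradation_spec(dilate_radius = 1L,
                                             flip_prob = 0))
  m2 <- out$data == 1L
  # independent computation from voxel enumeration
  expected <- 2 * sum(m & m2) / (sum(m) + sum(m2))
  expect_equal(dice(structure_mask(lv, 1), structure_mask(out, 1)), expected)
  expect_lt(expected, 1)
  expect_true(all(m2[m])) # dilation is a superset
})

test_that("paired set shares anatomy and honors the pair count", {
  spec <- tiny_phantom_spec(noise_sd = 0.03, seed = 2)
  pairs <- make_paired_set(spec, n_pairs = 3, jitter_deg = 0, jitter_mm = 0)
  expect_length(pairs, 3)
  # jitter 0 and independent noise: same geometry, different intensities
  expect_false(identical(pairs[[1]]$scan1$data, pairs[[1]]$scan2$data))
  # anatomy identical across the pair by construction (shared labels)
  expect_s3_class(pairs[[1]]$labels, "label_volume")
  # identical seeds + zero noise: identical pair
  spec0 <- tiny_phantom_spec(noise_sd = 0, seed = 2)
  p0 <- make_paired_set(spec0, 1, jitter_deg = 0, jitter_mm = 0)
  expect_identical(p0[[1]]$scan1$data, p0[[1]]$scan2$data)
})

test_that("multicenter set renders one anatomy under site transforms", {
  spec <- tiny_phantom_spec(noise_sd = 0, seed = 4)
  mc <- make_multicenter_set(spec, n_sites = 12)
  expect_length(mc$scans, 12)
  # identity transforms and zero noise give identical volumes
  mc0 <- make_multicenter_set(spec, n_sites = 3, scales = 1, offsets = 0,
                              noise_sds = 0)
  expect_identical(mc0$scans[[1]]$data, mc0$scans[[2]]$data)
  expect_identical(mc0$scans[[2]]$data, mc0$scans[[3]]$data)
  # intensity scaling leaves geometry (labels) untouched
  mc2 <- make_multicenter_set(spec, n_sites = 2, scales = c(1, 2),
                              noise_sds = 0)
  expect_equal(mc2$scans[[2]]$data, mc2$scans[[1]]$data * 2)
})

test_that("out-of-grid ellipsoids are rejected", {
  tis <- data.frame(label = 1, cx = 2, cy = 2, cz = 2, ax = 5, ay = 2,
                    az = 2, mean = 1, sd = 0)
  expect_error(phantom_spec(c(8, 8, 8), tis), "outside the grid")
})
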