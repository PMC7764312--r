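test_that("identity backend returns the template grid and identity transform", {
  ph <- make_phantom(tiny_phantom_spec())
  out <- register_to_template(ph$volume, ph$volume, backend = "identity")
  expect_equal(out$volume$data, ph$volume$data)
  expect_equal(out$transform$angles, c(0, 0, 0))
  expect_equal(out$transform$translation, c(0, 0, 0))
})

test_that("oracle backend recovers a known rotation within interpolation error", {
  # smooth image (MRI-like content, no razor edges) so the error measures
  # the transform, not edge ringing of the double interpolation
  idx <- seq_len(32) - 16
  g <- exp(-outer(outer(idx^2, idx^2, "+"), idx^2, "+") / (2 * 8^2))
  v <- volume3d(0.8 * g + 0.1)
  ctr <- (dim(v$data) - 1) / 2 * v$spacing
  tr <- rigid_transform(angles = c(5, 0, 0), center = ctr)
  # moving image: template rotated away by the inverse of tr
  moving <- apply_rigid(v, invert_rigid(tr))
  rec <- register_to_template(moving, v, backend = tr)
  rng <- diff(range(v$data))
  inner <- 5:28 # ignore borders clipped by resampling
  err <- mean(abs(rec$volume$data[inner, inner, inner] -
                    v$data[inner, inner, inner]))
  expect_lt(err, 0.02 * rng)
  expect_equal(dim(rec$volume$data), dim(v$data))
})

test_that("padding adds zero faces and preserves world coordinates", {
  v <- volume3d(array(runif(6^3), c(6, 6, 6)), spacing = c(1, 1.5, 2))
  p <- pad_volume(v, c(2, 3, 4))
  expect_equal(dim(p$data), c(10, 12, 14))
  expect_equal(p$data[3, 4, 5], v$data[1, 1, 1])
  expect_true(all(p$data[1:2, , ] == 0))
  # world coordinate of original voxel (0,0,0) is unchanged
  w_old <- v$affine %*% c(0, 0, 0, 1)
  w_new <- p$affine %*% c(2, 3, 4, 1)
  expect_equal(w_new, w_old)
  # test-time padding arithmetic: 256 + 2*24 = 304 per axis
  expect_equal(6 + 2 * 2, 10)
  # pad 0 is the identity; pad-then-crop is the identity
  expect_identical(pad_volume(v, 0)$data, v$data)
  rt <- crop_volume(p, c(2, 3, 4))
  expect_equal(rt$data, v$data)
  expect_equal(rt$affine, v$affine)
})

test_that("single-volume landmarks map the volume onto itself", {
  ph <- make_phantom(tiny_phantom_spec(noise_sd = 0.05, seed = 9))
  lm <- learn_landmarks(list(ph$volume))
  out <- standardize_intensity(ph$volume, lm)
  fg <- ph$volume$data > 0
  # percentiles map to themselves up to the linear rescaling to [0,1]
  q_in <- quantile(ph$volume$data[fg], lm$percentiles / 100, names = FALSE)
  mapped <- (q_in - q_in[1]) / (q_in[length(q_in)] - q_in[1])
  q_out <- quantile(out$data[fg], lm$percentiles / 100, names = FALSE)
  expect_equal(q_out, mapped, tolerance = 0.02)
  # idempotence: standardizing the standardized volume changes little
  out2 <- standardize_intensity(out, learn_landmarks(list(out)))
  expect_lt(mean(abs(out2$data[fg] - out$data[fg])), 0.01)
})

test_that("two identical volumes learn the same landmarks as one", {
  ph <- make_phantom(tiny_phantom_spec(noise_sd = 0.02, seed = 3))
  lm1 <- learn_landmarks(list(ph$volume))
  lm2 <- learn_landmarks(list(ph$volume, ph$volume))
  expect_equal(lm1$standard, lm2$standard)
})

test_that("landmark means match an explicit percentile oracle", {
  set.seed(11)
  # foregrounds uniform on (0,100] and (0,200]
  v1 <- volume3d(array(runif(20^3, 1e-6, 100), c(20, 20, 20)))
  v2 <- volume3d(array(runif(20^3, 1e-6, 200), c(20, 20, 20)))
  pct <- c(1, 50, 99)
  lm <- learn_landmarks(list(v1, v2), percentiles = pct)
  oracle <- rowMeans(sapply(list(v1, v2), function(v) {
    q <- quantile(v$data[v$data > 0], pct / 100, names = FALSE)
    (q - q[1]) / (q[3] - q[1])
  }))
  expect_equal(lm$standard, oracle, tolerance = 1e-12)
})

test_that("standardization is monotone and nearly scale-invariant", {
  ph <- make_phantom(tiny_phantom_spec(noise_sd = 0.05, seed = 5))
  v1 <- ph$volume
  v2 <- volume3d(v1$data * 2, v1$spacing, v1$affine)
  lm <- learn_landmarks(list(v1))
  s1 <- standardize_intensity(v1, lm)
  s2 <- standardize_intensity(v2, lm)
  fg <- v1$data > 0
  m1 <- median(s1$data[fg]); m2 <- median(s2$data[fg])
  expect_lt(abs(m1 - m2) / max(abs(m1), 1e-9), 0.01)
  # monotonicity on sampled voxel pairs
  set.seed(1)
  idx <- sample(which(fg), 500)
  o <- order(v1$data[idx])
  expect_true(all(diff(s1$data[idx][o]) >= -1e-12))
})

test_that("degenerate foregrounds are rejected", {
  flat <- volume3d(array(1, c(6, 6, 6)))
  lm <- learn_landmarks(list(volume3d(array(runif(6^3), c(6, 6, 6)))))
  expect_error(standardize_intensity(flat, lm), "degenerate")
  none <- volume3d(array(0, c(6, 6, 6)) - 1)
  expect_error(learn_landmarks(list(none)), "foreground")
})
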