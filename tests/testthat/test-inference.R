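test_that("grid planning tiles with the published stride and clamps", {
  # small instance: 40-voxel volume, 16-voxel patches, 4-voxel overlap
  plan <- plan_patches(c(40, 40, 40), 16L, 4L, mode = "grid")
  expect_equal(sort(unique(plan$origins[, 1])), c(0, 12, 24))
  expect_equal(nrow(plan$origins), 27)
  expect_true(plan_covers(plan))
  # volume equal to patch: a single patch at the origin
  p1 <- plan_patches(c(16, 16, 16), 16L)
  expect_equal(nrow(p1$origins), 1)
  expect_equal(p1$origins[1, ], c(0, 0, 0))
  expect_error(plan_patches(c(8, 8, 8), 16L), "impossible")
})

test_that("random planning draws the published count and repairs coverage", {
  plan <- plan_patches(c(48, 48, 48), 16L, 4L, mode = "random",
                       n_patches = 128L, seed = 5)
  expect_gte(nrow(plan$origins), 128)
  expect_true(plan_covers(plan))
  expect_equal(plan$n_random, 128L)
  # coverage repair engages when few random patches are drawn
  plan2 <- plan_patches(c(48, 48, 48), 16L, 4L, mode = "random",
                        n_patches = 2L, seed = 5)
  expect_gt(nrow(plan2$origins), 2)
  expect_true(plan_covers(plan2))
})

make_const_patch <- function(s, N, probs) {
  p <- array(rep(probs, each = s^3), c(s, s, s, N))
  p
}

test_that("single-patch fusion is the identity on the argmax", {
  sc <- label_schema(0:2, c("background", "a", "b"))
  plan <- plan_patches(c(8, 8, 8), 8L)
  set.seed(6)
  pr <- array(runif(8^3 * 3), c(8, 8, 8, 3))
  pr <- pr / array(rep(apply(pr, 1:3, sum), 3), dim(pr))
  fused <- fuse_or_logical(list(pr), plan, sc)
  am <- apply(pr, 1:3, which.max) - 1L
  expect_identical(fused$data, array(as.integer(am), c(8, 8, 8)))
})

test_that("fusion is permutation-invariant and preserves agreement", {
  sc <- label_schema(0:2, c("background", "a", "b"))
  plan <- plan_patches(c(12, 8, 8), 8L, 4L)
  expect_equal(nrow(plan$origins), 2)
  set.seed(7)
  mk <- function() {
    pr <- array(runif(8^3 * 3), c(8, 8, 8, 3))
    pr / array(rep(apply(pr, 1:3, sum), 3), dim(pr))
  }
  p1 <- mk(); p2 <- mk()
  f12 <- fuse_or_logical(list(p1, p2), plan, sc)
  plan_rev <- plan
  plan_rev$origins <- plan$origins[2:1, , drop = FALSE]
  f21 <- fuse_or_logical(list(p2, p1), plan_rev, sc)
  expect_identical(f12$data, f21$data)
  # two overlapping patches agreeing everywhere preserve the agreement
  psame <- plan_patches(c(8, 8, 8), 8L, mode = "grid")
  psame$origins <- rbind(psame$origins, psame$origins)
  fsame <- fuse_or_logical(list(p1, p1), psame, sc)
  am <- apply(p1, 1:3, which.max) - 1L
  expect_identical(fsame$data, array(as.integer(am), c(8, 8, 8)))
})

test_that("background loses to any non-background claim; conflicts use summed probability", {
  sc <- label_schema(0:3, c("background", "a", "b", "c"))
  plan <- plan_patches(c(4, 4, 4), 4L)
  plan$origins <- rbind(c(0, 0, 0), c(0, 0, 0)) # two patches, full overlap
  # patch A: confident background (p = 0.9); patch B: label 3 at p = 0.6
  pa <- make_const_patch(4, 4, c(0.9, 0.04, 0.03, 0.03))
  pb <- make_const_patch(4, 4, c(0.3, 0.05, 0.05, 0.6))
  fused <- fuse_or_logical(list(pa, pb), plan, sc)
  expect_true(all(fused$data == 3L)) # non-background wins over background
  # conflicting non-background labels: largest summed probability wins
  pc <- make_const_patch(4, 4, c(0.1, 0.8, 0.05, 0.05))
  pd <- make_const_patch(4, 4, c(0.1, 0.0, 0.85, 0.05))
  fused2 <- fuse_or_logical(list(pc, pd), plan, sc)
  # label 1 sum 0.8, label 2 sum 0.9 -> label 2
  expect_true(all(fused2$data == 2L))
  # tie in summed probability: smallest label id wins
  pe <- make_const_patch(4, 4, c(0.2, 0.8, 0.0, 0.0))
  pf <- make_const_patch(4, 4, c(0.2, 0.0, 0.8, 0.0))
  fused3 <- fuse_or_logical(list(pe, pf), plan, sc)
  expect_true(all(fused3$data == 1L))
})

test_that("native-space mapping round-trips a rotated registration", {
  ph <- make_phantom(default_phantom_spec(grid = c(48, 48, 48), seed = 5,
                                          noise_sd = 0))
  v <- ph$volume
  ctr <- (dim(v$data) - 1) / 2 * v$spacing
  tr <- rigid_transform(angles = c(0, 0, 5), center = ctr)
  # pretend the labels were produced in template space under tr
  template_labels <- apply_rigid(ph$labels, tr)
  native <- to_native_space(template_labels, tr, v)
  for (id in setdiff(unique(as.vector(ph$labels$data)), 0L)) {
    mt <- structure_mask(ph$labels, id)
    mn <- structure_mask(native, id)
    expect_gte(dice(mt, mn), 0.9)
  }
  expect_true(all(unique(as.vector(native$data)) %in%
                    unique(as.vector(ph$labels$data))))
  # identity transform changes nothing
  same <- to_native_space(ph$labels, rigid_transform(), v)
  expect_identical(same$data, ph$labels$data)
  expect_error(to_native_space(ph$labels, NULL, v), "missing")
})

test_that("segment_volume composes the pipeline deterministically", {
  spec <- tiny_phantom_spec(grid = 24L, noise_sd = 0.02, seed = 12)
  ph <- make_phantom(spec)
  cfg <- network_config(levels = 2, base_channels = 8,
                        n_classes = n_classes(spec$schema))
  w <- init_network(cfg, seed = 1)
  opts <- pipeline_config(pad = 4L, patch_size = 16L, overlap = 4L)
  seg1 <- segment_volume(w, ph$volume, spec$schema, opts)
  seg2 <- segment_volume(w, ph$volume, spec$schema, opts)
  expect_identical(seg1$data, seg2$data)
  expect_equal(dim(seg1$data), dim(ph$volume$data))
  expect_s3_class(seg1, "label_volume")
  # schema class count must match the checkpoint
  expect_error(segment_volume(w, ph$volume, default_schema(), opts),
               "class count")
})
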