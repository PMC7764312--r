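test_that("dice matches voxel-enumeration cases", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1:2, 1:2] <- TRUE          # |A| = 8
  b[1:2, 1:2, 2:3] <- TRUE          # |B| = 8, 4 shared
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  d <- array(FALSE, c(4, 4, 4)); d[4, 4, 4] <- TRUE
  expect_equal(dice(a, d), 0)       # disjoint
  expect_equal(dice(a & FALSE, b & FALSE), 1) # both empty
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "mismatch")
  # symmetry
  expect_equal(dice(a, b), dice(b, a))
})

test_that("boundary extraction follows the 6-connected definition", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  expect_equal(boundary(m), matrix(c(2, 2, 2), 1, 3,
                                   dimnames = list(NULL, NULL)),
               ignore_attr = TRUE)
  cube <- array(FALSE, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- TRUE
  b <- boundary(cube)
  expect_equal(nrow(b), 26) # all but the center voxel
  # boundary is a subset of the mask
  expect_true(all(cube[b + 1]))
  expect_error(boundary(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("assd matches hand computations and is symmetric", {
  a <- array(FALSE, c(8, 4, 4)); b <- a
  a[2, 2, 2] <- TRUE
  b[5, 2, 2] <- TRUE # 3 voxels apart at 1 mm spacing
  expect_equal(assd(a, b), 3)
  expect_equal(assd(b, a), 3)
  expect_equal(assd(a, a), 0)
  expect_error(assd(a, a & FALSE), "empty")
  # anisotropic spacing is honored
  ma <- structure_mask(array(as.integer(a), dim(a)) , 1, spacing = c(2, 1, 1))
  mb <- structure_mask(array(as.integer(b), dim(b)) , 1, spacing = c(2, 1, 1))
  expect_equal(assd(ma, mb), 6)
})

test_that("assd equals the brute-force oracle on random masks", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    a <- array(runif(n^3) < 0.3, c(n, n, n))
    b <- array(runif(n^3) < 0.3, c(n, n, n))
    if (!any(a) || !any(b)) next
    expect_equal(assd(a, b), assd_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("volume_cc multiplies count by voxel volume", {
  m <- array(FALSE, c(20, 20, 20)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(volume_cc(structure_mask(array(as.integer(m), dim(m)), 1)), 1)
  expect_equal(volume_cc(structure_mask(array(as.integer(m), dim(m)), 1,
                                        spacing = c(1, 1, 1.2))), 1.2)
  expect_equal(volume_cc(structure_mask(array(0L, c(4, 4, 4)), 1)), 0)
})

test_that("coefficients of variation match the hand-computed examples", {
  expect_equal(cv_intra_session(matrix(c(100, 102), 1, 2)), 0.990099,
               tolerance = 1e-6)
  expect_equal(cv_intra_session(rbind(c(100, 102), c(200, 196))), 1.000099,
               tolerance = 1e-4)
  expect_equal(cv_intra_session(rbind(c(5, 5), c(7, 7))), 0)
  expect_equal(cv_total(c(10, 12, 14)), 13.6083, tolerance = 1e-4)
  expect_equal(cv_total(c(1, 3)), 50)
  expect_equal(cv_total(rep(4, 6)), 0)
  # scale invariance
  set.seed(1)
  x <- matrix(runif(20, 50, 150), 10, 2)
  expect_equal(cv_intra_session(x), cv_intra_session(3.7 * x))
  expect_equal(cv_total(x[, 1]), cv_total(3.7 * x[, 1]))
  expect_error(cv_intra_session(matrix(0, 1, 2)), "positive")
  expect_error(cv_total(5), "at least 2")
})

test_that("evaluation report covers presence/absence contracts", {
  sc <- label_schema(0:3, c("background", "a", "b", "c"))
  truth <- array(0L, c(8, 8, 8)); truth[2:4, 2:4, 2:4] <- 1L
  truth[6:7, 6:7, 6:7] <- 2L
  pred <- truth
  pred[2, 2, 2] <- 0L # slightly degrade label 1, keep 2, 3 absent in both
  tv <- label_volume(truth, sc)
  pv <- label_volume(pred, sc)
  rep <- evaluate_report(pv, tv)
  expect_equal(rep$flag[rep$id == 3], "absent_both")
  expect_equal(rep$dice[rep$id == 3], 1)
  expect_true(is.na(rep$assd_mm[rep$id == 3]))
  expect_equal(rep$dice[rep$id == 2], 1)
  expect_lt(rep$dice[rep$id == 1], 1)
  # identical volumes: all Dice 1, ASSD 0
  rep2 <- evaluate_report(tv, tv, ids = 1:2)
  expect_true(all(rep2$dice == 1))
  expect_true(all(rep2$assd_mm == 0))
  # summary is the unweighted mean of rows
  s <- attr(rep, "summary")
  expect_equal(unname(s["dice_mean"]), mean(rep$dice))
  # per-structure values equal independent recomputation
  expect_equal(rep$dice[rep$id == 1],
               dice(structure_mask(pv, 1), structure_mask(tv, 1)))
  expect_equal(rep$assd_mm[rep$id == 1],
               assd(structure_mask(pv, 1), structure_mask(tv, 1)))
  # absent from exactly one volume
  pred2 <- truth; pred2[truth == 2L] <- 0L
  rep3 <- evaluate_report(label_volume(pred2, sc), tv, ids = 2)
  expect_equal(rep3$dice, 0)
  expect_equal(rep3$flag, "absent_one")
})
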