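test_that("evonorm_s0 matches the hand-computed two-value case", {
  # one group holding values +1 and -1 in equal numbers: group mean 0,
  # sd 1; with gamma 1, beta 0, v 0 the gate is sigmoid(0) = 1/2, so
  # y = 0.5 * x / sqrt(1 + eps)
  x <- array(rep(c(1, -1), each = 4), c(2, 2, 2, 1))
  y <- evonorm_s0(x, gamma = 1, beta = 0, v = 0, groups = 1, eps = 0)
  expect_equal(y, 0.5 * x, tolerance = 1e-12)
})

test_that("evonorm_s0 is finite on constant input and preserves shape", {
  x <- array(3, c(4, 4, 4, 6))
  y <- evonorm_s0(x, gamma = rep(1, 6), beta = rep(0, 6), v = rep(1, 6),
                  groups = 3)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(evonorm_s0(x, rep(1, 6), rep(0, 6), rep(1, 6), groups = 4),
               "divisible")
})

test_that("compiled evonorm agrees with the plain R reference", {
  set.seed(5)
  x <- array(rnorm(6^3 * 4 * 2), c(6, 6, 6, 4, 2))
  gam <- runif(4, 0.5, 2); bet <- rnorm(4); v <- rnorm(4)
  a <- sauseg:::cpp_evonorm_forward(x, gam, bet, v, 2L, 1e-5)$y
  b <- sauseg:::evonorm_forward(x, gam, bet, v, 2L, 1e-5)$y
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("conv_unit preserves spatial shape and conv is linear", {
  cfg <- tiny_net_config()
  w <- init_network(cfg, seed = 1)
  wu <- w$nodes$n0_0$convs[[1]]
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  y <- conv_unit(x, wu, cfg)
  expect_equal(dim(y), c(8, 8, 8, 4))
  # linearity of the convolution stage (before normalization)
  y1 <- sauseg:::cpp_conv3d_forward(sauseg:::ensure5d(x), wu$w, 0 * wu$b)
  y2 <- sauseg:::cpp_conv3d_forward(sauseg:::ensure5d(3 * x), wu$w, 0 * wu$b)
  expect_equal(y2, 3 * y1, tolerance = 1e-5)
})

test_that("split attention instantiates K*R parallel feature groups", {
  cfg <- network_config(levels = 2, base_channels = 8, n_classes = 3)
  w <- init_network(cfg, seed = 2)
  rn <- w$nodes$n0_1$resnest
  expect_length(rn$splits, cfg$cardinality * cfg$radix) # G = 4 by default
  expect_length(rn$att, cfg$cardinality)
  # output channel count is C / R after cardinal concatenation
  x <- array(rnorm(8^3 * 8), c(8, 8, 8, 8))
  sa <- split_attention(x, cfg, rn)
  expect_equal(dim(sa)[4], 8 / cfg$radix)
})

test_that("radix attention weights sum to one per channel", {
  set.seed(6)
  a <- sauseg:::tp_radix_softmax(sauseg:::nd(array(rnorm(5 * 3 * 4),
                                                   c(5, 3, 4))))
  sums <- apply(sauseg:::nd_value(a), c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("identical splits collapse the attention to a single split", {
  cfg <- network_config(levels = 2, base_channels = 8, n_classes = 3)
  w <- init_network(cfg, seed = 3)
  rn <- w$nodes$n0_1$resnest
  # force every split branch identical and the input groups identical
  for (g in 2:4) rn$splits[[g]] <- rn$splits[[1]]
  rn$att[[2]] <- rn$att[[1]]
  xg <- array(rnorm(6^3 * 2), c(6, 6, 6, 2))
  x <- array(0, c(6, 6, 6, 8))
  for (g in 1:4) x[, , , (g - 1) * 2 + 1:2] <- xg
  sa <- split_attention(x, cfg, rn)
  # with identical split features U, weights (1/2, 1/2) give sum a_r U = U
  U <- conv_unit(xg, rn$splits[[1]], cfg)
  expect_equal(sa[, , , 1:2], U, tolerance = 1e-6)
  expect_equal(sa[, , , 3:4], U, tolerance = 1e-6)
})

test_that("resnest block reduces to the shortcut when weights vanish", {
  cfg <- network_config(levels = 2, base_channels = 8, n_classes = 3)
  w <- init_network(cfg, seed = 4)
  rn <- w$nodes$n0_1$resnest
  rn$proj$w[] <- 0
  rn$proj$b[] <- 0
  x <- array(rnorm(8^3 * 8), c(8, 8, 8, 8))
  out <- resnest_block(x, cfg, rn)
  expect_equal(out, x, tolerance = 1e-12) # identity shortcut
  expect_equal(dim(out)[4], 8)
})

test_that("the node lattice enumerates exactly the valid addresses", {
  cfg2 <- network_config(levels = 2, base_channels = 8, n_classes = 3)
  nodes <- node_addresses(cfg2)
  expect_equal(nrow(nodes), 3)
  expect_setequal(paste(nodes$p, nodes$q), c("0 0", "1 0", "0 1"))
  cfg4 <- network_config(levels = 4)
  expect_equal(nrow(node_addresses(cfg4)), 10) # P(P+1)/2
})

test_that("decoder nodes concatenate all same-level predecessors", {
  cfg <- network_config(levels = 3, base_channels = 8, n_classes = 3)
  w <- init_network(cfg, seed = 5)
  # input channels of node (0,2)'s first conv = (q+1) * c0 = 3 * 8
  expect_equal(dim(w$nodes$n0_2$convs[[1]]$w)[4], 24)
  # dense connectivity is real: x^{0,0} reaches (0,2)
  x00 <- array(rnorm(8^3 * 8), c(8, 8, 8, 8, 1))
  x01 <- array(rnorm(8^3 * 8), c(8, 8, 8, 8, 1))
  deep <- array(rnorm(4^3 * 16), c(4, 4, 4, 16, 1))
  out1 <- node_forward(0, 2, list(x00, x01, deep), cfg, w$nodes$n0_2)
  out2 <- node_forward(0, 2, list(x00 + 1, x01, deep), cfg, w$nodes$n0_2)
  expect_false(isTRUE(all.equal(out1, out2)))
})

test_that("classifier emits N softmax-normalized channels", {
  cfg <- network_config(levels = 2, base_channels = 8) # default N = 34
  w <- init_network(cfg, seed = 6)
  x <- array(rnorm(4^3 * 8), c(4, 4, 4, 8))
  p <- classifier(x, w$classifier)
  expect_equal(dim(p)[4], 34)
  expect_true(all(abs(apply(p, 1:3, sum) - 1) < 1e-6))
  # all-equal logits give the uniform distribution
  w0 <- w$classifier
  w0$w[] <- 0
  w0$b[] <- 0
  p0 <- classifier(x, w0)
  expect_equal(as.vector(p0), rep(1 / 34, length(p0)), tolerance = 1e-12)
})

test_that("full forward keeps input resolution and is deterministic", {
  cfg <- desk_network_config(n_classes = 9L)
  w <- init_network(cfg, seed = 7)
  x <- array(rnorm(16^3), c(16, 16, 16))
  p1 <- sau_forward(w, x)
  p2 <- sau_forward(w, x)
  expect_equal(dim(p1), c(16, 16, 16, 9))
  expect_identical(p1, p2)
  expect_error(sau_forward(w, array(0, c(15, 15, 15))), "divisible")
  # scaled-down preset stays under one million parameters
  expect_lt(count_parameters(w), 1e6)
})
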