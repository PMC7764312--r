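# Gradient correctness of the tape against central finite differences.
# Convolutions run in single precision, so FD checks use loose-but-honest
# tolerances; the R-side ops are checked tightly.

fd_grad <- function(f, x, i, eps = 1e-5) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

test_that("conv3d satisfies the adjoint identity and matches FD for weights", {
  set.seed(1)
  x <- array(rnorm(5^3 * 3 * 2), c(5, 5, 5, 3, 2))
  w <- array(rnorm(27 * 3 * 2) * 0.3, c(3, 3, 3, 3, 2))
  b <- rnorm(2)
  gy <- array(rnorm(5^3 * 2 * 2), c(5, 5, 5, 2, 2))
  bk <- sauseg:::cpp_conv3d_backward(x, w, gy)
  lhs <- sum(sauseg:::cpp_conv3d_forward(x, w, 0 * b) * gy)
  expect_equal(sum(x * bk$gx), lhs, tolerance = 1e-5)
  f <- function(ww) sum(sauseg:::cpp_conv3d_forward(x, ww, b) * gy)
  for (i in sample(length(w), 5)) {
    expect_equal(bk$gw[i], fd_grad(f, w, i, 1e-3), tolerance = 5e-3)
  }
  expect_equal(bk$gb, apply(gy, 4, sum), tolerance = 1e-5)
})

test_that("evonorm gradients match finite differences exactly", {
  set.seed(2)
  x <- array(rnorm(4^3 * 4 * 2), c(4, 4, 4, 4, 2))
  gam <- runif(4, 0.5, 1.5); bet <- rnorm(4); v <- rnorm(4)
  g <- array(rnorm(length(x)), dim(x))
  fw <- sauseg:::cpp_evonorm_forward(x, gam, bet, v, 2L, 1e-5)
  bk <- sauseg:::cpp_evonorm_backward(g, x, gam, v, 2L, fw$mu, fw$sd)
  f_x <- function(xx) sum(sauseg:::cpp_evonorm_forward(xx, gam, bet, v, 2L,
                                                       1e-5)$y * g)
  for (i in sample(length(x), 6)) {
    expect_equal(bk$gx[i], fd_grad(f_x, x, i), tolerance = 1e-6)
  }
  f_v <- function(vv) sum(sauseg:::cpp_evonorm_forward(x, gam, bet, vv, 2L,
                                                       1e-5)$y * g)
  for (i in 1:4) expect_equal(bk$gv[i], fd_grad(f_v, v, i), tolerance = 1e-6)
})

test_that("pooling and upsampling are exact adjoints", {
  set.seed(3)
  x <- array(rnorm(4^3 * 2 * 2), c(4, 4, 4, 2, 2))
  fw <- sauseg:::cpp_maxpool2_forward(x)
  gy <- array(rnorm(length(fw$y)), dim(fw$y))
  gx <- sauseg:::cpp_maxpool2_backward(gy, fw$idx, dim(x))
  # gradient flows only to the argmax voxels
  expect_equal(sum(gx != 0), sum(gy != 0))
  up <- sauseg:::cpp_upsample2_forward(x)
  gu <- array(rnorm(length(up)), dim(up))
  gxu <- sauseg:::cpp_upsample2_backward(gu, dim(x))
  expect_equal(sum(up * gu), sum(x * gxu), tolerance = 1e-10)
})

test_that("vector-path ops (dense, bn, radix softmax, gap) backprop correctly", {
  set.seed(4)
  nd <- sauseg:::nd
  # dense
  x <- matrix(rnorm(6 * 3), 6, 3)
  W <- matrix(rnorm(4 * 6), 4, 6); b <- rnorm(4)
  xn <- nd(x); Wn <- nd(W)
  out <- sauseg:::tp_dense(xn, Wn, nd(b))
  loss <- sauseg:::nd(sum(out$value^2), list(out),
                      function(g) list(2 * out$value * g))
  sauseg:::nd_backward(loss)
  f <- function(WW) sum((WW %*% x + b)^2)
  for (i in sample(length(W), 4)) {
    expect_equal(Wn$grad[i], fd_grad(f, W, i), tolerance = 1e-6)
  }
  # bn (training mode, batch statistics)
  st <- sauseg:::new_bn_state(4)
  xb <- matrix(rnorm(4 * 8), 4, 8)
  xbn <- nd(xb)
  bno <- sauseg:::tp_bn_vec(xbn, nd(rep(1.3, 4)), nd(rep(0.2, 4)), st, TRUE)
  l2 <- sauseg:::nd(sum(bno$value^2), list(bno),
                    function(g) list(2 * bno$value * g))
  sauseg:::nd_backward(l2)
  fbn <- function(xx) {
    s2 <- sauseg:::new_bn_state(4)
    sum(sauseg:::nd_value(sauseg:::tp_bn_vec(nd(xx), nd(rep(1.3, 4)),
                                             nd(rep(0.2, 4)), s2, TRUE))^2)
  }
  for (i in sample(length(xb), 4)) {
    num <- fd_grad(fbn, xb, i)
    expect_lt(abs(xbn$grad[i] - num), 1e-6 + 1e-3 * abs(num))
  }
  # radix softmax
  a <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  an <- nd(a)
  sm <- sauseg:::tp_radix_softmax(an)
  tgtw <- array(rnorm(length(a)), dim(a))
  l3 <- sauseg:::nd(sum(sm$value * tgtw), list(sm),
                    function(g) list(tgtw * g))
  sauseg:::nd_backward(l3)
  fs <- function(aa) {
    sum(sauseg:::nd_value(sauseg:::tp_radix_softmax(nd(aa))) * tgtw)
  }
  for (i in sample(length(a), 4)) {
    expect_equal(an$grad[i], fd_grad(fs, a, i), tolerance = 1e-6)
  }
})

test_that("whole-graph gradients agree with finite differences", {
  cfg <- tiny_net_config()
  w <- init_network(cfg, seed = 2)
  set.seed(3)
  x <- array(rnorm(8^3), c(8, 8, 8, 1, 1))
  tgt <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8, 1))
  lossval <- function(ww) {
    net <- sauseg:::tp_network(sauseg:::nd(x), ww, training = FALSE)
    sauseg:::nd_value(sauseg:::tp_softmax_ce(net$logits, tgt))
  }
  net <- sauseg:::tp_network(sauseg:::nd(x), w, training = FALSE)
  loss <- sauseg:::tp_softmax_ce(net$logits, tgt)
  sauseg:::nd_backward(loss)
  params <- net$params
  set.seed(4)
  for (nm in sample(names(params), 6)) {
    node <- params[[nm]]
    i <- sample(length(node$value), 1)
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    perturb <- function(delta) {
      rec <- function(obj, p) {
        key <- p[1]
        ii <- suppressWarnings(as.integer(key))
        sel <- if (!is.na(ii) && is.null(names(obj))) ii else key
        if (length(p) == 1) {
          obj[[sel]][i] <- obj[[sel]][i] + delta
        } else {
          obj[[sel]] <- rec(obj[[sel]], p[-1])
        }
        obj
      }
      rec(w, path)
    }
    num <- (lossval(perturb(1e-3)) - lossval(perturb(-1e-3))) / 2e-3
    expect_equal(node$grad[i], num, tolerance = 2e-2,
                 label = paste("grad of", nm))
  }
})

test_that("one AdamW step on a fixed batch decreases the loss", {
  cfg <- tiny_net_config()
  w <- init_network(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 1, 2))
  tgt <- array(sample(0:2, 8^3 * 2, TRUE), c(8, 8, 8, 2))
  state <- sauseg:::new_adamw_state()
  net <- sauseg:::tp_network(sauseg:::nd(x), w, training = TRUE)
  l0 <- sauseg:::tp_softmax_ce(net$logits, tgt)
  sauseg:::nd_backward(l0)
  w2 <- sauseg:::adamw_step(w, list(nodes = net$wnodes$nodes,
                                    classifier = net$wnodes$classifier),
                            state, 1e-4, 0)
  net2 <- sauseg:::tp_network(sauseg:::nd(x), w2, training = TRUE)
  l1 <- sauseg:::tp_softmax_ce(net2$logits, tgt)
  expect_lt(sauseg:::nd_value(l1), sauseg:::nd_value(l0))
})
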