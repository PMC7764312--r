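# A minimal reverse-mode tape for the network graph.
#
# Nodes are environments holding a value, their parent nodes, and a
# backward closure mapping the node's output gradient to per-parent
# gradients. Creation order doubles as a topological order, so backward
# propagation is a single reverse sweep over reachable nodes. Only the
# operations the network needs are implemented; heavy kernels (convolution,
# pooling, upsampling) call into compiled code, the rest is vectorized R.

.nd_state <- new.env(parent = emptyenv())
.nd_state$id <- 0L

nd <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .nd_state$id <- .nd_state$id + 1L
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$id <- .nd_state$id
  class(e) <- "sau_node"
  e
}

is_node <- function(x) inherits(x, "sau_node")
as_node <- function(x) if (is_node(x)) x else nd(x)
nd_value <- function(x) if (is_node(x)) x$value else x

# Reverse sweep from `loss`; afterwards every reachable node carries its
# gradient in $grad. Leaf (parameter) nodes keep accumulated gradients.
nd_backward <- function(loss, seed = 1) {
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)),
               decreasing = TRUE)
  for (n in nodes) n$grad <- NULL
  loss$grad <- seed
  for (i in ord) {
    n <- nodes[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
    if (length(n$parents)) n$grad <- NULL # free activation gradients early
  }
  invisible(loss)
}

# ---- primitive ops ---------------------------------------------------------

tp_conv3d <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  y <- cpp_conv3d_forward(x$value, w$value, b$value)
  # a leaf data input (the image patch) never needs its gradient
  need_gx <- !(is.null(x$backfn) && length(x$parents) == 0L)
  nd(y, list(x, w, b), function(g) {
    bk <- cpp_conv3d_backward(x$value, w$value, g, need_gx)
    list(if (need_gx) bk$gx else NULL, bk$gw, bk$gb)
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# EvoNorm-S0: y = gamma * x * sigmoid(v x) / sqrt(var_group + eps) + beta.
# The group variance is taken over a contiguous channel group and all
# spatial positions, per sample.
evonorm_forward <- function(x, gamma, beta, v, groups, eps) {
  d <- dim(x)
  C <- d[4]; B <- if (length(d) > 4) d[5] else 1L
  if (C %% groups != 0) stop("channels not divisible by norm groups")
  xyz <- prod(d[1:3])
  cg <- C %/% groups
  m <- matrix(x, xyz * cg, groups * B)
  mu <- colMeans(m)
  var <- colMeans(m * m) - mu * mu
  s <- sqrt(pmax(var, 0) + eps)
  sexp <- rep(s, each = xyz * cg)
  vexp <- rep(rep(v, each = xyz), times = B)
  gexp <- rep(rep(gamma, each = xyz), times = B)
  bexp <- rep(rep(beta, each = xyz), times = B)
  sig <- sigmoid(vexp * as.vector(x))
  n <- as.vector(x) * sig
  y <- array(gexp * n / sexp + bexp, d)
  list(y = y, mu = mu, s = s, sig = sig, n = n, xyz = xyz, cg = cg,
       gexp = gexp, vexp = vexp)
}

evonorm_backward <- function(g, x, gamma, beta, v, groups, eps, cache) {
  d <- dim(x)
  C <- d[4]; B <- if (length(d) > 4) d[5] else 1L
  xyz <- cache$xyz; cg <- cache$cg
  M <- xyz * cg
  gv_ <- as.vector(g)
  xv <- as.vector(x)
  sexp <- rep(cache$s, each = M)
  muexp <- rep(cache$mu, each = M)
  # per-channel reductions: reshape (xyz, C*B) and sum over batch
  chan_sum <- function(z) {
    rowSums(matrix(colSums(matrix(z, xyz, C * B)), C, B))
  }
  ggamma <- chan_sum(gv_ * cache$n / sexp)
  gbeta <- chan_sum(gv_)
  gvpar <- chan_sum(gv_ * cache$gexp * xv * xv * cache$sig * (1 - cache$sig) /
                      sexp)
  # dL/dx: swish term plus variance term
  Tg <- colSums(matrix(gv_ * cache$gexp * cache$n, M, groups * B))
  Texp <- rep(Tg, each = M)
  dn_dx <- cache$sig * (1 + cache$vexp * xv * (1 - cache$sig))
  gx <- cache$gexp * dn_dx * gv_ / sexp -
    (xv - muexp) / (M * sexp^3) * Texp
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta, gv = gvpar)
}

tp_evonorm <- function(x, gamma, beta, v, groups, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  v <- as_node(v)
  fw <- cpp_evonorm_forward(x$value, gamma$value, beta$value, v$value,
                            groups, eps)
  nd(fw$y, list(x, gamma, beta, v), function(g) {
    bk <- cpp_evonorm_backward(g, x$value, gamma$value, v$value, groups,
                               fw$mu, fw$sd)
    list(bk$gx, bk$ggamma, bk$gbeta, bk$gv)
  })
}

tp_maxpool2 <- function(x) {
  x <- as_node(x)
  fw <- cpp_maxpool2_forward(x$value)
  xd <- dim(x$value)
  nd(fw$y, list(x), function(g) {
    list(cpp_maxpool2_backward(g, fw$idx, as.integer(xd)))
  })
}

tp_upsample2 <- function(x) {
  x <- as_node(x)
  xd <- dim(x$value)
  nd(cpp_upsample2_forward(x$value), list(x), function(g) {
    list(cpp_upsample2_backward(g, as.integer(xd)))
  })
}

# Concatenate 5D feature grids along the channel axis (axis 4).
tp_concat <- function(xs) {
  xs <- lapply(xs, as_node)
  vals <- lapply(xs, function(n) n$value)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[4], numeric(1))
  out <- array(0, c(d1[1:3], sum(chans), d1[5]))
  at <- 0L
  for (v in vals) {
    out[, , , at + seq_len(dim(v)[4]), ] <- v
    at <- at + dim(v)[4]
  }
  nd(out, xs, function(g) {
    at <- 0L
    lapply(vals, function(v) {
      ch <- dim(v)[4]
      gv <- g[, , , at + seq_len(ch), , drop = FALSE]
      at <<- at + ch
      array(gv, dim(v))
    })
  })
}

# Channel slice (axis 4) of a 5D grid; backward scatters into zeros.
tp_slice_ch <- function(x, idx) {
  x <- as_node(x)
  xd <- dim(x$value)
  val <- array(x$value[, , , idx, , drop = FALSE],
               c(xd[1:3], length(idx), xd[5]))
  nd(val, list(x), function(g) {
    gx <- array(0, xd)
    gx[, , , idx, ] <- g
    list(gx)
  })
}

tp_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  nd(a$value + b$value, list(a, b), function(g) list(g, g))
}

tp_relu <- function(x) {
  x <- as_node(x)
  mask <- x$value > 0
  nd(x$value * mask, list(x), function(g) list(g * mask))
}

tp_sigmoid <- function(x) {
  x <- as_node(x)
  s <- sigmoid(x$value)
  nd(s, list(x), function(g) list(g * s * (1 - s)))
}

# Global average pooling of (X,Y,Z,C,B) to a (C,B) matrix.
tp_gap <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  xyz <- prod(d[1:3])
  val <- matrix(colMeans(matrix(x$value, xyz, d[4] * d[5])), d[4], d[5])
  nd(val, list(x), function(g) {
    list(array(rep(as.vector(g), each = xyz) / xyz, d))
  })
}

# Dense layer on (Cin,B) feature vectors: y = W x + b.
tp_dense <- function(x, W, b) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  val <- W$value %*% x$value + b$value
  nd(val, list(x, W, b), function(g) {
    list(t(W$value) %*% g, g %*% t(x$value), rowSums(g))
  })
}

# Batch normalization over the batch axis of (C,B) vectors. `state` is an
# environment carrying running_mean / running_var, updated in place while
# training and used directly in evaluation mode.
tp_bn_vec <- function(x, gamma, beta, state, training, momentum = 0.1,
                      eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$value
  B <- ncol(xv)
  if (training && B > 1) {
    mu <- rowMeans(xv)
    var <- rowMeans(xv * xv) - mu * mu
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * var * B / max(B - 1, 1)
    use_batch <- TRUE
  } else {
    mu <- state$running_mean
    var <- state$running_var
    use_batch <- FALSE
  }
  s <- sqrt(pmax(var, 0) + eps)
  xh <- (xv - mu) / s
  val <- gamma$value * xh + beta$value
  nd(val, list(x, gamma, beta), function(g) {
    ggamma <- rowSums(g * xh)
    gbeta <- rowSums(g)
    if (use_batch) {
      gx <- (gamma$value / s) *
        (g - rowMeans(g) - xh * rowMeans(g * xh))
    } else {
      gx <- (gamma$value / s) * g
    }
    list(gx, ggamma, gbeta)
  })
}

# Softmax across the radix axis of an (m, R, B) array, per channel and
# sample; the R attention weights of every channel sum to one.
tp_radix_softmax <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  m <- d[1]; R <- d[2]; B <- d[3]
  xm <- x$value
  mx <- apply(xm, c(1, 3), max)
  ex <- exp(xm - aperm(array(mx, c(m, B, R)), c(1, 3, 2)))
  den <- apply(ex, c(1, 3), sum)
  a <- ex / aperm(array(den, c(m, B, R)), c(1, 3, 2))
  nd(a, list(x), function(g) {
    dotsum <- apply(g * a, c(1, 3), sum)
    list(a * (g - aperm(array(dotsum, c(m, B, R)), c(1, 3, 2))))
  })
}

# Broadcast-multiply a (X,Y,Z,m,B) grid by per-channel weights (m,B).
tp_mul_bcast <- function(U, a) {
  U <- as_node(U); a <- as_node(a)
  d <- dim(U$value)
  xyz <- prod(d[1:3])
  aexp <- rep(as.vector(a$value), each = xyz)
  nd(array(as.vector(U$value) * aexp, d), list(U, a), function(g) {
    gU <- array(as.vector(g) * aexp, d)
    ga <- matrix(colSums(matrix(as.vector(g) * as.vector(U$value), xyz,
                                d[4] * d[5])), d[4], d[5])
    list(gU, ga)
  })
}

# Per-voxel softmax over the channel axis of (X,Y,Z,N,B) logits.
softmax_channels <- function(logits) {
  cpp_softmax_channels(logits)
}

# Fused per-voxel softmax + mean cross-entropy against 0-based integer
# targets of dim (X,Y,Z,B).
tp_softmax_ce <- function(logits, target) {
  logits <- as_node(logits)
  storage.mode(target) <- "integer"
  ce <- cpp_softmax_ce(logits$value, target)
  nd(ce$loss, list(logits), function(g) list(ce$grad * g))
}
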