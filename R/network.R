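#' Network configuration
#'
#' Architecture knobs of the split-attention nested U-Net: pyramid depth
#' `levels` (channel width doubles per level), split-attention cardinality
#' `K` and radix `R` (the block instantiates `G = K * R` parallel feature
#' groups), attention bottleneck reduction, EvoNorm group count, class
#' count, and the number of convolution units per node.
#'
#' @param levels Pyramid depth P (>= 2).
#' @param base_channels Channels at the top level; doubled per level.
#' @param cardinality Cardinality K (>= 1).
#' @param radix Radix R (>= 1).
#' @param reduction Attention bottleneck reduction factor.
#' @param norm_groups EvoNorm-S0 group count (clamped per layer to the
#'   largest divisor of the channel count not exceeding this).
#' @param n_classes Output classes N including background (default 34:
#'   33 structures + background).
#' @param conv_units Convolution units per node.
#' @param eps Variance floor of the normalization layers.
#' @return An object of class `network_config`.
#' @export
network_config <- function(levels = 4L, base_channels = 32L,
                           cardinality = 2L, radix = 2L, reduction = 4L,
                           norm_groups = 8L, n_classes = 34L,
                           conv_units = 2L, eps = 1e-5) {
  cfg <- list(levels = as.integer(levels),
              base_channels = as.integer(base_channels),
              cardinality = as.integer(cardinality),
              radix = as.integer(radix),
              reduction = as.integer(reduction),
              norm_groups = as.integer(norm_groups),
              n_classes = as.integer(n_classes),
              conv_units = as.integer(conv_units),
              eps = eps)
  stopifnot(cfg$levels >= 2, cfg$cardinality >= 1, cfg$radix >= 1,
            cfg$n_classes >= 2, cfg$conv_units >= 1)
  G <- cfg$cardinality * cfg$radix
  if (cfg$base_channels %% G != 0)
    stop("base_channels must be divisible by cardinality * radix")
  class(cfg) <- "network_config"
  cfg
}

#' Desk-scale preset: 3 levels, 8 base channels, for 32-voxel patches
#' @param n_classes Class count (default 9, the desk phantom schema).
#' @param ... Overrides passed to [network_config()].
#' @return A [network_config()].
#' @export
desk_network_config <- function(n_classes = 9L, ...) {
  network_config(levels = 3L, base_channels = 8L, n_classes = n_classes, ...)
}

channels_at <- function(cfg, p) cfg$base_channels * 2L^p

# largest divisor of C that does not exceed the configured group count
norm_groups_for <- function(cfg, C) {
  g <- min(cfg$norm_groups, C)
  while (C %% g != 0) g <- g - 1L
  g
}

#' Enumerate the node lattice of the nested skip pathways
#'
#' Valid node addresses `(p, q)` satisfy `0 <= p < P` and
#' `0 <= q <= P - 1 - p`.
#'
#' @param cfg A [network_config()].
#' @return Data.frame with columns `p`, `q`.
#' @export
node_addresses <- function(cfg) {
  P <- cfg$levels
  do.call(rbind, lapply(0:(P - 1), function(p) {
    data.frame(p = p, q = 0:(P - 1 - p))
  }))
}

# ---- weight construction ---------------------------------------------------

kaiming_conv <- function(k, cin, cout) {
  array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        c(k, k, k, cin, cout))
}

new_conv_unit_w <- function(k, cin, cout) {
  list(w = kaiming_conv(k, cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout), v = rep(1, cout))
}

new_bn_state <- function(n) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(n)
  e$running_var <- rep(1, n)
  e
}

new_resnest_w <- function(cfg, cin, cout) {
  K <- cfg$cardinality; R <- cfg$radix; G <- K * R
  if (cin %% G != 0) stop("resnest: channels not divisible by K*R")
  m <- cin %/% G
  h <- max((m * R) %/% cfg$reduction, 8L)
  splits <- lapply(seq_len(G), function(g) new_conv_unit_w(3L, m, m))
  att <- lapply(seq_len(K), function(k) list(
    W1 = matrix(stats::rnorm(h * m, 0, sqrt(2 / m)), h, m),
    b1 = numeric(h),
    bn_gamma = rep(1, h), bn_beta = numeric(h), bn_state = new_bn_state(h),
    W2 = matrix(stats::rnorm(m * R * h, 0, sqrt(2 / h)), m * R, h),
    b2 = numeric(m * R)))
  proj <- list(w = kaiming_conv(1L, (cin %/% R), cout), b = numeric(cout))
  shortcut <- if (cin == cout) NULL else
    list(w = kaiming_conv(1L, cin, cout), b = numeric(cout))
  list(splits = splits, att = att, proj = proj, shortcut = shortcut)
}

#' Initialize network weights
#'
#' Kaiming fan-in initialization for convolution and dense weights, unit
#' gain and zero shift for the normalization layers.
#'
#' @param cfg A [network_config()].
#' @param in_channels Image channels (1 for T1 volumes).
#' @param seed Integer seed.
#' @return Nested weight list (class `sau_weights`).
#' @export
init_network <- function(cfg, in_channels = 1L, seed = 1L) {
  with_seed(seed, {
    P <- cfg$levels
    nodes <- list()
    for (p in 0:(P - 1)) {
      cp <- channels_at(cfg, p)
      for (q in 0:(P - 1 - p)) {
        key <- node_key(p, q)
        if (q == 0) {
          cin1 <- if (p == 0) in_channels else channels_at(cfg, p - 1)
          convs <- vector("list", cfg$conv_units)
          convs[[1]] <- new_conv_unit_w(3L, cin1, cp)
          for (u in seq_len(cfg$conv_units - 1)) {
            convs[[u + 1]] <- new_conv_unit_w(3L, cp, cp)
          }
          nodes[[key]] <- list(convs = convs)
        } else {
          up <- list(w = kaiming_conv(1L, channels_at(cfg, p + 1), cp),
                     b = numeric(cp))
          cin1 <- (q + 1L) * cp # q same-level predecessors + upsampled input
          convs <- vector("list", cfg$conv_units)
          convs[[1]] <- new_conv_unit_w(3L, cin1, cp)
          for (u in seq_len(cfg$conv_units - 1)) {
            convs[[u + 1]] <- new_conv_unit_w(3L, cp, cp)
          }
          nodes[[key]] <- list(up = up, convs = convs,
                               resnest = new_resnest_w(cfg, cp, cp))
        }
      }
    }
    cls <- list(w = kaiming_conv(1L, cfg$base_channels, cfg$n_classes),
                b = numeric(cfg$n_classes))
    structure(list(cfg = cfg, in_channels = as.integer(in_channels),
                   nodes = nodes, classifier = cls),
              class = "sau_weights")
  })
}

node_key <- function(p, q) sprintf("n%d_%d", p, q)

#' Count network parameters
#' @param weights A `sau_weights` object.
#' @return Total number of scalar parameters.
#' @export
count_parameters <- function(weights) {
  n <- 0
  walk <- function(x) {
    if (is.environment(x)) return() # bn running stats are not parameters
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.numeric(x)) {
      n <<- n + length(x)
    }
  }
  walk(weights$nodes)
  walk(weights$classifier)
  n
}

# ---- tape-level blocks -----------------------------------------------------

ensure5d <- function(x) {
  d <- dim(x)
  if (length(d) == 3) {
    array(x, c(d, 1L, 1L))
  } else if (length(d) == 4) {
    array(x, c(d, 1L))
  } else x
}

tp_conv_unit <- function(x, wu, cfg) {
  cout <- length(nd_value(wu$b))
  y <- tp_conv3d(x, wu$w, wu$b)
  tp_evonorm(y, wu$gamma, wu$beta, wu$v, norm_groups_for(cfg, cout),
             cfg$eps)
}

# Split-attention over G = K*R channel groups; returns the concatenation
# of the K cardinal-group outputs (C / R channels total).
tp_split_attention <- function(x, cfg, w, training = FALSE) {
  K <- cfg$cardinality; R <- cfg$radix; G <- K * R
  C <- dim(nd_value(x))[4]
  if (C %% G != 0) stop("split_attention: channels not divisible by K*R")
  m <- C %/% G
  outs <- vector("list", K)
  for (k in seq_len(K)) {
    Us <- vector("list", R)
    for (r in seq_len(R)) {
      g <- (k - 1L) * R + r
      xg <- tp_slice_ch(x, (g - 1L) * m + seq_len(m))
      Us[[r]] <- tp_conv_unit(xg, w$splits[[g]], cfg)
    }
    Usum <- Us[[1]]
    if (R > 1) for (r in 2:R) Usum <- tp_add(Usum, Us[[r]])
    s <- tp_gap(Usum)                                   # (m, B)
    ak <- w$att[[k]]
    z <- tp_dense(s, ak$W1, ak$b1)
    z <- tp_bn_vec(z, ak$bn_gamma, ak$bn_beta, ak$bn_state, training)
    z <- tp_relu(z)
    logits <- tp_dense(z, ak$W2, ak$b2)                 # (m*R, B)
    B <- ncol(nd_value(logits))
    lg3 <- nd(array(nd_value(logits), c(m, R, B)), list(logits),
              function(g) list(matrix(g, m * R, B)))
    a <- if (R > 1) tp_radix_softmax(lg3) else tp_sigmoid(lg3)
    acc <- NULL
    for (r in seq_len(R)) {
      ar <- nd(matrix(nd_value(a)[, r, ], m, B), list(a), local({
        rr <- r
        function(g) {
          ga <- array(0, c(m, R, B))
          ga[, rr, ] <- g
          list(ga)
        }
      }))
      term <- tp_mul_bcast(Us[[r]], ar)
      acc <- if (is.null(acc)) term else tp_add(acc, term)
    }
    outs[[k]] <- acc
  }
  if (K > 1) tp_concat(outs) else outs[[1]]
}

tp_resnest_block <- function(x, cfg, w, training = FALSE) {
  sa <- tp_split_attention(x, cfg, w, training)
  y <- tp_conv3d(sa, w$proj$w, w$proj$b)
  sc <- if (is.null(w$shortcut)) x else
    tp_conv3d(x, w$shortcut$w, w$shortcut$b)
  tp_add(y, sc)
}

tp_node_forward <- function(p, q, inputs, cfg, wnode, training = FALSE) {
  if (q == 0) {
    h <- inputs[[1]]
    if (p > 0) h <- tp_maxpool2(h)
    for (wu in wnode$convs) h <- tp_conv_unit(h, wu, cfg)
    h
  } else {
    n_in <- length(inputs)
    deep <- inputs[[n_in]] # x^{p+1, q-1}
    up <- tp_conv3d(tp_upsample2(deep), wnode$up$w, wnode$up$b)
    h <- tp_concat(c(inputs[-n_in], list(up)))
    for (wu in wnode$convs) h <- tp_conv_unit(h, wu, cfg)
    tp_resnest_block(h, cfg, wnode$resnest, training)
  }
}

# Full graph: returns the classifier logits node. `wrap` converts each
# weight array to a tape node; pass `as_node` for inference or a
# parameter-collecting wrapper for training.
tp_network <- function(x, weights, training = FALSE, wrap = as_node) {
  cfg <- weights$cfg
  P <- cfg$levels
  wnodes <- wrap_weights(weights, wrap)
  xs <- list()
  for (p in 0:(P - 1)) {
    key <- node_key(p, 0)
    inp <- if (p == 0) list(x) else list(xs[[node_key(p - 1, 0)]])
    xs[[key]] <- tp_node_forward(p, 0, inp, cfg, wnodes$nodes[[key]],
                                 training)
  }
  for (q in 1:(P - 1)) {
    for (p in 0:(P - 1 - q)) {
      key <- node_key(p, q)
      same <- lapply(0:(q - 1), function(qq) xs[[node_key(p, qq)]])
      deep <- xs[[node_key(p + 1, q - 1)]]
      xs[[key]] <- tp_node_forward(p, q, c(same, list(deep)), cfg,
                                   wnodes$nodes[[key]], training)
    }
  }
  top <- xs[[node_key(0, P - 1)]]
  logits <- tp_conv3d(top, wnodes$classifier$w, wnodes$classifier$b)
  list(logits = logits, params = attr(wnodes, "params"), wnodes = wnodes)
}

# Recursively wrap weight arrays as tape nodes, collecting the wrapped
# parameter nodes into a flat named list (for the optimizer).
wrap_weights <- function(weights, wrap) {
  params <- list()
  rec <- function(x, path) {
    if (is.environment(x)) return(x) # bn state stays mutable
    if (is.list(x)) {
      out <- lapply(seq_along(x), function(i) {
        nm <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i]
              else as.character(i)
        rec(x[[i]], c(path, nm))
      })
      names(out) <- names(x)
      return(out)
    }
    if (is.numeric(x)) {
      n <- wrap(x)
      if (is_node(n)) params[[paste(path, collapse = ".")]] <<- n
      return(n)
    }
    x
  }
  out <- list(nodes = rec(weights$nodes, "nodes"),
              classifier = rec(weights$classifier, "classifier"))
  attr(out, "params") <- params
  out
}

# ---- user-facing (plain array) operations ---------------------------------

#' EvoNorm-S0 normalization-activation
#'
#' `y = gamma * x * sigmoid(v * x) / sqrt(Var_g(x) + eps) + beta`, with the
#' variance taken per sample over each contiguous channel group and all
#' spatial positions. Combines group-style normalization with a
#' sigmoid-weighted (Swish-like) gate and is independent of batch size.
#'
#' @param x Feature grid `(X,Y,Z,C)` or `(X,Y,Z,C,B)`.
#' @param gamma,beta,v Per-channel gain, shift and gate parameters.
#' @param groups Number of channel groups (must divide C).
#' @param eps Variance floor.
#' @return Array of the same shape as `x`.
#' @export
evonorm_s0 <- function(x, gamma, beta, v, groups, eps = 1e-5) {
  x5 <- ensure5d(x)
  out <- evonorm_forward(x5, gamma, beta, v, groups, eps)$y
  array(out, dim(x))
}

#' Convolution unit: 3x3x3 convolution followed by EvoNorm-S0
#'
#' @param x Feature grid `(X,Y,Z,Cin[,B])`.
#' @param wu Weight list with `w (3,3,3,Cin,Cout)`, `b`, `gamma`, `beta`,
#'   `v` (as produced inside [init_network()]).
#' @param cfg A [network_config()] (for group count and eps).
#' @return Feature grid `(X,Y,Z,Cout[,B])`; spatial size is preserved.
#' @export
conv_unit <- function(x, wu, cfg) {
  x5 <- ensure5d(x)
  out <- nd_value(tp_conv_unit(nd(x5), wu, cfg))
  drop_batch_like(out, x)
}

drop_batch_like <- function(out, x) {
  if (length(dim(x)) < 5) {
    d <- dim(out)
    array(out, d[seq_along(dim(x))])
  } else out
}

#' Split-attention module
#'
#' Splits the input channels into `G = K * R` parallel feature groups, each
#' processed by a 3x3x3 convolution unit. Within each cardinal group the R
#' split features are summed, globally average-pooled, passed through a
#' bottleneck (dense, batch-norm, rectifier), and turned into per-channel
#' attention weights by a softmax across the R splits (sigmoid when
#' R = 1); the group output is the attention-weighted sum of its splits.
#' Cardinal-group outputs are concatenated along channels, giving `C / R`
#' output channels.
#'
#' @param x Feature grid `(X,Y,Z,C[,B])` with C divisible by `K * R`.
#' @param cfg A [network_config()].
#' @param w Resnest weight list from [init_network()] (fields `splits`,
#'   `att`).
#' @param training Use batch statistics in the bottleneck batch-norm.
#' @return Feature grid with `C / R` channels.
#' @export
split_attention <- function(x, cfg, w, training = FALSE) {
  x5 <- ensure5d(x)
  out <- nd_value(tp_split_attention(nd(x5), cfg, w, training))
  drop_batch_like(out, x)
}

#' ResNeSt block
#'
#' [split_attention()] followed by a 1x1x1 projection convolution and a
#' shortcut connection (identity when the input width equals the declared
#' block width, else a 1x1x1 projection). Stride is 1 everywhere in the
#' skip pathways.
#'
#' @inheritParams split_attention
#' @return Feature grid with the block's declared output channels.
#' @export
resnest_block <- function(x, cfg, w, training = FALSE) {
  x5 <- ensure5d(x)
  out <- nd_value(tp_resnest_block(nd(x5), cfg, w, training))
  drop_batch_like(out, x)
}

#' Single node of the nested skip pathways
#'
#' For `q = 0` the node downsamples (2x2x2 max-pool, for `p > 0`) and
#' applies its convolution units. For `q > 0` the deepest input
#' `x^{p+1,q-1}` is upsampled (trilinear x2 plus 1x1x1 convolution),
#' concatenated with all same-level predecessors `x^{p,0..q-1}`, passed
#' through the convolution units, and finished with a ResNeSt block.
#'
#' @param p,q Node address (0-based level and dense index).
#' @param inputs List of feature grids: for `q = 0` the single previous
#'   encoder output (or the image for `p = 0`); for `q > 0` the q
#'   same-level predecessors followed by `x^{p+1,q-1}`.
#' @param cfg A [network_config()].
#' @param wnode This node's weight list from [init_network()].
#' @param training Batch-norm mode for the attention bottleneck.
#' @return The node's output feature grid at level-p resolution.
#' @export
node_forward <- function(p, q, inputs, cfg, wnode, training = FALSE) {
  ins <- lapply(inputs, function(i) nd(ensure5d(i)))
  out <- nd_value(tp_node_forward(p, q, ins, cfg, wnode, training))
  drop_batch_like(out, inputs[[length(inputs)]])
}

#' Classifier block
#'
#' 1x1x1 convolution to N channels followed by a per-voxel softmax; the
#' class probabilities at every voxel sum to one.
#'
#' @param x Feature grid from the final node `(0, P-1)`.
#' @param w Classifier weights (`w`, `b`) from [init_network()].
#' @return Probability grid with N channels.
#' @export
classifier <- function(x, w) {
  x5 <- ensure5d(x)
  logits <- cpp_conv3d_forward(x5, w$w, w$b)
  out <- softmax_channels(logits)
  drop_batch_like(out, x)
}

#' Full network forward pass
#'
#' Runs a patch through the nested split-attention graph and the classifier
#' head. The patch spatial dimensions must be divisible by `2^(P-1)`.
#'
#' @param weights A `sau_weights` checkpoint from [init_network()].
#' @param patch 3D array / [volume3d()] (one channel) or `(X,Y,Z,C,B)`
#'   feature grid.
#' @param training Batch-norm mode.
#' @return Per-voxel class probability grid `(X,Y,Z,N[,B])`.
#' @export
sau_forward <- function(weights, patch, training = FALSE) {
  x <- if (inherits(patch, "volume3d")) patch$data else patch
  x5 <- ensure5d(x)
  d <- dim(x5)
  P <- weights$cfg$levels
  if (any(d[1:3] %% 2L^(P - 1) != 0))
    stop("patch spatial dims must be divisible by 2^(levels-1)")
  out <- tp_network(nd(x5), weights, training = training)
  probs <- softmax_channels(nd_value(out$logits))
  if (length(dim(x)) < 5 && d[5] == 1) array(probs, dim(probs)[1:4])
  else probs
}
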