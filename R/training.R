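#' Training configuration
#'
#' Stage hyperparameters of the two-step strategy. Published defaults:
#' learning rate 0.001 for pre-training and 0.0001 for fine-tuning, batch
#' size 4, 96-voxel patches, cross-entropy loss, and a decoupled
#' weight-decay adaptive-moment optimizer with maximum-of-second-moment
#' correction (AdamW + AMSGrad). The full-scale schedule is 300,000
#' iterations; the desk preset trains a 3-level, 8-channel network on
#' 32-voxel patches for a few hundred iterations.
#'
#' @param stage `"pretrain"` or `"finetune"`.
#' @param learning_rate Constant learning rate (> 0); defaults to 0.001
#'   for pre-training and 0.0001 for fine-tuning.
#' @param batch_size Patches per iteration.
#' @param iterations Optimizer steps.
#' @param patch_size Cubic patch edge in voxels.
#' @param network A [network_config()].
#' @param augment An [augment_config()] applied per sampled patch, or
#'   `NULL` to disable augmentation.
#' @param weight_decay Decoupled weight decay on convolution and dense
#'   weights.
#' @param balanced_sampling Off by default (patch origins are uniform, the
#'   published behavior). When `TRUE`, half of the sampled patches are
#'   centered on a voxel of a uniformly chosen foreground structure, which
#'   equalizes gradient exposure of small structures — useful for
#'   desk-scale phantom runs with tight iteration budgets.
#' @param checkpoint_every Iterations between retained loss-trace rows.
#' @param seed Integer seed; the stage is deterministic given the seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage = c("pretrain", "finetune"),
                         learning_rate = NULL, batch_size = 4L,
                         iterations = 300000L, patch_size = 96L,
                         network = network_config(), augment = augment_config(),
                         weight_decay = 1e-2, balanced_sampling = FALSE,
                         checkpoint_every = 10L, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(learning_rate)) {
    learning_rate <- if (stage == "pretrain") 1e-3 else 1e-4
  }
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 0,
            patch_size %% 2L^(network$levels - 1) == 0)
  structure(list(stage = stage, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 patch_size = as.integer(patch_size),
                 network = network, augment = augment,
                 weight_decay = weight_decay,
                 balanced_sampling = isTRUE(balanced_sampling),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Sample a random training patch
#'
#' The patch origin is uniform over all valid origins; image and labels
#' are cropped identically.
#'
#' @param v A [volume3d()] or 3D array.
#' @param lv A [label_volume()] or integer 3D array aligned with `v`.
#' @param size Cubic patch edge (or length-3).
#' @return List with `volume`, `labels` (plain 3D arrays) and `origin`
#'   (0-based voxel origin).
#' @export
sample_patch <- function(v, lv, size) {
  x <- as_vol_data(v)
  l <- if (inherits(lv, "label_volume")) lv$data else lv
  size <- rep_len(as.integer(size), 3)
  d <- dim(x)
  if (any(d < size)) stop("volume smaller than patch size")
  origin <- vapply(1:3, function(ax) {
    if (d[ax] == size[ax]) 0L else sample.int(d[ax] - size[ax] + 1L, 1) - 1L
  }, integer(1))
  ix <- lapply(1:3, function(ax) origin[ax] + seq_len(size[ax]))
  list(volume = x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = l[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       origin = origin)
}

# Patch centered (up to boundary clamping) on a random voxel of a
# uniformly drawn foreground structure.
sample_patch_centered <- function(v, l, size, idx_by_class) {
  size <- rep_len(as.integer(size), 3)
  d <- dim(v)
  if (!length(idx_by_class)) return(sample_patch(v, l, size))
  cls <- sample(names(idx_by_class), 1)
  lin <- idx_by_class[[cls]][sample.int(length(idx_by_class[[cls]]), 1)] - 1L
  ctr <- c(lin %% d[1], (lin %/% d[1]) %% d[2], lin %/% (d[1] * d[2]))
  origin <- pmin(pmax(ctr - size %/% 2L, 0L), d - size)
  ix <- lapply(1:3, function(ax) origin[ax] + seq_len(size[ax]))
  list(volume = v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = l[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       origin = origin)
}

#' Mean cross-entropy of per-voxel class probabilities
#'
#' `mean over voxels of -log p(target class)`; zero exactly when the
#' prediction is certain and correct at every voxel.
#'
#' @param probs Probability grid `(X,Y,Z,N[,B])`.
#' @param target Integer label array `(X,Y,Z[,B])` with 0-based class ids
#'   (a [label_volume()] is accepted).
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(probs, target) {
  if (inherits(target, "label_volume")) target <- target$data
  d <- dim(probs)
  has_batch <- length(d) == 5
  N <- if (has_batch) d[4] else d[4]
  if (max(target) + 1 > N) stop("target label id >= number of classes")
  xyz <- prod(d[1:3])
  B <- if (has_batch) d[5] else 1L
  p5 <- ensure5d(probs)
  t4 <- array(target, c(d[1:3], B))
  total <- 0
  for (b in seq_len(B)) {
    pm <- matrix(p5[, , , , b], xyz, N)
    tb <- as.vector(t4[, , , b]) + 1L
    total <- total - sum(log(pmax(pm[cbind(seq_len(xyz), tb)], 1e-300)))
  }
  total / (xyz * B)
}

# ---- AdamW with AMSGrad ----------------------------------------------------

new_adamw_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e$vhat <- list()
  e
}

# Walk weights and freshly wrapped nodes in lockstep, applying one AdamW
# step per parameter leaf. Weight decay is decoupled and applied only to
# convolution / dense kernels (leaf names w, W1, W2).
adamw_step <- function(weights, wrapped, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(w, n, path) {
    if (is.environment(w)) return(w)
    if (is.list(w)) {
      for (i in seq_along(w)) {
        nm <- if (!is.null(names(w)) && nzchar(names(w)[i])) names(w)[i]
              else as.character(i)
        w[[i]] <- rec(w[[i]], n[[i]], c(path, nm))
      }
      return(w)
    }
    if (!is.numeric(w)) return(w)
    g <- n$grad
    if (is.null(g)) return(w)
    key <- paste(path, collapse = ".")
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- 0 * w
      state$v[[key]] <- 0 * w
      state$vhat[[key]] <- 0 * w
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    state$vhat[[key]] <- pmax(state$vhat[[key]], state$v[[key]])
    mhat <- state$m[[key]] / bc1
    vhat <- state$vhat[[key]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    leaf <- path[length(path)]
    if (leaf %in% c("w", "W1", "W2")) upd <- upd + weight_decay * w
    w - lr * upd
  }
  weights$nodes <- rec(weights$nodes, wrapped$nodes, "nodes")
  weights$classifier <- rec(weights$classifier, wrapped$classifier,
                            "classifier")
  weights
}

#' Run one training stage
#'
#' Iterates sample patch, augment, forward, cross-entropy, AdamW step for
#' the configured number of iterations. Deterministic given the config
#' seed. Aborts with diagnostics if the loss becomes non-finite.
#'
#' @param cfg A [train_config()].
#' @param data List of training cases, each `list(volume =, labels =)`
#'   ([volume3d()] / [label_volume()] or plain arrays). Volumes are
#'   expected pre-processed (standardized, padded).
#' @param init Optional initial checkpoint (`sau_weights` or the result of
#'   a previous [run_stage()]); required when `cfg$stage == "finetune"`.
#' @param verbose Print a loss line every `checkpoint_every` iterations.
#' @return List of class `sau_checkpoint`: `weights`, `loss_trace`
#'   (data.frame `iteration`, `loss`), `config`, `stage`.
#' @export
run_stage <- function(cfg, data, init = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (cfg$stage == "finetune" && is.null(init))
    stop("fine-tuning requires an initial checkpoint")
  weights <- if (is.null(init)) {
    init_network(cfg$network, in_channels = 1L, seed = cfg$seed)
  } else {
    if (inherits(init, "sau_checkpoint")) init$weights else init
  }
  ps <- cfg$patch_size
  vols <- lapply(data, function(d) as_vol_data(d$volume))
  labs <- lapply(data, function(d) {
    l <- d$labels
    if (inherits(l, "label_volume")) l$data else l
  })
  class_idx <- if (cfg$balanced_sampling) {
    lapply(labs, function(l) {
      ids <- setdiff(sort(unique(as.vector(l))), 0L)
      setNames(lapply(ids, function(id) which(l == id)), ids)
    })
  }

  state <- new_adamw_state()
  trace_it <- integer(0)
  trace_loss <- numeric(0)
  set.seed(cfg$seed + 1L)
  if (cfg$iterations > 0) for (it in seq_len(cfg$iterations)) {
    xb <- array(0, c(ps, ps, ps, 1L, cfg$batch_size))
    tb <- array(0L, c(ps, ps, ps, cfg$batch_size))
    for (b in seq_len(cfg$batch_size)) {
      ci <- sample.int(length(vols), 1)
      pt <- if (cfg$balanced_sampling && stats::runif(1) < 0.5) {
        sample_patch_centered(vols[[ci]], labs[[ci]], ps, class_idx[[ci]])
      } else {
        sample_patch(vols[[ci]], labs[[ci]], ps)
      }
      if (!is.null(cfg$augment)) {
        aug <- apply_augment(cfg$augment, pt$volume, pt$labels)
        pt$volume <- aug$volume
        pt$labels <- aug$labels
      }
      xb[, , , 1L, b] <- pt$volume
      tb[, , , b] <- pt$labels
    }
    net <- tp_network(nd(xb), weights, training = TRUE)
    loss <- tp_softmax_ce(net$logits, tb)
    if (!is.finite(loss$value)) {
      stop(sprintf("non-finite loss at iteration %d (last finite: %s)",
                   it, if (length(trace_loss))
                     format(trace_loss[length(trace_loss)]) else "none"))
    }
    nd_backward(loss)
    weights <- adamw_step(weights, list(nodes = net$wnodes$nodes,
                                        classifier = net$wnodes$classifier),
                          state, cfg$learning_rate, cfg$weight_decay)
    trace_it <- c(trace_it, it)
    trace_loss <- c(trace_loss, loss$value)
    if (verbose && it %% cfg$checkpoint_every == 0) {
      message(sprintf("[%s] iter %d loss %.4f", cfg$stage, it, loss$value))
    }
  }
  structure(list(weights = weights,
                 loss_trace = data.frame(iteration = trace_it,
                                         loss = trace_loss),
                 config = cfg, stage = cfg$stage),
            class = "sau_checkpoint")
}

#' Two-step training: pre-train on auxiliary labels, fine-tune on manual
#' labels
#'
#' Stage one trains from random initialization on pairs of images and
#' auxiliary labels (automatically generated, systematically imperfect).
#' Stage two continues from the stage-one weights on manually labeled
#' pairs, rectifying the discrepancies between auxiliary and manual labels
#' rather than learning from scratch. Both checkpoints are returned so the
#' pre-trained and fine-tuned models can be compared.
#'
#' @param pre_data Auxiliary-labeled cases (as in [run_stage()]).
#' @param fine_data Manually labeled cases; must share the label schema.
#' @param pre_cfg,fine_cfg [train_config()] for the two stages.
#' @return List with `pretrained` and `finetuned` checkpoints.
#' @export
two_step_train <- function(pre_data, fine_data, pre_cfg, fine_cfg) {
  s1 <- schema_of(pre_data)
  s2 <- schema_of(fine_data)
  if (!is.null(s1) && !is.null(s2) && !identical(s1$entries, s2$entries))
    stop("pre-training and fine-tuning data use different label schemas")
  stopifnot(pre_cfg$stage == "pretrain", fine_cfg$stage == "finetune")
  pre <- run_stage(pre_cfg, pre_data)
  fine <- run_stage(fine_cfg, fine_data, init = pre)
  list(pretrained = pre, finetuned = fine)
}

schema_of <- function(data) {
  for (d in data) {
    if (inherits(d$labels, "label_volume")) return(d$labels$schema)
  }
  NULL
}

#' Save / load a checkpoint
#'
#' Checkpoints are written with R serialization; the mutable batch-norm
#' state environments are converted to plain lists on disk. An
#' architecture JSON (the embedded [network_config()]) is written
#' alongside for auditability.
#'
#' @param ckpt A `sau_checkpoint` or `sau_weights`.
#' @param path Output `.rds` path.
#' @return `path` invisibly; `load_checkpoint()` returns the object.
#' @export
save_checkpoint <- function(ckpt, path) {
  obj <- rapply_env_to_list(ckpt)
  saveRDS(obj, path)
  w <- if (inherits(ckpt, "sau_checkpoint")) ckpt$weights else ckpt
  jsonlite::write_json(unclass(w$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  rapply_list_to_env(readRDS(path))
}

rapply_env_to_list <- function(x) {
  if (is.environment(x)) {
    return(structure(as.list(x), class = "bn_state_list"))
  }
  if (is.list(x) && !is.data.frame(x)) {
    out <- lapply(x, rapply_env_to_list)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

rapply_list_to_env <- function(x) {
  if (inherits(x, "bn_state_list")) {
    e <- new.env(parent = emptyenv())
    for (nm in names(x)) assign(nm, x[[nm]], envir = e)
    return(e)
  }
  if (is.list(x) && !is.data.frame(x)) {
    out <- lapply(x, rapply_list_to_env)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}
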