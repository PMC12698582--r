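# Adam optimizer over a named list of parameter arrays.

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] - opt$lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  params
}

#' Training configuration
#'
#' Mirrors the reference optimization protocol: Adam with learning rate
#' `1e-4` and `beta1 = 0.9`; a reduce-on-plateau schedule on validation
#' loss (factor 0.5, patience 10 epochs, floor 5e-7); gradient
#' accumulation over 2 micro-batches; an exponential moving average of
#' the weights with decay 0.995 updated every 8 optimizer steps after a
#' warm-up (30000 steps at full scale; configurable for desk-scale
#' runs).
#'
#' @param epochs training epochs (reference default 100).
#' @param lr,beta1 Adam settings.
#' @param lr_decay_factor,lr_patience_epochs,lr_min plateau scheduler.
#' @param accumulate_grad_batches micro-batches per optimizer step.
#' @param ema_decay,ema_update_every,ema_warmup_steps EMA settings.
#' @param batch_size micro-batch size.
#' @param max_steps optional cap on optimizer steps (desk-scale runs).
#' @param rng_seed seed controlling batch order, time draws and noise.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, lr = 1e-4, beta1 = 0.9,
                         lr_decay_factor = 0.5, lr_patience_epochs = 10L,
                         lr_min = 5e-7, accumulate_grad_batches = 2L,
                         ema_decay = 0.995, ema_update_every = 8L,
                         ema_warmup_steps = 30000L, batch_size = 4L,
                         max_steps = Inf, rng_seed = 0L) {
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1) {
    stop("configuration error: lr_decay_factor must be in (0,1)")
  }
  if (ema_decay <= 0 || ema_decay >= 1) {
    stop("configuration error: ema_decay must be in (0,1)")
  }
  structure(as.list(environment()), class = "train_config")
}

#' Split a dataset 70-5-25 with a seeded permutation
#'
#' Sizes follow the largest-remainder rule on `round(n * frac)` with any
#' residual assigned to the training set, reproducing the reference
#' splits: 200 volumes give 140/10/50 and 300 give 180/20/100.
#'
#' @param n_items number of items.
#' @param spec a [split_spec()].
#' @return list with integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive) and `folds`: `k_folds` cross-validation folds
#'   partitioning the training pool (the test fraction stays fixed).
#' @export
split_dataset <- function(n_items, spec = split_spec()) {
  if (n_items < 1) stop("data error: n_items must be >= 1")
  fr <- c(spec$train_frac, spec$val_frac, spec$test_frac)
  raw <- n_items * fr
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n_items - sum(sizes)
  if (short > 0) {
    for (j in order(rem, decreasing = TRUE)[seq_len(short)]) {
      sizes[j] <- sizes[j] + 1
    }
  }
  sizes[1] <- sizes[1] + (n_items - sum(sizes))   # residual -> train
  perm <- local_seed(spec$rng_seed, sample.int(n_items))
  train <- sort(perm[seq_len(sizes[1])])
  val <- sort(perm[sizes[1] + seq_len(sizes[2])])
  test <- sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  folds <- split(train, rep_len(seq_len(spec$k_folds), length(train)))
  list(train = train, val = val, test = test, folds = unname(folds))
}

#' Dataset split specification
#'
#' @param train_frac,val_frac,test_frac fractions summing to 1
#'   (defaults 0.70 / 0.05 / 0.25).
#' @param k_folds cross-validation folds over the training pool (default 3).
#' @param rng_seed permutation seed.
#' @export
split_spec <- function(train_frac = 0.70, val_frac = 0.05,
                       test_frac = 0.25, k_folds = 3L, rng_seed = 0L) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("configuration error: split fractions must be nonnegative and sum to 1")
  }
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, k_folds = as.integer(k_folds),
                 rng_seed = rng_seed), class = "split_spec")
}

# Encode a list of paired images into [H,W,C,N] latent stacks.
.encode_pairs <- function(pairs, codec) {
  n <- length(pairs)
  z0 <- codec_encode(codec, pairs[[1]]$octa)
  d <- dim(z0)
  x0 <- array(0, c(d, n)); y <- array(0, c(d, n))
  for (i in seq_len(n)) {
    x0[, , , i] <- codec_encode(codec, pairs[[i]]$octa)
    y[, , , i] <- codec_encode(codec, pairs[[i]]$oct)
  }
  list(x0 = x0, y = y)
}

.l1_grad_step <- function(den_env, schedule, x0b, yb, tvec, noise) {
  # one micro-batch forward/backward; returns list(loss, grads)
  mv <- schedule$m[tvec + 1L]
  dv <- schedule$delta[tvec + 1L]
  d <- dim(x0b); B <- d[4]
  mt <- array(rep(mv, each = prod(d[1:3])), d)
  st <- array(rep(sqrt(dv), each = prod(d[1:3])), d)
  target <- mt * (yb - x0b) + st * noise
  x_t <- x0b + target
  xin <- array(0, c(d[1], d[2], 2L * d[3], B))
  xin[, , seq_len(d[3]), ] <- x_t
  xin[, , d[3] + seq_len(d[3]), ] <- yb
  tp <- tape_new()
  fw <- .denoiser_tape_forward(tp, den_env$params, den_env$spec, xin, tvec)
  # clean-image parameterization: |r_hat - r| == |g - x0| exactly
  ov <- tp$vals[[fw$out]]
  loss <- mean(abs(ov - x0b))
  gb <- tp_backward(tp, fw$out, sign(ov - x0b) / length(ov))
  g <- lapply(names(den_env$params), function(nm) {
    gg <- gb[[fw$ids[[nm]]]]
    if (is.null(gg)) den_env$params[[nm]] * 0 else gg
  })
  names(g) <- names(den_env$params)
  list(loss = loss, grads = g)
}

#' Train the bridge denoiser
#'
#' Minimizes the L1 loss between the U-Net output and the bridge residual
#' [training_target()] over uniformly drawn steps `t in [1, T]`, with
#' gradient accumulation, an EMA weight copy and a reduce-on-plateau
#' learning-rate schedule driven by validation L1 loss.
#'
#' @param pairs list of paired images, each a list with elements `oct`
#'   and `octa` (grayscale matrices in `[0,1]`).
#' @param codec a [make_codec()] object.
#' @param denoiser a [build_denoiser()] function (updated in place).
#' @param schedule a [make_schedule()] object.
#' @param cfg a [train_config()].
#' @param val_pairs optional validation pairs (drives the LR plateau
#'   schedule; defaults to the training pairs).
#' @return The denoiser function, with `attr(, "env")` now containing
#'   `params` (raw), `ema_params` (NULL until past warm-up) and `log`
#'   (per-epoch data frame: epoch, train_loss, val_loss, lr).
#' @export
train_bbdm <- function(pairs, codec, denoiser, schedule,
                       cfg = train_config(), val_pairs = NULL) {
  if (length(pairs) == 0L) stop("data error: empty training set")
  e <- attr(denoiser, "env")
  enc <- .encode_pairs(pairs, codec)
  encv <- if (is.null(val_pairs)) enc else .encode_pairs(val_pairs, codec)
  n <- dim(enc$x0)[4]
  opt <- adam_new(e$params, lr = cfg$lr, beta1 = cfg$beta1)
  ema <- NULL
  lr <- cfg$lr
  best_val <- Inf; stall <- 0L
  steps_per_epoch <- max(1L, ceiling(n / (cfg$batch_size *
                                          cfg$accumulate_grad_batches)))
  log <- NULL
  opt_steps <- 0L
  local_seed(cfg$rng_seed, {
    for (ep in seq_len(cfg$epochs)) {
      if (opt_steps >= cfg$max_steps) break
      ep_loss <- 0; ep_batches <- 0L
      for (sidx in seq_len(steps_per_epoch)) {
        if (opt_steps >= cfg$max_steps) break
        acc <- NULL; acc_loss <- 0
        for (micro in seq_len(cfg$accumulate_grad_batches)) {
          bi <- sample.int(n, min(cfg$batch_size, n))
          x0b <- enc$x0[, , , bi, drop = FALSE]
          yb <- enc$y[, , , bi, drop = FALSE]
          tvec <- sample.int(schedule$T, length(bi))
          noise <- array(stats::rnorm(length(x0b)), dim(x0b))
          r <- .l1_grad_step(e, schedule, x0b, yb, tvec, noise)
          if (!is.finite(r$loss)) {
            stop("numerical failure: non-finite loss at optimizer step ",
                 opt_steps + 1L)
          }
          acc_loss <- acc_loss + r$loss
          acc <- if (is.null(acc)) r$grads else
            mapply(`+`, acc, r$grads, SIMPLIFY = FALSE)
        }
        g <- lapply(acc, function(x) x / cfg$accumulate_grad_batches)
        opt$lr <- lr
        e$params <- adam_step(opt, e$params, g)
        opt_steps <- opt_steps + 1L
        ep_loss <- ep_loss + acc_loss / cfg$accumulate_grad_batches
        ep_batches <- ep_batches + 1L
        if (opt_steps >= cfg$ema_warmup_steps) {
          if (is.null(ema)) {
            ema <- e$params           # EMA initialized as a copy
          } else if ((opt_steps - cfg$ema_warmup_steps) %%
                     cfg$ema_update_every == 0L) {
            ema <- mapply(function(a, b) cfg$ema_decay * a +
                            (1 - cfg$ema_decay) * b,
                          ema, e$params, SIMPLIFY = FALSE)
          }
        }
      }
      # validation L1 at fixed mid-trajectory steps drives the plateau
      # (capped at 8 pairs and 3 steps to keep the epoch overhead small)
      nv_ <- min(dim(encv$x0)[4], 8L)
      vx0 <- encv$x0[, , , seq_len(nv_), drop = FALSE]
      vy <- encv$y[, , , seq_len(nv_), drop = FALSE]
      tval <- as.integer(round(schedule$T * c(0.25, 0.6, 0.95)))
      vloss <- 0
      for (tv in tval) {
        nz <- array(stats::rnorm(length(vx0)), dim(vx0))
        mv <- schedule$m[tv + 1L]; dv <- schedule$delta[tv + 1L]
        tgt <- mv * (vy - vx0) + sqrt(dv) * nz
        x_t <- vx0 + tgt
        pred <- denoiser(x_t, rep(tv, nv_), vy)
        vloss <- vloss + mean(abs(pred - tgt))
      }
      vloss <- vloss / length(tval)
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$lr_patience_epochs) {
          lr <- max(lr * cfg$lr_decay_factor, cfg$lr_min)
          stall <- 0L
        }
      }
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = ep_loss / max(ep_batches, 1L),
                                   val_loss = vloss, lr = lr))
    }
  })
  e$ema_params <- ema
  e$log <- log
  denoiser
}

#' Translate a cohort of source images
#'
#' Encodes each source (OCT) image, runs the accelerated reverse bridge
#' and decodes the result.  EMA weights are used when available (i.e.
#' training passed the warm-up); raw weights otherwise.  Deterministic at
#' `eta = 0` under a fixed seed.
#'
#' @param sources list of grayscale matrices in `[0,1]`.
#' @param denoiser a trained [build_denoiser()] function.
#' @param codec the codec used in training.
#' @param schedule the training [make_schedule()].
#' @param sampler_cfg a [sampler_config()].
#' @param rng_seed base seed; item i uses `rng_seed + i`.
#' @return list with `images` (translated, same order) and `errors`
#'   (per-item messages, NULL when clean).
#' @export
translate_cohort <- function(sources, denoiser, codec, schedule,
                             sampler_cfg = sampler_config(
                               T_steps = schedule$T),
                             rng_seed = 0L) {
  e <- attr(denoiser, "env")
  use_params <- e$ema_params %||% e$params
  saved <- e$params
  out <- vector("list", length(sources))
  errs <- vector("list", length(sources))
  e$params <- use_params
  on.exit(e$params <- saved)
  for (i in seq_along(sources)) {
    res <- tryCatch({
      z <- codec_encode(codec, sources[[i]])
      zi <- bridge_sample(z, denoiser, schedule, sampler_cfg,
                          rng_seed = rng_seed + i)
      codec_decode(codec, zi)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      errs[[i]] <- conditionMessage(res)
    } else {
      out[[i]] <- res
    }
  }
  list(images = out, errors = errs)
}
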