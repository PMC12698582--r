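#' Sinusoidal time-step embedding
#'
#' Standard diffusion-model embedding: `dim/2` (sin, cos) pairs at
#' geometrically spaced frequencies `1/base^(2k/dim)`, evaluated at the
#' integer step `t`.  All components lie in `[-1, 1]`; at `t = 0` the sin
#' components are 0 and the cos components are 1.
#'
#' @param t integer step (vectorized: one column per element).
#' @param dim even embedding dimension.
#' @param base frequency base (conventional 10000).
#' @return A `dim x length(t)` matrix.
#' @export
time_embedding <- function(t, dim = 32L, base = 10000) {
  if (dim %% 2L != 0L) stop("configuration error: embedding dim must be even")
  half <- dim %/% 2L
  freq <- base^(-(0:(half - 1L)) / half)
  ang <- outer(freq, as.numeric(t))        # half x B
  rbind(sin(ang), cos(ang))
}

#' Denoiser architecture description
#'
#' The residual predictor is a compact 2D U-Net: the noisy latent is
#' concatenated channel-wise with the source (OCT) latent, giving
#' `in_channels = 2 * out_channels` (the reference configuration is six
#' in, three out); a sinusoidal time embedding passes through a small MLP
#' and is injected additively at every resolution level.
#'
#' @param in_channels input channels after concatenation (default 6).
#' @param out_channels predicted residual channels (default 3).
#' @param base_width channel width of the first level (desk default 16).
#' @param depth number of resolution levels (desk default 3); spatial
#'   sizes must be divisible by `2^(depth - 1)`.
#' @param time_embed_dim sinusoidal embedding dimension (even).
#' @return A `denoiser_spec` list.
#' @export
denoiser_spec <- function(in_channels = 6L, out_channels = 3L,
                          base_width = 16L, depth = 3L,
                          time_embed_dim = 32L) {
  if (in_channels != 2L * out_channels) {
    stop("configuration error: concatenation conditioning requires ",
         "in_channels == 2 * out_channels")
  }
  if (time_embed_dim %% 2L != 0L) {
    stop("configuration error: time_embed_dim must be even")
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 time_embed_dim = as.integer(time_embed_dim)),
            class = "denoiser_spec")
}

.gn_groups <- function(C) {
  for (g in c(8L, 4L, 2L)) if (C %% g == 0L) return(g)
  1L
}

.he_conv <- function(cin9, cout) {
  matrix(stats::rnorm(cin9 * cout, sd = sqrt(2 / cin9)), cin9, cout)
}

.unet_param_init <- function(spec) {
  w <- spec$base_width
  widths <- w * 2L^(0:(spec$depth - 1L))
  td <- spec$time_embed_dim
  th <- 2L * td
  p <- list(
    tmlp1_w = matrix(stats::rnorm(td * th, sd = sqrt(2 / td)), td, th),
    tmlp1_b = numeric(th),
    tmlp2_w = matrix(stats::rnorm(th * th, sd = sqrt(2 / th)), th, th),
    tmlp2_b = numeric(th),
    stem_w = .he_conv(9L * spec$in_channels, widths[1]),
    stem_b = numeric(widths[1])
  )
  blk <- function(cin, cout, tag) {
    out <- list(
      .he_conv(9L * cin, cout), numeric(cout),          # c1
      rep(1, cout), numeric(cout),                      # gn1 gamma/beta
      matrix(stats::rnorm(th * cout, sd = sqrt(1 / th)), th, cout),
      numeric(cout),                                    # time proj
      .he_conv(9L * cout, cout), numeric(cout),         # c2
      rep(1, cout), numeric(cout)                       # gn2
    )
    names(out) <- paste0(tag, "_", c("c1_w", "c1_b", "gn1_g", "gn1_b",
                                     "t_w", "t_b", "c2_w", "c2_b",
                                     "gn2_g", "gn2_b"))
    out
  }
  for (i in seq_len(spec$depth)) {
    cin <- if (i == 1L) widths[1] else widths[i - 1L]
    p <- c(p, blk(cin, widths[i], paste0("down", i)))
  }
  if (spec$depth > 1L) {
    for (i in seq(spec$depth - 1L, 1L)) {
      p <- c(p, blk(widths[i + 1L] + widths[i], widths[i], paste0("up", i)))
    }
  }
  p$head_w <- matrix(0, 9L * widths[1], spec$out_channels)  # zero init
  p$head_b <- numeric(spec$out_channels)
  p
}

.unet_forward <- function(tp, ids, spec, x, tvec) {
  # ids: named list of tape node ids (or raw param arrays when tp NULL)
  d <- dim(x)
  div <- 2L^(spec$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop("configuration error: spatial size ", d[1], "x", d[2],
         " must be divisible by 2^(depth-1) = ", div)
  }
  widths <- spec$base_width * 2L^(0:(spec$depth - 1L))
  te <- time_embedding(tvec, spec$time_embed_dim)
  if (ncol(te) == 1L && d[4] > 1L) te <- te[, rep(1L, d[4]), drop = FALSE]
  h_t <- tp_leaf(tp, te)
  h_t <- op_silu(tp, op_linear(tp, h_t, ids$tmlp1_w, ids$tmlp1_b))
  h_t <- op_silu(tp, op_linear(tp, h_t, ids$tmlp2_w, ids$tmlp2_b))
  block <- function(h, tag, cout) {
    h <- op_conv3(tp, h, ids[[paste0(tag, "_c1_w")]],
                  ids[[paste0(tag, "_c1_b")]])
    h <- op_groupnorm(tp, h, ids[[paste0(tag, "_gn1_g")]],
                      ids[[paste0(tag, "_gn1_b")]], .gn_groups(cout))
    tv <- op_linear(tp, h_t, ids[[paste0(tag, "_t_w")]],
                    ids[[paste0(tag, "_t_b")]])
    h <- op_silu(tp, op_add_chan(tp, h, tv))
    h <- op_conv3(tp, h, ids[[paste0(tag, "_c2_w")]],
                  ids[[paste0(tag, "_c2_b")]])
    h <- op_groupnorm(tp, h, ids[[paste0(tag, "_gn2_g")]],
                      ids[[paste0(tag, "_gn2_b")]], .gn_groups(cout))
    op_silu(tp, h)
  }
  h <- op_conv3(tp, tp_leaf(tp, x), ids$stem_w, ids$stem_b, input_grad = FALSE)
  skips <- vector("list", spec$depth)
  for (i in seq_len(spec$depth)) {
    h <- block(h, paste0("down", i), widths[i])
    if (i < spec$depth) {
      skips[[i]] <- h
      h <- op_avgpool2(tp, h)
    }
  }
  if (spec$depth > 1L) {
    for (i in seq(spec$depth - 1L, 1L)) {
      h <- op_upsample2(tp, h)
      h <- op_concat_c(tp, h, skips[[i]])
      h <- block(h, paste0("up", i), widths[i])
    }
  }
  op_conv3(tp, h, ids$head_w, ids$head_b)
}

.as_hwcb <- function(x, C) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {       # single-channel matrix
    x <- array(x, c(dim(as.matrix(x)), 1L, 1L))
    d <- dim(x)
  } else if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  if (d[3] == 1L && C > 1L) {                # replicate grayscale
    x <- array(rep(x, C), c(d[1], d[2], d[4], C))
    x <- aperm(x, c(1L, 2L, 4L, 3L))
  }
  x
}

#' Build a trainable U-Net residual denoiser
#'
#' Returns a callable `f(x_t, t, y)` predicting the bridge residual from
#' the noisy latent, the integer step and the source latent.  Inputs may
#' be `[H, W, C]` single images or `[H, W, C, B]` batches; `t` may be a
#' scalar or a per-example vector.  Internally the network is
#' parameterized in clean-image form: the U-Net emits an estimate
#' `g ~ x0` and the callable returns `x_t - g`, so the L1 residual loss
#' `|r_hat - r| = |g - x0|` trains the network against the fixed clean
#' latent instead of the per-draw noise -- algebraically the same
#' objective, far better conditioned.  Initialization is deterministic
#' under `rng_seed`; the zero-initialized head makes a fresh network
#' emit `g = 0`, i.e. predict the whole of `x_t` as residual.  The
#' parameter list lives in `attr(f, "env")$params` and is updated in
#' place by [train_bbdm()].
#'
#' @param spec a [denoiser_spec()].
#' @param rng_seed integer seed for weight initialization.
#' @return A function of class `denoiser_fn`.
#' @export
build_denoiser <- function(spec = denoiser_spec(), rng_seed = 0L) {
  params <- local_seed(rng_seed, .unet_param_init(spec))
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$spec <- spec
  f <- function(x_t, t, y) {
    x_t <- .as_hwcb(x_t, e$spec$out_channels)
    y <- .as_hwcb(y, e$spec$out_channels)
    squeeze <- length(dim(x_t)) == 4L && dim(x_t)[4] == 1L
    x <- array(0, c(dim(x_t)[1:2], dim(x_t)[3] + dim(y)[3], dim(x_t)[4]))
    x[, , seq_len(dim(x_t)[3]), ] <- x_t
    x[, , dim(x_t)[3] + seq_len(dim(y)[3]), ] <- y
    g <- .unet_forward(NULL, e$params, e$spec, x, t)
    out <- x_t - g
    if (squeeze) dim(out) <- dim(out)[1:3]
    out
  }
  attr(f, "env") <- e
  class(f) <- c("denoiser_fn", "function")
  f
}

# Forward pass on a tape for training; x already concatenated [H,W,2C,B].
.denoiser_tape_forward <- function(tp, params, spec, x, tvec) {
  ids <- lapply(params, function(pv) tp_leaf(tp, pv))
  out_id <- .unet_forward(tp, ids, spec, x, tvec)
  list(ids = ids, out = out_id)
}
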