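#' Latent codec specification
#'
#' The diffusion bridge runs in a latent space produced by a pluggable
#' codec.  The reference pipeline uses a frozen pre-trained VQGAN; here
#' the codec is a stand-in with three kinds: `identity` (channel
#' replication plus the `[0,1] -> [-1,1]` range map; the default, so the
#' whole diffusion stack is testable with no codec training on the
#' critical path), `ae` (a small convolutional autoencoder) and `vqae`
#' (the same autoencoder with a vector-quantized bottleneck and
#' straight-through gradients).
#'
#' @param kind one of `"identity"`, `"ae"`, `"vqae"`.
#' @param downsample_factor spatial reduction, a power of two (identity: 1).
#' @param latent_channels channels of the latent (default 3, matching the
#'   six-in/three-out denoiser convention).
#' @param codebook_size vqae only: number of codebook vectors.
#' @param commitment_weight vqae only: commitment loss weight.
#' @return A `codec_spec` list.
#' @export
codec_spec <- function(kind = c("identity", "ae", "vqae"),
                       downsample_factor = if (kind[1] == "identity") 1L else 2L,
                       latent_channels = 3L, codebook_size = 64L,
                       commitment_weight = 0.25) {
  kind <- match.arg(kind)
  if (downsample_factor < 1 ||
      bitwAnd(as.integer(downsample_factor),
              as.integer(downsample_factor) - 1L) != 0L) {
    stop("configuration error: downsample_factor must be a power of two")
  }
  if (kind == "identity" && downsample_factor != 1L) {
    stop("configuration error: identity codec cannot downsample")
  }
  structure(list(kind = kind,
                 downsample_factor = as.integer(downsample_factor),
                 latent_channels = as.integer(latent_channels),
                 codebook_size = as.integer(codebook_size),
                 commitment_weight = commitment_weight),
            class = "codec_spec")
}

#' Construct a codec object
#'
#' Identity codecs are ready to use; `ae`/`vqae` codecs carry randomly
#' initialized weights and should be passed through [train_codec()].
#'
#' @param spec a [codec_spec()].
#' @param rng_seed seed for weight initialization (ignored by identity).
#' @return A `codec` list with fields `spec`, `params` (NULL for identity).
#' @export
make_codec <- function(spec = codec_spec(), rng_seed = 0L) {
  params <- NULL
  if (spec$kind != "identity") {
    C <- spec$latent_channels
    w <- 16L
    params <- local_seed(rng_seed, {
      p <- list(
        enc1_w = .he_conv(9L, w), enc1_b = numeric(w),
        enc2_w = .he_conv(9L * w, w), enc2_b = numeric(w),
        enc3_w = .he_conv(9L * w, C), enc3_b = numeric(C),
        dec1_w = .he_conv(9L * C, w), dec1_b = numeric(w),
        dec2_w = .he_conv(9L * w, w), dec2_b = numeric(w),
        dec3_w = .he_conv(9L * w, 1L), dec3_b = numeric(1L)
      )
      if (spec$kind == "vqae") {
        p$codebook <- matrix(stats::rnorm(spec$codebook_size * C, sd = 0.5),
                             spec$codebook_size, C)
      }
      p
    })
  }
  structure(list(spec = spec, params = params), class = "codec")
}

.check_image01 <- function(image) {
  r <- range(image)
  if (r[1] < 0 || r[2] > 1) {
    stop("range error: image values outside [0,1] (min ", r[1],
         ", max ", r[2], ")")
  }
}

# Encoder/decoder network cores (shared by ae and vqae).  Downsampling is
# one avgpool per factor-of-two; upsampling mirrors it.
.codec_enc_net <- function(tp, p, x, spec) {
  h <- op_silu(tp, op_conv3(tp, x, p$enc1_w, p$enc1_b, input_grad = FALSE))
  f <- spec$downsample_factor
  while (f > 1L) { h <- op_avgpool2(tp, h); f <- f %/% 2L }
  h <- op_silu(tp, op_conv3(tp, h, p$enc2_w, p$enc2_b))
  op_conv3(tp, h, p$enc3_w, p$enc3_b)
}

.codec_dec_net <- function(tp, p, z, spec) {
  h <- op_silu(tp, op_conv3(tp, z, p$dec1_w, p$dec1_b))
  f <- spec$downsample_factor
  while (f > 1L) { h <- op_upsample2(tp, h); f <- f %/% 2L }
  h <- op_silu(tp, op_conv3(tp, h, p$dec2_w, p$dec2_b))
  op_conv3(tp, h, p$dec3_w, p$dec3_b)
}

.vq_lookup <- function(z, codebook) {
  # z: [H,W,C,B]; returns quantized latent and code indices
  d <- dim(z); C <- d[3]
  zm <- matrix(aperm(z, c(1, 2, 4, 3)), ncol = C)      # (HWB) x C
  d2 <- outer(rowSums(zm^2), rowSums(codebook^2), "+") -
    2 * tcrossprod(zm, codebook)
  idx <- max.col(-d2, ties.method = "first")
  q <- codebook[idx, , drop = FALSE]
  qa <- array(q, c(d[1], d[2], d[4], C))
  list(z_q = aperm(qa, c(1, 2, 4, 3)), codes = idx)
}

#' Encode an image into the diffusion latent space
#'
#' @param codec a [make_codec()] object.
#' @param image grayscale matrix or `[H,W,C]` array with values in `[0,1]`.
#' @return Latent array `[H', W', latent_channels]` (batched input
#'   `[H,W,C,B]` gives a batched latent).  Identity codec: the image is
#'   replicated to `latent_channels` channels and mapped to `[-1, 1]`.
#' @export
codec_encode <- function(codec, image) {
  .check_image01(image)
  x <- .as_hwcb(image, 1L)
  squeeze <- dim(x)[4] == 1L
  if (codec$spec$kind == "identity") {
    z <- .as_hwcb(2 * x - 1, codec$spec$latent_channels)
  } else {
    p <- codec$params
    z <- .codec_enc_net(NULL, p, 2 * x - 1, codec$spec)
    if (codec$spec$kind == "vqae") z <- .vq_lookup(z, p$codebook)$z_q
  }
  if (squeeze) dim(z) <- dim(z)[1:3]
  z
}

#' Decode a latent back to image space
#'
#' @param codec a [make_codec()] object.
#' @param latent array produced by [codec_encode()].
#' @return Image in `[0, 1]` (values clamped).  Identity codec: channel
#'   mean, then the inverse range map.
#' @export
codec_decode <- function(codec, latent) {
  z <- latent
  if (length(dim(z)) == 3L) dim(z) <- c(dim(z), 1L)
  if (dim(z)[3] != codec$spec$latent_channels) {
    stop("contract error: latent has ", dim(z)[3],
         " channels, codec expects ", codec$spec$latent_channels)
  }
  if (codec$spec$kind == "identity") {
    d <- dim(z)
    y <- z[, , 1L, , drop = FALSE]
    if (d[3] > 1L) {
      for (c in 2:d[3]) y <- y + z[, , c, , drop = FALSE]
      y <- y / d[3]
    }
    img <- (y + 1) / 2
  } else {
    img <- .codec_dec_net(NULL, codec$params, z, codec$spec)
    img <- (img + 1) / 2
  }
  img <- pmin(pmax(img, 0), 1)
  d <- dim(img)
  dim(img) <- NULL
  dim(img) <- d
  if (dim(img)[4] == 1L) {
    out <- img[, , , 1L]
    if (length(dim(out)) == 3L && dim(out)[3] == 1L) out <- out[, , 1L]
    out
  } else img
}

#' Train an autoencoder codec on a set of images
#'
#' L1 reconstruction training with Adam; the `vqae` kind adds codebook and
#' commitment terms with a straight-through estimator (the codebook is
#' updated by gradient on the quantization loss, the encoder receives the
#' decoder gradient unchanged through the quantization).
#'
#' @param images list of grayscale matrices in `[0,1]`, equal sizes.
#' @param spec a non-identity [codec_spec()].
#' @param epochs full-batch gradient steps.
#' @param rng_seed seed for initialization.
#' @param lr Adam learning rate.
#' @return A fitted `codec` with a `history` attribute (per-epoch L1 loss
#'   and, for vqae, codebook perplexity).
#' @export
train_codec <- function(images, spec, epochs = 200L, rng_seed = 0L,
                        lr = 2e-3) {
  if (spec$kind == "identity") {
    stop("identity codec has nothing to train")
  }
  if (length(images) == 0L) stop("data error: empty image collection")
  codec <- make_codec(spec, rng_seed)
  x <- array(0, c(dim(images[[1]]), 1L, length(images)))
  for (i in seq_along(images)) {
    .check_image01(images[[i]])
    x[, , 1L, i] <- images[[i]]
  }
  x <- 2 * x - 1
  opt <- adam_new(codec$params, lr = lr)
  loss_hist <- numeric(epochs)
  perp <- NA_real_
  for (ep in seq_len(epochs)) {
    tp <- tape_new()
    ids <- lapply(codec$params, function(pv) tp_leaf(tp, pv))
    xin <- tp_leaf(tp, x)
    z <- .codec_enc_net(tp, ids, xin, spec)
    zv <- tp$vals[[z]]
    extra_g <- NULL
    if (spec$kind == "vqae") {
      vq <- .vq_lookup(zv, codec$params$codebook)
      zq <- vq$z_q
      # straight-through: decode zv + (zq - zv) with the bracket constant
      zin <- emit(tp, zq, z, function(dy) list(dy))
      # codebook + commitment gradients, handled outside the tape
      n_use <- tabulate(vq$codes, nbins = spec$codebook_size)
      pr <- n_use / sum(n_use)
      perp <- exp(-sum(pr[pr > 0] * log(pr[pr > 0])))
      C <- dim(zv)[3]
      zm <- matrix(aperm(zv, c(1, 2, 4, 3)), ncol = C)
      diffm <- zm - codec$params$codebook[vq$codes, , drop = FALSE]
      dcb <- matrix(0, spec$codebook_size, C)
      for (c in seq_len(C)) {
        dcb[, c] <- -2 * as.vector(tapply(diffm[, c], factor(vq$codes,
          levels = seq_len(spec$codebook_size)), sum, default = 0))
      }
      dcb[is.na(dcb)] <- 0
      extra_g <- list(codebook = dcb / nrow(zm),
                      z_commit = spec$commitment_weight * 2 *
                        aperm(array(diffm, c(dim(zv)[1], dim(zv)[2],
                                             dim(zv)[4], C)),
                              c(1, 2, 4, 3)) / nrow(zm))
    } else {
      zin <- z
    }
    out <- .codec_dec_net(tp, ids, zin, spec)
    ov <- tp$vals[[out]]
    loss_hist[ep] <- mean(abs(ov - x))
    dout <- sign(ov - x) / length(ov)
    grads_by_id <- tp_backward(tp, out, dout)
    g <- lapply(names(codec$params), function(nm) {
      gg <- grads_by_id[[ids[[nm]]]]
      if (is.null(gg)) array(0, dim(codec$params[[nm]]) %||%
                               length(codec$params[[nm]])) else gg
    })
    names(g) <- names(codec$params)
    if (!is.null(extra_g)) {
      g$codebook <- g$codebook + extra_g$codebook
      gz <- grads_by_id[[z]]
      # commitment pulls encoder outputs toward their codes
      enc_names <- grep("^enc", names(g), value = TRUE)
      tp2 <- tape_new()
      ids2 <- lapply(codec$params, function(pv) tp_leaf(tp2, pv))
      z2 <- .codec_enc_net(tp2, ids2, tp_leaf(tp2, x), spec)
      gb2 <- tp_backward(tp2, z2, extra_g$z_commit)
      for (nm in enc_names) {
        gg <- gb2[[ids2[[nm]]]]
        if (!is.null(gg)) g[[nm]] <- g[[nm]] + gg
      }
    }
    codec$params <- adam_step(opt, codec$params, g)
  }
  attr(codec, "history") <- list(l1 = loss_hist, perplexity = perp)
  codec
}
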