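# Minimal reverse-mode autodiff over dense arrays.
#
# Feature maps are numeric arrays [H, W, C, B] (column-major, H fastest);
# fully-connected activations are matrices [features, B].  A "tape" records
# one backward closure per op; tp = NULL runs the same ops in pure
# inference mode with no recording.  This is deliberately small: only the
# ops a compact U-Net denoiser and convolutional codec need.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- list()
  tp$bw <- list()       # closures: grad_out -> named? list of parent grads
  tp$parents <- list()  # integer vectors
  tp
}

tp_leaf <- function(tp, value) {
  if (is.null(tp)) return(value)
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- value
  tp$bw[tp$n] <- list(NULL)
  tp$parents[tp$n] <- list(integer(0))
  tp$n
}

nv <- function(tp, x) {
  # force the node argument before touching tp$vals: nested op calls
  # mutate the tape while their promise is evaluated
  i <- x
  if (is.null(tp)) i else tp$vals[[i]]
}

emit <- function(tp, value, parents, bw) {
  if (is.null(tp)) return(value)
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- value
  tp$parents[[tp$n]] <- as.integer(parents)
  tp$bw[[tp$n]] <- bw
  tp$n
}

# Backward pass from node `out` seeded with gradient `dout`.
# Returns list of gradients indexed by node id (NULL where unreached).
tp_backward <- function(tp, out, dout) {
  grads <- vector("list", tp$n)
  grads[[out]] <- dout
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g) || is.null(tp$bw[[id]])) next
    pg <- tp$bw[[id]](g)
    ps <- tp$parents[[id]]
    for (k in seq_along(ps)) {
      p <- ps[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[id] <- list(NULL)  # free memory as we go
  }
  grads
}

# ---- im2col machinery for 3x3 convolutions (pad = 1) -------------------
#
# Gather/scatter linear-index vectors are precomputed per feature-map
# shape and cached: building the im2col matrix and its transpose scatter
# through plain vector indexing is several times faster than subarray
# arithmetic in R.

.conv_idx_cache <- new.env(parent = emptyenv())

.conv_idx <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  # interior of the padded array, vectorized in (h, w, c, b) order
  h <- rep.int(2:(H + 1L), W)
  w <- rep(2:(W + 1L), each = H)
  base_hw <- h + (w - 1L) * Hp                       # length H*W
  cb_off <- as.vector(outer((seq_len(C) - 1L) * (Hp * Wp),
                            (seq_len(B) - 1L) * (Hp * Wp * C), "+"))
  interior <- as.vector(outer(base_hw, cb_off, "+")) # (h,w,c,b) order
  # per-offset gather indices in im2col row order (h, w, b) x channel c
  hwb_c <- function(di, dj) {
    bhw <- (h + di) + (w + dj - 1L) * Hp
    b_off <- (seq_len(B) - 1L) * (Hp * Wp * C)
    hwb <- as.vector(outer(bhw, b_off, "+"))         # (h,w,b)
    c_off <- (seq_len(C) - 1L) * (Hp * Wp)
    as.vector(outer(hwb, c_off, "+"))                # cols: channels
  }
  gather <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    gather[[k]] <- hwb_c(di, dj)
  }
  # permutation taking a (H*W*B) x C block vector (h,w,b,c order) to
  # (h,w,c,b) order, used for the conv output and its gradient
  hw <- seq_len(H * W)
  # permutation: target (h,w,c,b) position <- source (h,w,b,c) position
  perm_to_hwcb <- integer(H * W * C * B)
  i <- 0L
  for (b_ in seq_len(B)) for (c_ in seq_len(C)) {
    perm_to_hwcb[i + hw] <- hw + (b_ - 1L) * (H * W) +
      (c_ - 1L) * (H * W * B)
    i <- i + H * W
  }
  perm_to_hwbc <- integer(H * W * C * B)
  perm_to_hwbc[perm_to_hwcb] <- seq_len(H * W * C * B)
  out <- list(gather = gather, interior = interior,
              to_hwcb = perm_to_hwcb, to_hwbc = perm_to_hwbc,
              Hp = Hp, Wp = Wp)
  .conv_idx_cache[[key]] <- out
  out
}

.im2col3 <- function(xp, idx, H, W, C, B) {
  col <- matrix(0, H * W * B, 9L * C)
  for (k in 1:9) {
    col[, ((k - 1L) * C + 1L):(k * C)] <- xp[idx$gather[[k]]]
  }
  col
}

# 3x3 same-padding convolution.  Weight w is a (9*C_in) x C_out matrix
# whose rows are ordered offset-major (columns then rows of the kernel),
# input-channel-minor (matching .im2col3); b is a length-C_out bias.
# input_grad = FALSE skips the (expensive) scatter back to the input,
# for convolutions whose input is a network input, not an activation.
op_conv3 <- function(tp, x, w, b, input_grad = TRUE) {
  xv <- nv(tp, x); wv <- nv(tp, w); bv <- nv(tp, b)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Cout <- length(bv)
  idx <- .conv_idx(H, W, C, B)
  xp <- numeric(idx$Hp * idx$Wp * C * B)
  xp[idx$interior] <- xv
  col <- .im2col3(xp, idx, H, W, C, B)
  ym <- col %*% wv
  ym <- ym + rep(bv, each = nrow(ym))
  y <- ym[.conv_idx(H, W, Cout, B)$to_hwcb]
  dim(y) <- c(H, W, Cout, B)
  emit(tp, y, c(x, w, b), function(dy) {
    idx_out <- .conv_idx(H, W, Cout, B)
    dym <- as.vector(dy)[idx_out$to_hwbc]
    dim(dym) <- c(H * W * B, Cout)
    dw <- crossprod(col, dym)
    db <- colSums(dym)
    dx <- NULL
    if (input_grad) {
      dcol <- tcrossprod(dym, wv)
      dxp <- numeric(idx$Hp * idx$Wp * C * B)
      for (k in 1:9) {
        gk <- idx$gather[[k]]
        dxp[gk] <- dxp[gk] + dcol[, ((k - 1L) * C + 1L):(k * C)]
      }
      dx <- dxp[idx$interior]
      dim(dx) <- d
    }
    list(dx, dw, db)
  })
}

op_silu <- function(tp, x) {
  xv <- nv(tp, x)
  s <- 1 / (1 + exp(-xv))
  y <- xv * s
  emit(tp, y, x, function(dy) list(dy * (s * (1 + xv * (1 - s)))))
}

# Group normalization over [H, W, C/groups] per (group, batch), with a
# per-channel affine (gamma, beta).
op_groupnorm <- function(tp, x, gamma, beta, groups, eps = 1e-5) {
  xv <- nv(tp, x); gv <- nv(tp, gamma); bv <- nv(tp, beta)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  cpg <- C %/% groups
  n <- H * W * cpg
  xr <- xv; dim(xr) <- c(n, groups * B)
  mu <- .colMeans(xr, n, groups * B)
  xc <- xr - rep(mu, each = n)
  v <- .colMeans(xc * xc, n, groups * B)
  isd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(isd, each = n)
  gfull <- rep(rep(gv, each = H * W), times = B)
  bfull <- rep(rep(bv, each = H * W), times = B)
  y <- xhat; dim(y) <- c(H * W * C, B); dim(y) <- NULL
  y <- y * gfull + bfull
  dim(y) <- c(H, W, C, B)
  emit(tp, y, c(x, gamma, beta), function(dy) {
    dyv <- as.vector(dy)
    xhat_flat <- as.vector(xhat)
    dgamma <- .colSums(matrix(dyv * xhat_flat, H * W, C * B), H * W, C * B)
    dgamma <- .rowSums(matrix(dgamma, C, B), C, B)
    dbeta <- .colSums(matrix(dyv, H * W, C * B), H * W, C * B)
    dbeta <- .rowSums(matrix(dbeta, C, B), C, B)
    dxhat <- matrix(dyv * gfull, n, groups * B)
    m1 <- .colMeans(dxhat, n, groups * B)
    m2 <- .colMeans(dxhat * xhat, n, groups * B)
    dx <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
      rep(isd, each = n)
    dim(dx) <- c(H, W, C, B)
    list(dx, dgamma, dbeta)
  })
}

# Broadcast-add a (C, B) matrix (e.g. a time-embedding projection) over
# the spatial dimensions of an [H, W, C, B] map.
op_add_chan <- function(tp, x, v) {
  xv <- nv(tp, x); vv <- nv(tp, v)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  y <- xv + array(rep(vv, each = H * W), dim = d)
  emit(tp, y, c(x, v), function(dy) {
    dv <- .colSums(matrix(dy, H * W, C * B), H * W, C * B)
    dim(dv) <- c(C, B)
    list(dy, dv)
  })
}

op_avgpool2 <- function(tp, x) {
  xv <- nv(tp, x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  io <- seq(1L, H, by = 2L); ie <- io + 1L
  jo <- seq(1L, W, by = 2L); je <- jo + 1L
  y <- (xv[io, jo, , , drop = FALSE] + xv[ie, jo, , , drop = FALSE] +
        xv[io, je, , , drop = FALSE] + xv[ie, je, , , drop = FALSE]) / 4
  emit(tp, y, x, function(dy) {
    dx <- array(0, d)
    q <- dy / 4
    dx[io, jo, , ] <- q; dx[ie, jo, , ] <- q
    dx[io, je, , ] <- q; dx[ie, je, , ] <- q
    list(dx)
  })
}

op_upsample2 <- function(tp, x) {
  xv <- nv(tp, x)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  io <- seq(1L, 2L * H, by = 2L); ie <- io + 1L
  jo <- seq(1L, 2L * W, by = 2L); je <- jo + 1L
  y <- array(0, c(2L * H, 2L * W, C, B))
  y[io, jo, , ] <- xv; y[ie, jo, , ] <- xv
  y[io, je, , ] <- xv; y[ie, je, , ] <- xv
  emit(tp, y, x, function(dy) {
    list(dy[io, jo, , , drop = FALSE] + dy[ie, jo, , , drop = FALSE] +
         dy[io, je, , , drop = FALSE] + dy[ie, je, , , drop = FALSE])
  })
}

op_concat_c <- function(tp, a, b) {
  av <- nv(tp, a); bv <- nv(tp, b)
  da <- dim(av); db_ <- dim(bv)
  y <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
  y[, , seq_len(da[3]), ] <- av
  y[, , da[3] + seq_len(db_[3]), ] <- bv
  emit(tp, y, c(a, b), function(dy) {
    list(dy[, , seq_len(da[3]), , drop = FALSE],
         dy[, , da[3] + seq_len(db_[3]), , drop = FALSE])
  })
}

# Dense layer on [features, B] matrices: y = t(w) %*% x + b.
op_linear <- function(tp, x, w, b) {
  xv <- nv(tp, x); wv <- nv(tp, w); bv <- nv(tp, b)
  y <- crossprod(wv, xv) + bv
  emit(tp, y, c(x, w, b), function(dy) {
    list(wv %*% dy, xv %*% t(dy), rowSums(dy))
  })
}
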