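# Image-quality and cohort-comparison metrics: SSIM, PCQI, Frechet
# distance with a pluggable embedding, the automated hallucination score,
# and Welch two-tailed t-tests.

.gauss_kernel <- function(window, sigma) {
  h <- (window - 1) / 2
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable "valid" 2-D filtering with a 1-D kernel.
.filter2_valid <- function(x, k) {
  n <- length(k)
  H <- nrow(x); W <- ncol(x)
  # rows
  out <- matrix(0, H - n + 1L, W)
  for (t in seq_len(n)) out <- out + k[t] * x[t:(H - n + t), , drop = FALSE]
  out2 <- matrix(0, nrow(out), W - n + 1L)
  for (t in seq_len(n)) out2 <- out2 + k[t] * out[, t:(W - n + t), drop = FALSE]
  out2
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with the conventional stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, a Gaussian window
#' (`sigma = 1.5`) and mean pooling over the valid region.
#'
#' @param a,b grayscale matrices of equal size.
#' @param window odd window width (default 11).
#' @param L dynamic range of the data (default 1 for `[0,1]` images).
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, window = 11L, L = 1) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  if (window %% 2L == 0L) stop("configuration error: window must be odd")
  if (min(dim(a)) < window) {
    window <- min(dim(a)) - (1 - min(dim(a)) %% 2L)
  }
  k <- .gauss_kernel(window, 1.5)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- .filter2_valid(a, k); mu_b <- .filter2_valid(b, k)
  va <- .filter2_valid(a * a, k) - mu_a^2
  vb <- .filter2_valid(b * b, k) - mu_b^2
  vab <- .filter2_valid(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * vab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}

#' Patch-based contrast quality index (PCQI)
#'
#' Each non-overlapping `patch x patch` tile is decomposed into its mean
#' intensity, signal strength (standard deviation) and structure; the
#' per-patch quality is the product of a contrast-change term
#' `4/pi * atan((s_ab + C) / (s_a^2 + C))`, a structure term
#' `(s_ab + C) / (s_a s_b + C)` and a mean-intensity term
#' `exp(-|mu_a - mu_b| / L)`.  Identical inputs score exactly 1 in every
#' patch.
#'
#' @param a,b grayscale matrices of equal size (`a` is the reference).
#' @param patch tile side in pixels (default 16).
#' @param L dynamic range (default 1).
#' @param C stabilizer (default `3 * (L/256)^2`, the conventional
#'   constant rescaled from 8-bit to the data range).
#' @return list with `mean` and the per-patch `map`.
#' @export
pcqi <- function(a, b, patch = 16L, L = 1, C = 3 * (L / 256)^2) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  H <- nrow(a); W <- ncol(a)
  if (patch > H || patch > W) {
    stop("configuration error: patch larger than image")
  }
  nh <- H %/% patch; nw <- W %/% patch
  map <- matrix(0, nh, nw)
  for (ti in seq_len(nh)) for (tj in seq_len(nw)) {
    ri <- ((ti - 1L) * patch + 1L):(ti * patch)
    rj <- ((tj - 1L) * patch + 1L):(tj * patch)
    xa <- a[ri, rj]; xb <- b[ri, rj]
    mua <- mean(xa); mub <- mean(xb)
    da <- xa - mua; db <- xb - mub
    n <- length(xa)
    sa2 <- sum(da * da) / n; sb2 <- sum(db * db) / n
    sab <- sum(da * db) / n
    qc <- (4 / pi) * atan((sab + C) / (sa2 + C))
    qs <- (sab + C) / (sqrt(sa2) * sqrt(sb2) + C)
    qi <- exp(-abs(mua - mub) / L)
    map[ti, tj] <- qc * qs * qi
  }
  list(mean = mean(map), map = map)
}

.sqrtm_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two Gaussian fits of feature sets
#'
#' The squared Frechet distance between `N(mu_a, S_a)` and
#' `N(mu_b, S_b)` fitted by sample moments:
#' `d^2 = |mu_a - mu_b|^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})`.
#' With an image-embedding function this is the FID statistic; the
#' package default embedder ([embed_downsample()]) is deterministic and
#' download-free, so reported values are comparable only within one
#' embedding choice.
#'
#' @param features_a,features_b numeric matrices, one feature vector per
#'   row (at least 2 rows each, equal number of columns).
#' @return Nonnegative scalar distance (the square root convention is not
#'   taken: this is `d^2`, matching FID usage).
#' @export
frechet_distance <- function(features_a, features_b) {
  fa <- as.matrix(features_a); fb <- as.matrix(features_b)
  if (ncol(fa) != ncol(fb)) stop("shape mismatch: feature dimensions differ")
  if (nrow(fa) < 2L || nrow(fb) < 2L) {
    stop("data error: need at least 2 feature vectors per set")
  }
  mu_a <- colMeans(fa); mu_b <- colMeans(fb)
  Sa <- stats::cov(fa); Sb <- stats::cov(fb)
  A <- .sqrtm_psd(Sa)
  M <- A %*% Sb %*% A
  tr_sqrt <- sum(diag(.sqrtm_psd(M)))
  d2 <- sum((mu_a - mu_b)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * tr_sqrt
  max(d2, 0)
}

#' Downsampled-pixel embedding for the Frechet statistic
#'
#' Block-averages an image to `side x side` and flattens it — a
#' deterministic, dependency-free stand-in for a pretrained deep
#' embedding.
#'
#' @param image grayscale matrix.
#' @param side output side length (default 8).
#' @return Numeric vector of length `side^2`.
#' @export
embed_downsample <- function(image, side = 8L) {
  H <- nrow(image); W <- ncol(image)
  bi <- pmin(floor((seq_len(H) - 1L) * side / H) + 1L, side)
  bj <- pmin(floor((seq_len(W) - 1L) * side / W) + 1L, side)
  acc <- rowsum(image, bi)
  acc <- t(rowsum(t(acc), bj))
  cnt <- tcrossprod(tabulate(bi, side), tabulate(bj, side))
  as.vector(acc / cnt)
}

#' Automated vascular hallucination score
#'
#' Proxy for clinician grading of fake vessels: the image is tiled into
#' non-overlapping `patch x patch` patches; a patch is flagged when the
#' generated mask has at least `min_pixels` vessel pixels where the
#' reference patch has fewer than `min_pixels`.  More than five flagged
#' patches score 10 (the stated ceiling rule); below the ceiling the
#' score interpolates as `round(10 * flagged / 6)`.
#'
#' @param generated_mask,reference_mask binary matrices of equal size.
#' @param patch patch side (default 10).
#' @param min_pixels vessel-pixel threshold per patch (default 5).
#' @return Integer score in `[0, 10]` (lower is better).
#' @export
hallucination_score <- function(generated_mask, reference_mask,
                                patch = 10L, min_pixels = 5L) {
  if (!identical(dim(generated_mask), dim(reference_mask))) {
    stop("shape mismatch between masks")
  }
  g <- generated_mask > 0; r <- reference_mask > 0
  H <- nrow(g); W <- ncol(g)
  nh <- H %/% patch; nw <- W %/% patch
  flagged <- 0L
  for (ti in seq_len(nh)) for (tj in seq_len(nw)) {
    ri <- ((ti - 1L) * patch + 1L):(ti * patch)
    rj <- ((tj - 1L) * patch + 1L):(tj * patch)
    if (sum(g[ri, rj]) >= min_pixels && sum(r[ri, rj]) < min_pixels) {
      flagged <- flagged + 1L
    }
  }
  if (flagged > 5L) 10L else as.integer(round(10 * flagged / 6))
}

#' Welch two-tailed t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.  When both samples have
#' zero variance and equal means the result is `t = 0, p = 1` with a
#' `degenerate` flag.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
two_tailed_ttest <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2L || nb < 2L) stop("data error: each sample needs n >= 2")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  ma <- mean(sample_a); mb <- mean(sample_b)
  if (va + vb <= 0) {
    if (ma == mb) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(ma - mb) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       degenerate = FALSE)
}

#' Evaluate a translated cohort against ground truth
#'
#' Computes per-pair SSIM and PCQI, a pooled Frechet distance over the
#' chosen embedding, per-image hallucination scores (on segmented
#' masks) and Welch t-tests comparing each vascular feature column of
#' the translated cohort against the ground-truth cohort.
#'
#' @param translated,ground_truth lists of grayscale matrices, paired by
#'   position.
#' @param embedder function image -> feature vector (default
#'   [embed_downsample()]).
#' @param seg_method,seg_threshold segmentation settings for masks and
#'   features.
#' @param patch,min_pixels hallucination-score settings.
#' @return A `metric_report` list: `ssim_mean`, `ssim_range`,
#'   `pcqi_mean`, `pcqi_sd`, `frechet`, `embedding`,
#'   `hallucination_scores`, `hallucination_mean`, `ttest` (data frame:
#'   feature, t, df, p), `features` (both cohort feature tables).
#' @export
evaluate_cohorts <- function(translated, ground_truth,
                             embedder = embed_downsample,
                             seg_method = "otsu", seg_threshold = NULL,
                             patch = 10L, min_pixels = 5L) {
  n <- length(translated)
  if (n == 0L || n != length(ground_truth)) {
    stop("pairing error: cohorts must be nonempty and of equal length")
  }
  ssims <- numeric(n); pcqis <- numeric(n); halls <- integer(n)
  fa <- NULL; fb <- NULL
  for (i in seq_len(n)) {
    tr <- translated[[i]]; gt <- ground_truth[[i]]
    ssims[i] <- ssim(tr, gt)
    pcqis[i] <- pcqi(gt, tr)$mean
    mt <- segment_vessels(tr, seg_method, seg_threshold)
    mg <- segment_vessels(gt, seg_method, seg_threshold)
    halls[i] <- hallucination_score(mt, mg, patch, min_pixels)
    fa <- rbind(fa, embedder(tr))
    fb <- rbind(fb, embedder(gt))
  }
  fr <- if (n >= 2L) frechet_distance(fa, fb) else NA_real_
  feat_tr <- cohort_features(translated, seg_method, seg_threshold)
  feat_gt <- cohort_features(ground_truth, seg_method, seg_threshold)
  tt <- NULL
  for (f in c("bvd", "bvc", "bvt", "vpi")) {
    if (n >= 2L) {
      r <- two_tailed_ttest(feat_tr$table[[f]], feat_gt$table[[f]])
      tt <- rbind(tt, data.frame(feature = f, t = r$t, df = r$df, p = r$p))
    }
  }
  structure(list(
    ssim_mean = mean(ssims), ssim_range = range(ssims),
    pcqi_mean = mean(pcqis),
    pcqi_sd = if (n > 1) stats::sd(pcqis) else NA_real_,
    frechet = fr, embedding = "downsample",
    hallucination_scores = halls, hallucination_mean = mean(halls),
    ttest = tt,
    features = list(translated = feat_tr, ground_truth = feat_gt)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("SSIM %.4f [%.4f, %.4f]  PCQI %.4f  Frechet(%s) %.4f\n",
              x$ssim_mean, x$ssim_range[1], x$ssim_range[2],
              x$pcqi_mean, x$embedding, x$frechet))
  cat(sprintf("hallucination mean %.2f (scores: %s)\n",
              x$hallucination_mean,
              paste(x$hallucination_scores, collapse = " ")))
  if (!is.null(x$ttest)) {
    cat("Welch t-tests (translated vs ground truth):\n")
    print(x$ttest, row.names = FALSE)
  }
  invisible(x)
}
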