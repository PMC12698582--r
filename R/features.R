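# Vessel morphometry: segmentation, thinning, branch decomposition and
# the four OCTA biomarkers (BVD, BVC, BVT, VPI).

.otsu <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  which.max(sb2) / nbins
}

#' Segment vessels from a grayscale angiogram
#'
#' Vessels are the bright structures.  The default applies a global Otsu
#' threshold after min-max contrast stretching; `method = "fixed"` uses
#' the given threshold directly (pixels `>= threshold` are vessel).
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold scalar in `(0, 1)`, required for `"fixed"`.
#' @return Logical matrix, `TRUE` = vessel.
#' @export
segment_vessels <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL) {
  method <- match.arg(method)
  if (length(image) == 0L) stop("data error: empty image")
  if (method == "fixed") {
    if (is.null(threshold)) stop("configuration error: fixed method needs a threshold")
    return(image >= threshold)
  }
  r <- range(image)
  if (r[2] - r[1] < 1e-12) {
    warning("degenerate histogram: constant image, returning empty mask")
    return(array(FALSE, dim(image)))
  }
  xs <- (image - r[1]) / (r[2] - r[1])
  xs >= .otsu(xs)
}

# TRUE where any 8-neighbor of m is TRUE.
.shift_any <- function(m) {
  s <- .shift8(m)
  s$P2 | s$P3 | s$P4 | s$P5 | s$P6 | s$P7 | s$P8 | s$P9
}

# Padded neighbor shift: returns the 8 neighbor planes of a logical matrix.
.shift8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m
  i <- 2:(H + 1L); j <- 2:(W + 1L)
  list(P2 = p[i - 1L, j],      P3 = p[i - 1L, j + 1L],
       P4 = p[i, j + 1L],      P5 = p[i + 1L, j + 1L],
       P6 = p[i + 1L, j],      P7 = p[i + 1L, j - 1L],
       P8 = p[i, j - 1L],      P9 = p[i - 1L, j - 1L])
}

# Zhang-Suen thinning to a 1-pixel 8-connected skeleton.
.thin_zs <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      s <- .shift8(m)
      B <- s$P2 + s$P3 + s$P4 + s$P5 + s$P6 + s$P7 + s$P8 + s$P9
      seqs <- list(s$P2, s$P3, s$P4, s$P5, s$P6, s$P7, s$P8, s$P9, s$P2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1L]])
      if (pass == 1L) {
        c1 <- !(s$P2 & s$P4 & s$P6); c2 <- !(s$P4 & s$P6 & s$P8)
      } else {
        c1 <- !(s$P2 & s$P4 & s$P8); c2 <- !(s$P2 & s$P6 & s$P8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) { m <- m & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

.label_components <- function(m, block_diag_near = NULL) {
  # 8-connected component labels of a logical matrix (BFS, integer
  # stack).  When block_diag_near is given, diagonal steps between two
  # pixels that both touch that set are disallowed -- used to keep
  # branch arms from reconnecting around a removed junction pixel.
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nextlab <- 0L
  idx <- which(m)
  off_i <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_j <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  diag_step <- off_i != 0L & off_j != 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- (cur - 1L) %% H + 1L
      cj <- (cur - 1L) %/% H + 1L
      ni <- ci + off_i; nj <- cj + off_j
      ok <- ni >= 1L & ni <= H & nj >= 1L & nj <= W
      if (!is.null(block_diag_near) && block_diag_near[cur]) {
        ok <- ok & !(diag_step & block_diag_near[pmin(pmax((nj - 1L), 0L) * H +
                                                       pmin(pmax(ni, 1L), H),
                                                     H * W)])
      }
      nn <- (nj[ok] - 1L) * H + ni[ok]
      nn <- nn[m[nn] & lab[nn] == 0L]
      if (length(nn)) {
        lab[nn] <- nextlab
        stack <- c(stack, nn)
      }
    }
  }
  lab
}

# Order the pixels of a path-like component by walking from an endpoint.
.trace_path <- function(coords) {
  n <- nrow(coords)
  if (n <= 2L) return(coords)
  key <- paste(coords[, 1], coords[, 2])
  pos <- new.env(parent = emptyenv(), size = n)
  for (k in seq_len(n)) assign(key[k], k, envir = pos)
  deg <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(n)) {
    nb <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      kk <- paste(coords[k, 1] + di, coords[k, 2] + dj)
      p <- get0(kk, envir = pos, ifnotfound = NULL)
      if (!is.null(p)) nb <- c(nb, p)
    }
    adj[[k]] <- nb
    deg[k] <- length(nb)
  }
  start <- which(deg <= 1L)[1]
  if (is.na(start)) start <- 1L          # cycle: arbitrary start
  visited <- logical(n)
  order_ <- integer(0)
  cur <- start
  while (!is.na(cur)) {
    visited[cur] <- TRUE
    order_ <- c(order_, cur)
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nxt) == 0L) break
    # prefer axial moves to avoid skipping across staircase corners
    if (length(nxt) > 1L) {
      dist <- abs(coords[nxt, 1] - coords[cur, 1]) +
        abs(coords[nxt, 2] - coords[cur, 2])
      nxt <- nxt[order(dist)]
    }
    cur <- nxt[1]
  }
  coords[order_, , drop = FALSE]
}

.path_chain_length <- function(path) {
  if (nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  sum(ifelse(d[, 1] + d[, 2] == 2L, sqrt(2), 1))
}

# Arc length of a smoothed version of the pixel path.  The raw
# axial/diagonal chain overestimates smooth curves by up to ~8%
# (staircase effect); a short moving average of the coordinates recovers
# the underlying curve length to about 1% while leaving straight
# segments untouched.
.path_arc_length <- function(path, window = 5L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  if (n <= window) return(sqrt(sum((path[n, ] - path[1, ])^2)))
  sm <- apply(path, 2, function(v) stats::filter(v, rep(1 / window, window),
                                                 sides = 2))
  half <- window %/% 2L
  sm[seq_len(half), ] <- path[seq_len(half), ]
  sm[(n - half + 1L):n, ] <- path[(n - half + 1L):n, ]
  sum(sqrt(rowSums(diff(sm)^2)))
}

# Marching-squares contour length of a binary mask at the 0.5 level
# (midpoint crossings), contours closed by zero padding.
.contour_length <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- mask
  a <- p[1:(H + 1L), 1:(W + 1L)]
  b <- p[1:(H + 1L), 2:(W + 2L)]
  cc <- p[2:(H + 2L), 2:(W + 2L)]
  d <- p[2:(H + 2L), 1:(W + 1L)]
  code <- a + 2L * b + 4L * cc + 8L * d
  s <- sqrt(2) / 2
  len <- c(0, s, s, 1, s, 1, sqrt(2), s, s, sqrt(2), 1, s, 1, s, s, 0)
  sum(len[code + 1L])
}

#' Skeletonize a vessel mask and decompose it into branches
#'
#' Thins the mask to a 1-pixel centerline (Zhang-Suen), classifies
#' skeleton pixels by 8-connected neighbor count (endpoints: 1 neighbor;
#' junctions: 3 or more), and traces the branch paths between them.
#' Branch lengths are reported both as the axial/diagonal chain sum
#' (`chain_length`, steps of 1 and sqrt(2)) and as a smoothed arc length
#' (`arc_length`) used by the tortuosity feature; `chord_length` is the
#' Euclidean distance between the branch endpoints.
#'
#' @param mask logical (or 0/1) matrix.
#' @return A `vessel_analysis` list: `mask`, `skeleton`, `branches`
#'   (list of path matrices), `branch_table` (data frame with
#'   chain/arc/chord lengths), `n_junction_clusters`, `boundary_length`,
#'   `skeleton_length`, `area_px`, `image_area_px`.
#' @export
skeletonize_and_branch <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  empty <- list(mask = mask, skeleton = mask & FALSE, branches = list(),
                branch_table = data.frame(chain_length = numeric(0),
                                          arc_length = numeric(0),
                                          chord_length = numeric(0)),
                n_junction_clusters = 0L, boundary_length = 0,
                skeleton_length = 0, area_px = sum(mask),
                image_area_px = H * W)
  class(empty) <- "vessel_analysis"
  if (!any(mask)) return(empty)
  sk <- .thin_zs(mask)
  # junction classification by crossing number (Rutovitz): number of
  # 0->1 transitions around the 8-neighborhood.  A plain neighbor count
  # over-flags diagonal staircase pixels as junctions.
  crossing <- function(sk) {
    s <- .shift8(sk)
    seqs <- list(s$P2, s$P3, s$P4, s$P5, s$P6, s$P7, s$P8, s$P9, s$P2)
    A <- matrix(0L, nrow(sk), ncol(sk))
    for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1L]])
    A
  }
  # prune 1-2 px spurs hanging off junctions (thinning artifacts)
  for (it in 1:3) {
    A <- crossing(sk)
    s <- .shift8(sk)
    nbr <- s$P2 + s$P3 + s$P4 + s$P5 + s$P6 + s$P7 + s$P8 + s$P9
    spur_seed <- sk & nbr == 1L & .shift_any(sk & A >= 3L)
    if (!any(spur_seed)) break
    sk <- sk & !spur_seed
  }
  A <- crossing(sk)
  s <- .shift8(sk)
  nbr <- s$P2 + s$P3 + s$P4 + s$P5 + s$P6 + s$P7 + s$P8 + s$P9
  junction <- sk & A >= 3L
  branch_px <- sk & !junction
  near_j <- .shift_any(junction)
  lab <- .label_components(branch_px, block_diag_near = near_j)
  nb <- max(lab)
  branches <- vector("list", nb)
  bt <- data.frame(chain_length = numeric(nb), arc_length = numeric(nb),
                   chord_length = numeric(nb))
  near_junction <- .shift_any(junction)
  # extend free branch ends into the mask along the local direction:
  # thinning erodes roughly width/2 pixels from every open end
  extend_end <- function(path, at_start) {
    n <- nrow(path)
    p1 <- if (at_start) path[1, ] else path[n, ]
    if (near_junction[p1[1], p1[2]]) return(path)
    p0 <- if (at_start) path[min(5L, n), ] else path[max(1L, n - 4L), ]
    d <- p1 - p0
    len <- sqrt(sum(d^2))
    if (len < 1) return(path)
    step <- d / len
    ext <- NULL
    q <- p1
    for (s_ in 1:20) {
      qn <- round(p1 + step * s_)
      if (any(qn < 1) || qn[1] > H || qn[2] > W) break
      if (identical(qn, q)) next
      if (!mask[qn[1], qn[2]] || sk[qn[1], qn[2]]) break
      ext <- rbind(ext, qn)
      q <- qn
    }
    if (is.null(ext)) return(path)
    if (at_start) rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE], path)
    else rbind(path, ext)
  }
  for (k in seq_len(nb)) {
    w <- which(lab == k)
    coords <- cbind((w - 1L) %% H + 1L, (w - 1L) %/% H + 1L)
    path <- .trace_path(coords)
    if (nrow(path) >= 2L) {
      path <- extend_end(path, at_start = TRUE)
      path <- extend_end(path, at_start = FALSE)
    }
    branches[[k]] <- path
    bt$chain_length[k] <- .path_chain_length(path)
    bt$arc_length[k] <- .path_arc_length(path)
    bt$chord_length[k] <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  }
  # fold extensions back into the skeleton before measuring its length
  for (k in seq_len(nb)) {
    p <- branches[[k]]
    sk[p] <- TRUE
  }
  # skeleton length: adjacency-graph edges, diagonal edges dropped when a
  # shared axial neighbor already connects the pair
  skp <- matrix(FALSE, H + 2L, W + 2L)
  skp[2:(H + 1L), 2:(W + 1L)] <- sk
  i <- 2:(H + 1L); j <- 2:(W + 1L)
  e_ax <- sum(skp[i, j] & skp[i + 1L, j]) + sum(skp[i, j] & skp[i, j + 1L])
  se_ok <- skp[i, j] & skp[i + 1L, j + 1L] &
    !(skp[i + 1L, j] | skp[i, j + 1L])
  sw_ok <- skp[i, j] & skp[i + 1L, j - 1L] &
    !(skp[i + 1L, j] | skp[i, j - 1L])
  sk_len <- e_ax + sqrt(2) * (sum(se_ok) + sum(sw_ok))
  jc <- .label_components(junction)
  out <- list(mask = mask, skeleton = sk, branches = branches,
              branch_table = bt,
              n_junction_clusters = max(jc),
              boundary_length = .contour_length(mask),
              skeleton_length = sk_len,
              area_px = sum(mask), image_area_px = H * W)
  class(out) <- "vessel_analysis"
  out
}

#' Compute the four vascular biomarkers from a vessel analysis
#'
#' \describe{
#'   \item{BVD}{vessel-area fraction: `kappa_bvd * area_px / image_area_px`.}
#'   \item{BVC}{vessel caliber: `kappa_bvc * area_px / skeleton_length`
#'     (0 with a warning when the skeleton is empty but the mask is not).}
#'   \item{BVT}{tortuosity: length-weighted ratio of summed branch arc
#'     lengths to summed chord lengths, branches with chord < 2 px
#'     excluded; 1 when no eligible branch exists.}
#'   \item{VPI}{perimeter index: `kappa_vpi * boundary_length /
#'     image_area_px`.}
#' }
#' The default scales `kappa = 1` give dimensionless ratios; clinical
#' conventions with other units can be injected through `scales`.
#'
#' @param analysis a [skeletonize_and_branch()] result.
#' @param scales named numeric vector `c(bvd = , bvc = , vpi = )`.
#' @return A `feature_panel` list with `bvd`, `bvc`, `bvt`, `vpi`.
#' @export
compute_features <- function(analysis, scales = c(bvd = 1, bvc = 1,
                                                  vpi = 1)) {
  a <- analysis
  bvd <- scales[["bvd"]] * a$area_px / a$image_area_px
  if (a$area_px > 0 && a$skeleton_length <= 0) {
    warning("zero skeleton length with nonzero vessel area; BVC set to 0")
    bvc <- 0
  } else if (a$area_px == 0) {
    bvc <- 0
  } else {
    bvc <- scales[["bvc"]] * a$area_px / a$skeleton_length
  }
  bt <- a$branch_table
  el <- bt$chord_length >= 2
  bvt <- if (any(el)) sum(bt$arc_length[el]) / sum(bt$chord_length[el]) else 1
  bvt <- max(bvt, 1)  # arc >= chord up to rasterization; clamp tiny dips
  vpi <- scales[["vpi"]] * a$boundary_length / a$image_area_px
  structure(list(bvd = bvd, bvc = bvc, bvt = bvt, vpi = vpi),
            class = "feature_panel")
}

#' Per-image feature table and cohort summary
#'
#' @param images list of grayscale matrices (or logical masks).
#' @param method,threshold passed to [segment_vessels()] (masks are used
#'   as-is).
#' @param scales passed to [compute_features()].
#' @return list with `table` (one row per image: bvd, bvc, bvt, vpi and an
#'   `error` column, NA when clean) and `summary` (mean and sample SD per
#'   feature; SD is NA with a flag when n = 1).
#' @export
cohort_features <- function(images, method = "otsu", threshold = NULL,
                            scales = c(bvd = 1, bvc = 1, vpi = 1)) {
  if (length(images) < 1L) stop("data error: need at least one image")
  rows <- lapply(seq_along(images), function(i) {
    res <- tryCatch({
      img <- images[[i]]
      mask <- if (is.logical(img)) img else
        segment_vessels(img, method, threshold)
      fp <- compute_features(skeletonize_and_branch(mask), scales)
      data.frame(id = i, bvd = fp$bvd, bvc = fp$bvc, bvt = fp$bvt,
                 vpi = fp$vpi, error = NA_character_)
    }, error = function(e) {
      data.frame(id = i, bvd = NA, bvc = NA, bvt = NA, vpi = NA,
                 error = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  ok <- tab[is.na(tab$error), , drop = FALSE]
  n <- nrow(ok)
  summ <- data.frame(
    feature = c("bvd", "bvc", "bvt", "vpi"),
    mean = vapply(c("bvd", "bvc", "bvt", "vpi"),
                  function(f) mean(ok[[f]]), 0),
    sd = vapply(c("bvd", "bvc", "bvt", "vpi"),
                function(f) if (n > 1) stats::sd(ok[[f]]) else NA_real_, 0),
    n = n, row.names = NULL
  )
  list(table = tab, summary = summ)
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("Vascular features: BVD %.4f  BVC %.4f  BVT %.4f  VPI %.4f\n",
              x$bvd, x$bvc, x$bvt, x$vpi))
  invisible(x)
}

#' @export
print.vessel_analysis <- function(x, ...) {
  cat(sprintf(paste0("Vessel analysis: %d/%d vessel px, %d branches, ",
                     "%d junction clusters, skeleton %.1f px, boundary %.1f px\n"),
              x$area_px, x$image_area_px, length(x$branches),
              x$n_junction_clusters, x$skeleton_length, x$boundary_length))
  invisible(x)
}
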