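# Seeded generator of paired pseudo-OCT / pseudo-OCTA images with
# analytic vessel ground truth and disease-severity presets.
#
# The OCTA side renders bright curvilinear vessel trees over a dim
# speckled background; the OCT side is a deterministic transform of the
# same geometry and the same speckle field (vessels at reduced contrast
# over horizontal layer texture, mildly blurred), so the OCT -> OCTA
# translation is learnable in principle.  Severity presets thin the tree
# (fewer roots, less branching, narrower vessels), ordering the expected
# vessel-area fraction and perimeter density control >= mild >= moderate
# >= severe -- the direction of the reference trends, with no claim about
# their magnitudes.

.severity_scales <- list(
  control = list(density = 1.00, branch = 1.00, width = 1.00),
  mild = list(density = 0.85, branch = 0.90, width = 0.95),
  moderate = list(density = 0.65, branch = 0.75, width = 0.90),
  severe = list(density = 0.45, branch = 0.55, width = 0.85)
)

#' Synthetic paired-scan specification
#'
#' @param size image side in pixels (default 224, the reference
#'   projection-map size; tests typically use 64).
#' @param n_trees vessel trees entering from the image border (default 4;
#'   scaled by the severity preset).
#' @param branching_prob per-step probability that a growing vessel
#'   spawns a child branch (default 0.06, scaled by severity).
#' @param tortuosity_amp amplitude (radians) of the sinusoidal heading
#'   perturbation along centerlines (default 0.35; 0 gives straight
#'   vessels).
#' @param vessel_width_px integer range of root vessel widths (default
#'   `c(2, 4)`).
#' @param speckle_sigma multiplicative log-normal speckle level (default
#'   0.05, the residual level of an averaged projection map).
#' @param severity one of `"control"`, `"mild"`, `"moderate"`,
#'   `"severe"`.
#' @param rng_seed integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(size = 224L, n_trees = 4L, branching_prob = 0.06,
                       tortuosity_amp = 0.35, vessel_width_px = c(2L, 4L),
                       speckle_sigma = 0.05,
                       severity = c("control", "mild", "moderate",
                                    "severe"),
                       rng_seed = 0L) {
  severity <- match.arg(severity)
  if (max(vessel_width_px) >= size) {
    stop("configuration error: vessel width must be smaller than the image")
  }
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 branching_prob = branching_prob,
                 tortuosity_amp = tortuosity_amp,
                 vessel_width_px = vessel_width_px,
                 speckle_sigma = speckle_sigma, severity = severity,
                 rng_seed = rng_seed), class = "synth_spec")
}

# Grow one vessel polyline by small heading increments with a sinusoidal
# tortuosity term; returns the polyline, spawned children, and width.
.grow_branch <- function(pos, heading, width, spec, sc, depth, step = 1.5) {
  n_max <- round(spec$size * (0.9 + 0.4 * stats::runif(1)) / step)
  period <- spec$size / (3 + 2 * stats::runif(1))
  phase <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, n_max + 1L, 2)
  pts[1, ] <- pos
  children <- list()
  k <- 1L
  for (s in seq_len(n_max)) {
    turn <- spec$tortuosity_amp * ((2 * pi * step / period) *
      cos(2 * pi * s * step / period + phase) +
      stats::rnorm(1, 0, 0.06))
    heading <- heading + turn
    pos <- pos + step * c(cos(heading), sin(heading))
    if (any(pos < 2) || any(pos > spec$size - 1)) break
    k <- k + 1L
    pts[k, ] <- pos
    if (depth < 3L && width > 1.2 &&
        stats::runif(1) < spec$branching_prob * sc$branch) {
      children[[length(children) + 1L]] <-
        list(pos = pos,
             heading = heading + sample(c(-1, 1), 1) *
               stats::runif(1, pi / 7, pi / 3.5),
             width = width * stats::runif(1, 0.6, 0.8))
    }
  }
  list(pts = pts[seq_len(k), , drop = FALSE], children = children,
       width = width)
}

# Anti-aliased render of a set of polylines with per-branch widths.
.render_polylines <- function(branches, size) {
  alpha <- matrix(0, size, size)
  for (br in branches) {
    pts <- br$pts
    if (nrow(pts) < 2L) next
    hw <- br$width / 2
    pad <- ceiling(hw + 1)
    lo <- pmax(floor(apply(pts, 2, min)) - pad, 1)
    hi <- pmin(ceiling(apply(pts, 2, max)) + pad, size)
    xi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]
    gx <- matrix(xi, length(xi), length(yi))
    gy <- matrix(yi, length(xi), length(yi), byrow = TRUE)
    dmin <- matrix(Inf, length(xi), length(yi))
    for (s in seq_len(nrow(pts) - 1L)) {
      p1 <- pts[s, ]; p2 <- pts[s + 1L, ]
      vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
      l2 <- vx * vx + vy * vy
      if (l2 == 0) next
      tt <- ((gx - p1[1]) * vx + (gy - p1[2]) * vy) / l2
      tt <- pmin(pmax(tt, 0), 1)
      dx <- gx - (p1[1] + tt * vx); dy <- gy - (p1[2] + tt * vy)
      dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
    }
    a <- pmin(pmax(hw + 0.5 - dmin, 0), 1)
    alpha[xi, yi] <- pmax(alpha[xi, yi], a)
  }
  alpha
}

.smooth3 <- function(x) {
  k <- c(0.25, 0.5, 0.25)
  H <- nrow(x); W <- ncol(x)
  xp <- rbind(x[1, ], x, x[H, ])
  x2 <- k[1] * xp[1:H, ] + k[2] * xp[2:(H + 1), ] + k[3] * xp[3:(H + 2), ]
  xp <- cbind(x2[, 1], x2, x2[, W])
  k[1] * xp[, 1:W] + k[2] * xp[, 2:(W + 1)] + k[3] * xp[, 3:(W + 2)]
}

#' Generate one paired pseudo-OCT / pseudo-OCTA image
#'
#' Fully reproducible under `spec$rng_seed`.  The returned ground truth
#' records the exact rendered geometry: per-branch analytic centerline
#' arc lengths (polyline sums) and chord lengths, the rendered-mask
#' vessel pixel count (bookkeeping of the `alpha >= 0.5` mask, not a
#' re-measurement), and a stadium-approximation perimeter
#' (`sum(2 arc + pi width)`, ignoring branch overlaps).
#'
#' @param spec a [synth_spec()].
#' @return list with `oct`, `octa` (matrices in `[0,1]`), `gt` (a
#'   `synth_ground_truth` list with `centerlines`, `arc_lengths`,
#'   `chord_lengths`, `widths`, `vessel_pixel_count`, `perimeter_length`,
#'   `severity_label`, `mask`, `vessel_alpha`).
#' @export
generate_pair <- function(spec = synth_spec()) {
  sc <- .severity_scales[[spec$severity]]
  local_seed(spec$rng_seed, {
    n_roots <- max(1L, round(spec$n_trees * sc$density))
    queue <- list()
    for (r in seq_len(n_roots)) {
      side <- sample.int(4L, 1L)
      u <- stats::runif(1, 0.15, 0.85) * spec$size
      pos <- switch(side, c(2, u), c(spec$size - 1, u), c(u, 2),
                    c(u, spec$size - 1))
      heading <- switch(side, 0, pi, pi / 2, -pi / 2) +
        stats::runif(1, -pi / 5, pi / 5)
      width <- stats::runif(1, spec$vessel_width_px[1],
                            spec$vessel_width_px[2]) * sc$width
      queue[[length(queue) + 1L]] <-
        list(pos = pos, heading = heading, width = width, depth = 0L)
    }
    branches <- list()
    while (length(queue) > 0L) {
      job <- queue[[1L]]; queue <- queue[-1L]
      g <- .grow_branch(job$pos, job$heading, job$width, spec, sc,
                        job$depth)
      if (nrow(g$pts) >= 2L) branches[[length(branches) + 1L]] <- g
      for (ch in g$children) {
        queue[[length(queue) + 1L]] <-
          list(pos = ch$pos, heading = ch$heading, width = ch$width,
               depth = job$depth + 1L)
      }
    }
    alpha <- .render_polylines(branches, spec$size)
    mask <- alpha >= 0.5
    arc <- vapply(branches, function(b)
      sum(sqrt(rowSums(diff(b$pts)^2))), 0)
    chord <- vapply(branches, function(b)
      sqrt(sum((b$pts[nrow(b$pts), ] - b$pts[1, ])^2)), 0)
    widths <- vapply(branches, `[[`, 0, "width")
    perimeter <- sum(2 * arc + pi * widths)
    # shared speckle field (smoothed log-normal)
    sp <- .smooth3(matrix(stats::rnorm(spec$size^2), spec$size))
    sp <- sp / stats::sd(sp)
    speckle <- exp(spec$speckle_sigma * sp - spec$speckle_sigma^2 / 2)
    octa <- pmin(pmax((0.10 + 0.80 * alpha) * speckle, 0), 1)
    # OCT: horizontal retinal layer texture + low-contrast blurred vessels,
    # modulated by the same speckle field at reduced amplitude
    rows <- seq_len(spec$size) / spec$size
    layers <- 0.45 + 0.25 * sin(2 * pi * rows * 3 + 1) +
      0.10 * sin(2 * pi * rows * 9)
    layer_img <- matrix(rep(layers, spec$size), spec$size)
    vb <- .smooth3(.smooth3(alpha))
    oct_img <- (0.50 * layer_img + 0.30 * vb + 0.08) *
      exp(0.6 * spec$speckle_sigma * sp)
    oct_img <- pmin(pmax(oct_img, 0), 1)
    gt <- structure(list(
      centerlines = lapply(branches, `[[`, "pts"),
      arc_lengths = arc, chord_lengths = chord, widths = widths,
      vessel_pixel_count = sum(mask), perimeter_length = perimeter,
      severity_label = spec$severity, mask = mask, vessel_alpha = alpha
    ), class = "synth_ground_truth")
    list(oct = oct_img, octa = octa, gt = gt)
  })
}

#' Generate and write a paired cohort to disk
#'
#' Layout: `<root>/oct/<id>.png`, `<root>/octa/<id>.png` (pairing by
#' identical stem), plus `manifest.json` with the per-image ground truth
#' and `index.csv` with severity labels.  Item `i` uses seed
#' `spec$rng_seed + i`, so regeneration under the same master seed is
#' bit-identical.
#'
#' @param n number of pairs.
#' @param spec a [synth_spec()]; `severity` may also be a vector of
#'   length `n` for mixed cohorts.
#' @param dir output directory (created if needed).
#' @param severity optional per-item severity labels overriding the spec.
#' @return Invisibly, the manifest as a list.
#' @export
generate_cohort <- function(n, spec = synth_spec(), dir,
                            severity = NULL) {
  if (n < 1) stop("data error: n must be >= 1")
  ok <- dir.create(file.path(dir, "oct"), recursive = TRUE,
                   showWarnings = FALSE)
  dir.create(file.path(dir, "octa"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "oct"))) {
    stop("I/O error: cannot create output directory ", dir)
  }
  sev <- severity %||% rep(spec$severity, n)
  if (length(sev) == 1L) sev <- rep(sev, n)
  manifest <- vector("list", n)
  index <- data.frame(id = character(n), severity = character(n),
                      vessel_pixel_count = integer(n),
                      perimeter_length = numeric(n))
  for (i in seq_len(n)) {
    sp_i <- spec
    sp_i$severity <- sev[i]
    sp_i$rng_seed <- spec$rng_seed + i
    pair <- generate_pair(sp_i)
    id <- sprintf("img%04d", i)
    write_image(file.path(dir, "oct", paste0(id, ".png")), pair$oct)
    write_image(file.path(dir, "octa", paste0(id, ".png")), pair$octa)
    manifest[[i]] <- list(
      id = id, severity = sev[i], seed = sp_i$rng_seed,
      vessel_pixel_count = pair$gt$vessel_pixel_count,
      perimeter_length = pair$gt$perimeter_length,
      arc_lengths = pair$gt$arc_lengths,
      chord_lengths = pair$gt$chord_lengths
    )
    index$id[i] <- id
    index$severity[i] <- sev[i]
    index$vessel_pixel_count[i] <- pair$gt$vessel_pixel_count
    index$perimeter_length[i] <- pair$gt$perimeter_length
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(manifest)
}
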