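# Image and configuration I/O.
#
# PNG is handled through the `png` package (8/16-bit, gray or RGB; RGB
# is collapsed by Rec.601 luminance).  TIFF support is a minimal
# self-contained reader/writer for uncompressed grayscale baseline TIFF
# (8/16-bit, little-endian, single- or multi-page) because no TIFF
# package ships with the environment.  Images are matrices in [0,1] with
# rows = image rows.

.rec601 <- c(0.299, 0.587, 0.114)

#' Read a grayscale image
#'
#' @param path PNG or TIFF file.  8- or 16-bit; RGB is collapsed to
#'   luminance.  Multi-page TIFF returns a 3-D array `[H, W, pages]`.
#' @return Matrix (or array) with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) {
      nc <- dim(x)[3]
      if (nc >= 3L) {
        x <- .rec601[1] * x[, , 1] + .rec601[2] * x[, , 2] +
          .rec601[3] * x[, , 3]
      } else {
        x <- x[, , 1]
      }
    }
    return(x)
  }
  if (ext %in% c("tif", "tiff")) return(.read_tiff_gray(path))
  if (ext %in% c("pgm", "pnm")) return(.read_pgm(path))
  stop("format error: unsupported image format for file ", path)
}

#' Write a grayscale image
#'
#' @param path output file; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, `.pgm`).
#' @param image matrix in `[0, 1]` (or `[H, W, pages]` array for
#'   multi-page TIFF).
#' @param bit_depth 8 or 16.
#' @export
write_image <- function(path, image, bit_depth = 8L) {
  if (any(image < 0) || any(image > 1)) {
    stop("range error: image values outside [0,1]")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path, dpi = NULL,
                  asp = NULL)
    return(invisible(path))
  }
  if (ext %in% c("tif", "tiff")) {
    .write_tiff_gray(path, image, bit_depth)
    return(invisible(path))
  }
  if (ext == "pgm") {
    .write_pgm(path, image, bit_depth)
    return(invisible(path))
  }
  stop("format error: unsupported image format for file ", path)
}

# writePNG quantizes at 8 bit by default; for 16-bit round trips store
# integer matrices ourselves
.write_pgm <- function(path, image, bit_depth = 8L) {
  mx <- if (bit_depth == 16L) 65535L else 255L
  q <- round(image * mx)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(mx)),
             con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
}

.read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("format error: only plain PGM (P2) supported: ",
                            path)
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  mx <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, H, W, byrow = TRUE) / mx
}

# ---- minimal uncompressed grayscale TIFF ------------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")

.write_tiff_gray <- function(path, image, bit_depth = 8L) {
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  H <- dim(image)[1]; W <- dim(image)[2]; P <- dim(image)[3]
  mx <- if (bit_depth == 16L) 65535 else 255
  bps <- as.integer(bit_depth)
  data_size <- H * W * (bps %/% 8L)
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  entry <- function(tag, type, count, value_raw4) {
    c(.u16(tag), .u16(type), .u32(count), value_raw4)
  }
  # layout: header(8) | page1 data | IFD1 | page2 data | IFD2 | ...
  chunks <- list()
  for (p in seq_len(P)) {
    q <- as.integer(round(t(image[, , p]) * mx))   # row-major strip
    dat <- if (bps == 16L) writeBin(q, raw(), size = 2, endian = "little")
    else as.raw(q)
    data_off <- 8L + (p - 1L) * (data_size + ifd_size)
    ifd_off <- data_off + data_size
    next_ifd <- if (p < P) ifd_off + ifd_size + data_size else 0L
    ifd <- c(.u16(n_entries),
             entry(256L, 3L, 1L, c(.u16(W), .u16(0))),       # width
             entry(257L, 3L, 1L, c(.u16(H), .u16(0))),       # height
             entry(258L, 3L, 1L, c(.u16(bps), .u16(0))),     # bits/sample
             entry(259L, 3L, 1L, c(.u16(1L), .u16(0))),      # no compression
             entry(262L, 3L, 1L, c(.u16(1L), .u16(0))),      # black is zero
             entry(273L, 4L, 1L, .u32(data_off)),            # strip offset
             entry(278L, 3L, 1L, c(.u16(H), .u16(0))),       # rows/strip
             entry(279L, 4L, 1L, .u32(data_size)),           # strip bytes
             .u32(next_ifd))
    chunks[[length(chunks) + 1L]] <- dat
    chunks[[length(chunks) + 1L]] <- ifd
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42), .u32(8L + data_size),
             unlist(chunks)), con)
  invisible(path)
}

.read_tiff_gray <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  if (!identical(rawToChar(raw[1:2]), "II")) {
    stop("format error: only little-endian TIFF supported: ", path)
  }
  rd16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                size = 2, endian = "little", signed = FALSE)
  rd32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                                size = 4, endian = "little")
  ifd_off <- rd32(4L)
  pages <- list()
  while (ifd_off != 0L) {
    n <- rd16(ifd_off)
    tags <- list()
    for (k in seq_len(n)) {
      base <- ifd_off + 2L + (k - 1L) * 12L
      tag <- rd16(base); type <- rd16(base + 2L)
      val <- if (type == 3L) rd16(base + 8L) else rd32(base + 8L)
      tags[[as.character(tag)]] <- val
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    bps <- tags[["258"]] %||% 8L
    if ((tags[["259"]] %||% 1L) != 1L) {
      stop("format error: compressed TIFF not supported: ", path)
    }
    off <- tags[["273"]]
    nbytes <- H * W * (bps %/% 8L)
    bytes <- raw[(off + 1):(off + nbytes)]
    v <- if (bps == 16L) {
      readBin(bytes, "integer", n = H * W, size = 2, endian = "little",
              signed = FALSE) / 65535
    } else {
      as.integer(bytes) / 255
    }
    pages[[length(pages) + 1L]] <- t(matrix(v, W, H))
    ifd_off <- rd32(ifd_off + 2L + n * 12L)
  }
  if (length(pages) == 1L) return(pages[[1L]])
  array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}

#' Project a 3-D image stack to a 2-D map
#'
#' @param stack `[H, W, depth]` array.
#' @param method `"max"` (default) or `"mean"` projection along depth.
#' @return Matrix `[H, W]`.
#' @export
project_stack <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(dim(stack)) != 3L) stop("data error: need a 3-D stack")
  if (method == "max") apply(stack, c(1, 2), max)
  else apply(stack, c(1, 2), mean)
}

# ---- run configuration -------------------------------------------------

.default_config <- function() {
  list(
    seed = 0L,
    schedule = list(T = 1000L, s = 1.0),
    sampler = list(n_steps = 20L, eta = 0.0),
    denoiser = list(in_channels = 6L, out_channels = 3L, base_width = 16L,
                    depth = 3L, time_embed_dim = 32L),
    codec = list(kind = "identity", downsample_factor = 1L,
                 latent_channels = 3L, codebook_size = 64L,
                 commitment_weight = 0.25),
    train = list(epochs = 100L, lr = 1e-4, beta1 = 0.9,
                 lr_decay_factor = 0.5, lr_patience_epochs = 10L,
                 lr_min = 5e-7, accumulate_grad_batches = 2L,
                 ema_decay = 0.995, ema_update_every = 8L,
                 ema_warmup_steps = 30000L, batch_size = 4L,
                 max_steps = Inf),
    split = list(train_frac = 0.70, val_frac = 0.05, test_frac = 0.25,
                 k_folds = 3L),
    synth = list(size = 224L, n_trees = 4L, branching_prob = 0.06,
                 tortuosity_amp = 0.35, vessel_width_px = c(2L, 4L),
                 speckle_sigma = 0.05, severity = "control"),
    metrics = list(ssim_window = 11L, pcqi_patch = 16L,
                   hallucination_patch = 10L, min_pixels = 5L,
                   seg_method = "otsu", seg_threshold = NULL)
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) file and merges it over the package defaults.
#' Unknown keys are rejected; every field has a default, so an empty file
#' is a valid configuration.
#'
#' @param path YAML/JSON file, or NULL for pure defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_into <- function(base, upd, prefix = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) {
        stop("configuration error: unknown key '", prefix, nm, "'")
      }
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]],
                                 paste0(prefix, nm, "."))
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  merge_into(cfg, user)
}

#' Echo a resolved configuration into an output directory
#' @param cfg configuration list.
#' @param dir output directory.
#' @keywords internal
echo_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
}

# Stable serialization of feature/metric tables: fixed column order,
# 6 significant digits.
.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
}
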