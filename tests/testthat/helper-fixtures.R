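# Shared fixtures built in code.

fix_latents <- function(seed = 1, d = c(8, 8, 1, 2)) {
  set.seed(seed)
  list(x0 = array(rnorm(prod(d)), d),
       y = array(rnorm(prod(d)), d),
       noise = array(rnorm(prod(d)), d))
}

# rasterized semicircular band: radius r, total width w, opening right
fix_semicircle <- function(r = 40, w = 3, size = 100) {
  cx <- size / 2; cy <- 10
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    rho <- sqrt((i - cx)^2 + (j - cy)^2)
    if (abs(rho - r) <= w / 2 && j >= cy) m[i, j] <- TRUE
  }
  m
}

fix_bar <- function(len = 100, w = 5, H = 40, W = 120) {
  m <- matrix(FALSE, H, W)
  r0 <- (H - w) %/% 2 + 1
  m[r0:(r0 + w - 1), 11:(10 + len)] <- TRUE
  m
}

# masks for the hallucination rule: blobs centered in k distinct 10x10
# grid patches of an empty 100x100 reference
fix_hallucination_masks <- function(k) {
  gen <- matrix(0, 100, 100)
  for (q in seq_len(k)) {
    c0 <- (q - 1) * 10 + 5   # center column/row of patch q on the diagonal
    gen[c0 + (-2:2), c0 + (-2:2)] <- 1
  }
  list(generated = gen, reference = matrix(0, 100, 100))
}
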