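# U-Net residual denoiser and its autograd substrate.

oct <- asNamespace("octabridge")

test_that("time embedding matches hand evaluation and stays bounded", {
  e0 <- time_embedding(0, 8)
  expect_equal(e0[1:4, 1], rep(0, 4))
  expect_equal(e0[5:8, 1], rep(1, 4))
  # dim = 4, t = 1, base 10000: frequencies 1, 10000^(-1/2)
  e1 <- time_embedding(1, 4)
  expect_equal(as.vector(e1),
               c(sin(1), sin(10000^-0.5), cos(1), cos(10000^-0.5)))
  for (t in c(0, 1, 17, 999)) {
    expect_true(all(abs(time_embedding(t, 32)) <= 1))
  }
  expect_error(time_embedding(1, 7), "even")
})

test_that("denoiser spec validates the conditioning arithmetic", {
  expect_error(denoiser_spec(in_channels = 5L), "in_channels")
  expect_error(denoiser_spec(time_embed_dim = 9L), "even")
  s <- denoiser_spec()
  expect_identical(s$in_channels, 6L)
  expect_identical(s$out_channels, 3L)
})

test_that("denoiser honors the shape contract and seeded determinism", {
  den <- build_denoiser(denoiser_spec(), rng_seed = 5)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  y <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  o <- den(x, 10, y)
  expect_identical(dim(o), c(32L, 32L, 3L))
  # zero-initialized head: fresh clean-image estimate is 0, so the
  # predicted residual is the whole noisy input
  expect_equal(o, x)
  den2 <- build_denoiser(denoiser_spec(), rng_seed = 5)
  e <- attr(den2, "env")
  expect_identical(attr(den, "env")$params, e$params)
  # depth 1: no downsampling, 8x8 works
  d1 <- build_denoiser(denoiser_spec(depth = 1L), rng_seed = 1)
  o1 <- d1(array(rnorm(192), c(8, 8, 3)), 3, array(rnorm(192), c(8, 8, 3)))
  expect_identical(dim(o1), c(8L, 8L, 3L))
  # indivisible size rejected
  d3 <- build_denoiser(denoiser_spec(depth = 3L), rng_seed = 1)
  expect_error(d3(array(rnorm(6 * 6 * 3), c(6, 6, 3)), 1,
                  array(rnorm(6 * 6 * 3), c(6, 6, 3))),
               "divisible")
  # batched input with per-example t
  xb <- array(rnorm(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  ob <- den(xb, c(1, 500, 999), xb)
  expect_identical(dim(ob), c(16L, 16L, 3L, 3L))
  # grayscale matrices are replicated to the 3-channel convention
  om <- den(matrix(rnorm(256), 16), 5, matrix(rnorm(256), 16))
  expect_identical(dim(om), c(16L, 16L, 3L))   # singleton batch squeezed
})

test_that("tape gradients agree with central differences", {
  set.seed(9)
  H <- 4; W <- 4; Cin <- 2; B <- 2; Cout <- 4
  x <- array(rnorm(H * W * Cin * B), c(H, W, Cin, B))
  w1 <- matrix(rnorm(9 * Cin * Cout, sd = 0.3), 9 * Cin, Cout)
  b1 <- rnorm(Cout)
  g1 <- runif(Cout, 0.5, 1.5); be1 <- rnorm(Cout) * 0.1
  v <- matrix(rnorm(Cout * B), Cout, B)
  w2 <- matrix(rnorm(9 * 2 * Cout, sd = 0.3), 9 * 2 * Cout, 1)
  b2 <- rnorm(1)
  run <- function(xv, w1v, b1v, g1v, be1v, vv, w2v, b2v, tp = NULL) {
    xi <- oct$tp_leaf(tp, xv)
    h <- oct$op_conv3(tp, xi, oct$tp_leaf(tp, w1v), oct$tp_leaf(tp, b1v))
    h <- oct$op_groupnorm(tp, h, oct$tp_leaf(tp, g1v),
                          oct$tp_leaf(tp, be1v), 2L)
    h <- oct$op_add_chan(tp, h, oct$tp_leaf(tp, vv))
    h <- oct$op_silu(tp, h)
    hp <- oct$op_avgpool2(tp, h)
    hu <- oct$op_upsample2(tp, hp)
    hc <- oct$op_concat_c(tp, hu, h)
    oct$op_conv3(tp, hc, oct$tp_leaf(tp, w2v), oct$tp_leaf(tp, b2v))
  }
  tp <- oct$tape_new()
  # re-register leaves so we can address them; replay the graph
  xi <- oct$tp_leaf(tp, x); w1i <- oct$tp_leaf(tp, w1)
  b1i <- oct$tp_leaf(tp, b1); g1i <- oct$tp_leaf(tp, g1)
  be1i <- oct$tp_leaf(tp, be1); vi <- oct$tp_leaf(tp, v)
  w2i <- oct$tp_leaf(tp, w2); b2i <- oct$tp_leaf(tp, b2)
  h <- oct$op_conv3(tp, xi, w1i, b1i)
  h <- oct$op_groupnorm(tp, h, g1i, be1i, 2L)
  h <- oct$op_add_chan(tp, h, vi)
  h <- oct$op_silu(tp, h)
  hp <- oct$op_avgpool2(tp, h)
  hu <- oct$op_upsample2(tp, hp)
  hc <- oct$op_concat_c(tp, hu, h)
  out <- oct$op_conv3(tp, hc, w2i, b2i)
  ov <- tp$vals[[out]]
  gr <- oct$tp_backward(tp, out, 2 * ov)
  lossfun <- function(...) sum(run(...)^2)
  num_grad <- function(val, f) {
    g <- array(0, dim(val) %||% length(val))
    for (k in seq_along(val)) {
      vp <- val; vp[k] <- vp[k] + 1e-6
      vm <- val; vm[k] <- vm[k] - 1e-6
      g[k] <- (f(vp) - f(vm)) / 2e-6
    }
    g
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  cases <- list(
    list(id = xi, val = x,
         f = function(z) lossfun(z, w1, b1, g1, be1, v, w2, b2)),
    list(id = w1i, val = w1,
         f = function(z) lossfun(x, z, b1, g1, be1, v, w2, b2)),
    list(id = g1i, val = g1,
         f = function(z) lossfun(x, w1, b1, z, be1, v, w2, b2)),
    list(id = vi, val = v,
         f = function(z) lossfun(x, w1, b1, g1, be1, z, w2, b2)),
    list(id = w2i, val = w2,
         f = function(z) lossfun(x, w1, b1, g1, be1, v, z, b2))
  )
  for (cs in cases) {
    ng <- num_grad(cs$val, cs$f)
    expect_lt(max(abs(ng - gr[[cs$id]])) / (max(abs(ng)) + 1e-8), 1e-5)
  }
})

test_that("one-pair overfit drives the L1 loss below 10% of start", {
  den <- build_denoiser(denoiser_spec(base_width = 16L, depth = 2L),
                        rng_seed = 2)
  e <- attr(den, "env")
  sch <- make_schedule(1000)
  set.seed(21)
  x0 <- array(runif(16 * 16 * 3), c(16, 16, 3, 1)) * 2 - 1
  y <- array(runif(16 * 16 * 3), c(16, 16, 3, 1)) * 2 - 1
  opt <- oct$adam_new(e$params, lr = 5e-3)
  losses <- numeric(500)
  set.seed(22)
  for (k in seq_len(500)) {
    tv <- sample.int(1000, 1)
    nz <- array(rnorm(length(x0)), dim(x0))
    r <- oct$.l1_grad_step(e, sch, x0, y, tv, nz)
    losses[k] <- r$loss
    e$params <- oct$adam_step(opt, e$params, r$grads)
  }
  expect_lt(mean(losses[481:500]), 0.10 * losses[1])
})
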