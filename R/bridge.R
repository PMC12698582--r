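#' Brownian-bridge diffusion schedule
#'
#' Builds the time discretization of a Brownian bridge between a source
#' latent (the structural OCT image) and a target latent (the OCTA
#' angiogram).  Unlike a standard diffusion process, the bridge is pinned
#' at both endpoints: the marginal variance \eqn{\delta_t} vanishes at
#' \eqn{t = 0} and \eqn{t = T} and peaks halfway through the trajectory.
#'
#' Under the linear schedule the interpolation coefficient is
#' \eqn{m_t = t/T} and the marginal variance is
#' \eqn{\delta_t = 2 s m_t (1 - m_t)}, so \eqn{\delta_{T/2} = s/2}.
#'
#' @param T_steps integer number of diffusion steps (training default 1000).
#' @param s positive scalar scale of the maximum variance (default 1).
#' @param form schedule family; only `"linear"` is defined.
#' @return An object of class `bridge_schedule` with fields `T`, `m`
#'   (length `T+1`, `m[t+1]` is \eqn{m_t}), `delta` (length `T+1`) and `s`.
#' @examples
#' sch <- make_schedule(1000)
#' sch$delta[1]        # 0: pinned at the source
#' sch$delta[501]      # 0.5: maximal mixing at T/2
#' @export
make_schedule <- function(T_steps = 1000L, s = 1.0, form = c("linear")) {
  form <- match.arg(form)
  if (!is.numeric(T_steps) || length(T_steps) != 1L || T_steps < 2 ||
      T_steps != round(T_steps)) {
    stop("invalid parameter 'T_steps': need an integer >= 2, got ",
         deparse(T_steps))
  }
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    stop("invalid parameter 's': need a positive scalar, got ", deparse(s))
  }
  T_steps <- as.integer(T_steps)
  m <- (0:T_steps) / T_steps
  delta <- 2 * s * m * (1 - m)
  structure(list(T = T_steps, m = m, delta = delta, s = s),
            class = "bridge_schedule")
}

#' @export
print.bridge_schedule <- function(x, ...) {
  cat(sprintf("Brownian-bridge schedule: T = %d, s = %g, linear m_t = t/T\n",
              x$T, x$s))
  cat(sprintf("  delta_t = 2 s m_t (1 - m_t); max delta = %g at t = T/2\n",
              max(x$delta)))
  invisible(x)
}

.check_latents <- function(...) {
  xs <- list(...)
  d1 <- dim(xs[[1]]) %||% length(xs[[1]])
  for (x in xs[-1]) {
    d <- dim(x) %||% length(x)
    if (!identical(d1, d)) {
      stop("shape mismatch between latents: ", paste(d1, collapse = "x"),
           " vs ", paste(d, collapse = "x"))
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_t <- function(t, schedule) {
  if (!is.numeric(t) || length(t) != 1L || t != round(t) || t < 0 ||
      t > schedule$T) {
    stop("step index t out of range [0, ", schedule$T, "]: ", t)
  }
  as.integer(t)
}

#' Forward marginal of the bridge
#'
#' Draws (or evaluates, given the noise) the forward-process marginal
#' \deqn{x_t = (1 - m_t) x_0 + m_t y + \sqrt{\delta_t}\,\epsilon,}
#' where \eqn{x_0} is the target-domain latent (OCTA), \eqn{y} the
#' source-domain latent (OCT) and \eqn{\epsilon} unit Gaussian noise.
#' Because \eqn{\delta_0 = \delta_T = 0}, the marginal is exactly
#' \eqn{x_0} at \eqn{t = 0} and exactly \eqn{y} at \eqn{t = T}.
#'
#' @param x0 target latent (numeric array).
#' @param y source latent, same shape as `x0`.
#' @param t integer step in `[0, T]`.
#' @param schedule a [make_schedule()] object.
#' @param noise unit-Gaussian array of the same shape; drawn internally
#'   when omitted.
#' @return A `bridge_state` list with fields `x_t`, `t`, `y`, `x0`.
#' @export
forward_marginal <- function(x0, y, t, schedule, noise = NULL) {
  if (is.null(noise)) noise <- array(stats::rnorm(length(x0)),
                                     dim = dim(x0) %||% length(x0))
  .check_latents(x0, y, noise)
  t <- .check_t(t, schedule)
  m_t <- schedule$m[t + 1L]
  d_t <- schedule$delta[t + 1L]
  # built as x0 + residual so that x_t - training_target == x0 bit-wise;
  # the pinned endpoints are returned exactly
  x_t <- if (t == 0L) x0 else if (t == schedule$T) y else
    x0 + (m_t * (y - x0) + sqrt(d_t) * noise)
  structure(list(x_t = x_t, t = t, y = y, x0 = x0), class = "bridge_state")
}

#' Training target of the bridge denoiser
#'
#' The network is trained with an L1 loss to predict the residual
#' \deqn{r_t = x_t - x_0 = m_t (y - x_0) + \sqrt{\delta_t}\,\epsilon}
#' from \eqn{(x_t, t, y)} — the displacement of the noisy latent away
#' from the clean target.  With the same noise draw,
#' `x_t - r_t = x0` holds to within one ulp ([forward_marginal()] builds
#' the state as `x0 + r_t`).
#'
#' @inheritParams forward_marginal
#' @return The residual latent, same shape as `x0`.
#' @export
training_target <- function(x0, y, t, schedule, noise = NULL) {
  if (is.null(noise)) noise <- array(stats::rnorm(length(x0)),
                                     dim = dim(x0) %||% length(x0))
  .check_latents(x0, y, noise)
  t <- .check_t(t, schedule)
  m_t <- schedule$m[t + 1L]
  d_t <- schedule$delta[t + 1L]
  m_t * (y - x0) + sqrt(d_t) * noise
}

#' Recover the clean-latent estimate from a residual prediction
#'
#' Inverts [training_target()]: \eqn{\hat x_0 = x_t - \hat r_t}.
#'
#' @param x_t noisy latent.
#' @param t integer step (kept for interface symmetry; the inversion is
#'   t-independent).
#' @param y source latent (unused by the identity inversion, part of the
#'   denoiser contract).
#' @param predicted_residual the denoiser output.
#' @export
estimate_x0 <- function(x_t, t, y, predicted_residual) {
  .check_latents(x_t, predicted_residual)
  x_t - predicted_residual
}

#' One reverse (denoising) transition of the bridge
#'
#' Non-Markovian jump from step `state$t` to `t_next < state$t`, given an
#' estimate `x0_hat` of the clean target latent.  The realized noise
#' displacement at `t` is
#' \eqn{d_t = x_t - (1-m_t)\hat x_0 - m_t y}; the transition re-scales it
#' to the variance budget of `t_next` and (for `eta > 0`) refreshes part
#' of it with new noise:
#' \deqn{x_{t'} = (1-m_{t'})\hat x_0 + m_{t'} y
#'   + \sqrt{(\delta_{t'} - \sigma^2)/\delta_t}\, d_t + \sigma z.}
#' The noise scale uses the bridge-consistent conditional variance
#' \eqn{\sigma^2 = \eta^2\, \delta_{t'}\, \delta_{t|t'} / \delta_t} with
#' \eqn{\delta_{t|t'} = \delta_t - \delta_{t'}\big((1-m_t)/(1-m_{t'})\big)^2},
#' which makes the chain's marginal variance equal \eqn{\delta_t} at every
#' visited step for any `eta` when `x0_hat` is exact.  `eta = 0` is fully
#' deterministic.  At `t_next = 0` the result is exactly `x0_hat`.
#'
#' @param state a `bridge_state` (from [forward_marginal()] or a previous
#'   reverse step).
#' @param t_next integer target step, `0 <= t_next < state$t`.
#' @param x0_hat clean-latent estimate, usually from [estimate_x0()].
#' @param schedule a [make_schedule()] object.
#' @param eta stochasticity in `[0, 1]`; 0 = deterministic.
#' @param noise optional unit-Gaussian array (drawn when omitted and
#'   `eta > 0`).
#' @return A new `bridge_state` at `t_next` (with `x0` carried over).
#' @export
reverse_step <- function(state, t_next, x0_hat, schedule, eta = 0,
                         noise = NULL) {
  t <- state$t
  t_next <- .check_t(t_next, schedule)
  if (t_next >= t) stop("ordering error: t_next (", t_next,
                        ") must be < state t (", t, ")")
  .check_latents(state$x_t, x0_hat)
  tiny <- 1e-12
  m_t <- schedule$m[t + 1L];      d_t <- schedule$delta[t + 1L]
  m_n <- schedule$m[t_next + 1L]; d_n <- schedule$delta[t_next + 1L]
  disp <- state$x_t - (1 - m_t) * x0_hat - m_t * state$y
  # conditional variance of x_{t_next} given x_t under the bridge
  # covariance Cov(B_s, B_t) = delta_s (1 - m_t)/(1 - m_s), s <= t; tends
  # to delta_{t_next} as delta_t -> 0 (a pinned point carries no noise)
  cond_var <- if (d_t > 0) {
    max(d_n - d_n^2 * ((1 - m_t) / (1 - m_n))^2 / d_t, 0)
  } else d_n
  sigma2 <- eta^2 * cond_var
  carry <- if (d_t > 0) sqrt(max(d_n - sigma2, 0) / max(d_t, tiny)) else 0
  x_new <- (1 - m_n) * x0_hat + m_n * state$y + carry * disp
  if (sigma2 > 0) {
    if (is.null(noise)) noise <- array(stats::rnorm(length(x0_hat)),
                                       dim = dim(x0_hat) %||% length(x0_hat))
    .check_latents(x0_hat, noise)
    x_new <- x_new + sqrt(sigma2) * noise
  }
  structure(list(x_t = x_new, t = t_next, y = state$y, x0 = state$x0),
            class = "bridge_state")
}

#' Accelerated sampler configuration
#'
#' The reverse process visits a strictly decreasing subsequence of
#' `[0, T]` starting at `T` and ending at `0` (default: `n_steps` evenly
#' spaced jumps, the full-scale default being 20 inference steps over
#' 1000 training steps).
#'
#' @param n_steps number of inference steps (default 20).
#' @param eta stochasticity of the reverse transitions in `[0,1]`.
#' @param T_steps total diffusion steps of the schedule the config will be
#'   used with.
#' @return A `sampler_config` list with `n_steps`, `eta`, `step_indices`.
#' @export
sampler_config <- function(n_steps = 20L, eta = 0, T_steps = 1000L) {
  if (n_steps < 1 || n_steps > T_steps) {
    stop("invalid parameter 'n_steps': need 1 <= n_steps <= T")
  }
  if (eta < 0 || eta > 1) stop("invalid parameter 'eta': need eta in [0,1]")
  idx <- unique(as.integer(floor(seq(T_steps, 0, length.out = n_steps + 1L))))
  idx <- sort(idx, decreasing = TRUE)
  # rounding collisions shrink the list; refill from unused indices so the
  # contract len(step_indices) == n_steps + 1 holds whenever possible
  if (length(idx) < n_steps + 1L) {
    pool <- setdiff(T_steps:0, idx)
    idx <- sort(c(idx, pool[seq_len(n_steps + 1L - length(idx))]),
                decreasing = TRUE)
  }
  structure(list(n_steps = as.integer(n_steps), eta = eta,
                 step_indices = idx),
            class = "sampler_config")
}

#' Sample a target latent from a source latent
#'
#' Runs the accelerated reverse bridge: initialize \eqn{x = y} at
#' \eqn{t = T}, then alternate [estimate_x0()] (through the denoiser) and
#' [reverse_step()] along `cfg$step_indices`, returning the latent at
#' \eqn{t = 0}.  With `eta = 0` the sampler is fully deterministic; with
#' the exact-residual oracle as denoiser it recovers `x0` to machine
#' precision for any step subsequence.
#'
#' @param y source latent.
#' @param denoiser a function `(x_t, t, y) -> residual` of matching shape.
#' @param schedule a [make_schedule()] object.
#' @param cfg a [sampler_config()].
#' @param rng_seed integer seed for the reverse noise (only used when
#'   `eta > 0`).
#' @return The sampled target latent at `t = 0`.
#' @export
bridge_sample <- function(y, denoiser, schedule, cfg = sampler_config(
                            T_steps = schedule$T), rng_seed = 0L) {
  stopifnot(inherits(cfg, "sampler_config"))
  if (cfg$step_indices[1] != schedule$T ||
      cfg$step_indices[length(cfg$step_indices)] != 0L) {
    stop("sampler step_indices must start at T and end at 0")
  }
  local_seed(rng_seed, {
    state <- structure(list(x_t = y, t = schedule$T, y = y, x0 = NULL),
                       class = "bridge_state")
    steps <- cfg$step_indices
    for (k in seq_len(length(steps) - 1L)) {
      t <- steps[k]; t_next <- steps[k + 1L]
      r_hat <- denoiser(state$x_t, t, y)
      if (!identical(dim(r_hat) %||% length(r_hat),
                     dim(state$x_t) %||% length(state$x_t))) {
        stop("contract violation: denoiser output shape mismatch at step t = ",
             t)
      }
      x0_hat <- estimate_x0(state$x_t, t, y, r_hat)
      state <- reverse_step(state, t_next, x0_hat, schedule, eta = cfg$eta)
    }
    state$x_t
  })
}

# ---- conditional-DDPM ablation baseline --------------------------------

#' Linear beta schedule of the conditional-DDPM baseline
#'
#' @param T_steps number of diffusion steps.
#' @param beta_start,beta_end linear range of per-step variances
#'   (conventional defaults 1e-4 and 0.02).
#' @return list with `beta` (length `T`), `alpha_bar` (length `T+1`,
#'   `alpha_bar[1] = 1` so `t = 0` leaves the image untouched).
#' @export
ddpm_schedule <- function(T_steps = 1000L, beta_start = 1e-4,
                          beta_end = 0.02) {
  if (T_steps < 1) stop("invalid parameter 'T_steps'")
  beta <- seq(beta_start, beta_end, length.out = T_steps)
  alpha_bar <- c(1, cumprod(1 - beta))
  list(T = as.integer(T_steps), beta = beta, alpha_bar = alpha_bar)
}

#' Forward corruption of the conditional-DDPM baseline
#'
#' Standard DDPM marginal
#' \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#' The baseline network consumes `(x_t, t, y)` (with the OCT latent
#' concatenated channel-wise) and is trained with an L1 loss against the
#' clean image `x0` itself.
#'
#' @param x0 clean target latent.
#' @param t integer step in `[0, T]`.
#' @param sch a [ddpm_schedule()].
#' @param noise optional unit-Gaussian array.
#' @return The corrupted latent `x_t`.
#' @export
cddpm_training_target <- function(x0, t, sch, noise = NULL) {
  if (t < 0 || t > sch$T || t != round(t)) {
    stop("step index t out of range [0, ", sch$T, "]: ", t)
  }
  if (is.null(noise)) noise <- array(stats::rnorm(length(x0)),
                                     dim = dim(x0) %||% length(x0))
  .check_latents(x0, noise)
  ab <- sch$alpha_bar[t + 1L]
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Deterministic DDIM sampling of the conditional-DDPM baseline
#'
#' Clean-image parameterization: at each visited step the network's
#' \eqn{\hat x_0 = f(x_t, t, y)} is combined with the implied noise
#' direction \eqn{\hat\epsilon = (x_t - \sqrt{\bar\alpha_t}\hat x_0)/
#' \sqrt{1-\bar\alpha_t}} to jump to the next step.
#'
#' @param y source latent (conditioning only; the chain starts from pure
#'   noise).
#' @param denoiser function `(x_t, t, y) -> x0_hat`.
#' @param sch a [ddpm_schedule()].
#' @param n_steps number of evenly spaced DDIM steps.
#' @param rng_seed seed for the initial noise draw.
#' @export
cddpm_sample <- function(y, denoiser, sch, n_steps = 20L, rng_seed = 0L) {
  steps <- unique(as.integer(floor(seq(sch$T, 0, length.out = n_steps + 1L))))
  steps <- sort(steps, decreasing = TRUE)
  local_seed(rng_seed, {
    x <- array(stats::rnorm(length(y)), dim = dim(y) %||% length(y))
    for (k in seq_len(length(steps) - 1L)) {
      t <- steps[k]; t_next <- steps[k + 1L]
      x0_hat <- denoiser(x, t, y)
      if (!identical(dim(x0_hat) %||% length(x0_hat),
                     dim(x) %||% length(x))) {
        stop("contract violation: denoiser output shape mismatch at step t = ",
             t)
      }
      ab_t <- sch$alpha_bar[t + 1L]
      ab_n <- sch$alpha_bar[t_next + 1L]
      eps_hat <- (x - sqrt(ab_t) * x0_hat) / sqrt(max(1 - ab_t, 1e-12))
      x <- sqrt(ab_n) * x0_hat + sqrt(1 - ab_n) * eps_hat
    }
    x
  })
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' internals do not disturb user-level randomness.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
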