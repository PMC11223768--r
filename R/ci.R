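#' Causal attribution probability of the cursor
#'
#' Probability of attributing the clamped cursor to one's own action:
#' `p = S * N(x_v; 0, sigma^2) / (N(x_v; 0, sigma^2) + C)` with the
#' normalised Gaussian density `N`. Symmetric in `x_v` and strictly
#' decreasing in `|x_v|`: far-off cursors are discounted.
#'
#' @param x_v visual cue direction, degrees (vectorised).
#' @param params a [ci_params()].
#' @return Attribution probability in `[0, 1]`.
#' @export
ci_attribution <- function(x_v, params) {
  stopifnot(inherits(params, "ci_params"))
  dens <- stats::dnorm(x_v, 0, params$sigma)
  params$S * dens / (dens + params$C)
}

#' Simulate an adaptation trajectory under the causal-inference model
#'
#' Per-cycle update `x[n+1] = A * x[n] + B * (target - p * x_v)` with
#' the attribution probability `p` from [ci_attribution()]. Feedback
#' modes mirror [simulate_pea()]: on no-feedback cycles the visual term
#' is absent and the state simply decays at rate `A`; on veridical
#' cycles the cursor sits at the hand. A positive clamp drives the state
#' negative; `extent_deg = -state_deg`.
#'
#' The extent-versus-size profile is non-monotone: attribution (and
#' hence learning) collapses for large clamps, so extent peaks at
#' mid-size clamps and declines steeply beyond.
#'
#' @param params a [ci_params()].
#' @param schedule a [feedback_schedule()].
#' @param target target direction, degrees.
#' @return A data.frame of class `"pea_trajectory"` (same schema as
#'   [simulate_pea()]; `x_hat_deg` holds the attributed visual error
#'   `p * x_v`, `sigma_hat_deg` is `NA`).
#' @export
simulate_ci <- function(params, schedule, target = 0) {
  stopifnot(inherits(params, "ci_params"),
            inherits(schedule, "feedback_schedule"))
  n <- nrow(schedule)
  state <- numeric(n)
  attributed <- numeric(n)
  md <- schedule$mode
  clamp <- schedule$clamp_deg
  x <- 0
  for (i in seq_len(n)) {
    state[i] <- x
    err <- switch(md[i],
                  clamp = {
                    xv <- clamp[i]
                    ci_attribution(xv, params) * xv
                  },
                  veridical = {
                    xv <- x - target
                    ci_attribution(xv, params) * xv
                  },
                  none = 0)
    attributed[i] <- err
    x <- params$A * x - params$B * err
  }
  out <- data.frame(
    cycle = schedule$cycle,
    phase = if ("phase" %in% names(schedule)) schedule$phase
            else schedule$mode,
    mode = schedule$mode,
    clamp_deg = schedule$clamp_deg,
    state_deg = state,
    x_hat_deg = attributed,
    sigma_hat_deg = NA_real_,
    perceptual_error_deg = -attributed,
    extent_deg = -(state - target))
  attr(out, "target") <- target
  class(out) <- c("pea_trajectory", "data.frame")
  out
}

# sigma of the integrated cue for a blurred cursor, under the fixed
# sigma_v : sigma_p = 1 : 2 decomposition
ci_blur_sigma <- function(sigma, blur_ratio) {
  sigma * sqrt(5 * blur_ratio^2 / (blur_ratio^2 + 4))
}

#' Single-trial learning under the causal-inference model
#'
#' One learning step from an unadapted state:
#' `B * (target - p * x_v)` with `p` from [ci_attribution()]. Blurring
#' widens the integrated-cue s.d. via
#' `sigma_blur = sigma * sqrt(5 * R^2 / (R^2 + 4))` (the mapping implied
#' by scaling the visual s.d. by `R` with `sigma_v : sigma_p` fixed at
#' 1:2). For large clamps a wider density *raises* the attribution
#' probability, so blur increases learning there -- the model's
#' signature reversal.
#'
#' @param x_v visual cue (clamp) direction, degrees (vectorised).
#' @param params a [ci_params()].
#' @param blur_ratio blur factor, >= 1.
#' @param target target direction, degrees.
#' @return Single-trial change in hand direction, degrees (negative for
#'   a positive clamp).
#' @export
ci_single_trial <- function(x_v, params, blur_ratio = 1, target = 0) {
  stopifnot(inherits(params, "ci_params"))
  if (any(blur_ratio < 1)) stop("'blur_ratio' must be >= 1")
  sigma_b <- ci_blur_sigma(params$sigma, blur_ratio)
  dens <- stats::dnorm(x_v, 0, sigma_b)
  p <- params$S * dens / (dens + params$C)
  -params$B * p * x_v
}
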