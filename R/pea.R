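#' Eccentricity-dependent visual uncertainty
#'
#' The s.d. of the visual (cursor) cue grows linearly with the cursor's
#' angular eccentricity from fixation: `sigma_v = a + b * |theta|`, in
#' degrees. A blurred cursor multiplies the result by `blur_ratio`.
#'
#' @param theta signed cursor direction relative to the target, degrees
#'   (only its magnitude matters; may be a vector).
#' @param params a [pea_params()] object supplying `a` and `b`.
#' @param blur_ratio multiplicative blur factor, >= 1 (1 = clear cursor).
#' @return Visual cue s.d. in degrees, same length as `theta`.
#' @examples
#' visual_uncertainty(64, pea_params())   # 21.629 with the default law
#' @export
visual_uncertainty <- function(theta, params, blur_ratio = 1) {
  stopifnot(inherits(params, "pea_params"))
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  if (any(blur_ratio < 1)) stop("'blur_ratio' must be >= 1")
  blur_ratio * (params$a + params$b * abs(theta))
}

#' One trial's worth of sensory cues
#'
#' Container for the three movement-direction cues and their
#' uncertainties on a single trial: visual (`x_v`), proprioceptive
#' (`x_p`) and predictive (`x_u`), all in degrees.
#'
#' @param x_v,x_p,x_u cue values, degrees.
#' @param sigma_v,sigma_p,sigma_u cue s.d.s, degrees (> 0).
#' @return An object of class `"cue_sample"`.
#' @export
cue_sample <- function(x_v, x_p, x_u, sigma_v, sigma_p, sigma_u) {
  vals <- c(x_v = x_v, x_p = x_p, x_u = x_u)
  sds <- c(sigma_v = sigma_v, sigma_p = sigma_p, sigma_u = sigma_u)
  if (any(!is.finite(vals))) stop("cue values must be finite")
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("cue uncertainties must be finite and strictly positive")
  structure(as.list(c(vals, sds)), class = "cue_sample")
}

#' Precision-weighted cue combination
#'
#' Maximum-likelihood combination of the three movement-direction cues:
#' `x_hat = sum(W_i * x_i)` with precision weights
#' `W_i = (1 / sigma_i^2) / sum(1 / sigma_j^2)` over `i, j` in
#' `{u, p, v}`. The posterior s.d. of the combined estimate is
#' `1 / sqrt(sum(1 / sigma_j^2))`.
#'
#' @param cues a [cue_sample()].
#' @return An object of class `"hand_estimate"`: a list with `x_hat`
#'   (degrees), `sigma_hat` (degrees) and `weights` (named fractions
#'   `u`, `p`, `v` summing to 1).
#' @examples
#' cc <- combine_cues(cue_sample(64, 0, 0, 21.629, 11.119, 5.048))
#' cc$x_hat      # about 2.77: the percept barely follows a 64 deg cursor
#' @export
combine_cues <- function(cues) {
  stopifnot(inherits(cues, "cue_sample"))
  prec <- c(u = 1 / cues$sigma_u^2, p = 1 / cues$sigma_p^2,
            v = 1 / cues$sigma_v^2)
  w <- prec / sum(prec)
  x <- c(u = cues$x_u, p = cues$x_p, v = cues$x_v)
  structure(list(x_hat = sum(w * x),
                 sigma_hat = 1 / sqrt(sum(prec)),
                 weights = w),
            class = "hand_estimate")
}

#' State-space update of the adapted hand direction
#'
#' One cycle of trial-to-trial adaptation: the next hand direction is
#' `A * x_p_state + B * (target - x_hat)`, i.e. retention of the current
#' state plus correction of a fraction of the perceptual error (the
#' deviation of the combined hand estimate from the target).
#'
#' @param x_p_state current adapted hand direction, degrees.
#' @param x_hat combined hand-direction estimate for the cycle, degrees.
#' @param target target direction, degrees.
#' @param params a [pea_params()] supplying `A` and `B`.
#' @return The updated hand direction, degrees.
#' @export
update_state <- function(x_p_state, x_hat, target, params) {
  stopifnot(inherits(params, "pea_params"))
  params$A * x_p_state + params$B * (target - x_hat)
}

# Per-cycle affine form of the deterministic percept:
# x_hat = alpha + beta * state, plus the posterior sd and the visual sd
# actually in play. sigma_v_override replaces the eccentricity law with a
# fixed clear-cursor sd (still scaled by blur).
pea_cycle_coefs <- function(params, schedule, target,
                            sigma_v_override = NULL) {
  n <- nrow(schedule)
  prec_p <- 1 / params$sigma_p^2
  prec_u <- 1 / params$sigma_u^2
  sigma_v <- if (is.null(sigma_v_override)) {
    visual_uncertainty(schedule$clamp_deg, params, schedule$blur_ratio)
  } else {
    if (sigma_v_override <= 0) stop("'sigma_v_override' must be positive")
    schedule$blur_ratio * sigma_v_override
  }
  # veridical cursor sits near fixation: intercept-level uncertainty
  sigma_v[schedule$mode == "veridical"] <-
    if (is.null(sigma_v_override)) {
      (params$a * schedule$blur_ratio)[schedule$mode == "veridical"]
    } else {
      (sigma_v_override * schedule$blur_ratio)[schedule$mode == "veridical"]
    }
  prec_v <- 1 / sigma_v^2
  has_v <- schedule$mode != "none"
  prec_tot <- prec_p + prec_u + ifelse(has_v, prec_v, 0)
  w_u <- prec_u / prec_tot
  w_p <- prec_p / prec_tot
  w_v <- ifelse(has_v, prec_v / prec_tot, 0)
  # cue means: x_u = target; x_p = state; x_v = target + clamp (clamp
  # cycles) or state (veridical cycles); absent on none cycles
  alpha <- w_u * target +
    ifelse(schedule$mode == "clamp", w_v * (target + schedule$clamp_deg), 0)
  beta <- w_p + ifelse(schedule$mode == "veridical", w_v, 0)
  list(alpha = alpha, beta = beta,
       sigma_hat = 1 / sqrt(prec_tot), sigma_v = sigma_v,
       w_u = w_u, w_p = w_p, w_v = w_v, has_v = has_v)
}

#' Simulate an adaptation trajectory under the PEA model
#'
#' Iterates cue combination ([combine_cues()]) and the state-space update
#' ([update_state()]) over a feedback schedule, starting from an
#' unadapted state of 0. In deterministic mode (`noise = FALSE`) every
#' cue sits at its mean: the visual cue at the clamp direction on clamp
#' cycles and at the hand on veridical cycles (and is dropped, with the
#' remaining weights renormalised, on no-feedback cycles); the
#' proprioceptive cue at the current state; the predictive cue at the
#' target. With `noise = TRUE` each available cue is drawn from its
#' Gaussian on every cycle.
#'
#' Sign convention: a positive clamp drives the adapted state negative
#' (away from the cursor); `extent_deg = -state_deg` is the adaptation
#' extent on the usual positive-adaptation plotting scale.
#'
#' @param params a [pea_params()].
#' @param schedule a [feedback_schedule()] or [clamp_schedule()].
#' @param target target direction, degrees.
#' @param noise draw cues stochastically?
#' @param seed optional integer seed used when `noise = TRUE`.
#' @param sigma_v_override optional fixed visual s.d. (degrees) replacing
#'   the eccentricity law, used when fitting free per-size uncertainties.
#' @return A data.frame of class `"pea_trajectory"` with one row per
#'   cycle: `cycle`, `phase`, `mode`, `clamp_deg`, `state_deg`,
#'   `x_hat_deg`, `sigma_hat_deg`, `perceptual_error_deg`, `extent_deg`.
#' @examples
#' tr <- simulate_pea(pea_params(), clamp_schedule(8))
#' tail(tr$extent_deg[tr$phase == "clamp"], 1)  # near the 20.7 deg plateau
#' @export
simulate_pea <- function(params, schedule, target = 0, noise = FALSE,
                         seed = NULL, sigma_v_override = NULL) {
  stopifnot(inherits(params, "pea_params"),
            inherits(schedule, "feedback_schedule"))
  n <- nrow(schedule)
  cf <- pea_cycle_coefs(params, schedule, target, sigma_v_override)
  state <- numeric(n)
  x_hat <- numeric(n)
  x <- 0
  if (!noise) {
    c1 <- params$A - params$B * cf$beta
    c0 <- params$B * (target - cf$alpha)
    for (i in seq_len(n)) {
      state[i] <- x
      x_hat[i] <- cf$alpha[i] + cf$beta[i] * x
      x <- c1[i] * x + c0[i]
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    z_v <- stats::rnorm(n)
    z_p <- stats::rnorm(n)
    z_u <- stats::rnorm(n)
    md <- schedule$mode
    mean_v <- ifelse(md == "clamp", target + schedule$clamp_deg, NA_real_)
    for (i in seq_len(n)) {
      state[i] <- x
      mv <- if (md[i] == "veridical") x else mean_v[i]
      xu <- target + params$sigma_u * z_u[i]
      xp <- x + params$sigma_p * z_p[i]
      xh <- cf$w_u[i] * xu + cf$w_p[i] * xp
      if (cf$has_v[i]) xh <- xh + cf$w_v[i] * (mv + cf$sigma_v[i] * z_v[i])
      x_hat[i] <- xh
      x <- params$A * x + params$B * (target - xh)
    }
  }
  out <- data.frame(
    cycle = schedule$cycle,
    phase = if ("phase" %in% names(schedule)) schedule$phase
            else schedule$mode,
    mode = schedule$mode,
    clamp_deg = schedule$clamp_deg,
    state_deg = state,
    x_hat_deg = x_hat,
    sigma_hat_deg = cf$sigma_hat,
    perceptual_error_deg = target - x_hat,
    extent_deg = -(state - target))
  attr(out, "target") <- target
  class(out) <- c("pea_trajectory", "data.frame")
  out
}

#' Closed-form adaptation asymptote of the PEA model
#'
#' Long-run fixed point of the adapted state under a constant error
#' clamp: `-(B / sigma_v^2) / (B / sigma_p^2 + (1 - A) * sum(1 / sigma_j^2))
#' * theta`, with `sigma_v` from [visual_uncertainty()]. The positive
#' effect of clamp size on adaptation is counteracted by the rise of
#' visual uncertainty with eccentricity, giving a concave extent-vs-size
#' profile.
#'
#' @param theta signed clamp size, degrees (vectorised).
#' @param params a [pea_params()].
#' @param blur_ratio blur factor applied to `sigma_v`, >= 1.
#' @return The asymptotic state in degrees (negative for a positive
#'   clamp); negate for the adaptation extent.
#' @examples
#' -pea_asymptote(8, pea_params())   # extent of about 20.7 deg
#' @export
pea_asymptote <- function(theta, params, blur_ratio = 1) {
  stopifnot(inherits(params, "pea_params"))
  if (params$A == 1 && params$B == 0)
    stop("asymptote undefined for A = 1, B = 0")
  sigma_v <- visual_uncertainty(theta, params, blur_ratio)
  prec_sum <- 1 / sigma_v^2 + 1 / params$sigma_p^2 + 1 / params$sigma_u^2
  denom <- params$B / params$sigma_p^2 + (1 - params$A) * prec_sum
  if (any(denom <= 0)) stop("asymptote undefined: non-positive denominator")
  -(params$B / sigma_v^2) / denom * theta
}

#' Ratio-parameterised asymptote with full retention
#'
#' With retention `A = 1` the learning rate cancels from the asymptote,
#' leaving `-(R1_ext / (1 + R2_ext * |theta|))^2 * theta` with
#' `R1_ext = sigma_p / a` and `R2_ext = b / a`. This two-parameter form
#' is used to fit adaptation-extent-versus-size data alone.
#'
#' @param theta signed clamp size, degrees (vectorised).
#' @param R1_ext ratio `sigma_p / a` (> 0, unitless).
#' @param R2_ext ratio `b / a` (per degree, >= 0).
#' @return Asymptotic state in degrees.
#' @export
asymptote_ratio_form <- function(theta, R1_ext, R2_ext) {
  if (R1_ext <= 0) stop("'R1_ext' must be strictly positive")
  -(R1_ext / (1 + R2_ext * abs(theta)))^2 * theta
}

#' Reported hand position after a reach
#'
#' When the hand rests at the end of a reach and its position is
#' reported, the report combines the just-formed hand estimate with the
#' proprioceptive cue from the static hand:
#' `x_hat + sigma_hat^2 / (sigma_hat^2 + sigma_p^2) * (x_p_state - x_hat)`.
#' Applied cycle-by-cycle over an adaptation run this reproduces the
#' characteristic drift of active hand localisation: biased toward the
#' cursor early, drifting past the target late.
#'
#' @param x_hat combined hand estimate, degrees.
#' @param sigma_hat posterior s.d. of the estimate, degrees (> 0).
#' @param x_p_state actual (adapted) hand direction, degrees.
#' @param sigma_p proprioceptive s.d., degrees (> 0).
#' @return Reported hand position, degrees (vectorised).
#' @export
report_hand <- function(x_hat, sigma_hat, x_p_state, sigma_p) {
  if (any(sigma_hat <= 0) || any(sigma_p <= 0))
    stop("uncertainties must be strictly positive")
  w <- sigma_hat^2 / (sigma_hat^2 + sigma_p^2)
  x_hat + w * (x_p_state - x_hat)
}

#' Proprioceptive bias induced by the hand estimate
#'
#' Passive localisation of the hand is biased by a fraction `Rp` of the
#' recent hand estimate's deviation from the true (passively placed)
#' hand: `bias = Rp * x_hat`. The bias points toward the clamp whenever
#' the estimate does.
#'
#' @param x_hat recent hand estimate, degrees (vectorised).
#' @param Rp influence fraction, in `(0, 1]`.
#' @return Probe bias in degrees.
#' @export
proprioceptive_bias <- function(x_hat, Rp) {
  if (Rp <= 0 || Rp > 1) stop("'Rp' must lie in (0, 1]")
  Rp * x_hat
}

#' Single-trial learning under the PEA model
#'
#' For an isolated perturbation trial flanked by no-feedback trials the
#' predictive and proprioceptive cues share the target as their mean and
#' are merged into one integrated cue with variance
#' `sigma_int^2 = sigma_u^2 * sigma_p^2 / (sigma_u^2 + sigma_p^2)`.
#' The percept is the precision-weighted mix of the integrated cue (at
#' the target) and the visual cue (at the clamp); single-trial learning
#' is `B * (target - x_hat)`. Blurring scales `sigma_v` by `blur_ratio`,
#' attenuating learning most for large clamps, whose visual weight has
#' the most to lose.
#'
#' @param theta signed clamp size, degrees (vectorised).
#' @param params a [pea_params()].
#' @param blur_ratio blur factor, >= 1.
#' @param target target direction, degrees.
#' @return Single-trial change in hand direction, degrees (negative for
#'   a positive clamp).
#' @export
pea_single_trial <- function(theta, params, blur_ratio = 1, target = 0) {
  stopifnot(inherits(params, "pea_params"))
  if (any(blur_ratio < 1)) stop("'blur_ratio' must be >= 1")
  sigma_v <- visual_uncertainty(theta, params, blur_ratio)
  prec_int <- 1 / params$sigma_u^2 + 1 / params$sigma_p^2
  prec_v <- 1 / sigma_v^2
  w_v <- prec_v / (prec_int + prec_v)
  x_hat <- (1 - w_v) * target + w_v * (target + theta)
  params$B * (target - x_hat)
}
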