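#' Perceived hand position under the PReMo model
#'
#' The proprioceptive re-alignment account: the hand percept is shifted
#' by a saturating function of the visual-proprioceptive discrepancy,
#' `percept = beta_p + R2 * x_p_state` with
#' `beta_p = -sign(d) * min(beta_sat, eta_p * |d|)` and
#' `d = R1 * x_v - R2 * x_p_state`. The saturation is applied to the
#' magnitude of the discrepancy, so clockwise and counter-clockwise
#' clamps behave symmetrically.
#'
#' PReMo's printed equations carry the positive-adaptation convention:
#' a positive visual cue yields a negative percept, hence a positive
#' error and a state that grows positive (away from the cursor).
#'
#' @param x_p_state current adapted hand direction, degrees.
#' @param x_v visual cue direction, degrees (`NA` for no feedback, in
#'   which case the visual shift is absent and the percept is
#'   `R2 * x_p_state`).
#' @param params a [premo_params()].
#' @return The perceived hand direction, degrees.
#' @export
premo_percept <- function(x_p_state, x_v, params) {
  stopifnot(inherits(params, "premo_params"))
  if (is.na(x_v)) return(params$R2 * x_p_state)
  d <- params$R1 * x_v - params$R2 * x_p_state
  beta_p <- -sign(d) * min(params$beta_sat, params$eta_p * abs(d))
  beta_p + params$R2 * x_p_state
}

#' Simulate an adaptation trajectory under the PReMo model
#'
#' Per-cycle update `x[n+1] = A * x[n] + B * (target - percept)` with the
#' percept from [premo_percept()]. Feedback modes mirror
#' [simulate_pea()]: the visual cue is the clamp direction on clamp
#' cycles, the hand on veridical cycles, and absent on no-feedback
#' cycles. Because PReMo's state already lives on the
#' positive-adaptation scale, `extent_deg` equals `state_deg`.
#'
#' Once the saturation binds, the predicted extent-versus-size profile is
#' a ramp: linear for small clamps, flat beyond the binding size.
#'
#' @param params a [premo_params()].
#' @param schedule a [feedback_schedule()].
#' @param target target direction, degrees.
#' @return A data.frame of class `"pea_trajectory"` (same schema as
#'   [simulate_pea()]; `x_hat_deg` holds the PReMo percept,
#'   `sigma_hat_deg` is `NA`).
#' @export
simulate_premo <- function(params, schedule, target = 0) {
  stopifnot(inherits(params, "premo_params"),
            inherits(schedule, "feedback_schedule"))
  n <- nrow(schedule)
  state <- numeric(n)
  percept <- numeric(n)
  md <- schedule$mode
  clamp <- schedule$clamp_deg
  x <- 0
  for (i in seq_len(n)) {
    state[i] <- x
    x_v <- switch(md[i],
                  clamp = target + clamp[i],
                  veridical = x,
                  none = NA_real_)
    pc <- premo_percept(x, x_v, params)
    percept[i] <- pc
    x <- params$A * x + params$B * (target - pc)
  }
  out <- data.frame(
    cycle = schedule$cycle,
    phase = if ("phase" %in% names(schedule)) schedule$phase
            else schedule$mode,
    mode = schedule$mode,
    clamp_deg = schedule$clamp_deg,
    state_deg = state,
    x_hat_deg = percept,
    sigma_hat_deg = NA_real_,
    perceptual_error_deg = target - percept,
    extent_deg = state - target)
  attr(out, "target") <- target
  class(out) <- c("pea_trajectory", "data.frame")
  out
}

# Map a blur ratio onto PReMo's R1 by decomposing it into sigma_u and
# sigma_v (sigma_v recovered from R1 given sigma_u) and rescaling
# sigma_v by the blur ratio.
premo_blur_r1 <- function(params, blur_ratio) {
  sigma_v2 <- params$sigma_u^2 * (1 - params$R1) / params$R1
  params$sigma_u^2 / (params$sigma_u^2 + blur_ratio^2 * sigma_v2)
}

#' Single-trial learning under the PReMo model
#'
#' One learning step from an unadapted state:
#' `B * (target - percept)` with the percept from [premo_percept()].
#' Cursor blurring scales the visual s.d. hidden inside `R1`:
#' `R1' = sigma_u^2 / (sigma_u^2 + (blur_ratio * sigma_v)^2)` with
#' `sigma_v` recovered from the fitted `R1` and the carried `sigma_u`.
#' When the saturation binds, blur has no effect: learning is pinned at
#' `B * beta_sat` regardless of visual uncertainty.
#'
#' @param x_v visual cue (clamp) direction, degrees (vectorised).
#' @param params a [premo_params()].
#' @param blur_ratio blur factor, >= 1.
#' @param target target direction, degrees.
#' @return Single-trial change in hand direction, degrees.
#' @export
premo_single_trial <- function(x_v, params, blur_ratio = 1, target = 0) {
  stopifnot(inherits(params, "premo_params"))
  if (any(blur_ratio < 1)) stop("'blur_ratio' must be >= 1")
  r1 <- premo_blur_r1(params, blur_ratio)
  d <- r1 * x_v           # state = 0, so the R2 term vanishes
  beta_p <- -sign(d) * pmin(params$beta_sat, params$eta_p * abs(d))
  params$B * (target - beta_p)
}
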