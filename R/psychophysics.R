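#' Two-parameter logistic psychometric function
#'
#' Probability of judging the reference point counter-clockwise of the
#' cursor: `p = 1 / (1 + exp(-k * (x - x0)))`, with slope `k` (per
#' degree) and point of subjective equality `x0` (degrees).
#'
#' @param x reference offset relative to the cursor, degrees, CCW
#'   positive (vectorised).
#' @param k logistic slope, per degree.
#' @param x0 point of subjective equality, degrees.
#' @return Response probability.
#' @export
logistic_p <- function(x, k, x0) {
  1 / (1 + exp(-k * (x - x0)))
}

#' Visual uncertainty from the logistic slope
#'
#' Discrimination uncertainty is defined as the offset span between the
#' 25% and 75% points of the psychometric function:
#' `sigma_v = (log(3) - log(1/3)) / k = 2 * log(3) / k`.
#'
#' @param k logistic slope, per degree (> 0).
#' @return `sigma_v` in degrees.
#' @examples
#' sigma_from_slope(0.2197)  # about 10 degrees
#' @export
sigma_from_slope <- function(k) {
  if (any(k <= 0)) stop("'k' must be strictly positive")
  2 * log(3) / k
}

#' Maximum-likelihood fit of the 2AFC psychometric function
#'
#' Fits the two-parameter logistic ([logistic_p()]) to binary
#' direction judgments by Bernoulli maximum likelihood (logistic
#' regression on the offset), and converts the slope to a visual
#' uncertainty via [sigma_from_slope()]. No lapse-rate parameter is
#' included.
#'
#' @param samples a data.frame with columns `reference_offset_deg`
#'   (signed, CCW positive) and `response_ccw` (0/1 or logical).
#' @return An object of class `"psychometric_fit"`: a list with `k`,
#'   `x0`, `sigma_v`, `n_trials`, and the underlying `glm` fit.
#' @section Errors:
#' Fails with an explicit error when fewer than 4 distinct offsets are
#' present, when all responses fall in one category, or when the
#' responses are completely separated (the ML slope diverges).
#' @export
fit_logistic <- function(samples) {
  need <- c("reference_offset_deg", "response_ccw")
  if (!all(need %in% names(samples)))
    stop("'samples' must contain columns: ", paste(need, collapse = ", "))
  x <- samples$reference_offset_deg
  y <- as.integer(samples$response_ccw)
  if (any(!is.finite(x))) stop("offsets must be finite")
  if (!all(y %in% 0:1)) stop("'response_ccw' must be binary")
  if (length(unique(x)) < 4L)
    stop("need responses at >= 4 distinct offsets")
  if (length(unique(y)) < 2L)
    stop("responses all fall in one category; slope is not identifiable")
  # complete separation: every CCW response lies above every CW response
  if (min(x[y == 1]) > max(x[y == 0]))
    stop("responses are completely separated; slope is not identifiable")
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial("logit")))
  k <- unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0)
    stop("logistic fit produced a non-positive slope")
  x0 <- -unname(stats::coef(fit)[1]) / k
  structure(list(k = k, x0 = x0, sigma_v = sigma_from_slope(k),
                 n_trials = length(y), glm_fit = fit),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric fit: k = %.4g /deg, x0 = %.4g deg, sigma_v = %.4g deg (n = %d)\n",
              x$k, x$x0, x$sigma_v, x$n_trials))
  invisible(x)
}

#' Start a PEST staircase round
#'
#' Initialises one round of the adaptive staircase used to measure the
#' cursor-direction discrimination threshold. The reference offset
#' starts at 30 degrees on the given side of the cursor and steps toward
#' it in 10-degree steps; the step is halved and the movement direction
#' reversed whenever the judgment changes; a round terminates when the
#' step falls below `termination_step` or the trial count exceeds
#' `max_trials`. Successive rounds start on alternating sides.
#'
#' @param start_side `"cw"` or `"ccw"`: side of the cursor on which the
#'   reference starts (CW = negative offsets).
#' @param start_offset unsigned starting offset, degrees.
#' @param start_step initial step size, degrees.
#' @return An object of class `"pest_state"`.
#' @seealso [pest_step()], [run_pest_round()]
#' @export
pest_start <- function(start_side = c("ccw", "cw"), start_offset = 30,
                       start_step = 10) {
  start_side <- match.arg(start_side)
  if (start_offset <= 0) stop("'start_offset' must be positive")
  if (start_step <= 0) stop("'start_step' must be positive")
  side <- if (start_side == "ccw") 1 else -1
  structure(list(offset = side * start_offset,
                 step = start_step,
                 direction = -side,   # first steps move toward the cursor
                 last_response = NA,
                 trial = 0L,
                 start_side = start_side,
                 terminated = FALSE,
                 history = data.frame(trial = integer(),
                                      offset_deg = numeric(),
                                      step_deg = numeric(),
                                      response_ccw = integer())),
            class = "pest_state")
}

#' Advance a PEST staircase by one judgment
#'
#' Records the observer's response at the current offset, halves the
#' step and reverses direction if the judgment changed from the previous
#' trial, then moves the offset by the (possibly updated) step. The
#' round terminates when the step drops below `termination_step` or when
#' `max_trials` responses have been recorded.
#'
#' @param state a `"pest_state"` from [pest_start()].
#' @param response_ccw the binary judgment at the current offset
#'   (1/TRUE = "reference is CCW of the cursor").
#' @param termination_step step-size criterion, degrees.
#' @param max_trials trial cap per round.
#' @return The updated `"pest_state"`; check `$terminated`.
#' @export
pest_step <- function(state, response_ccw, termination_step = 1,
                      max_trials = 30L) {
  stopifnot(inherits(state, "pest_state"))
  if (state$terminated) stop("round already terminated")
  response_ccw <- as.integer(response_ccw)
  if (!response_ccw %in% 0:1) stop("'response_ccw' must be binary")
  state$trial <- state$trial + 1L
  state$history <- rbind(state$history,
                         data.frame(trial = state$trial,
                                    offset_deg = state$offset,
                                    step_deg = state$step,
                                    response_ccw = response_ccw))
  if (!is.na(state$last_response) &&
      response_ccw != state$last_response) {
    state$step <- state$step / 2
    state$direction <- -state$direction
  }
  state$last_response <- response_ccw
  if (state$step < termination_step || state$trial >= max_trials) {
    state$terminated <- TRUE
  } else {
    state$offset <- state$offset + state$direction * state$step
  }
  state
}

#' Run one PEST round against an observer function
#'
#' Drives [pest_step()] with responses from `respond(offset)` until the
#' round terminates.
#'
#' @param respond a function mapping a signed offset (degrees) to a
#'   binary CCW judgment.
#' @param start_side,start_offset,start_step see [pest_start()].
#' @param termination_step,max_trials see [pest_step()].
#' @return The round's history data.frame (columns `trial`,
#'   `offset_deg`, `step_deg`, `response_ccw`).
#' @export
run_pest_round <- function(respond, start_side = "ccw",
                           start_offset = 30, start_step = 10,
                           termination_step = 1, max_trials = 30L) {
  state <- pest_start(start_side, start_offset, start_step)
  while (!state$terminated) {
    r <- respond(state$offset)
    state <- pest_step(state, r, termination_step, max_trials)
  }
  state$history
}

#' Linear eccentricity law of visual uncertainty
#'
#' Regresses per-condition visual uncertainties on the absolute clamp
#' size with a gamma-family GLM and identity link, returning the
#' intercept `a` and slope `b` of `sigma_v = a + b * |theta|`. The gamma
#' family reflects that uncertainty estimates are positive and
#' right-skewed across observers.
#'
#' @param sigma_v_by_theta a data.frame with columns `theta_abs`
#'   (degrees, >= 0) and `sigma_v` (degrees, > 0); typically one row per
#'   observer and clamp size.
#' @return An object of class `"uncertainty_law"`: a list with `a`, `b`,
#'   their standard errors and Wald 95% confidence intervals, and the
#'   underlying `glm` fit.
#' @export
fit_uncertainty_law <- function(sigma_v_by_theta) {
  need <- c("theta_abs", "sigma_v")
  if (!all(need %in% names(sigma_v_by_theta)))
    stop("need columns: ", paste(need, collapse = ", "))
  df <- sigma_v_by_theta
  if (length(unique(df$theta_abs)) < 2L)
    stop("need at least 2 distinct |theta| values")
  if (any(df$sigma_v <= 0)) stop("'sigma_v' must be strictly positive")
  start <- unname(stats::coef(stats::lm(sigma_v ~ theta_abs, data = df)))
  if (start[1] <= 0) start[1] <- min(df$sigma_v) / 2
  if (start[2] < 0) start[2] <- 0
  # exact-fit data drive the gamma dispersion to zero, which sprays
  # harmless NaN warnings from the IRLS internals; convergence and the
  # coefficients are checked explicitly below
  fit <- suppressWarnings(
    stats::glm(sigma_v ~ theta_abs, data = df,
               family = stats::Gamma(link = "identity"),
               start = start))
  if (!fit$converged) stop("gamma GLM did not converge")
  if (any(!is.finite(stats::coef(fit))))
    stop("gamma GLM produced non-finite coefficients")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(a = unname(cf[1]), b = unname(cf[2]),
                 se_a = unname(se[1]), se_b = unname(se[2]),
                 ci_a = unname(cf[1] + c(-1.96, 1.96) * se[1]),
                 ci_b = unname(cf[2] + c(-1.96, 1.96) * se[2]),
                 glm_fit = fit),
            class = "uncertainty_law")
}

#' @export
print.uncertainty_law <- function(x, ...) {
  cat(sprintf("sigma_v = %.4g + %.4g * |theta|  (deg)\n", x$a, x$b))
  cat(sprintf("  95%% CI  a: [%.3g, %.3g]  b: [%.3g, %.3g]\n",
              x$ci_a[1], x$ci_a[2], x$ci_b[1], x$ci_b[2]))
  invisible(x)
}

#' Per-condition uncertainty estimates from a 2AFC dataset
#'
#' Splits a tidy 2AFC trial table by subject and signed clamp size,
#' fits the psychometric function to each cell ([fit_logistic()]), and
#' returns the per-cell slope, PSE and visual uncertainty. Cells whose
#' fit fails (too few offsets, one-sided responses, separation) are
#' dropped with a warning.
#'
#' @param trials a data.frame with columns `subject`, `clamp_deg`
#'   (signed), `reference_offset_deg`, `response_ccw`.
#' @return A data.frame with one row per (subject, clamp size):
#'   `subject`, `clamp_deg`, `theta_abs`, `k`, `x0`, `sigma_v`,
#'   `n_trials`.
#' @export
estimate_sigma_v <- function(trials) {
  need <- c("subject", "clamp_deg", "reference_offset_deg", "response_ccw")
  if (!all(need %in% names(trials)))
    stop("need columns: ", paste(need, collapse = ", "))
  cells <- split(trials, list(trials$subject, trials$clamp_deg),
                 drop = TRUE)
  rows <- lapply(cells, function(cell) {
    fit <- tryCatch(fit_logistic(cell), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(subject = cell$subject[1],
               clamp_deg = cell$clamp_deg[1],
               theta_abs = abs(cell$clamp_deg[1]),
               k = fit$k, x0 = fit$x0, sigma_v = fit$sigma_v,
               n_trials = fit$n_trials)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " subject-by-size cells dropped (unfittable)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("no subject-by-size cell could be fitted")
  rownames(out) <- NULL
  out[order(out$subject, out$clamp_deg), , drop = FALSE]
}
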