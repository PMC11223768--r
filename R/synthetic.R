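new_synthetic_dataset <- function(experiment, data, truth, seed) {
  structure(list(experiment = experiment, data = data,
                 truth = truth, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset '%s': %d rows (seed %d)\n",
              x$experiment, nrow(x$data), x$seed))
  utils::str(x$truth, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Synthetic multi-group error-clamp adaptation experiment
#'
#' Emulates the seven-group adaptation design: per subject and cycle,
#' the stochastic PEA simulator (cues drawn from their Gaussians) plus
#' additive motor execution noise produces an observed hand angle.
#' Clamp directions are counterbalanced across subjects and the table is
#' sign-folded to the positive-adaptation convention, so group means
#' converge to the deterministic trajectory as the group grows. Motor
#' noise enters at the cycle level as the mean of `trials_per_cycle`
#' independent per-trial deviations.
#'
#' @param seed integer seed (required).
#' @param clamp_sizes unsigned clamp sizes, degrees, one group each.
#' @param n_subjects subjects per group.
#' @param params truth [pea_params()].
#' @param motor_noise_sd per-trial motor execution s.d., degrees
#'   (default matches typical baseline movement variability).
#' @param trials_per_cycle reaches averaged into one cycle.
#' @param cue_noise draw sensory cues stochastically? (`FALSE` gives the
#'   deterministic trajectory plus motor noise only.)
#' @param schedule_args named list passed to [clamp_schedule()].
#' @return A `"synthetic_dataset"` whose `$data` has columns `subject`,
#'   `clamp_deg` (unsigned group size), `direction`, `cycle`, `phase`,
#'   `mode`, `hand_deg` (sign-folded), and whose `$truth` records the
#'   generating parameters.
#' @export
gen_adaptation <- function(seed,
                           clamp_sizes = c(2, 4, 8, 16, 32, 64, 95),
                           n_subjects = 12,
                           params = pea_params(),
                           motor_noise_sd = 5.128,
                           trials_per_cycle = 4,
                           cue_noise = TRUE,
                           schedule_args = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_subjects < 1) stop("'n_subjects' must be positive")
  set.seed(seed)
  cycle_noise_sd <- motor_noise_sd / sqrt(trials_per_cycle)
  rows <- list()
  subj_id <- 0L
  for (theta in clamp_sizes) {
    for (s in seq_len(n_subjects)) {
      subj_id <- subj_id + 1L
      dir <- if (s <= ceiling(n_subjects / 2)) 1 else -1
      sched <- do.call(clamp_schedule, c(list(theta = dir * theta),
                                         schedule_args))
      tr <- simulate_pea(params, sched, noise = cue_noise)
      hand <- dir * tr$extent_deg +
        stats::rnorm(nrow(tr), 0, cycle_noise_sd)
      rows[[subj_id]] <- data.frame(
        subject = subj_id, clamp_deg = theta, direction = dir,
        cycle = tr$cycle, phase = tr$phase, mode = tr$mode,
        hand_deg = hand)
    }
  }
  new_synthetic_dataset("exp2_adaptation", do.call(rbind, rows),
                        list(params = unclass(params),
                             motor_noise_sd = motor_noise_sd,
                             trials_per_cycle = trials_per_cycle,
                             cue_noise = cue_noise),
                        as.integer(seed))
}

#' Synthetic 2AFC cursor-direction discrimination experiment
#'
#' Emulates the visual-uncertainty measurement: for each subject, signed
#' clamp size and day, PEST staircase rounds
#' ([run_pest_round()], alternating starting side, first round CW) are
#' driven by a logistic observer whose slope encodes the truth
#' eccentricity law: `k = 2 * log(3) / (a + b * |theta|)`, PSE at 0.
#'
#' @param seed integer seed (required).
#' @param clamp_sizes unsigned clamp sizes; both directions are run.
#' @param n_subjects number of observers.
#' @param n_days simulated sessions (data are pooled across days when
#'   fitting).
#' @param rounds_per_day PEST rounds per signed size per day.
#' @param a,b truth eccentricity law (degrees; degrees per degree).
#' @param termination_step,max_trials staircase stopping rules
#'   (see [pest_step()]).
#' @return A `"synthetic_dataset"` whose `$data` has columns `subject`,
#'   `day`, `clamp_deg` (signed), `round`, `trial_in_round`,
#'   `reference_offset_deg`, `response_ccw`.
#' @export
gen_2afc <- function(seed,
                     clamp_sizes = c(4, 16, 64),
                     n_subjects = 18,
                     n_days = 3,
                     rounds_per_day = 4,
                     a = 1.853, b = 0.309,
                     termination_step = 1,
                     max_trials = 30L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  signed <- c(clamp_sizes, -clamp_sizes)
  rows <- list()
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (theta in signed) {
      sigma_v <- a + b * abs(theta)
      k <- 2 * log(3) / sigma_v
      respond <- function(offset)
        as.integer(stats::runif(1) < logistic_p(offset, k, 0))
      for (day in seq_len(n_days)) {
        for (r in seq_len(rounds_per_day)) {
          side <- if (r %% 2 == 1) "cw" else "ccw"
          hist <- run_pest_round(respond, start_side = side,
                                 termination_step = termination_step,
                                 max_trials = max_trials)
          i <- i + 1L
          rows[[i]] <- data.frame(
            subject = s, day = day, clamp_deg = theta, round = r,
            trial_in_round = hist$trial,
            reference_offset_deg = hist$offset_deg,
            response_ccw = hist$response_ccw)
        }
      }
    }
  }
  new_synthetic_dataset("exp1_2afc", do.call(rbind, rows),
                        list(a = a, b = b,
                             sigma_v = stats::setNames(
                               a + b * clamp_sizes,
                               paste0("theta_", clamp_sizes))),
                        as.integer(seed))
}

#' Synthetic proprioception-probe experiment
#'
#' Emulates the alternating design of reaching and passive-probe blocks:
#' each block holds six stochastic error-clamp reaches at one signed
#' clamp size (randomised across blocks) followed by three passive
#' probes. The probe bias is the hand-estimate influence
#' ([proprioceptive_bias()]) decayed geometrically across the three
#' probes, plus report noise; the hand estimate is the one formed on the
#' block's final reach. Initial veridical and no-feedback blocks mirror
#' the session warm-up.
#'
#' @param seed integer seed (required).
#' @param clamp_sizes unsigned clamp sizes; both directions are used.
#' @param n_subjects number of participants.
#' @param blocks_per_size perturbation blocks per signed size.
#' @param reaches_per_block clamp reaches per block.
#' @param n_probes passive probe trials per block.
#' @param params truth [pea_params()].
#' @param rparams truth [report_params()] (influence fraction and
#'   per-probe decay).
#' @param report_noise_sd probe report noise s.d., degrees.
#' @param cue_noise draw reach cues stochastically?
#' @return A `"synthetic_dataset"` whose `$data` has columns `subject`,
#'   `block`, `clamp_deg` (signed; 0 and `NA`-free), `probe`,
#'   `bias_deg`.
#' @export
gen_proprioception <- function(seed,
                               clamp_sizes = c(10, 20, 40, 80),
                               n_subjects = 11,
                               blocks_per_size = 4,
                               reaches_per_block = 6,
                               n_probes = 3,
                               params = pea_params(),
                               rparams = report_params(),
                               report_noise_sd = 4,
                               cue_noise = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  signed <- c(clamp_sizes, -clamp_sizes)
  rows <- list()
  i <- 0L
  for (s in seq_len(n_subjects)) {
    block_sizes <- sample(rep(signed, blocks_per_size))
    x <- 0
    for (blk in seq_along(block_sizes)) {
      theta <- block_sizes[blk]
      sched <- feedback_schedule(rep("clamp", reaches_per_block),
                                 clamp_deg = theta)
      # continue the running state across blocks
      tr <- simulate_reaches_from(params, sched, x, cue_noise)
      x <- tr$final_state
      x_hat_last <- tr$x_hat_last
      for (probe in seq_len(n_probes)) {
        influence <- rparams$decay_lambda^(probe - 1)
        bias <- proprioceptive_bias(x_hat_last, rparams$Rp) * influence +
          stats::rnorm(1, 0, report_noise_sd)
        i <- i + 1L
        rows[[i]] <- data.frame(subject = s, block = blk,
                                clamp_deg = theta, probe = probe,
                                bias_deg = bias)
      }
    }
  }
  new_synthetic_dataset("exp3_proprioception", do.call(rbind, rows),
                        list(params = unclass(params),
                             rparams = unclass(rparams),
                             report_noise_sd = report_noise_sd),
                        as.integer(seed))
}

# run a short reach schedule continuing from a given state; returns the
# final state and the hand estimate of the last reach
simulate_reaches_from <- function(params, schedule, state0, cue_noise) {
  n <- nrow(schedule)
  cf <- pea_cycle_coefs(params, schedule, target = 0)
  x <- state0
  x_hat <- NA_real_
  for (i in seq_len(n)) {
    if (cue_noise) {
      xu <- params$sigma_u * stats::rnorm(1)
      xp <- x + params$sigma_p * stats::rnorm(1)
      xv <- schedule$clamp_deg[i] + cf$sigma_v[i] * stats::rnorm(1)
      x_hat <- cf$w_u[i] * xu + cf$w_p[i] * xp + cf$w_v[i] * xv
    } else {
      x_hat <- cf$alpha[i] + cf$beta[i] * x
    }
    x <- params$A * x + params$B * (0 - x_hat)
  }
  list(final_state = x, x_hat_last = x_hat)
}

#' Synthetic single-trial learning experiment with cursor blurring
#'
#' Emulates the triplet design: each perturbation trial (clear or
#' blurred cursor, one of several signed clamp sizes) is flanked by two
#' no-feedback trials, and single-trial learning is the hand-angle
#' difference between the flanking trials. The observed value is the
#' model's single-trial learning ([pea_single_trial()]) sign-folded to
#' the positive-adaptation convention plus the difference of two
#' independent motor noise draws. Triplets are independent, mirroring
#' the randomised, history-free design.
#'
#' @param seed integer seed (required).
#' @param clamp_sizes unsigned clamp sizes; both directions are used.
#' @param n_subjects number of participants.
#' @param n_days,blocks_per_day mini-block counts.
#' @param blur_ratio truth visual-uncertainty ratio of the blurred
#'   cursor (>= 1).
#' @param params truth [pea_params()].
#' @param motor_noise_sd per-trial motor noise s.d., degrees.
#' @return A `"synthetic_dataset"` whose `$data` has columns `subject`,
#'   `day`, `block`, `clamp_deg` (unsigned), `direction`, `blurred`,
#'   `stl_deg` (sign-folded).
#' @export
gen_stl_triplets <- function(seed,
                             clamp_sizes = c(4, 16, 64),
                             n_subjects = 19,
                             n_days = 3,
                             blocks_per_day = 15,
                             blur_ratio = 2,
                             params = pea_params(),
                             motor_noise_sd = 5.128) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (blur_ratio < 1) stop("'blur_ratio' must be >= 1")
  set.seed(seed)
  combos <- expand.grid(direction = c(1, -1), clamp = clamp_sizes,
                        blurred = c(FALSE, TRUE))
  blocks <- expand.grid(combo = seq_len(nrow(combos)),
                        block = seq_len(blocks_per_day),
                        day = seq_len(n_days),
                        subject = seq_len(n_subjects))
  # randomise perturbation order within each mini-block
  blk_id <- with(blocks, interaction(subject, day, block, drop = TRUE))
  blocks$trial <- stats::ave(seq_len(nrow(blocks)), blk_id,
                             FUN = function(ix) sample(length(ix)))
  blocks <- blocks[order(blocks$subject, blocks$day, blocks$block,
                         blocks$trial), ]
  dir <- combos$direction[blocks$combo]
  theta <- combos$clamp[blocks$combo]
  blurred <- combos$blurred[blocks$combo]
  rv <- ifelse(blurred, blur_ratio, 1)
  stl <- pea_single_trial(dir * theta, params, blur_ratio = rv)
  eps_pre <- stats::rnorm(nrow(blocks), 0, motor_noise_sd)
  eps_post <- stats::rnorm(nrow(blocks), 0, motor_noise_sd)
  dat <- data.frame(subject = blocks$subject, day = blocks$day,
                    block = blocks$block, clamp_deg = theta,
                    direction = dir, blurred = blurred,
                    stl_deg = -dir * (stl + eps_post - eps_pre))
  rownames(dat) <- NULL
  new_synthetic_dataset("exp4_stl", dat,
                        list(params = unclass(params),
                             blur_ratio = blur_ratio,
                             motor_noise_sd = motor_noise_sd),
                        as.integer(seed))
}

#' Synthetic continuous hand-report drift during adaptation
#'
#' Emulates the active-localisation setting: a long error-clamp block
#' (default 30 degrees) during which the hand position is reported on
#' every trial. Reports follow [report_hand()] applied to the evolving
#' hand estimate and adapted state, and are emitted on the
#' positive-adaptation plotting convention, on which they drift from
#' negative (toward the cursor) to positive as adaptation accrues.
#'
#' @param seed integer seed (required).
#' @param clamp_deg unsigned clamp size, degrees.
#' @param n_baseline veridical baseline trials.
#' @param n_clamp clamp trials.
#' @param params truth [pea_params()].
#' @param cue_noise draw cues stochastically?
#' @param report_noise_sd report noise s.d., degrees.
#' @return A `"synthetic_dataset"` whose `$data` has columns `trial`,
#'   `phase`, `mode`, `hand_deg` (adapted extent), `x_hat_deg`,
#'   `report_deg`.
#' @export
gen_report_drift <- function(seed,
                             clamp_deg = 30,
                             n_baseline = 10,
                             n_clamp = 100,
                             params = pea_params(),
                             cue_noise = FALSE,
                             report_noise_sd = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  sched <- clamp_schedule(clamp_deg,
                          n_baseline_veridical = n_baseline,
                          n_baseline_none = 0,
                          n_clamp = n_clamp, n_washout = 0)
  tr <- simulate_pea(params, sched, noise = cue_noise)
  rep_internal <- report_hand(tr$x_hat_deg, tr$sigma_hat_deg,
                              tr$state_deg, params$sigma_p)
  noise <- if (report_noise_sd > 0)
    stats::rnorm(nrow(tr), 0, report_noise_sd) else 0
  dat <- data.frame(trial = tr$cycle, phase = tr$phase, mode = tr$mode,
                    hand_deg = tr$extent_deg,
                    x_hat_deg = tr$x_hat_deg,
                    report_deg = -rep_internal + noise)
  new_synthetic_dataset("report_drift", dat,
                        list(params = unclass(params),
                             clamp_deg = clamp_deg,
                             report_noise_sd = report_noise_sd,
                             cue_noise = cue_noise),
                        as.integer(seed))
}
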