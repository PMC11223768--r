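test_that("the adaptation generator is seed-deterministic and noise-free exact", {
  a <- gen_adaptation(seed = 3, clamp_sizes = 8, n_subjects = 2)
  b <- gen_adaptation(seed = 3, clamp_sizes = 8, n_subjects = 2)
  expect_identical(a$data, b$data)
  # no cue noise, no motor noise: each subject equals the deterministic run
  quiet <- gen_adaptation(seed = 4, clamp_sizes = 8, n_subjects = 2,
                          motor_noise_sd = 0, cue_noise = FALSE)
  det <- simulate_pea(fitted_params(), clamp_schedule(8))
  for (s in unique(quiet$data$subject))
    expect_equal(quiet$data$hand_deg[quiet$data$subject == s],
                 det$extent_deg, tolerance = 1e-12)
  expect_true(!is.null(quiet$truth$params))
})

test_that("large synthetic groups converge to the closed-form asymptote", {
  ds <- gen_adaptation(seed = 12, clamp_sizes = 8, n_subjects = 200)
  d <- ds$data
  terminal <- mean(d$hand_deg[d$phase == "clamp" & d$cycle > 100])
  expect_equal(terminal, -pea_asymptote(8, fitted_params()),
               tolerance = 1.5 / 20.67)
})

test_that("the 2AFC generator produces recoverable uncertainties per size", {
  ds <- gen_2afc(seed = 42, n_subjects = 6)
  est <- estimate_sigma_v(ds$data)
  truth_sv <- 1.853 + 0.309 * est$theta_abs
  med <- stats::aggregate(cbind(sigma_v, truth = truth_sv) ~ theta_abs,
                          est, stats::median)
  expect_true(all(abs(med$sigma_v - med$truth) / med$truth < 0.20))
  # symmetric directions give matching uncertainties at the group level
  pos <- stats::median(est$sigma_v[est$clamp_deg == 16])
  neg <- stats::median(est$sigma_v[est$clamp_deg == -16])
  expect_equal(pos, neg, tolerance = 0.35)
})

test_that("a near-deterministic observer collapses the staircase onto its PSE", {
  ds <- gen_2afc(seed = 5, n_subjects = 1, clamp_sizes = 4,
                 a = 0.05, b = 0, n_days = 1)
  finals <- stats::aggregate(
    reference_offset_deg ~ round + clamp_deg, ds$data,
    FUN = function(x) utils::tail(x, 1))
  expect_true(all(abs(finals$reference_offset_deg) < 2.5))
})

test_that("proprioception probes show the hand-estimate influence and its decay", {
  # no influence at all: probe bias is pure report noise around zero
  quietish <- gen_proprioception(seed = 6, n_subjects = 8,
                                 rparams = report_params(Rp = 1e-9),
                                 report_noise_sd = 1)
  expect_lt(abs(mean(quietish$data$bias_deg)), 0.5)
  # folded first-probe bias is unimodal in clamp size with the defaults
  ds <- gen_proprioception(seed = 7, n_subjects = 60)
  d <- ds$data
  d$fold <- d$bias_deg * sign(d$clamp_deg)
  first <- stats::aggregate(fold ~ abs(clamp_deg), d[d$probe == 1, ],
                            mean)
  names(first) <- c("theta", "bias")
  expect_gt(max(first$bias[first$theta %in% c(20, 40)]),
            first$bias[first$theta == 80])
  expect_true(all(first$bias[first$theta %in% c(10, 20, 40)] > 0))
  # the geometric decay drops the third probe into the report-noise
  # floor (9% of the first-probe influence, against a 4-degree noise
  # s.d.); the first probe carries a clear signal, the third does not
  by_probe <- stats::aggregate(fold ~ probe, d, mean)
  expect_gt(by_probe$fold[by_probe$probe == 1], 0.4)
  expect_lt(abs(by_probe$fold[by_probe$probe == 3]), 0.4)
  expect_lt(abs(by_probe$fold[by_probe$probe == 3]),
            0.5 * by_probe$fold[by_probe$probe == 1])
})

test_that("single-trial triplets reproduce the blur-by-size interaction", {
  # zero noise: each folded triplet equals the model's single-trial step
  quiet <- gen_stl_triplets(seed = 8, n_subjects = 1, n_days = 1,
                            blocks_per_day = 1, motor_noise_sd = 0)
  p <- fitted_params()
  for (i in seq_len(nrow(quiet$data))) {
    row <- quiet$data[i, ]
    rv <- if (row$blurred) quiet$truth$blur_ratio else 1
    expect_equal(row$stl_deg,
                 -pea_single_trial(row$clamp_deg, p, blur_ratio = rv),
                 tolerance = 1e-12)
  }
  # realistic motor noise: the blur main effect at 64 degrees stands out
  # (theory 0.43 deg against a ~0.11 deg standard error at this n)
  ds <- gen_stl_triplets(seed = 9, n_subjects = 100)
  agg <- stats::aggregate(stl_deg ~ clamp_deg + blurred, ds$data, mean)
  red <- sapply(c(4, 64), function(th)
    agg$stl_deg[agg$clamp_deg == th & !agg$blurred] -
      agg$stl_deg[agg$clamp_deg == th & agg$blurred])
  expect_gt(red[2], 0)            # blur reduces learning at 64 degrees
  # the blur-by-size interaction (~0.15 deg) sits far below the 5.1-deg
  # motor noise at realistic counts, so the mean structure is checked
  # with the noise dialled down
  lown <- gen_stl_triplets(seed = 9, n_subjects = 20,
                           motor_noise_sd = 0.5)
  agg2 <- stats::aggregate(stl_deg ~ clamp_deg + blurred, lown$data, mean)
  red2 <- sapply(c(4, 64), function(th)
    agg2$stl_deg[agg2$clamp_deg == th & !agg2$blurred] -
      agg2$stl_deg[agg2$clamp_deg == th & agg2$blurred])
  expect_gt(red2[2], red2[1])     # and more so than at 4 degrees
})

test_that("simulated hand reports drift from negative to positive", {
  ds <- gen_report_drift(seed = 10)
  r <- ds$data$report_deg[ds$data$phase == "clamp"]
  expect_lt(r[1], 0)
  expect_gt(utils::tail(r, 1), 0)
  expect_equal(sum(diff(sign(r)) != 0), 1)
  # the adapted hand itself keeps growing positive
  expect_gt(utils::tail(ds$data$hand_deg, 1), 10)
  # no learning: reports stay pinned on the negative side
  frozen <- gen_report_drift(seed = 11,
                             params = pea_params(B = 0))
  rf <- frozen$data$report_deg[frozen$data$phase == "clamp"]
  expect_true(all(rf < 0))
  expect_lt(max(abs(diff(rf))), 1e-9)
})

test_that("asymptotic reports agree with the report operator at the fixed point", {
  p <- fitted_params()
  ds <- gen_report_drift(seed = 12, n_clamp = 4000)
  last <- utils::tail(ds$data, 1)
  x_asym <- pea_asymptote(30, p)
  sv <- visual_uncertainty(30, p)
  prec <- c(1 / sv^2, 1 / p$sigma_p^2, 1 / p$sigma_u^2)
  x_hat <- (prec[1] * 30 + prec[2] * x_asym) / sum(prec)
  expected <- -report_hand(x_hat, 1 / sqrt(sum(prec)), x_asym, p$sigma_p)
  expect_equal(last$report_deg, expected, tolerance = 1e-6)
})

test_that("dataset round trips to CSV with its truth sidecar", {
  tmp <- withr::local_tempdir()
  ds <- gen_adaptation(seed = 13, clamp_sizes = 8, n_subjects = 1)
  paths <- write_dataset_csv(ds, file.path(tmp, "exp2"))
  back <- read_adaptation_csv(file.path(tmp, "exp2.csv"))
  expect_equal(nrow(back), nrow(ds$data))
  expect_equal(back$hand_deg, ds$data$hand_deg, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(tmp, "exp2_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$truth$params$A, 0.974)
  expect_equal(truth$seed, 13)
})
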