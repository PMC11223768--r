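test_that("visual uncertainty follows the linear eccentricity law with blur scaling", {
  p <- fitted_params()
  expect_equal(visual_uncertainty(0, p), 1.853)
  expect_equal(visual_uncertainty(64, p), 21.629)
  expect_equal(visual_uncertainty(64, p, blur_ratio = 2), 43.258)
  expect_equal(visual_uncertainty(-64, p), visual_uncertainty(64, p))
  th <- seq(0, 95, by = 5)
  expect_true(all(diff(visual_uncertainty(th, p)) > 0))
  expect_error(visual_uncertainty(8, p, blur_ratio = 0.5), "blur_ratio")
})

test_that("cue combination uses precision weights that normalise and interpolate", {
  eq <- combine_cues(cue_sample(30, 0, 0, 5, 5, 5))
  expect_equal(eq$x_hat, 10)
  cc <- combine_cues(cue_sample(64, 0, 0, 21.629, 11.119, 5.048))
  expect_equal(cc$x_hat, 2.766, tolerance = 1e-3)
  expect_equal(unname(cc$weights["v"]), 0.0432, tolerance = 1e-2)
  # infinite-uncertainty limit: the visual cue drops out
  two_cue <- (0 / 11.119^2 + 0 / 5.048^2) / (1 / 11.119^2 + 1 / 5.048^2)
  far <- combine_cues(cue_sample(64, 0, 0, 1e6, 11.119, 5.048))
  expect_equal(far$x_hat, two_cue, tolerance = 1e-6)
  expect_error(combine_cues(cue_sample(NaN, 0, 0, 1, 1, 1)), "finite")
  expect_error(cue_sample(1, 1, 1, -1, 1, 1), "positive")
})

test_that("weights normalise and the estimate stays within the cue range", {
  set.seed(11)
  for (i in 1:50) {
    cues <- cue_sample(stats::runif(1, -90, 90), stats::runif(1, -90, 90),
                       stats::runif(1, -90, 90), stats::runif(1, 0.5, 40),
                       stats::runif(1, 0.5, 40), stats::runif(1, 0.5, 40))
    est <- combine_cues(cues)
    expect_equal(sum(est$weights), 1, tolerance = 1e-12)
    xs <- c(cues$x_v, cues$x_p, cues$x_u)
    expect_gte(est$x_hat, min(xs) - 1e-12)
    expect_lte(est$x_hat, max(xs) + 1e-12)
  }
})

test_that("the state update retains and corrects as specified", {
  p <- fitted_params()
  expect_equal(update_state(3, 5, 5, pea_params(A = 1, B = 0)), 3)
  expect_equal(update_state(0, 2.766, 0, p), -0.575, tolerance = 1e-3)
  # zero perceptual error leaves pure decay
  expect_equal(update_state(7, 2, 2, p), p$A * 7)
})

test_that("simulated trajectories reach the closed-form fixed point", {
  p <- fitted_params()
  quiet <- simulate_pea(p, feedback_schedule(rep("none", 40)))
  expect_true(all(quiet$state_deg == 0))
  tr <- simulate_pea(p, clamp_schedule(8))
  terminal <- utils::tail(tr$state_deg[tr$phase == "clamp"], 1)
  # 80 clamp cycles close to (but measurably short of) the fixed point
  expect_lt(abs(terminal - pea_asymptote(8, p)), 0.7)
  expect_equal(terminal, -20.67, tolerance = 0.04)
  # washout contracts toward zero when A < 1
  wash <- tr$state_deg[tr$phase == "washout"]
  expect_true(all(diff(abs(wash)) < 0))
  expect_error(simulate_pea(p, feedback_schedule(character(0))), "cycle")
})

test_that("stochastic simulation is seed-reproducible and unbiased in the mean", {
  p <- fitted_params()
  s <- clamp_schedule(16)
  a <- simulate_pea(p, s, noise = TRUE, seed = 5)
  b <- simulate_pea(p, s, noise = TRUE, seed = 5)
  expect_identical(a, b)
  c <- simulate_pea(p, s, noise = TRUE, seed = 6)
  expect_false(identical(a$state_deg, c$state_deg))
})

test_that("the asymptote matches long simulations for random parameter draws", {
  p <- fitted_params()
  expect_equal(pea_asymptote(0, p), 0)
  expect_equal(pea_asymptote(8, p), -20.67, tolerance = 1e-3)
  set.seed(21)
  thetas <- c(2, 5, 8, 16, 32, 64, 95)
  for (i in 1:20) {
    pp <- random_pea_params()
    for (theta in sample(thetas, 3)) {
      sim <- simulate_pea(pp, clamp_schedule(theta, 0, 0, 10000, 0))
      expect_equal(utils::tail(sim$state_deg, 1),
                   pea_asymptote(theta, pp), tolerance = 1e-6)
    }
  }
  expect_error(pea_asymptote(8, pea_params(A = 1, B = 0)), "undefined")
})

test_that("the ratio form is the full-retention reduction of the asymptote", {
  expect_equal(asymptote_ratio_form(0, 6, 0.1), 0)
  expect_equal(asymptote_ratio_form(8, 11.119 / 1.853, 0.309 / 1.853),
               -52.88, tolerance = 1e-3)
  set.seed(31)
  for (i in 1:10) {
    pp <- random_pea_params()
    pA1 <- pea_params(A = 1, B = pp$B, sigma_p = pp$sigma_p,
                      sigma_u = pp$sigma_u, a = pp$a, b = pp$b)
    theta <- stats::runif(1, 1, 95)
    expect_equal(pea_asymptote(theta, pA1),
                 asymptote_ratio_form(theta, pp$sigma_p / pp$a,
                                      pp$b / pp$a),
                 tolerance = 1e-9)
  }
})

test_that("hand reports interpolate between the estimate and the adapted hand", {
  expect_equal(report_hand(-3, 4, 9, 4), (-3 + 9) / 2)
  expect_equal(report_hand(-3, 1e-9, 9, 4), -3, tolerance = 1e-6)
  expect_equal(report_hand(-2, sqrt(20), 10, sqrt(120)),
               -2 + 20 / 140 * 12)
  expect_error(report_hand(0, -1, 0, 1), "positive")
})

test_that("proprioceptive bias scales the hand estimate and is unimodal in clamp size", {
  expect_equal(proprioceptive_bias(0, 0.2), 0)
  expect_equal(proprioceptive_bias(2.766, 0.2), 0.553, tolerance = 1e-3)
  expect_error(proprioceptive_bias(1, 0), "Rp")
  # at the adapted steady state, |bias| rises then falls with theta
  p <- fitted_params()
  th <- 1:95
  x_asym <- pea_asymptote(th, p)
  sv <- visual_uncertainty(th, p)
  prec <- cbind(v = 1 / sv^2, p = 1 / p$sigma_p^2, u = 1 / p$sigma_u^2)
  x_hat <- (prec[, "v"] * th + prec[, "p"] * x_asym) / rowSums(prec)
  bias <- proprioceptive_bias(x_hat, 0.2)
  peak <- which.max(abs(bias))
  expect_gt(peak, 1)
  expect_lt(peak, length(th))
  expect_true(all(diff(abs(bias[1:peak])) > 0))
  expect_true(all(diff(abs(bias[peak:length(th)])) < 0))
})

test_that("single-trial learning equals one update step and shrinks under blur", {
  p <- fitted_params()
  expect_equal(pea_single_trial(0, p), 0)
  # equivalence with the three-cue path: one update from an unadapted state
  cc <- combine_cues(cue_sample(64, 0, 0, visual_uncertainty(64, p),
                                p$sigma_p, p$sigma_u))
  expect_equal(pea_single_trial(64, p), update_state(0, cc$x_hat, 0, p),
               tolerance = 1e-12)
  expect_equal(pea_single_trial(64, p), -0.575, tolerance = 1e-3)
  for (theta in c(2, 8, 32, 64, 95)) {
    stl <- abs(pea_single_trial(theta, p, blur_ratio = c(1, 1.5, 2, 3)))
    expect_true(all(diff(stl) < 0))
  }
})

test_that("the integrated two-cue percept matches the three-cue percept at the target", {
  set.seed(41)
  for (i in 1:20) {
    pp <- random_pea_params()
    theta <- stats::runif(1, -95, 95)
    sv <- visual_uncertainty(theta, pp)
    three <- combine_cues(cue_sample(theta, 0, 0, sv, pp$sigma_p,
                                     pp$sigma_u))
    expect_equal(pea_single_trial(theta, pp),
                 pp$B * (0 - three$x_hat), tolerance = 1e-12)
  }
})
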