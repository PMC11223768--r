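test_that("the SSE loss is zero at the truth and rises when perturbed", {
  truth <- fitted_params()
  data <- noise_free_groups(truth, thetas = c(4, 16, 64))
  expect_equal(loss_sse(truth, data, "pea"), 0, tolerance = 1e-12)
  bumped <- pea_params(A = truth$A, B = truth$B * 1.05,
                       sigma_p = truth$sigma_p, sigma_u = truth$sigma_u,
                       a = truth$a, b = truth$b)
  expect_gt(loss_sse(bumped, data, "pea"), 0.1)
  # invariance to group ordering
  shuffled <- data[sample(nrow(data)), ]
  expect_equal(loss_sse(bumped, shuffled, "pea"),
               loss_sse(bumped, data, "pea"), tolerance = 1e-9)
})

test_that("multi-start refits recover the generating PEA parameters from noise-free data", {
  truth <- fitted_params()
  data <- noise_free_groups(truth, thetas = c(2, 8, 32, 95))
  spec <- fit_spec("pea", n_starts = 12, seed = 4,
                   fixed = list(a = truth$a, b = truth$b))
  fit <- multistart_fit(spec, data)
  for (nm in c("A", "B", "sigma_p", "sigma_u"))
    expect_equal(unname(fit$par[nm]), truth[[nm]],
                 tolerance = 0.02, label = nm)
  # a start at the truth can never be beaten
  fit2 <- multistart_fit(spec, data,
                         extra_starts = c(truth$A, truth$B,
                                          truth$sigma_p, truth$sigma_u))
  expect_lte(fit2$loss, fit$loss + 1e-9)
  expect_lt(fit2$loss, 1e-9)
})

test_that("PReMo round-trips through its own generator and fit", {
  truth <- premo_params()
  data <- do.call(rbind, lapply(c(2, 4, 8, 32, 64), function(theta) {
    tr <- simulate_premo(truth, clamp_schedule(theta))
    data.frame(clamp_deg = theta, cycle = tr$cycle, phase = tr$phase,
               mode = tr$mode, hand_deg = tr$extent_deg)
  }))
  spec <- fit_spec("premo", n_starts = 6, seed = 5)
  warm <- c(truth$R1, truth$R2, truth$beta_sat, truth$eta_p,
            truth$A, truth$B) *
    c(1.1, 1.1, 1.15, 1.15, 0.99, 1.15)   # perturbed, within bounds
  fit <- multistart_fit(spec, data, extra_starts = warm)
  # the six-parameter PReMo family is identified only in combinations
  # (rates and forcings); self-recovery is asserted on those and on the
  # reproduced trajectories
  expect_lt(fit$loss / fit$n, 1e-6)
  expect_equal(unname(fit$par["A"] - fit$par["B"] * fit$par["R2"]),
               truth$A - truth$B * truth$R2, tolerance = 0.01)
  expect_equal(unname(fit$par["B"] * fit$par["beta_sat"]),
               truth$B * truth$beta_sat, tolerance = 0.05)
})

test_that("seeded fits are reproducible and more starts never lose ground", {
  truth <- fitted_params()
  data <- noise_free_groups(truth, thetas = c(8, 64))
  s1 <- fit_spec("pea", n_starts = 4, seed = 9)
  a <- multistart_fit(s1, data)
  b <- multistart_fit(s1, data)
  expect_identical(a$par, b$par)
  expect_identical(a$loss, b$loss)
  s2 <- fit_spec("pea", n_starts = 8, seed = 9)
  c <- multistart_fit(s2, data)
  expect_lte(c$loss, a$loss + 1e-12)
})

test_that("stochastic group data still identify the truth within tolerance", {
  # full 7-group, 12-subject design; median relative error over noise
  # seeds stays below 10% for every parameter
  truth <- fitted_params()
  tv <- unlist(unclass(truth))[c("A", "B", "sigma_p", "sigma_u")]
  errs <- sapply(1:10, function(s) {
    ds <- gen_adaptation(seed = 200 + s)
    spec <- fit_spec("pea", n_starts = 6, seed = s,
                     fixed = list(a = truth$a, b = truth$b))
    fit <- multistart_fit(spec, ds)
    abs(fit$par[names(tv)] - tv) / tv
  })
  med <- apply(errs, 1, stats::median)
  expect_true(all(med < 0.10),
              info = paste(names(med), round(med, 3), collapse = " "))
})

test_that("under-determined free-uncertainty configurations are rejected", {
  truth <- fitted_params()
  data <- noise_free_groups(truth, thetas = c(8, 64))
  expect_error(fit_free_sigma_v(data), ">= 3 clamp-size groups")
})

test_that("free per-size uncertainties land on the generating line", {
  truth <- fitted_params()
  sizes <- c(2, 4, 8, 16, 32, 64, 95)
  data <- noise_free_groups(truth, thetas = sizes)
  law <- multistart_fit(fit_spec("pea", n_starts = 8, seed = 2,
                                 fixed = list(a = truth$a, b = truth$b)),
                        data)
  fit <- fit_free_sigma_v(data, n_starts = 6, seed = 3, law_fit = law)
  # the recovered per-size uncertainties are strongly linear in clamp size
  expect_gt(stats::cor(fit$sigma_v_table$sigma_v, sizes), 0.999)
  # and the refit reproduces the trajectories of the linear-law fit:
  # the per-size parameterisation is flat along a rate/uncertainty ridge,
  # so equivalence is asserted on predictions, not raw rate values
  expect_lt(fit$loss / fit$n, 1e-6)
  expect_lte(fit$loss, law$loss + 1e-9)
})

test_that("AIC ranking follows its Gaussian-SSE definition", {
  mk <- function(model, loss, n, k) {
    structure(list(model = model, loss = loss, n = n, k = k,
                   aic = n * log(loss / n) + 2 * k, r2 = NA_real_),
              class = "model_fit")
  }
  # equal SSE, fewer parameters wins; a useless parameter costs exactly 2
  lean <- mk("pea", 100, 840, 4)
  fat <- mk("premo", 100, 840, 6)
  tab <- compare_models(list(fat, lean))
  expect_equal(tab$model[1], "pea")
  expect_equal(tab$delta_aic[2], 4)
  one_more <- mk("pea", 100, 840, 5)
  expect_equal(one_more$aic - lean$aic, 2)
})

test_that("the generating model wins the AIC comparison on its own data", {
  truth <- fitted_params()
  data <- noise_free_groups(truth, thetas = c(2, 8, 32, 95))
  fits <- lapply(c("pea", "premo", "ci"), function(m) {
    spec <- fit_spec(m, n_starts = 8, seed = 6,
                     fixed = if (m == "pea")
                       list(a = truth$a, b = truth$b) else NULL)
    multistart_fit(spec, data)
  })
  tab <- compare_models(fits)
  expect_equal(tab$model[1], "pea")
  pea_aic <- tab$aic[tab$model == "pea"]
  expect_lt(pea_aic, tab$aic[tab$model == "premo"])
  expect_lt(pea_aic, tab$aic[tab$model == "ci"])
})
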