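# default box bounds for free parameters, by name
default_bounds <- function() {
  list(A = c(0.5, 1), B = c(0, 1),
       sigma_p = c(0.5, 45), sigma_u = c(0.5, 45),
       a = c(0.5, 45), b = c(0, 1),
       R1 = c(0.01, 0.99), R2 = c(0.01, 0.99),
       beta_sat = c(1, 45), eta_p = c(0.01, 5),
       sigma = c(0.5, 45), S = c(0, 10), C = c(1e-6, 1))
}

default_free <- function(model) {
  switch(model,
         pea = c("A", "B", "sigma_p", "sigma_u"),
         premo = c("R1", "R2", "beta_sat", "eta_p", "A", "B"),
         ci = c("sigma", "S", "C", "A", "B"))
}

default_fixed <- function(model) {
  switch(model,
         pea = list(a = 1.853, b = 0.309),
         premo = list(sigma_u = 5.048),
         ci = list())
}

#' Specify a multi-start model fit
#'
#' Describes which model to fit, which parameters are free (with box
#' bounds), which are held fixed, and the multi-start protocol: `n_starts`
#' uniform draws within the bounds, each refined by bounded local
#' least squares.
#'
#' @param model `"pea"`, `"premo"` or `"ci"`.
#' @param free either a character vector of free-parameter names (using
#'   default bounds) or a named list of `c(lower, upper)` bounds.
#'   Defaults: `A, B, sigma_p, sigma_u` for PEA (eccentricity law fixed);
#'   `R1, R2, beta_sat, eta_p, A, B` for PReMo; `sigma, S, C, A, B` for
#'   the causal-inference model.
#' @param fixed named list of fixed parameter values (defaults fill in
#'   whatever the model needs beyond the free set).
#' @param n_starts number of random starting points (>= 1).
#' @param seed integer seed for start sampling.
#' @param loss loss functional; only `"sse_cycles"` (sum of squared
#'   cycle-mean errors) is defined.
#' @return An object of class `"fit_spec"`.
#' @export
fit_spec <- function(model = c("pea", "premo", "ci"), free = NULL,
                     fixed = NULL, n_starts = 100, seed = 1,
                     loss = "sse_cycles") {
  model <- match.arg(model)
  loss <- match.arg(loss, "sse_cycles")
  if (n_starts < 1) stop("'n_starts' must be >= 1")
  bounds <- default_bounds()
  if (is.null(free)) free <- default_free(model)
  if (is.character(free)) {
    unknown <- setdiff(free, names(bounds))
    if (length(unknown) && !all(grepl("^sigma_v", unknown)))
      stop("no default bounds for: ", paste(unknown, collapse = ", "))
    free <- stats::setNames(
      lapply(free, function(nm)
        if (nm %in% names(bounds)) bounds[[nm]] else c(0.5, 45)),
      free)
  }
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds for '", nm, "' must be finite with lower < upper")
  }
  if (is.null(fixed)) fixed <- default_fixed(model)
  fixed <- fixed[setdiff(names(fixed), names(free))]
  structure(list(model = model, free = free, fixed = fixed,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 loss = loss),
            class = "fit_spec")
}

# Aggregate a subject-level trial table to per-group cycle means.
# Accepts a synthetic_dataset, a subject-level data.frame, or an
# already-aggregated table (no 'subject' column).
as_cycle_means <- function(data) {
  if (inherits(data, "synthetic_dataset")) data <- data$data
  need <- c("clamp_deg", "cycle", "mode", "hand_deg")
  if (!all(need %in% names(data)))
    stop("data must contain columns: ", paste(need, collapse = ", "))
  if (!"subject" %in% names(data)) return(data)
  keys <- list(clamp_deg = data$clamp_deg, cycle = data$cycle)
  agg <- stats::aggregate(data["hand_deg"], by = keys, FUN = mean)
  meta <- unique(data[c("clamp_deg", "cycle", "mode",
                        intersect(c("phase", "blur_ratio"), names(data)))])
  out <- merge(agg, meta, by = c("clamp_deg", "cycle"), sort = TRUE)
  out[order(out$clamp_deg, out$cycle), , drop = FALSE]
}

# Precompute the fitting context: per-group schedules and observations.
make_fit_context <- function(data) {
  means <- as_cycle_means(data)
  groups <- split(means, means$clamp_deg)
  list(groups = lapply(groups, function(g) {
    g <- g[order(g$cycle), , drop = FALSE]
    list(schedule = schedule_from_data(g), observed = g$hand_deg,
         clamp = g$clamp_deg[which(g$mode == "clamp")[1]])
  }),
  n = nrow(means),
  observed_all = unlist(lapply(groups, function(g)
    g$hand_deg[order(g$cycle)]), use.names = FALSE))
}

# Assemble a parameter object from free values + fixed values, without
# re-validating on every objective call. sigma_v_* entries are returned
# separately for the free-uncertainty fit.
assemble_params <- function(model, values) {
  sv <- grepl("^sigma_v_", names(values))
  pars <- as.list(values[!sv])
  obj <- switch(model,
    pea = structure(pars[c("A", "B", "sigma_p", "sigma_u", "a", "b")],
                    class = "pea_params"),
    premo = structure(pars[c("R1", "R2", "beta_sat", "eta_p", "A", "B",
                             "sigma_u")],
                      class = "premo_params"),
    ci = structure(pars[c("sigma", "S", "C", "A", "B")],
                   class = "ci_params"))
  list(params = obj, sigma_v = unlist(values[sv]))
}

# Model-predicted extent for one group context entry. Uses the lean
# deterministic predictors (no trajectory assembly) for speed inside
# the optimisation loop.
predict_group <- function(model, params, grp, sigma_v = NULL) {
  switch(model,
    pea = {
      ov <- NULL
      if (length(sigma_v)) {
        key <- paste0("sigma_v_", format_theta(grp$clamp))
        if (key %in% names(sigma_v)) ov <- sigma_v[[key]]
      }
      pea_predict_extent(params, grp$schedule, sigma_v_override = ov)
    },
    premo = premo_predict_extent(params, grp$schedule),
    ci = ci_predict_extent(params, grp$schedule))
}

# deterministic extent without trajectory assembly
pea_predict_extent <- function(params, schedule, target = 0,
                               sigma_v_override = NULL) {
  cf <- pea_cycle_coefs(params, schedule, target, sigma_v_override)
  n <- nrow(schedule)
  c1 <- params$A - params$B * cf$beta
  c0 <- params$B * (target - cf$alpha)
  state <- numeric(n)
  x <- 0
  for (i in seq_len(n)) {
    state[i] <- x
    x <- c1[i] * x + c0[i]
  }
  -(state - target)
}

premo_predict_extent <- function(params, schedule, target = 0) {
  n <- nrow(schedule)
  mode <- schedule$mode
  clamp <- schedule$clamp_deg
  R1 <- params$R1; R2 <- params$R2
  bsat <- params$beta_sat; eta <- params$eta_p
  A <- params$A; B <- params$B
  state <- numeric(n)
  x <- 0
  for (i in seq_len(n)) {
    state[i] <- x
    xv <- if (mode[i] == "clamp") target + clamp[i]
          else if (mode[i] == "veridical") x else NA_real_
    if (is.na(xv)) {
      pc <- R2 * x
    } else {
      d <- R1 * xv - R2 * x
      pc <- -sign(d) * min(bsat, eta * abs(d)) + R2 * x
    }
    x <- A * x + B * (target - pc)
  }
  state - target
}

ci_predict_extent <- function(params, schedule, target = 0) {
  n <- nrow(schedule)
  mode <- schedule$mode
  # attributed error is constant per clamp cycle; precompute it
  err_clamp <- ci_attribution(schedule$clamp_deg, params) *
    schedule$clamp_deg
  A <- params$A; B <- params$B
  state <- numeric(n)
  x <- 0
  for (i in seq_len(n)) {
    state[i] <- x
    err <- if (mode[i] == "clamp") err_clamp[i]
           else if (mode[i] == "veridical") {
             xv <- x - target
             ci_attribution(xv, params) * xv
           } else 0
    x <- A * x - B * err
  }
  -(state - target)
}

format_theta <- function(theta) gsub("-", "m", as.character(theta))

#' Sum-of-squares loss on cycle means
#'
#' Deterministic model trajectories are computed for every group in the
#' data (the schedule is reconstructed from the data's `mode` /
#' `clamp_deg` columns) and compared with the observed cycle-mean hand
#' angles; the loss is the sum over groups and cycles of the squared
#' difference.
#'
#' @param params a parameter object matching `model`.
#' @param data cycle-mean data (or a subject-level table / synthetic
#'   dataset, aggregated internally) with columns `clamp_deg`, `cycle`,
#'   `mode`, `hand_deg`.
#' @param model `"pea"`, `"premo"` or `"ci"`.
#' @return The scalar SSE (degrees squared).
#' @export
loss_sse <- function(params, data, model = c("pea", "premo", "ci")) {
  model <- match.arg(model)
  ctx <- make_fit_context(data)
  sum(vapply(ctx$groups, function(grp) {
    pred <- predict_group(model, params, grp)
    sum((pred - grp$observed)^2)
  }, numeric(1)))
}

# objective over the free-parameter vector
make_objective <- function(spec, ctx) {
  fixed <- unlist(spec$fixed)
  model <- spec$model
  function(par) {
    values <- c(as.list(par), as.list(fixed))
    if (model == "ci") {
      peak <- stats::dnorm(0, 0, values$sigma)
      cap <- values$S * peak / (peak + values$C)
      if (cap > 1) return(1e8 * cap)   # attribution must stay a probability
    }
    asm <- assemble_params(model, values)
    total <- 0
    for (grp in ctx$groups) {
      pred <- predict_group(model, asm$params, grp, asm$sigma_v)
      total <- total + sum((pred - grp$observed)^2)
    }
    total
  }
}

#' Multi-start bounded least-squares fit
#'
#' Fits a model to per-cycle group-mean trajectories by drawing
#' `n_starts` starting points uniformly within the box bounds (seeded)
#' and refining each by bounded quasi-Newton least squares
#' (`optim(method = "L-BFGS-B")`). The best result over all starts is
#' returned together with per-start diagnostics, the Gaussian-SSE AIC
#' (`n * log(SSE / n) + 2k`) and R-squared.
#'
#' @param spec a [fit_spec()].
#' @param data cycle-mean data (see [loss_sse()]).
#' @param extra_starts optional matrix/vector of additional starting
#'   points (columns = free parameters in spec order), appended to the
#'   random draws.
#' @return An object of class `"model_fit"`: a list with `model`, `par`
#'   (named best parameters, free and fixed), `params` (the assembled
#'   parameter object), `loss`, `starts` (per-start data.frame), `n`,
#'   `k`, `aic`, `r2`, `spec`.
#' @section Errors:
#' Fails when the data are empty or every start fails to evaluate.
#' @export
multistart_fit <- function(spec, data, extra_starts = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  ctx <- make_fit_context(data)
  if (ctx$n == 0L) stop("no data to fit")
  free_names <- names(spec$free)
  lower <- vapply(spec$free, `[`, numeric(1), 1)
  upper <- vapply(spec$free, `[`, numeric(1), 2)
  k <- length(free_names)
  set.seed(spec$seed)
  starts <- matrix(stats::runif(spec$n_starts * k,
                                rep(lower, each = spec$n_starts),
                                rep(upper, each = spec$n_starts)),
                   nrow = spec$n_starts, ncol = k,
                   dimnames = list(NULL, free_names))
  if (!is.null(extra_starts)) {
    extra_starts <- matrix(extra_starts, ncol = k,
                           dimnames = list(NULL, free_names))
    starts <- rbind(starts, extra_starts)
  }
  objective <- make_objective(spec, ctx)
  parscale <- pmax((upper - lower) / 10, 1e-3)
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch({
      fit <- stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500, parscale = parscale))
      list(par = fit$par, value = fit$value,
           converged = fit$convergence == 0)
    }, error = function(e) NULL)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all ", nrow(starts), " starts failed")
  values <- vapply(runs[ok], `[[`, numeric(1), "value")
  best <- runs[ok][[which.min(values)]]
  start_table <- data.frame(
    start = seq_len(nrow(starts))[ok],
    loss = values,
    converged = vapply(runs[ok], `[[`, logical(1), "converged"))
  par_full <- c(as.list(best$par), spec$fixed)
  asm <- assemble_params(spec$model, par_full)
  sse <- best$value
  n <- ctx$n
  aic <- if (sse > 0) n * log(sse / n) + 2 * k else -Inf
  sstot <- sum((ctx$observed_all - mean(ctx$observed_all))^2)
  r2 <- if (sstot > 0) 1 - sse / sstot else NA_real_
  out <- list(model = spec$model,
              par = unlist(par_full),
              params = asm$params,
              sigma_v = if (length(asm$sigma_v)) asm$sigma_v else NULL,
              loss = sse, starts = start_table,
              n = n, k = k, aic = aic, r2 = r2, spec = spec)
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s model fit: SSE = %.6g over %d points (%d free params)\n",
              x$model, x$loss, x$n, x$k))
  cat(sprintf("  AIC = %.6g  R^2 = %.4f\n", x$aic, x$r2))
  cat("  parameters:\n")
  for (nm in names(x$par))
    cat(sprintf("    %s = %.6g\n", nm, x$par[[nm]]))
  invisible(x)
}

#' PEA fit with free per-size visual uncertainties
#'
#' Refits the PEA model without assuming the linear eccentricity law:
#' each clamp size gets its own free visual s.d. (`sigma_v_<size>`)
#' alongside `A`, `B`, `sigma_p`, `sigma_u`. Regressing the recovered
#' uncertainties on `|theta|` afterwards checks the linearity of the law
#' without building it in. At least 3 clamp-size groups are required for
#' the configuration to be determined.
#'
#' The per-size parameterisation carries a nearly flat ridge (rate and
#' uncertainty-scale trade-offs change the trajectories only
#' marginally), so when a fit of the linear-law model is supplied via
#' `law_fit` its solution is added as a warm start -- the standard way
#' to anchor such a refit -- while the random starts keep exploring the
#' box.
#'
#' @param data cycle-mean data (see [loss_sse()]).
#' @param n_starts,seed multi-start protocol (see [fit_spec()]).
#' @param law_fit optional `"model_fit"` of the linear-law PEA
#'   parameterisation on the same data; its solution seeds a warm start.
#' @param extra_starts optional additional starting points.
#' @return A `"model_fit"` whose `sigma_v` element is a named vector of
#'   per-size uncertainties and whose `sigma_v_table` is a data.frame
#'   `(clamp_deg, sigma_v)`.
#' @export
fit_free_sigma_v <- function(data, n_starts = 40, seed = 1,
                             law_fit = NULL, extra_starts = NULL) {
  means <- as_cycle_means(data)
  thetas <- sort(unique(means$clamp_deg[means$mode == "clamp"]))
  if (length(thetas) < 3L)
    stop("free per-size uncertainties need >= 3 clamp-size groups; got ",
         length(thetas))
  free <- c("A", "B", "sigma_p", "sigma_u",
            paste0("sigma_v_", format_theta(thetas)))
  if (!is.null(law_fit)) {
    stopifnot(inherits(law_fit, "model_fit"), law_fit$model == "pea")
    lp <- law_fit$params
    warm <- c(lp$A, lp$B, lp$sigma_p, lp$sigma_u,
              visual_uncertainty(thetas, lp))
    extra_starts <- rbind(extra_starts, warm)
  }
  spec <- fit_spec("pea", free = free, fixed = list(a = 1.853, b = 0.309),
                   n_starts = n_starts, seed = seed)
  fit <- multistart_fit(spec, means, extra_starts = extra_starts)
  fit$sigma_v_table <- data.frame(clamp_deg = thetas,
                                  sigma_v = unname(fit$sigma_v))
  fit
}

#' Rank fitted models by AIC
#'
#' Collects the Gaussian-SSE AIC (`n * log(SSE / n) + 2k`) and
#' R-squared of a set of fits of the same data and ranks them by
#' ascending AIC, reporting differences to the best model.
#'
#' @param fits a list of `"model_fit"` objects.
#' @return A data.frame with one row per model, ordered by AIC:
#'   `model`, `k`, `n`, `loss`, `aic`, `delta_aic`, `r2`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "model_fit")))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, k = f$k, n = f$n, loss = f$loss,
               aic = f$aic, r2 = f$r2)))
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab[c("model", "k", "n", "loss", "aic", "delta_aic", "r2")]
}
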