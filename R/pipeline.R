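# End-to-end orchestration used both interactively and by the thin
# command-line wrapper shipped in inst/cli/peadapt.R.

#' Simulate extent-versus-size sweeps and trajectories
#'
#' Runs the chosen model deterministically over a sweep of clamp sizes,
#' writing one per-cycle trajectory CSV per size, an
#' extent-versus-size table, and a summary JSON with the resolved
#' configuration.
#'
#' @param model `"pea"`, `"premo"` or `"ci"`.
#' @param thetas clamp sizes to sweep, degrees.
#' @param params parameter object matching `model` (defaults to the
#'   model's default constructor).
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and just returns the sweep table.
#' @param schedule_args named list passed to [clamp_schedule()].
#' @return Invisibly, the sweep data.frame `(clamp_deg, extent_deg)`
#'   where `extent_deg` is the mean extent over the last 10 clamp
#'   cycles.
#' @export
run_simulate <- function(model = c("pea", "premo", "ci"),
                         thetas = c(2, 4, 8, 16, 32, 64, 95),
                         params = NULL, out_dir = NULL,
                         schedule_args = list()) {
  model <- match.arg(model)
  if (is.null(params))
    params <- switch(model, pea = pea_params(), premo = premo_params(),
                     ci = ci_params())
  sim <- switch(model,
                pea = function(s) simulate_pea(params, s),
                premo = function(s) simulate_premo(params, s),
                ci = function(s) simulate_ci(params, s))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  extent <- numeric(length(thetas))
  for (i in seq_along(thetas)) {
    sched <- do.call(clamp_schedule, c(list(theta = thetas[i]),
                                       schedule_args))
    tr <- sim(sched)
    clamp_rows <- which(tr$phase == "clamp")
    last10 <- utils::tail(clamp_rows, 10)
    extent[i] <- mean(tr$extent_deg[last10])
    if (!is.null(out_dir))
      write_trajectory_csv(tr, file.path(out_dir,
        sprintf("trajectory_%s_theta%s.csv", model,
                format_theta(thetas[i]))))
  }
  sweep <- data.frame(clamp_deg = thetas, extent_deg = extent)
  if (!is.null(out_dir)) {
    utils::write.csv(sweep, file.path(out_dir,
      sprintf("extent_sweep_%s.csv", model)), row.names = FALSE)
    jsonlite::write_json(
      list(command = "simulate", model = model, thetas = thetas,
           params = unclass(params),
           package_version = as.character(utils::packageVersion("peadapt"))),
      file.path(out_dir, sprintf("simulate_%s_config.json", model)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(sweep)
}

#' Closed-loop parameter recovery report
#'
#' Generates noise-free multi-group adaptation trajectories from a
#' truth parameter set, refits the PEA model by multi-start bounded
#' least squares, and reports truth versus recovered values with
#' relative errors. Used as the package's self-check that the fitting
#' machinery identifies the generating parameters.
#'
#' @param seed integer seed for start sampling.
#' @param truth truth [pea_params()].
#' @param clamp_sizes group clamp sizes, degrees.
#' @param n_starts random starts for the refit.
#' @param tolerance relative-error threshold flagged in the report.
#' @param out_dir optional directory for `recovery_report.json`.
#' @return Invisibly, a list with `table` (data.frame of truth,
#'   recovered, relative error per parameter), `fit` (the
#'   `"model_fit"`), and `ok` (all relative errors below `tolerance`).
#' @export
run_recover <- function(seed = 1, truth = pea_params(),
                        clamp_sizes = c(2, 4, 8, 16, 32, 64, 95),
                        n_starts = 100, tolerance = 0.02,
                        out_dir = NULL) {
  data <- do.call(rbind, lapply(clamp_sizes, function(theta) {
    tr <- simulate_pea(truth, clamp_schedule(theta))
    data.frame(clamp_deg = theta, cycle = tr$cycle, phase = tr$phase,
               mode = tr$mode, hand_deg = tr$extent_deg)
  }))
  spec <- fit_spec("pea", n_starts = n_starts, seed = seed,
                   fixed = list(a = truth$a, b = truth$b))
  fit <- multistart_fit(spec, data)
  free <- names(spec$free)
  truth_v <- unlist(unclass(truth))[free]
  rec <- fit$par[free]
  tab <- data.frame(parameter = free, truth = unname(truth_v),
                    recovered = unname(rec),
                    rel_error = unname(abs(rec - truth_v) / abs(truth_v)))
  ok <- all(tab$rel_error < tolerance)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(
      list(command = "recover", seed = seed, n_starts = n_starts,
           tolerance = tolerance, ok = ok,
           table = tab,
           package_version = as.character(utils::packageVersion("peadapt"))),
      file.path(out_dir, "recovery_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(table = tab, fit = fit, ok = ok))
}

#' Fit and rank all three models on one dataset
#'
#' Fits the PEA, PReMo and causal-inference models to the same
#' cycle-mean adaptation data with the shared multi-start protocol and
#' emits the AIC ranking from [compare_models()].
#'
#' @param data cycle-mean data (see [loss_sse()]).
#' @param n_starts random starts per model.
#' @param seed integer seed.
#' @param out_dir optional directory for `model_comparison.csv`/`.json`.
#' @return Invisibly, a list with `ranking` (the comparison data.frame)
#'   and `fits` (named list of `"model_fit"` objects).
#' @export
run_compare <- function(data, n_starts = 100, seed = 1, out_dir = NULL) {
  fits <- lapply(c(pea = "pea", premo = "premo", ci = "ci"),
                 function(m) {
                   spec <- fit_spec(m, n_starts = n_starts, seed = seed)
                   multistart_fit(spec, data)
                 })
  ranking <- compare_models(fits)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(ranking, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(command = "compare", seed = seed, n_starts = n_starts,
           ranking = ranking,
           package_version = as.character(utils::packageVersion("peadapt"))),
      file.path(out_dir, "model_comparison.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(ranking = ranking, fits = fits))
}

#' Generate a synthetic experiment to disk
#'
#' Dispatches to the experiment generators and writes the trial CSV
#' plus its sidecar truth JSON.
#'
#' @param experiment one of `"exp1_2afc"`, `"exp2_adaptation"`,
#'   `"exp3_proprioception"`, `"exp4_stl"`, `"report_drift"`.
#' @param seed integer seed (required by every generator).
#' @param out_dir output directory.
#' @param ... further arguments for the generator.
#' @return Invisibly, the `"synthetic_dataset"`.
#' @export
run_generate <- function(experiment = c("exp1_2afc", "exp2_adaptation",
                                        "exp3_proprioception", "exp4_stl",
                                        "report_drift"),
                         seed, out_dir, ...) {
  experiment <- match.arg(experiment)
  gen <- switch(experiment,
                exp1_2afc = gen_2afc,
                exp2_adaptation = gen_adaptation,
                exp3_proprioception = gen_proprioception,
                exp4_stl = gen_stl_triplets,
                report_drift = gen_report_drift)
  ds <- gen(seed = seed, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_dataset_csv(ds, file.path(out_dir, experiment))
  invisible(ds)
}

#' Psychometric pipeline: 2AFC trials to the eccentricity law
#'
#' Fits per-subject, per-size psychometric functions to a 2AFC trial
#' table ([estimate_sigma_v()]) and regresses the uncertainties on the
#' absolute clamp size ([fit_uncertainty_law()]).
#'
#' @param trials a 2AFC trial table or a `"synthetic_dataset"` from
#'   [gen_2afc()].
#' @param out optional JSON output path.
#' @return Invisibly, a list with `per_cell` (per subject-size fits)
#'   and `law` (the `"uncertainty_law"`).
#' @export
run_psychometric <- function(trials, out = NULL) {
  if (inherits(trials, "synthetic_dataset")) trials <- trials$data
  per_cell <- estimate_sigma_v(trials)
  law <- fit_uncertainty_law(per_cell)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(command = "psychometric",
           a = law$a, b = law$b, ci_a = law$ci_a, ci_b = law$ci_b,
           per_cell = per_cell,
           package_version = as.character(utils::packageVersion("peadapt"))),
      out, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(per_cell = per_cell, law = law))
}
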