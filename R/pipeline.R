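#' Pipeline configuration
#'
#' Collects every tunable of the synthetic-cohort pipeline.  The default
#' `design = "cohort216"` emulates a 26-subject, 216-trial study drawn
#' from three lab protocols: 9 subjects at 4 evenly spaced speeds over
#' 0.75-2.0 m/s, 5 subjects at 20 speeds over 1.0-2.6 m/s, and 12
#' subjects with 5,6,9,7,4,5,7,9,5,4,6,13 trials near their preferred
#' speed.  `design = "grid"` gives every subject the same speed grid
#' (`grid_speeds`).
#'
#' @param seed master seed; all randomness derives from it.
#' @param n_subjects cohort size.
#' @param design `"cohort216"` or `"grid"`.
#' @param grid_speeds speeds (m/s) used by the grid design.
#' @param noise_sd moment noise sd (N·m); 0 for noiseless trials.
#' @param coeffs a [gen_coeffs()] set (set `moment_cv = 0`,
#'   `excursion_cv = 0` for a deterministic generative model).
#' @param n_samples samples per trial.
#' @param c_pct landmark percent of point c.
#' @param landmark_pct generator landmark percents (b, c, d, e).
#' @param alpha stepwise significance threshold.
#' @param outlier_threshold studentized-residual outlier cut-off.
#' @param froude_opt,leg_coeff Froude-substitution constants.
#' @param basis_specs list of four [basis_spec()]s.
#' @param singular_tol dual-excursion singularity tolerance (rad).
#' @return A list of class `"run_config"`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 26L,
                            design = c("cohort216", "grid"),
                            grid_speeds = seq(0.8, 2.2, length.out = 8),
                            noise_sd = 8, coeffs = gen_coeffs(),
                            n_samples = 66, c_pct = 30,
                            landmark_pct = c(b = 10, c = 30, d = 48, e = 62),
                            alpha = 0.05, outlier_threshold = 3,
                            froude_opt = 0.25, leg_coeff = 0.53,
                            basis_specs = default_basis_specs(),
                            singular_tol = 1e-4) {
  design <- match.arg(design)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 design = design, grid_speeds = grid_speeds,
                 noise_sd = noise_sd, coeffs = coeffs,
                 n_samples = n_samples, c_pct = c_pct,
                 landmark_pct = landmark_pct, alpha = alpha,
                 outlier_threshold = outlier_threshold,
                 froude_opt = froude_opt, leg_coeff = leg_coeff,
                 basis_specs = basis_specs, singular_tol = singular_tol),
            class = "run_config")
}

trial_speeds_for <- function(config, cohort) {
  n <- nrow(cohort)
  if (config$design == "grid" || n != 26L) {
    return(lapply(seq_len(n), function(i) config$grid_speeds))
  }
  counts_c <- c(5, 6, 9, 7, 4, 5, 7, 9, 5, 4, 6, 13)
  lapply(seq_len(n), function(i) {
    if (i <= 9) seq(0.75, 2.0, length.out = 4)
    else if (i <= 14) seq(1.0, 2.6, length.out = 20)
    else {
      k <- counts_c[i - 14]
      cohort$preferred_speed[i] * seq(0.95, 1.05, length.out = k)
    }
  })
}

#' Generate a full synthetic dataset
#'
#' Samples a cohort, draws per-trial generative truths and renders the
#' trials, all deterministically from the config seed.
#'
#' @param config a [pipeline_config()].
#' @return List with `cohort`, `truths` and `trials` (parallel lists).
#' @export
simulate_dataset <- function(config = pipeline_config()) {
  cohort <- sample_cohort(config$n_subjects, seed = config$seed)
  speeds <- trial_speeds_for(config, cohort)
  n_trials <- sum(lengths(speeds))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_trials)
  truths <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    for (v in speeds[[i]]) {
      k <- k + 1L
      truths[[k]] <- ground_truth(subj, v, coeffs = config$coeffs,
                                  seed = sub_seeds[2L * k - 1L])
      trials[[k]] <- render_trial(subj, v, truths[[k]],
                                  n_samples = config$n_samples,
                                  noise_sd = config$noise_sd,
                                  seed = sub_seeds[2L * k],
                                  landmark_pct = config$landmark_pct)
    }
  }
  list(cohort = cohort, truths = truths, trials = trials)
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a dataset, summarizes every trial, fits the
#' four general-form models with PLS leave-one-subject-out component
#' selection and backward stepwise least squares, reduces each to a
#' stature-based model at the Froude-preferred speed, and compares the
#' mean percent errors of the general-form, stature-based and
#' cohort-average predictors.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-built dataset (list with `cohort`,
#'   `trials`); by default [simulate_dataset()] is run.
#' @param out_dir optional directory; when given, `report.json` and
#'   `report.txt` are written (byte-identical across reruns with the
#'   same seed).
#' @return An object of class `"ankle_report"`: `summaries`, `models`,
#'   `stature_models`, `mean_excursions`, `error_table`, `preferred`
#'   (selected preferred-speed summaries) and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         out_dir = NULL) {
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  cohort <- dataset$cohort
  summaries <- summarize_dataset(dataset$trials, c_pct = config$c_pct,
                                 singular_tol = config$singular_tol)

  responses <- c("K_df", "K_dl", "K_pf", "E")
  models <- lapply(responses, function(r)
    fit_general_model(summaries, cohort, config$basis_specs[[r]],
                      alpha = config$alpha,
                      outlier_threshold = config$outlier_threshold))
  names(models) <- responses

  preferred <- nearest_preferred_trials(summaries, cohort,
                                        froude_opt = config$froude_opt,
                                        leg_coeff = config$leg_coeff)
  mean_exc <- mean_excursions_at_preferred(preferred)
  stature_models <- lapply(models, reduce_model, mean_excursions = mean_exc,
                           froude_opt = config$froude_opt,
                           leg_coeff = config$leg_coeff)

  idxp <- match(preferred$subject_id, cohort$subject_id)
  Wp <- cohort$weight[idxp]; Hp <- cohort$height[idxp]
  resp_col <- c(K_df = "K_df", K_dl = "K_dl", K_pf = "K_pf", E = "E_loop")
  err <- lapply(responses, function(r) {
    m <- models[[r]]
    general <- m$mean_pct_error
    yp <- preferred[[resp_col[[r]]]]
    ok <- is.finite(yp) & if (r == "K_dl") !preferred$singular_dl else TRUE
    stature <- mean_pct_error(yp[ok],
                              predict(stature_models[[r]], Wp[ok], Hp[ok]))
    base <- baseline_mean_model(m$basis$y)
    baseline <- mean_pct_error(m$basis$y, predict(base, n = length(m$basis$y)),
                               exclude = match(m$outlier_rows, m$basis$rows))
    data.frame(response = r, general_form = general, stature_based = stature,
               average_values = baseline)
  })
  error_table <- do.call(rbind, err)

  report <- structure(list(seed = config$seed, summaries = summaries,
                           models = models, stature_models = stature_models,
                           mean_excursions = mean_exc,
                           preferred = preferred, error_table = error_table,
                           config = config),
                      class = "ankle_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_json_payload <- function(report) {
  list(
    seed = report$seed,
    n_trials = nrow(report$summaries),
    summaries = report$summaries,
    models = lapply(report$models, function(m) jsonlite::fromJSON(model_to_json(m))),
    stature_models = lapply(report$stature_models,
                            function(m) jsonlite::fromJSON(model_to_json(m))),
    mean_excursions = report$mean_excursions,
    error_table = report$error_table
  )
}

#' Write an analysis report to disk
#'
#' @param report an `"ankle_report"`.
#' @param out_dir output directory.
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fj <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_json_payload(report), fj, digits = NA,
                       auto_unbox = TRUE, dataframe = "rows", null = "null")
  ft <- file.path(out_dir, "report.txt")
  con <- file(ft, open = "wt")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(c(fj, ft))
}

#' @export
print.ankle_report <- function(x, ...) {
  cat(sprintf("Ankle quasi-stiffness pipeline report (seed %d, %d trials, %d subjects)\n\n",
              x$seed, nrow(x$summaries), length(unique(x$summaries$subject_id))))
  s <- x$summaries
  fin <- function(v) v[is.finite(v)]
  cat(sprintf("Cohort means: K_df %.0f  K_pf %.0f N.m/rad  E %.1f J\n",
              mean(fin(s$K_df)), mean(fin(s$K_pf)), mean(fin(s$E_loop))))
  cat(sprintf("Mean phase fit R2: dorsi %.0f%%  dual %.0f%%  plantar %.0f%%\n",
              100 * mean(fin(s$r2_df)), 100 * mean(fin(s$r2_dl)),
              100 * mean(fin(s$r2_pf))))
  cat(sprintf("Singular dual-flexion trials: %d\n\n", sum(s$singular_dl)))
  for (m in x$models) { print(m); cat("\n") }
  for (m in x$stature_models) { print(m); cat("\n") }
  cat("Mean percent error by model family:\n")
  print(x$error_table, row.names = FALSE)
  invisible(x)
}
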