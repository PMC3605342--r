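test_that("the Froude-optimal speed follows the square-root law", {
  expect_equal(optimal_speed(1.71), sqrt(0.25 * 9.81 * 0.53 * 1.71),
               tolerance = 1e-12)
  expect_equal(round(optimal_speed(1.71), 3), 1.491)
  expect_equal(optimal_speed(1.71, froude_opt = 0), 0)
  expect_gt(optimal_speed(1.87), optimal_speed(1.43))
  expect_error(optimal_speed(-1), "positive")
})

stature_fixture <- function() {
  # one subject whose Froude-optimal speed is exactly 1.5 m/s
  H <- 1.5^2 / (0.25 * 9.81 * 0.53)
  cohort <- data.frame(subject_id = c("A", "B"), weight = c(70, 55),
                       height = c(H, 1.60),
                       preferred_speed = optimal_speed(c(H, 1.60)),
                       singular_speed = c(2, 2))
  class(cohort) <- c("ankle_cohort", "data.frame")
  cohort
}

test_that("preferred-trial selection takes the nearest speed, slower on ties", {
  cohort <- stature_fixture()
  sm <- data.frame(
    subject_id = c("A", "A", "A", "B"),
    speed = c(1.0, 1.5, 2.0, 1.2),
    Gamma_df = c(0.2, 0.22, 0.24, 0.2),
    Gamma_dl_signed = c(0.05, 0.03, -0.02, 0.04),
    Gamma_pf = c(0.5, 0.52, 0.54, 0.5))
  sm$Gamma_dl <- abs(sm$Gamma_dl_signed)
  sel <- nearest_preferred_trials(sm, cohort)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$speed[sel$subject_id == "A"], 1.5)
  expect_equal(sel$speed[sel$subject_id == "B"], 1.2)  # single trial

  tie <- sm[sm$subject_id == "A", ][c(1, 3), ]
  tie$speed <- c(1.4, 1.6)  # equidistant from 1.5
  sel_tie <- nearest_preferred_trials(tie, cohort)
  expect_equal(sel_tie$speed, 1.4)
})

test_that("mean excursions average the selected trials", {
  sel <- data.frame(Gamma_df = c(0.2, 0.3), Gamma_dl_signed = c(0.05, 0.01),
                    Gamma_pf = c(0.5, 0.6))
  m <- mean_excursions_at_preferred(sel)
  expect_equal(m$G_df, 0.25)
  expect_equal(m$G_dl, 0.03)
  expect_equal(m$G_pf, 0.55)
  one <- mean_excursions_at_preferred(sel[1, ])
  expect_equal(one$G_df, 0.2)
  expect_error(mean_excursions_at_preferred(sel[0, ]), "empty")
})

test_that("generated excursions match their configured distribution means", {
  cfg <- pipeline_config(seed = 77, n_subjects = 12, design = "grid",
                         grid_speeds = c(1.4, 1.5, 1.6), noise_sd = 0)
  ds <- simulate_dataset(cfg)
  s <- summarize_dataset(ds$trials)
  # Gamma_df ~ N(0.22 - 0.02 (V - 1.5), 0.03): mean 0.22 at 1.5 m/s
  n <- nrow(s)
  expect_lt(abs(mean(s$Gamma_df) - 0.22), 2 * 0.03 / sqrt(n) + 0.002)
  expect_lt(abs(mean(s$Gamma_pf) - 0.50), 2 * 0.06 / sqrt(n) + 0.004)
})

test_that("stature reduction is an exact substitution identity", {
  fx_seed <- 33
  cfg <- pipeline_config(seed = fx_seed, n_subjects = 8, design = "grid",
                         grid_speeds = seq(0.9, 2.1, length.out = 5),
                         noise_sd = 3)
  ds <- simulate_dataset(cfg)
  sm <- summarize_dataset(ds$trials)
  model <- suppressMessages(
    fit_general_model(sm, ds$cohort, default_basis_specs()$K_df,
                      alpha = 0.05, cv = FALSE))
  pref <- nearest_preferred_trials(sm, ds$cohort)
  mexc <- mean_excursions_at_preferred(pref)
  red <- reduce_model(model, mexc)

  set.seed(fx_seed)
  W <- runif(100, 46, 94)
  H <- runif(100, 1.43, 1.87)
  nd <- data.frame(W = W, H = H, V = optimal_speed(H),
                   G_df = mexc$G_df, G_dl = mexc$G_dl, G_pf = mexc$G_pf)
  expect_lt(max(abs(predict(red, W, H) - predict(model, nd))), 1e-9)
  expect_false(red$low_confidence)
})

test_that("single-term and intercept-only models reduce symbolically", {
  mexc <- list(G_df = 0.22, G_dl = 0.03, G_pf = 0.50)
  one <- structure(list(
    term_objects = list(basis_term("WH.V/G_df", w = 1, h = 1, v = 1, g_df = -1)),
    coefficients = c("WH.V/G_df" = 2.5),
    intercept = FALSE,
    spec = default_basis_specs()$K_df),
    class = c("fitted_model", "ankle_model"))
  red <- reduce_model(one, mexc)
  # c W H V / G_df with V = cc sqrt(H) collapses to (c cc / G_df) W H^1.5
  expect_equal(red$w_exp, 1)
  expect_equal(red$h_exp, 1.5)
  cc <- sqrt(0.25 * 9.81 * 0.53)
  expect_equal(unname(red$coefficients), 2.5 * cc / 0.22, tolerance = 1e-12)

  const <- structure(list(
    term_objects = list(),
    coefficients = c("(Intercept)" = 42),
    intercept = TRUE,
    spec = default_basis_specs()$K_df),
    class = c("fitted_model", "ankle_model"))
  red_c <- reduce_model(const, mexc)
  expect_equal(predict(red_c, W = 80, H = 1.8), 42)

  dl_model <- structure(list(
    term_objects = list(basis_term("WH/G_dl", w = 1, h = 1, g_dl = -1)),
    coefficients = c("WH/G_dl" = 0.2),
    intercept = FALSE,
    spec = default_basis_specs()$K_dl),
    class = c("fitted_model", "ankle_model"))
  expect_true(reduce_model(dl_model, mexc)$low_confidence)
})

test_that("stature and general models serialize to JSON", {
  mexc <- list(G_df = 0.22, G_dl = 0.03, G_pf = 0.50)
  one <- structure(list(
    term_objects = list(basis_term("WH/G_df", w = 1, h = 1, g_df = -1)),
    coefficients = c("WH/G_df" = 2),
    intercept = FALSE, terms = "WH/G_df", p_values = c("WH/G_df" = 1e-8),
    r2 = 99.9, predicted_r2 = 99.5, n_components_cv = 1L,
    mean_pct_error = 3.2, outlier_rows = integer(0), alpha = 0.05,
    spec = default_basis_specs()$K_df),
    class = c("fitted_model", "ankle_model"))
  js <- jsonlite::fromJSON(model_to_json(one))
  expect_equal(js$kind, "general")
  expect_equal(js$terms, "WH/G_df")
  red <- reduce_model(one, mexc)
  js2 <- jsonlite::fromJSON(model_to_json(red))
  expect_equal(js2$kind, "stature")
  expect_equal(js2$coefficients, unname(red$coefficients))
})
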