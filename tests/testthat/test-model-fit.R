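make_summary_frame <- function(n, seed, gamma_dl = NULL) {
  set.seed(seed)
  cohort <- sample_cohort(25, seed = seed)
  sid <- sample(cohort$subject_id, n, replace = TRUE)
  g_dl <- if (is.null(gamma_dl))
    sample(c(-1, 1), n, TRUE) * runif(n, 0.03, 0.12) else gamma_dl
  sm <- data.frame(subject_id = sid, speed = runif(n, 0.6, 2.6),
                   Gamma_df = runif(n, 0.12, 0.32),
                   Gamma_dl_signed = g_dl,
                   Gamma_pf = runif(n, 0.30, 0.70))
  sm$Gamma_dl <- abs(sm$Gamma_dl_signed)
  sm$K_df <- sm$K_dl <- sm$K_pf <- sm$E_loop <- 1
  sm$singular_dl <- FALSE
  class(sm) <- c("joint_summary", "data.frame")
  list(summaries = sm, cohort = cohort)
}

test_that("basis terms evaluate to the documented monomials", {
  fx <- make_summary_frame(1, seed = 1)
  sm <- fx$summaries
  sm$subject_id <- fx$cohort$subject_id[1]
  fx$cohort$weight[1] <- 70
  fx$cohort$height[1] <- 1.7
  sm$speed <- 1.5
  sm$Gamma_df <- 0.2
  b <- build_basis(sm, fx$cohort, default_basis_specs()$K_df)
  expect_equal(unname(b$X[1, "WH/G_df"]), 70 * 1.7 / 0.2)     # 595
  expect_equal(unname(b$X[1, "WH.V/G_df"]), 70 * 1.7 * 1.5 / 0.2)  # 892.5
  expect_equal(unname(b$X[1, "(Intercept)"]), 1)
})

test_that("the work basis has exactly nine columns and no intercept", {
  spec <- default_basis_specs()$E
  expect_length(spec$terms, 9)
  expect_false(spec$include_intercept)
  fx <- make_summary_frame(20, seed = 2)
  b <- build_basis(fx$summaries, fx$cohort, spec)
  expect_equal(ncol(b$X), 9)

  empty <- fx$summaries[0, ]
  b0 <- build_basis(empty, fx$cohort, spec)
  expect_equal(nrow(b0$X), 0)
  expect_length(b0$y, 0)
})

test_that("singular and near-zero-excursion rows are dropped with reasons", {
  fx <- make_summary_frame(30, seed = 3)
  sm <- fx$summaries
  sm$singular_dl[c(4, 9)] <- TRUE
  sm$Gamma_dl_signed[15] <- 1e-6
  sm$Gamma_dl[15] <- 1e-6
  expect_message(
    b <- build_basis(sm, fx$cohort, default_basis_specs()$K_dl),
    "dropped")
  expect_equal(nrow(b$X), 27)
  expect_setequal(b$dropped$row, c(4, 9, 15))
})

test_that("PLS cross-validation finds exact low-rank structure", {
  set.seed(99)
  t1 <- rnorm(60)
  X1 <- outer(t1, rnorm(5))
  colnames(X1) <- paste0("x", 1:5)
  g1 <- rep(sprintf("g%d", 1:12), each = 5)
  r1 <- pls_loso_cv(X1, t1, g1, max_components = 1)
  expect_equal(r1$n_components, 1L)
  expect_equal(r1$r2, 100, tolerance = 1e-9)
  expect_equal(r1$predicted_r2, 100, tolerance = 1e-9)
})

test_that("PLS cross-validation recovers a rank-3 latent design", {
  set.seed(314)
  n <- 200
  T3 <- matrix(rnorm(n * 3), n, 3)
  X <- T3 %*% matrix(rnorm(3 * 8), 3, 8)
  colnames(X) <- paste0("x", 1:8)
  y <- drop(T3 %*% c(2, -1.5, 1)) + rnorm(n, 0, 0.3)
  groups <- rep(sprintf("g%02d", 1:20), each = 10)
  r <- pls_loso_cv(X, y, groups, max_components = 8)
  expect_equal(r$n_components, 3L)
  expect_lte(r$predicted_r2, r$r2 + 1e-9)
})

test_that("held-out predicted R2 never exceeds the training R2", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(120 * 6), 120, 6)
    colnames(X) <- paste0("x", 1:6)
    y <- drop(X %*% rnorm(6)) + rnorm(120, 0, 0.5)
    g <- rep(sprintf("g%d", 1:12), each = 10)
    r <- pls_loso_cv(X, y, g, max_components = 6)
    expect_lte(r$predicted_r2, r$r2 + 1e-9)
  }
  expect_error(pls_loso_cv(matrix(1:10, 5), 1:5, rep("a", 5)), "at least 2")
})

test_that("backward stepwise recovers a planted 2-of-5 support", {
  set.seed(500)
  n <- 500
  X <- cbind(1, matrix(runif(n * 4, 0.5, 2), n, 4))
  colnames(X) <- c("(Intercept)", paste0("x", 1:4))
  y <- drop(X[, c("x1", "x3")] %*% c(4, -2)) * (1 + rnorm(n, 0, 0.01))
  m <- stepwise_ols(X, y, alpha = 0.001)
  expect_setequal(m$terms, c("x1", "x3"))
  expect_equal(unname(m$coefficients["x1"]), 4, tolerance = 0.05)
  expect_equal(unname(m$coefficients["x3"]), -2, tolerance = 0.05)
})

test_that("stepwise keeps everything at alpha = 1 and nails exact fits", {
  set.seed(501)
  X <- matrix(rnorm(200 * 3), 200, 3)
  colnames(X) <- paste0("x", 1:3)
  y <- drop(X %*% c(1, 2, 3)) + rnorm(200, 0, 0.2)
  m_all <- stepwise_ols(X, y, alpha = 1.0)
  expect_setequal(m_all$terms, colnames(X))

  y3 <- 3 * X[, 1]
  m3 <- suppressWarnings(stepwise_ols(X, y3, alpha = 0.05))
  expect_equal(unname(m3$coefficients["x1"]), 3, tolerance = 1e-9)
  expect_lt(m3$p_values["x1"], 1e-10)

  expect_error(stepwise_ols(X[1:4, ], y[1:4]), "more rows")
})

test_that("outlier flagging isolates an injected corrupt row", {
  # bounded deterministic perturbation: a clean fit has no 3-sigma
  # studentized residuals by construction
  n <- 100
  X <- cbind(1, seq(1, 2, length.out = n))
  colnames(X) <- c("(Intercept)", "x")
  y <- drop(X %*% c(1, 5)) + 0.05 * sin(1:n)
  clean <- stepwise_ols(X, y, alpha = 0.5)
  expect_length(flag_outliers(clean), 0)

  y_bad <- y
  y_bad[37] <- 10 * y[37]
  m <- stepwise_ols(X, y_bad, alpha = 0.5)
  expect_equal(as.integer(flag_outliers(m)), 37L)
  expect_length(flag_outliers(m, threshold = Inf), 0)

  # excluding the corrupt row reduces the mean percent error
  err_with <- mean_pct_error(y_bad, m$fitted)
  err_without <- mean_pct_error(y_bad, m$fitted, exclude = 37)
  expect_lt(err_without, err_with)
})

test_that("percent error and the baseline predictor follow their definitions", {
  expect_equal(mean_pct_error(c(100, 200), c(110, 180)), 10)
  expect_equal(mean_pct_error(c(5, 5), c(5, 5)), 0)
  expect_message(mean_pct_error(c(0, 10), c(1, 10)), "zero-response")

  base <- baseline_mean_model(c(2, 4, 6))
  expect_equal(predict(base, n = 5), rep(4, 5))
  expect_equal(mean_pct_error(c(4, 4), predict(base, n = 2)), 0)
  one <- baseline_mean_model(7)
  expect_equal(predict(one, n = 1), 7)
  expect_error(baseline_mean_model(numeric(0)), "at least one")
})

test_that("general-form model predictions evaluate the retained monomials", {
  model <- structure(list(
    term_objects = list(basis_term("WH/G_df", w = 1, h = 1, g_df = -1)),
    coefficients = c("WH/G_df" = 2),
    intercept = FALSE,
    spec = default_basis_specs()$K_df),
    class = c("fitted_model", "ankle_model"))
  nd <- data.frame(W = 70, H = 1.7, G_df = 0.2)
  expect_equal(predict(model, nd), 2 * 70 * 1.7 / 0.2)  # 1190
  expect_error(predict(model, data.frame(W = 70, H = 1.7)), "missing columns")

  zero <- model
  zero$coefficients <- c("WH/G_df" = 0)
  expect_equal(predict(zero, nd), 0)
})

test_that("model metrics are invariant to row permutation", {
  fx <- make_summary_frame(120, seed = 7)
  sm <- fx$summaries
  b <- build_basis(sm, fx$cohort, default_basis_specs()$K_df)
  set.seed(8)
  y <- drop(b$X[, c("WH/G_df", "WH.V/G_df")] %*% c(0.28, 0.12)) *
    (1 + rnorm(nrow(b$X), 0, 0.02))
  m1 <- stepwise_ols(b$X, y, alpha = 0.01)
  perm <- sample(nrow(b$X))
  m2 <- stepwise_ols(b$X[perm, ], y[perm], alpha = 0.01)
  expect_setequal(m1$terms, m2$terms)
  expect_equal(sort(m1$coefficients), sort(m2$coefficients), tolerance = 1e-9)
  expect_equal(m1$r2, m2$r2, tolerance = 1e-9)
  expect_equal(mean_pct_error(y, m1$fitted),
               mean_pct_error(y[perm], m2$fitted), tolerance = 1e-9)
})
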