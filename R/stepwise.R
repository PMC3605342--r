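#' Backward stepwise least squares
#'
#' Fits ordinary least squares on the given design matrix and
#' iteratively removes the term with the largest p-value while any
#' p-value is at or above `alpha` (ties broken by dropping the later
#' column; rank-deficient aliased columns are dropped first).  The
#' intercept column, when present, competes like any other term.
#'
#' @param X design matrix with named columns (include an explicit
#'   `"(Intercept)"` column if wanted).
#' @param y response vector.
#' @param alpha significance threshold for retaining a term.
#' @return An object of class `"ankle_model"`: retained `terms`
#'   (column names), `coefficients`, `p_values`, `r2` (percent),
#'   `fitted`, `lm` (the final [stats::lm] fit), `dropped` (names in
#'   removal order) and `alpha`.
#' @export
stepwise_ols <- function(X, y, alpha = 0.05) {
  if (nrow(X) <= ncol(X) + 2L)
    stop("need more rows than columns + 2 for stepwise least squares")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cols <- colnames(X)
  dropped <- character(0)
  repeat {
    if (!length(cols)) stop("degenerate model: all terms removed")
    Xc <- X[, cols, drop = FALSE]
    fit <- stats::lm(y ~ Xc - 1)
    cf <- summary(fit)$coefficients
    est <- stats::coef(fit)
    names(est) <- cols
    if (anyNA(est)) {
      # aliased (collinear) column: drop the last one
      bad <- cols[max(which(is.na(est)))]
      dropped <- c(dropped, bad)
      cols <- setdiff(cols, bad)
      next
    }
    p <- cf[, "Pr(>|t|)"]
    names(p) <- cols
    if (max(p) < alpha) break
    worst <- max(which(p == max(p)))  # tie: later column
    dropped <- c(dropped, cols[worst])
    cols <- cols[-worst]
  }
  fitted <- drop(X[, cols, drop = FALSE] %*% est)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 100 else 100 * (1 - sum((y - fitted)^2) / ss_tot)
  structure(list(terms = cols, coefficients = est, p_values = p,
                 r2 = r2, fitted = fitted, lm = fit, dropped = dropped,
                 alpha = alpha),
            class = "ankle_model")
}

#' @export
print.ankle_model <- function(x, ...) {
  cat(sprintf("Stepwise OLS model (%d terms, R2 = %.1f%%, alpha = %g)\n",
              length(x$terms), x$r2, x$alpha))
  print(data.frame(term = x$terms, coefficient = unname(x$coefficients),
                   p_value = unname(x$p_values)), row.names = FALSE)
  invisible(x)
}

#' Flag regression outliers
#'
#' Rows whose externally studentized residual exceeds the threshold in
#' magnitude.
#'
#' @param model an `"ankle_model"`.
#' @param threshold studentized-residual cut-off (default 3).
#' @return Integer row indices (into the rows the model was fit on).
#' @export
flag_outliers <- function(model, threshold = 3) {
  t <- stats::rstudent(model$lm)
  which(abs(t) > threshold)
}

#' Mean absolute percent prediction error
#'
#' Mean over included rows of `100 |yhat - y| / |y|`; rows with zero
#' observed response are skipped (with a message), as are excluded rows
#' (e.g. flagged outliers).
#'
#' @param y observed values.
#' @param yhat predictions.
#' @param exclude row indices to exclude.
#' @return Percent error (scalar).
#' @export
mean_pct_error <- function(y, yhat, exclude = integer(0)) {
  keep <- setdiff(seq_along(y), exclude)
  zero <- keep[y[keep] == 0]
  if (length(zero)) {
    message("mean_pct_error: skipping ", length(zero), " zero-response row(s)")
    keep <- setdiff(keep, zero)
  }
  if (!length(keep)) stop("no usable rows for percent error")
  100 * mean(abs(yhat[keep] - y[keep]) / abs(y[keep]))
}

#' Cohort-average baseline predictor
#'
#' Constant model predicting the cohort mean of the response for every
#' trial — the "average values" sizing strategy used as the reference
#' point for the regression models.
#'
#' @param y response values.
#' @return An object of class `"baseline_model"` with the stored mean.
#' @export
baseline_mean_model <- function(y) {
  if (!length(y)) stop("need at least one value")
  structure(list(mean = mean(y), n = length(y)), class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, n = 1L, ...) {
  rep(object$mean, n)
}

#' Fit a general-form model for one response
#'
#' Composition of [build_basis()], [pls_loso_cv()] and [stepwise_ols()]:
#' builds the design for the response, cross-validates the component
#' count, runs backward stepwise least squares, flags outliers and
#' computes the mean percent error excluding them.
#'
#' @param summaries a `"joint_summary"` data frame.
#' @param cohort an `"ankle_cohort"`.
#' @param spec a [basis_spec()].
#' @param alpha stepwise significance threshold.
#' @param outlier_threshold studentized-residual cut-off.
#' @param cv run the PLS cross-validation (can be disabled for speed).
#' @return An object of class `"fitted_model"`: the `"ankle_model"`
#'   fields plus `spec`, retained `term_objects`, `n_components_cv`,
#'   `predicted_r2`, `mean_pct_error`, `outlier_rows` (indices into
#'   `summaries`) and `basis` (the [build_basis()] result).
#' @export
fit_general_model <- function(summaries, cohort, spec, alpha = 0.05,
                              outlier_threshold = 3, cv = TRUE) {
  b <- build_basis(summaries, cohort, spec)
  cvres <- if (cv) pls_loso_cv(b$X, b$y, b$groups) else NULL
  m <- stepwise_ols(b$X, b$y, alpha = alpha)
  out_rows <- flag_outliers(m, outlier_threshold)
  err <- mean_pct_error(b$y, m$fitted, exclude = out_rows)
  term_objects <- spec$terms[vapply(spec$terms, function(t) t$name, "") %in% m$terms]
  structure(c(unclass(m),
              list(spec = spec, term_objects = term_objects,
                   intercept = "(Intercept)" %in% m$terms,
                   n_components_cv = if (cv) cvres$n_components else NA_integer_,
                   predicted_r2 = if (cv) cvres$predicted_r2 else NA_real_,
                   cv_r2 = if (cv) cvres$r2 else NA_real_,
                   mean_pct_error = err,
                   outlier_rows = b$rows[out_rows],
                   basis = b)),
            class = c("fitted_model", "ankle_model"))
}

#' Predict a response from a fitted general-form model
#'
#' @param object a `"fitted_model"`.
#' @param newdata data frame with columns `W` (kg), `H` (m), `V` (m/s)
#'   and the excursions `G_df`, `G_dl` (signed, rad), `G_pf` the model's
#'   retained terms require.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  need <- unique(unlist(lapply(object$term_objects, function(t) {
    vars <- c("W", "H", "V", "G_df", "G_dl", "G_pf")
    vars[c(t$w, t$h, t$v, t$g_df, t$g_dl, t$g_pf) != 0]
  })))
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("missing columns needed by the model: ", paste(miss, collapse = ", "))
  for (v in setdiff(c("W", "H", "V", "G_df", "G_dl", "G_pf"), names(newdata)))
    newdata[[v]] <- 1  # unused by any retained term
  X <- eval_terms(object$term_objects, newdata)
  if (object$intercept) X <- cbind(`(Intercept)` = rep(1, nrow(X)), X)
  drop(X %*% object$coefficients[colnames(X)])
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("General-form model for %s\n", x$spec$response))
  cat(sprintf("  PLS-CV: %s components, predicted R2 %.1f%%\n",
              x$n_components_cv, x$predicted_r2))
  cat(sprintf("  stepwise OLS: %d terms, R2 %.1f%%, mean error %.1f%% (%d outliers)\n",
              length(x$terms), x$r2, x$mean_pct_error, length(x$outlier_rows)))
  print(data.frame(term = x$terms, coefficient = unname(x$coefficients),
                   p_value = unname(x$p_values)), row.names = FALSE)
  invisible(x)
}
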