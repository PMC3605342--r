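#' Leave-one-subject-out PLS cross-validation
#'
#' Selects the number of partial-least-squares components for a response
#' by leave-one-subject-out (stratified) cross-validation: for each
#' held-out subject a PLS regression (via \pkg{mixOmics}) is fit on the
#' remaining subjects' rows, held-out predictions are pooled across
#' folds, and the component count maximising predicted R² is chosen
#' (ties resolved toward fewer components).  The training R² is then
#' computed from a refit on all rows at that component count.
#'
#' Zero-variance columns (an intercept, if present) are removed before
#' the PLS, which centres and unit-scales the predictors.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param groups subject id per row; each fold holds out one subject.
#' @param max_components largest component count to consider (clamped to
#'   the usable column count and fold sizes).
#' @return List: `n_components`, `r2` and `predicted_r2` (percent), and
#'   `predicted_r2_by_ncomp` (percent, one per candidate count).
#' @export
pls_loso_cv <- function(X, y, groups, max_components = ncol(X)) {
  groups <- as.character(groups)
  ug <- unique(groups)
  if (length(ug) < 2L)
    stop("cross-validation error: need at least 2 subject groups")
  if (any(vapply(ug, function(g) all(groups == g), TRUE)))
    stop("cross-validation error: a group contains all rows")
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  Xp <- X[, keep, drop = FALSE]
  max_fold <- max(table(groups))
  rank_x <- qr(scale(Xp))$rank
  ncomp <- min(max_components, ncol(Xp), rank_x, nrow(Xp) - max_fold - 1L)
  if (ncomp < 1L) stop("no usable components")

  pred <- matrix(NA_real_, nrow(Xp), ncomp)
  for (g in ug) {
    tr <- groups != g
    fit <- mixOmics::pls(Xp[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                         mode = "regression")
    p <- stats::predict(fit, Xp[!tr, , drop = FALSE])$predict
    pred[!tr, ] <- p[, 1L, , drop = TRUE]
  }
  ss_tot <- sum((y - mean(y))^2)
  press <- colSums((pred - y)^2)
  pred_r2 <- 100 * (1 - press / ss_tot)
  best <- which(pred_r2 >= max(pred_r2) - 1e-8)[1]

  full <- mixOmics::pls(Xp, y, ncomp = best, mode = "regression")
  fitted <- stats::predict(full, Xp)$predict[, 1L, best]
  r2 <- 100 * (1 - sum((y - fitted)^2) / ss_tot)
  list(n_components = as.integer(best), r2 = r2,
       predicted_r2 = pred_r2[best], predicted_r2_by_ncomp = pred_r2)
}
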