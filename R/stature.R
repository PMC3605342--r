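#' Froude-optimal (preferred) walking speed from height
#'
#' Walkers of different statures prefer a common dimensionless Froude
#' number \eqn{Fr = V^2/(g\,l)}; with leg length proportional to height
#' (\eqn{l = c_l H}) the preferred speed is
#' \eqn{V_{opt} = \sqrt{Fr_{opt}\, g\, c_l\, H}}.
#'
#' @param H body height in m, positive.
#' @param froude_opt preferred Froude number (default 0.25).
#' @param leg_coeff leg length as a fraction of height (default 0.53).
#' @param g gravitational acceleration, m/s².
#' @return Preferred speed in m/s; monotone increasing in `H`.
#' @examples
#' optimal_speed(1.71)  # about 1.49 m/s
#' @export
optimal_speed <- function(H, froude_opt = 0.25, leg_coeff = 0.53, g = 9.81) {
  if (any(H <= 0)) stop("`H` must be positive")
  sqrt(froude_opt * g * leg_coeff * H)
}

#' Select each subject's trial closest to the preferred speed
#'
#' @param summaries a `"joint_summary"` data frame.
#' @param cohort an `"ankle_cohort"`.
#' @param froude_opt,leg_coeff,g passed to [optimal_speed()].
#' @return The subset of `summaries` (one row per subject) minimising
#'   `|speed - optimal_speed(H)|`; exact ties resolved toward the slower
#'   trial.
#' @export
nearest_preferred_trials <- function(summaries, cohort, froude_opt = 0.25,
                                     leg_coeff = 0.53, g = 9.81) {
  idx <- match(summaries$subject_id, cohort$subject_id)
  if (anyNA(idx)) stop("summaries contain subjects missing from the cohort")
  v_opt <- optimal_speed(cohort$height[idx], froude_opt, leg_coeff, g)
  gap <- abs(summaries$speed - v_opt)
  picked <- unlist(lapply(split(seq_len(nrow(summaries)), summaries$subject_id),
                          function(rows) {
                            g <- gap[rows]
                            best <- rows[g == min(g)]
                            if (length(best) > 1L)
                              best <- best[which.min(summaries$speed[best])]
                            best
                          }))
  out <- summaries[sort(unname(picked)), , drop = FALSE]
  class(out) <- class(summaries)
  out
}

#' Mean phase excursions at the preferred speed
#'
#' Arithmetic means of the phase excursions across the selected
#' preferred-speed trials; dorsi- and plantar-flexion as magnitudes, the
#' dual-flexion excursion signed (matching the basis convention).
#'
#' @param selected the [nearest_preferred_trials()] subset (>= 1 row).
#' @return Named list `G_df`, `G_dl`, `G_pf` in rad.
#' @export
mean_excursions_at_preferred <- function(selected) {
  if (!nrow(selected)) stop("empty selection")
  list(G_df = mean(selected$Gamma_df),
       G_dl = mean(selected$Gamma_dl_signed),
       G_pf = mean(selected$Gamma_pf))
}

#' Reduce a general-form model to a stature-based model
#'
#' Substitutes the Froude-optimal speed \eqn{V = \sqrt{Fr_{opt} g c_l H}}
#' and the cohort-mean excursions into every retained term of a fitted
#' general-form model.  Each monomial
#' \eqn{W^w H^h V^v \Gamma^{\gamma}} collapses to
#' \eqn{(c^v \bar\Gamma^{\gamma})\, W^w H^{h + v/2}}, so the reduced
#' predictor depends on weight and height only; like monomials are
#' merged.  Predictions agree exactly with the source model evaluated at
#' the substituted operating point.
#'
#' The dual-flexion reduction is flagged low-confidence: the dual-phase
#' quasi-stiffness is highly sensitive to its (small) excursion, which
#' stature does not predict.
#'
#' @param model a `"fitted_model"`.
#' @param mean_excursions a [mean_excursions_at_preferred()] triple.
#' @param froude_opt,leg_coeff,g Froude-substitution constants.
#' @return An object of class `"stature_model"`: `response`,
#'   `coefficients` with matching `w_exp`/`h_exp` monomial exponents,
#'   the substitution constants, and `low_confidence`.
#' @export
reduce_model <- function(model, mean_excursions, froude_opt = 0.25,
                         leg_coeff = 0.53, g = 9.81) {
  if (!inherits(model, "fitted_model")) stop("`model` must be a fitted_model")
  cc <- sqrt(froude_opt * g * leg_coeff)
  terms <- model$term_objects
  if (model$intercept)
    terms <- c(list(basis_term("(Intercept)")), terms)
  if (!length(terms)) stop("reduction error: model has no terms")
  rows <- lapply(terms, function(t) {
    coef <- model$coefficients[[t$name]]
    gbar <- mean_excursions$G_df^t$g_df * mean_excursions$G_dl^t$g_dl *
      mean_excursions$G_pf^t$g_pf
    data.frame(w_exp = t$w, h_exp = t$h + t$v / 2,
               coef = coef * cc^t$v * gbar)
  })
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(coef ~ w_exp + h_exp, data = tab, FUN = sum)
  agg <- agg[order(agg$w_exp, agg$h_exp), , drop = FALSE]
  mono <- ifelse(agg$w_exp == 0 & agg$h_exp == 0, "1",
                 paste0(ifelse(agg$w_exp != 0,
                               ifelse(agg$w_exp == 1, "W", sprintf("W^%g", agg$w_exp)), ""),
                        ifelse(agg$w_exp != 0 & agg$h_exp != 0, ".", ""),
                        ifelse(agg$h_exp != 0,
                               ifelse(agg$h_exp == 1, "H", sprintf("H^%g", agg$h_exp)), "")))
  structure(list(response = model$spec$response,
                 coefficients = stats::setNames(agg$coef, mono),
                 w_exp = agg$w_exp, h_exp = agg$h_exp,
                 froude_opt = froude_opt, leg_coeff = leg_coeff, g = g,
                 mean_excursions = mean_excursions,
                 low_confidence = model$spec$response == "K_dl"),
            class = "stature_model")
}

#' Predict from a stature-based model
#'
#' @param object a `"stature_model"`.
#' @param W weight in kg.
#' @param H height in m.
#' @param ... unused.
#' @return Predicted response (N·m/rad for quasi-stiffnesses, J for
#'   work) at the subject's preferred walking speed.
#' @export
predict.stature_model <- function(object, W, H, ...) {
  X <- outer(seq_along(W), seq_along(object$w_exp),
             function(i, j) W[i]^object$w_exp[j] * H[i]^object$h_exp[j])
  drop(X %*% object$coefficients)
}

#' @export
print.stature_model <- function(x, ...) {
  cat(sprintf("Stature-based model for %s%s\n", x$response,
              if (x$low_confidence) "  [low confidence]" else ""))
  print(data.frame(monomial = names(x$coefficients),
                   coefficient = unname(x$coefficients)), row.names = FALSE)
  invisible(x)
}

#' Serialize fitted and stature models to JSON
#'
#' @param model a `"fitted_model"` or `"stature_model"`.
#' @param path optional output path; with `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly the path when written).
#' @export
model_to_json <- function(model, path = NULL) {
  x <- if (inherits(model, "stature_model")) {
    list(kind = "stature", response = model$response,
         monomials = names(model$coefficients),
         w_exp = model$w_exp, h_exp = model$h_exp,
         coefficients = unname(model$coefficients),
         froude_opt = model$froude_opt, leg_coeff = model$leg_coeff,
         mean_excursions = model$mean_excursions,
         low_confidence = model$low_confidence)
  } else {
    list(kind = "general", response = model$spec$response,
         terms = model$terms, coefficients = unname(model$coefficients),
         p_values = unname(model$p_values), r2_pct = model$r2,
         predicted_r2_pct = model$predicted_r2,
         n_components_cv = model$n_components_cv,
         mean_pct_error = model$mean_pct_error,
         n_outliers = length(model$outlier_rows), alpha = model$alpha)
  }
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
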