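#' Render a stance-phase moment-angle trial
#'
#' Builds a sampled gait trial from a generative truth.  The angle trace
#' follows the stance-phase vertex sequence
#' \eqn{\theta_b \to \theta_c = \theta_b + \Gamma_{df} \to
#'      \theta_d = \theta_c + \Gamma_{dl,signed} \to
#'      \theta_e = \theta_d - \Gamma_{pf}}
#' with landmarks at configurable percents of the gait cycle, and the
#' moment is piecewise linear through \eqn{(\theta_b, 0)},
#' \eqn{(\theta_c, M_c)}, \eqn{(\theta_d, M_d)}, \eqn{(\theta_e, 0)}.
#' A heel-strike prefix (initial plantar-flexion with near-zero moment)
#' is prepended so that point b is a genuine local minimum of the angle,
#' and a short post-toe-off tail is appended so that point e is a local
#' minimum as well.
#'
#' Measurement noise is i.i.d. Gaussian on the moment channel only, with
#' standard deviation `noise_sd` scaled per phase by `phase_noise_scale`
#' (heel-strike prefix and dorsi-flexion, dual-flexion, plantar-flexion
#' and tail).  The default calibration reproduces field-typical average
#' per-phase linear-fit quality (about 96% dorsi, 73% dual, 93% plantar).
#'
#' Sample percents are an even grid over the covered cycle with the
#' landmark percents inserted exactly, so noiseless trials can be
#' segmented and refit without discretization error.
#'
#' @param subject cohort row (used for its `subject_id`).
#' @param speed gait speed m/s.
#' @param truth an `"ankle_truth"` from [ground_truth()].
#' @param n_samples target number of samples, at least 30.
#' @param noise_sd moment noise standard deviation in N·m (>= 0).
#' @param seed integer seed.
#' @param landmark_pct named numeric: gait-cycle percents of points
#'   b, c, d, e.
#' @param cover_pct start and end of the covered gait-cycle window.
#' @param theta_b ankle angle at point b (rad); dorsiflexion positive.
#' @param phase_noise_scale length-3 multipliers of `noise_sd` for the
#'   dorsi (and prefix), dual, and plantar (and tail) regions.
#' @return An object of class `"gait_trial"`: a list with `subject_id`,
#'   `speed`, `noise_sd` and `samples`, a data frame with strictly
#'   increasing `gait_pct`, `angle` (rad) and `moment` (N·m).
#' @export
render_trial <- function(subject, speed, truth, n_samples = 66,
                         noise_sd = 8, seed = 1L,
                         landmark_pct = c(b = 10, c = 30, d = 48, e = 62),
                         cover_pct = c(0, 65),
                         theta_b = -0.05,
                         phase_noise_scale = c(0.4, 1, 1)) {
  if (n_samples < 30) stop("`n_samples` must be at least 30")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  lp <- landmark_pct
  if (!(cover_pct[1] < lp["b"] && lp["b"] < lp["c"] && lp["c"] < lp["d"] &&
        lp["d"] < lp["e"] && lp["e"] < cover_pct[2]))
    stop("landmark percents must be ordered within the covered window")

  th_b <- theta_b
  th_c <- th_b + truth$Gamma_df
  th_d <- th_c + truth$Gamma_dl_signed
  th_e <- th_d - truth$Gamma_pf
  brk_pct <- c(cover_pct[1], lp["b"], lp["c"], lp["d"], lp["e"], cover_pct[2])
  brk_ang <- c(th_b + 0.06, th_b, th_c, th_d, th_e, th_e + 0.04)
  brk_mom <- c(0, 0, truth$M_c, truth$M_d, 0, 0)

  pct <- sort(unique(c(seq(cover_pct[1], cover_pct[2], length.out = n_samples),
                       unname(lp))))
  angle <- stats::approx(brk_pct, brk_ang, xout = pct)$y
  moment <- stats::approx(brk_pct, brk_mom, xout = pct)$y

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    sdv <- ifelse(pct <= lp["c"], phase_noise_scale[1],
                  ifelse(pct <= lp["d"], phase_noise_scale[2],
                         phase_noise_scale[3])) * noise_sd
    moment <- moment + stats::rnorm(length(pct), 0, sdv)
  }

  structure(list(subject_id = subject$subject_id, speed = speed,
                 noise_sd = noise_sd,
                 samples = data.frame(gait_pct = pct, angle = angle,
                                      moment = moment)),
            class = "gait_trial")
}

#' Construct / validate a gait trial
#'
#' @param subject_id subject identifier (no underscores; used in file names).
#' @param speed gait speed m/s.
#' @param samples data frame with `gait_pct` (strictly increasing percent
#'   of gait cycle), `angle` (rad) and `moment` (N·m); at least 30 rows.
#' @param noise_sd generator metadata; `NA` for real data.
#' @return A `"gait_trial"` object.
#' @export
gait_trial <- function(subject_id, speed, samples, noise_sd = NA_real_) {
  need <- c("gait_pct", "angle", "moment")
  if (!all(need %in% names(samples)))
    stop("`samples` must have columns ", paste(need, collapse = ", "))
  if (nrow(samples) < 30) stop("a trial needs at least 30 samples")
  if (any(diff(samples$gait_pct) <= 0))
    stop("`gait_pct` must be strictly increasing (first violation at row ",
         which(diff(samples$gait_pct) <= 0)[1] + 1, ")")
  structure(list(subject_id = subject_id, speed = speed, noise_sd = noise_sd,
                 samples = samples[, need]),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial  %s @ %.2f m/s  (%d samples, %.0f-%.0f%% of cycle)\n",
              x$subject_id, x$speed, nrow(x$samples),
              min(x$samples$gait_pct), max(x$samples$gait_pct)))
  invisible(x)
}
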