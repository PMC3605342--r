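#' Generative coefficient set for the synthetic gait model
#'
#' Coefficients of the generative model used by [ground_truth()].  The
#' transition moments scale with body size and gait speed:
#' \deqn{M_c = W H (a_0 + a_1 V) e^{\eta}, \qquad
#'       M_d = W H (b_0 + b_1 V + b_2 V^2) e^{\eta'}}
#' with \eqn{\eta, \eta'} zero-mean Gaussian on the log scale
#' (`moment_cv`), so the noise is multiplicative and the moments stay
#' positive.  The signed dual-flexion excursion is
#' \eqn{\Gamma_{dl} = s_0 (V_{sing} - V) e^{\eta''}}, which crosses zero
#' exactly at the subject's singular speed.  Dorsi- and plantar-flexion
#' excursions are Gaussian with a mild speed trend, truncated positive.
#'
#' The defaults are calibrated so that the default 26-subject cohort
#' reproduces field-typical cohort means (dorsi-flexion quasi-stiffness
#' near 246 N·m/rad, plantar-flexion near 202 N·m/rad, propulsive work
#' near 17.6 J).
#'
#' @param a0,a1 dorsi-to-dual transition moment polynomial (per kg·m).
#' @param b0,b1,b2 dual-to-plantar transition moment polynomial (per kg·m).
#' @param s0 dual-flexion excursion slope, rad per (m/s) of distance from
#'   the singular speed.
#' @param moment_cv log-scale standard deviation of the multiplicative
#'   moment noise; set to 0 for a deterministic generative model.
#' @param excursion_cv log-scale standard deviation of the multiplicative
#'   noise on the signed dual-flexion excursion.
#' @param gamma_df_mean,gamma_df_sd,gamma_df_vslope dorsi-flexion
#'   excursion distribution (rad); mean at 1.5 m/s and linear speed trend.
#' @param gamma_pf_mean,gamma_pf_sd,gamma_pf_vslope plantar-flexion
#'   excursion distribution (rad).
#' @return A named list of class `"gen_coeffs"`.
#' @export
gen_coeffs <- function(a0 = 0.268, a1 = 0.115,
                       b0 = 0.446, b1 = 0.171, b2 = 0.047,
                       s0 = 0.08,
                       moment_cv = 0.10,
                       excursion_cv = 0.15,
                       gamma_df_mean = 0.22, gamma_df_sd = 0.03,
                       gamma_df_vslope = -0.02,
                       gamma_pf_mean = 0.49, gamma_pf_sd = 0.06,
                       gamma_pf_vslope = 0.04) {
  structure(list(a0 = a0, a1 = a1, b0 = b0, b1 = b1, b2 = b2, s0 = s0,
                 moment_cv = moment_cv, excursion_cv = excursion_cv,
                 gamma_df_mean = gamma_df_mean, gamma_df_sd = gamma_df_sd,
                 gamma_df_vslope = gamma_df_vslope,
                 gamma_pf_mean = gamma_pf_mean, gamma_pf_sd = gamma_pf_sd,
                 gamma_pf_vslope = gamma_pf_vslope),
            class = "gen_coeffs")
}

#' Sample a synthetic walking cohort
#'
#' Draws subjects with body mass and height uniform over the configured
#' ranges.  Each subject gets a preferred (Froude-optimal) walking speed
#' derived from height via [optimal_speed()], and a subject-specific
#' singular gait speed — the speed at which the dual-flexion excursion
#' changes sign and the dual-flexion quasi-stiffness diverges — drawn
#' uniformly above the preferred speed.
#'
#' @param n_subjects number of subjects (may be 0).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param weight_range body-mass range in kg.
#' @param height_range body-height range in m.
#' @param singular_range multiplicative range of the singular speed
#'   relative to the preferred speed.
#' @return A data frame of class `"ankle_cohort"` with columns
#'   `subject_id`, `weight` (kg), `height` (m), `preferred_speed` (m/s)
#'   and `singular_speed` (m/s).
#' @examples
#' cohort <- sample_cohort(5, seed = 1)
#' range(cohort$weight)
#' @export
sample_cohort <- function(n_subjects, seed = 1L,
                          weight_range = c(46, 94),
                          height_range = c(1.43, 1.87),
                          singular_range = c(1, 1.5)) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 0)
    stop("`n_subjects` must be a single non-negative number")
  if (weight_range[1] >= weight_range[2] || height_range[1] >= height_range[2])
    stop("ranges must satisfy low < high")
  n_subjects <- as.integer(n_subjects)
  set.seed(as.integer(seed))
  w <- stats::runif(n_subjects, weight_range[1], weight_range[2])
  h <- stats::runif(n_subjects, height_range[1], height_range[2])
  v_pref <- optimal_speed(h)
  v_sing <- v_pref * stats::runif(n_subjects, singular_range[1], singular_range[2])
  # singular speed strictly above preferred speed
  v_sing <- pmax(v_sing, v_pref * (1 + 1e-6))
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    weight = w, height = h,
    preferred_speed = v_pref, singular_speed = v_sing,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ankle_cohort", "data.frame")
  out
}

rnorm_trunc_pos <- function(n, mean, sd, floor = 1e-3) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= floor
  tries <- 0L
  while (any(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= floor
    tries <- tries + 1L
  }
  x[x <= floor] <- floor
  x
}

#' Generative ground truth for one trial
#'
#' Draws the transition moments, per-phase excursions and the implied
#' quasi-stiffnesses and propulsive work for one subject at one speed.
#' The derived quantities obey, by construction,
#' \deqn{K_{df} = M_c/\Gamma_{df},\quad
#'       K_{dl} = (M_d - M_c)/\Gamma_{dl,signed},\quad
#'       K_{pf} = M_d/\Gamma_{pf}}
#' and the work equals the area of the quadrilateral spanned by the
#' phase-transition vertices (see [work_from_fits()]).
#'
#' @param subject one cohort row (or a list with `weight`, `height`,
#'   `singular_speed`, `subject_id`).
#' @param speed gait speed in m/s, positive.
#' @param coeffs a [gen_coeffs()] set.
#' @param seed integer seed.
#' @return A list of class `"ankle_truth"`: `M_c`, `M_d` (N·m),
#'   `Gamma_df`, `Gamma_pf` (rad, positive), `Gamma_dl_signed` (rad),
#'   `K_df`, `K_dl`, `K_pf` (N·m/rad), `E` (J), plus `subject_id` and
#'   `speed`.
#' @export
ground_truth <- function(subject, speed, coeffs = gen_coeffs(), seed = 1L) {
  if (length(speed) != 1L || speed <= 0) stop("`speed` must be a positive scalar")
  set.seed(as.integer(seed))
  W <- subject$weight; H <- subject$height
  v <- speed
  for (attempt in 1:100) {
    eta <- stats::rnorm(2, 0, coeffs$moment_cv)
    M_c <- W * H * (coeffs$a0 + coeffs$a1 * v) * exp(eta[1])
    M_d <- W * H * (coeffs$b0 + coeffs$b1 * v + coeffs$b2 * v^2) * exp(eta[2])
    if (M_d > M_c) break
  }
  if (M_d <= M_c)
    stop("degenerate loop: coefficient set gives M_d <= M_c at speed ", v)
  g_df <- rnorm_trunc_pos(1, coeffs$gamma_df_mean + coeffs$gamma_df_vslope * (v - 1.5),
                          coeffs$gamma_df_sd)
  g_pf <- rnorm_trunc_pos(1, coeffs$gamma_pf_mean + coeffs$gamma_pf_vslope * (v - 1.5),
                          coeffs$gamma_pf_sd)
  # multiplicative noise keeps the zero crossing exactly at the singular speed
  g_dl <- coeffs$s0 * (subject$singular_speed - v) *
    exp(stats::rnorm(1, 0, coeffs$excursion_cv))
  K_df <- M_c / g_df
  K_dl <- (M_d - M_c) / g_dl
  K_pf <- M_d / g_pf
  E <- work_from_fits(M_c, M_d, g_df, g_dl, g_pf)
  structure(list(subject_id = subject$subject_id, speed = v,
                 M_c = M_c, M_d = M_d,
                 Gamma_df = g_df, Gamma_dl_signed = g_dl, Gamma_pf = g_pf,
                 K_df = K_df, K_dl = K_dl, K_pf = K_pf, E = E),
            class = "ankle_truth")
}

#' @export
print.ankle_truth <- function(x, ...) {
  cat(sprintf("Ground truth  %s @ %.2f m/s\n", x$subject_id, x$speed))
  cat(sprintf("  M_c %.1f N.m  M_d %.1f N.m\n", x$M_c, x$M_d))
  cat(sprintf("  Gamma (df/dl/pf): %.3f / %+.4f / %.3f rad\n",
              x$Gamma_df, x$Gamma_dl_signed, x$Gamma_pf))
  cat(sprintf("  K (df/dl/pf): %.0f / %.0f / %.0f N.m/rad   E %.1f J\n",
              x$K_df, x$K_dl, x$K_pf, x$E))
  invisible(x)
}
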