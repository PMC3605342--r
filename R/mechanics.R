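#' Least-squares line fit to one phase segment
#'
#' Ordinary least squares of moment on angle over one phase of the
#' moment-angle loop; the slope is the phase quasi-stiffness.  When the
#' angle excursion vanishes (dual-flexion at the singular gait speed)
#' the regression line is vertical — the joint effectively locks with
#' unbounded quasi-stiffness — so the slope is reported non-finite with
#' a singularity flag rather than as an error.
#'
#' @param segment data frame with `angle` (rad) and `moment` (N·m),
#'   at least 3 rows.
#' @param var_tol angle-variance tolerance (rad²) below which the fit is
#'   flagged singular.
#' @return List: `slope` (N·m/rad), `intercept` (N·m), `r2` in \[0, 1\],
#'   `singular` flag.
#' @export
fit_phase_line <- function(segment, var_tol = 1e-12) {
  if (nrow(segment) < 3) stop("a phase fit needs at least 3 samples")
  x <- segment$angle; y <- segment$moment
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= var_tol)
    return(list(slope = NaN, intercept = NaN, r2 = NaN, singular = TRUE))
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_res <= .Machine$double.eps * ss_tot || ss_tot == 0) 1
        else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = max(0, min(1, r2)),
       singular = FALSE)
}

#' Angular excursion of a phase
#'
#' Final minus initial angle of the segment; independent of the absolute
#' joint angle.
#'
#' @param segment data frame with an `angle` column, at least 2 rows.
#' @return List with `signed` and `magnitude` excursions (rad).
#' @export
excursion <- function(segment) {
  if (nrow(segment) < 2) stop("an excursion needs at least 2 samples")
  signed <- segment$angle[nrow(segment)] - segment$angle[1]
  list(signed = signed, magnitude = abs(signed))
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Propulsive work from the raw moment-angle loop
#'
#' Area enclosed by the moment-angle samples over the progression period
#' b..e, closed by the chord e to b, via the shoelace rule.  For noisy,
#' self-intersecting loops the (absolute) shoelace value is still
#' returned.
#'
#' @param trial a `"gait_trial"`.
#' @param lm a `"phase_landmarks"`.
#' @return Work in J (non-negative).
#' @export
loop_work <- function(trial, lm) {
  s <- trial$samples[lm$idx_b:lm$idx_e, ]
  abs(shoelace(s$angle, s$moment))
}

#' Propulsive work from fitted phase lines
#'
#' Closed form for the area of the quadrilateral spanned by the
#' phase-transition vertices of the idealised piecewise-linear loop:
#' \deqn{E = \tfrac12\,|M_d(\Gamma_{pf} - \Gamma_{dl,signed})
#'               - M_c(\Gamma_{df} + \Gamma_{dl,signed})|}
#' which equals the shoelace area of the vertices \eqn{(0,0)},
#' \eqn{(\Gamma_{df}, M_c)},
#' \eqn{(\Gamma_{df}+\Gamma_{dl,signed}, M_d)},
#' \eqn{(\Gamma_{df}+\Gamma_{dl,signed}-\Gamma_{pf}, 0)}.
#'
#' @param M_c,M_d transition moments, N·m.
#' @param Gamma_df,Gamma_pf phase excursion magnitudes, rad (>= 0).
#' @param Gamma_dl_signed signed dual-flexion excursion, rad.
#' @return Work in J.
#' @export
work_from_fits <- function(M_c, M_d, Gamma_df, Gamma_dl_signed, Gamma_pf) {
  if (any(Gamma_df < 0) || any(Gamma_pf < 0))
    stop("`Gamma_df` and `Gamma_pf` must be non-negative")
  0.5 * abs(M_d * (Gamma_pf - Gamma_dl_signed) -
              M_c * (Gamma_df + Gamma_dl_signed))
}

#' Summarize one trial: quasi-stiffnesses, excursions, fit quality, work
#'
#' Runs landmark location (unless provided), slices the three phases,
#' fits the per-phase regression lines, and computes excursions and
#' propulsive work.  `E_loop` integrates the raw samples (shoelace);
#' `E_fit` is the area of the quadrilateral through the fitted-line
#' moments at the landmark angles (at a shared vertex the two adjacent
#' phase lines are averaged).
#'
#' Trials whose dual-flexion excursion magnitude falls below
#' `singular_tol` are flagged singular (`singular_dl`); their `K_dl` is
#' non-finite and they are excluded from dual-flexion model fitting.
#'
#' @param trial a `"gait_trial"`.
#' @param lm optional precomputed `"phase_landmarks"`.
#' @param c_pct passed to [locate_landmarks()].
#' @param singular_tol dual excursion magnitude (rad) below which the
#'   trial is flagged singular.
#' @return A one-row data frame of class `"joint_summary"` with columns
#'   `subject_id`, `speed`, `K_df`, `K_dl`, `K_pf` (N·m/rad),
#'   `Gamma_df`, `Gamma_dl`, `Gamma_pf` (rad, magnitudes),
#'   `Gamma_dl_signed` (rad), `r2_df`, `r2_dl`, `r2_pf`, `E_loop`,
#'   `E_fit` (J) and `singular_dl`.
#' @export
summarize_trial <- function(trial, lm = NULL, c_pct = 30,
                            singular_tol = 1e-4) {
  if (is.null(lm)) lm <- locate_landmarks(trial, c_pct = c_pct)
  seg <- slice_phases(trial, lm)
  f_df <- fit_phase_line(seg$dorsi)
  f_dl <- fit_phase_line(seg$dual)
  f_pf <- fit_phase_line(seg$plantar)
  e_df <- excursion(seg$dorsi)
  e_dl <- excursion(seg$dual)
  e_pf <- excursion(seg$plantar)

  singular <- f_dl$singular || e_dl$magnitude < singular_tol
  k_dl <- if (singular) NaN else f_dl$slope

  # fitted-line vertex moments; adjacent phase lines averaged at c and d
  s <- trial$samples
  th <- s$angle[c(lm$idx_b, lm$idx_c, lm$idx_d, lm$idx_e)]
  line_at <- function(f, th) f$intercept + f$slope * th
  m_b <- line_at(f_df, th[1])
  m_c <- if (singular) line_at(f_df, th[2])
         else mean(c(line_at(f_df, th[2]), line_at(f_dl, th[2])))
  m_d <- if (singular) line_at(f_pf, th[3])
         else mean(c(line_at(f_dl, th[3]), line_at(f_pf, th[3])))
  m_e <- line_at(f_pf, th[4])
  E_fit <- abs(shoelace(th, c(m_b, m_c, m_d, m_e)))

  out <- data.frame(
    subject_id = trial$subject_id, speed = trial$speed,
    K_df = f_df$slope, K_dl = k_dl, K_pf = f_pf$slope,
    Gamma_df = e_df$magnitude, Gamma_dl = e_dl$magnitude,
    Gamma_pf = e_pf$magnitude, Gamma_dl_signed = e_dl$signed,
    r2_df = f_df$r2, r2_dl = f_dl$r2, r2_pf = f_pf$r2,
    E_loop = loop_work(trial, lm), E_fit = E_fit,
    singular_dl = singular,
    stringsAsFactors = FALSE
  )
  class(out) <- c("joint_summary", "data.frame")
  out
}

#' Summarize every trial of a dataset
#'
#' @param trials list of `"gait_trial"` objects.
#' @param c_pct,singular_tol passed to [summarize_trial()].
#' @return A `"joint_summary"` data frame with one row per trial.
#' @export
summarize_dataset <- function(trials, c_pct = 30, singular_tol = 1e-4) {
  rows <- lapply(trials, summarize_trial, c_pct = c_pct,
                 singular_tol = singular_tol)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("joint_summary", "data.frame")
  out
}
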