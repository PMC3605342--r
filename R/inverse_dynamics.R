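#' Foot segment state for the ankle-moment balance
#'
#' Snapshot of the mechanical state of the support foot in a lab frame
#' with X anterior, Y up and Z mediolateral (the sagittal plane is X-Y
#' and sagittal moments act about Z).
#'
#' @param F_G ground reaction force, 3-vector N.
#' @param M_G ground reaction moment, 3-vector N·m.
#' @param cop centre of pressure position, 3-vector m.
#' @param ankle ankle joint centre position, 3-vector m.
#' @param com foot centre of mass position, 3-vector m.
#' @param foot_mass foot mass, kg (>= 0).
#' @param inertia 3x3 inertia tensor about the foot COM, kg·m²,
#'   symmetric positive semi-definite.
#' @param omega foot angular velocity, rad/s.
#' @param alpha foot angular acceleration, rad/s².
#' @param acc_com linear acceleration of the foot COM, m/s².
#' @param g gravitational acceleration, m/s².
#' @return A list of class `"foot_state"`.
#' @export
foot_state <- function(F_G = c(0, 0, 0), M_G = c(0, 0, 0),
                       cop = c(0, 0, 0), ankle = c(0, 0, 0),
                       com = c(0, 0, 0), foot_mass = 0,
                       inertia = diag(0, 3), omega = c(0, 0, 0),
                       alpha = c(0, 0, 0), acc_com = c(0, 0, 0),
                       g = 9.81) {
  v3 <- function(x, nm) {
    if (length(x) != 3 || !is.numeric(x)) stop("`", nm, "` must be a numeric 3-vector")
    as.numeric(x)
  }
  inertia <- as.matrix(inertia)
  if (!all(dim(inertia) == c(3, 3))) stop("`inertia` must be 3x3")
  if (max(abs(inertia - t(inertia))) > 1e-9 * (1 + max(abs(inertia))))
    stop("`inertia` must be symmetric")
  if (min(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values) < -1e-9)
    stop("`inertia` must be positive semi-definite")
  if (foot_mass < 0) stop("`foot_mass` must be non-negative")
  structure(list(F_G = v3(F_G, "F_G"), M_G = v3(M_G, "M_G"),
                 cop = v3(cop, "cop"), ankle = v3(ankle, "ankle"),
                 com = v3(com, "com"), foot_mass = foot_mass,
                 inertia = inertia, omega = v3(omega, "omega"),
                 alpha = v3(alpha, "alpha"), acc_com = v3(acc_com, "acc_com"),
                 g = g),
            class = "foot_state")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Full Newton-Euler ankle moment of the foot segment
#'
#' Single-segment moment balance about the ankle:
#' \deqn{M_A = I\alpha + \omega \times (I\omega)
#'   - r_{GA} \times F_G - M_G
#'   - r_{CA} \times (m\,g) + r_{CA} \times (m\,a_{com})}
#' where \eqn{r_{GA}} is the ankle-to-COP lever and \eqn{r_{CA}} the
#' ankle-to-COM lever.  With foot mass, inertia, angular terms and the
#' ground reaction moment all zero this reduces exactly to
#' \eqn{-r_{GA} \times F_G}.
#'
#' @param state a [foot_state()].
#' @return Ankle moment 3-vector, N·m (lab frame; the sagittal
#'   extensor-positive scalar is `-`z-component, see
#'   [foot_moment_sagittal()]).
#' @export
foot_moment_full <- function(state) {
  s <- state
  r_GA <- s$cop - s$ankle
  r_CA <- s$com - s$ankle
  g_vec <- c(0, -s$g, 0)
  drop(s$inertia %*% s$alpha) + cross3(s$omega, drop(s$inertia %*% s$omega)) -
    cross3(r_GA, s$F_G) - s$M_G -
    cross3(r_CA, s$foot_mass * g_vec) + cross3(r_CA, s$foot_mass * s$acc_com)
}

#' Simplified sagittal ankle moment
#'
#' The reduced phase-transition expression: the extensor-positive
#' z-component of \eqn{-(cop - ankle) \times F_G}, i.e. the moment due
#' to the ground reaction force alone, neglecting foot weight, inertial
#' terms and the ground reaction moment.
#'
#' @param state a [foot_state()].
#' @return Scalar sagittal ankle moment, N·m, extensor (plantar-flexor)
#'   positive.
#' @export
foot_moment_sagittal <- function(state) {
  r_GA <- state$cop - state$ankle
  m <- -cross3(r_GA, state$F_G)
  -m[3]
}

#' Audit the simplification gap
#'
#' Difference between the full Newton-Euler sagittal moment and the
#' simplified GRF-only expression, i.e. the collected size of the
#' neglected terms at this state.
#'
#' @param state a [foot_state()].
#' @return List with `eps_z` (N·m, extensor-positive difference),
#'   `relative_gap` (`|eps_z|` over the full moment magnitude; `NA` with
#'   `degenerate = TRUE` when the full sagittal moment is zero).
#' @export
assumption_gap <- function(state) {
  full <- -foot_moment_full(state)[3]
  simp <- foot_moment_sagittal(state)
  eps <- full - simp
  if (full == 0) {
    list(eps_z = eps, relative_gap = NA_real_, degenerate = TRUE)
  } else {
    list(eps_z = eps, relative_gap = abs(eps) / abs(full), degenerate = FALSE)
  }
}

#' Serialize / restore a foot state as JSON
#'
#' @param state a [foot_state()].
#' @param path file path; with `NULL`, [foot_state_to_json()] returns the
#'   JSON string.
#' @return [foot_state_to_json()]: the path (or JSON string) invisibly;
#'   [foot_state_from_json()]: a `"foot_state"`.
#' @export
foot_state_to_json <- function(state, path = NULL) {
  x <- unclass(state)
  x$inertia <- as.vector(x$inertia)  # column-major length 9
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname foot_state_to_json
#' @param json JSON string (alternative to `path`).
#' @export
foot_state_from_json <- function(path = NULL, json = NULL) {
  if (is.null(json)) json <- paste(readLines(path, warn = FALSE), collapse = "")
  x <- jsonlite::fromJSON(json)
  foot_state(F_G = x$F_G, M_G = x$M_G, cop = x$cop, ankle = x$ankle,
             com = x$com, foot_mass = x$foot_mass,
             inertia = matrix(x$inertia, 3, 3), omega = x$omega,
             alpha = x$alpha, acc_com = x$acc_com, g = x$g)
}
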