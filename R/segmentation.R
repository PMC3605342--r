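#' Locate the stance-phase landmarks b, c, d, e
#'
#' Landmark rules on the stance-phase moment-angle record:
#' * **b** — first local minimum of the (smoothed) angle after the
#'   heel-strike prefix: onset of the dorsi-flexion phase.
#' * **c** — the sample nearest `c_pct` percent of the gait cycle:
#'   dorsi- to dual-flexion transition.
#' * **e** — minimum of the (smoothed) angle after c: toe-off end of the
#'   plantar-flexion (push-off) phase.
#' * **d** — the moment maximum (dual- to plantar-flexion transition),
#'   located as the two-segment least-squares changepoint of the moment
#'   over c..e, which coincides with the argmax on noiseless data but is
#'   far more robust to moment noise on the shallow dual-phase side.
#'
#' Smoothing (centred moving average, `smooth_window` samples) is used
#' for landmark *detection only*; downstream fits always use the raw
#' samples.
#'
#' @param trial a `"gait_trial"`.
#' @param c_pct percent of the gait cycle assigned to point c.
#' @param search_after_pct ignore samples before this percent when
#'   looking for b (skips heel-strike transients).
#' @param smooth_window odd moving-average window for detection.
#' @return A list of class `"phase_landmarks"` with integer sample
#'   indices `idx_b < idx_c < idx_d < idx_e`.
#' @export
locate_landmarks <- function(trial, c_pct = 30, search_after_pct = 3,
                             smooth_window = 5) {
  s <- trial$samples
  n <- nrow(s)
  if (max(s$gait_pct) < c_pct)
    stop("trial does not cover c_pct = ", c_pct, "% of the gait cycle")
  ang <- smooth_ma(s$angle, smooth_window)
  mom <- smooth_ma(s$moment, smooth_window)

  half <- max(1L, (smooth_window - 1L) %/% 2L)
  # smoothing can skew a kink extremum when the flanking slopes differ, so
  # each smoothed-detected landmark is refined to the raw extremum nearby
  refine <- function(i, x, fun, lo = 1L, hi = n) {
    win <- max(lo, i - half):min(hi, i + half)
    win[fun(x[win])]
  }
  from <- which(s$gait_pct > search_after_pct)[1]
  idx_c <- which.min(abs(s$gait_pct - c_pct))
  cand <- seq(max(from, 2L), n - 1L)
  is_min <- ang[cand] <= ang[cand - 1L] & ang[cand] <= ang[cand + 1L]
  cand <- cand[is_min]
  cand <- cand[cand < idx_c]
  if (!length(cand))
    stop("landmark error: no local angle minimum before c_pct = ", c_pct, "%")
  idx_b <- refine(cand[1], s$angle, which.min, hi = idx_c - 1L)

  # e: minimum angle after c (the global post-c minimum is the toe-off
  # vertex; the dual phase never descends below it)
  idx_e <- refine(idx_c + which.min(ang[(idx_c + 1L):n]), s$angle,
                  which.min, lo = idx_c + 1L)
  # d: the moment maximum.  Under noise the raw argmax wanders along the
  # shallow dual-phase side, so d is located as the least-squares
  # two-segment changepoint of the moment over c..e (exact at the kink
  # for noiseless data, where it coincides with the argmax).
  idx_d <- if (idx_e - idx_c >= 5L) kink_split(s$moment, idx_c, idx_e)
           else refine(idx_c + which.max(mom[(idx_c + 1L):n]), s$moment,
                       which.max, lo = idx_c + 1L)

  lm <- list(idx_b = idx_b, idx_c = idx_c, idx_d = idx_d, idx_e = idx_e)
  ord <- unlist(lm)
  if (any(diff(ord) <= 0)) {
    bad <- which(diff(ord) <= 0)[1]
    nms <- names(ord)
    stop("segmentation error: landmark ordering violated between ",
         nms[bad], " and ", nms[bad + 1L])
  }
  structure(lm, class = "phase_landmarks")
}

kink_split <- function(y, lo, hi) {
  w <- lo:hi
  cand <- (lo + 2L):(hi - 2L)
  f <- function(ix) {
    if (length(ix) < 3L) return(0)
    sum(stats::lm.fit(cbind(1, ix), y[ix])$residuals^2)
  }
  sse <- vapply(cand, function(k) f(w[w <= k]) + f(w[w >= k]), 1)
  cand[which.min(sse)]
}

smooth_ma <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + length(x))]
}

#' Slice a trial into its three progression phases
#'
#' Dorsi-flexion is b..c, dual-flexion c..d and plantar-flexion d..e,
#' with shared endpoint samples, partitioning the progression period.
#'
#' @param trial a `"gait_trial"`.
#' @param lm a `"phase_landmarks"`.
#' @return Named list `dorsi`, `dual`, `plantar` of sample data frames
#'   (columns `gait_pct`, `angle`, `moment`), each with at least 3 rows.
#' @export
slice_phases <- function(trial, lm) {
  s <- trial$samples
  seg <- list(dorsi = s[lm$idx_b:lm$idx_c, , drop = FALSE],
              dual = s[lm$idx_c:lm$idx_d, , drop = FALSE],
              plantar = s[lm$idx_d:lm$idx_e, , drop = FALSE])
  short <- vapply(seg, nrow, 1L) < 3L
  if (any(short))
    stop("insufficient resolution: phase(s) ",
         paste(names(seg)[short], collapse = ", "), " have fewer than 3 samples")
  seg
}
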