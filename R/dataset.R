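#' Write a dataset to disk
#'
#' One CSV per trial (columns `gait_pct,angle_rad,moment_Nm`, file name
#' `<subject>_<speed>.csv` with the speed in m/s to three decimals),
#' plus `cohort.json` and, when ground truths are supplied,
#' `ground_truth.json`.  Values round-trip through [read_trials()] to
#' better than 1e-9.
#'
#' @param cohort an `"ankle_cohort"` (may have zero rows).
#' @param trials list of `"gait_trial"`s.
#' @param out_path output directory (created if needed).
#' @param truths optional list of `"ankle_truth"`s parallel to `trials`.
#' @return Invisibly, the vector of files written.
#' @export
emit_dataset <- function(cohort, trials, out_path, truths = NULL) {
  dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_path)) stop("cannot create output path: ", out_path)
  files <- character(0)
  cj <- file.path(out_path, "cohort.json")
  cohort_rec <- data.frame(subject_id = cohort$subject_id,
                           weight_kg = cohort$weight,
                           height_m = cohort$height)
  jsonlite::write_json(cohort_rec, cj, digits = NA, dataframe = "rows")
  files <- c(files, cj)
  for (tr in trials) {
    fn <- file.path(out_path,
                    sprintf("%s_%.3f.csv", tr$subject_id, tr$speed))
    df <- data.frame(gait_pct = tr$samples$gait_pct,
                     angle_rad = tr$samples$angle,
                     moment_Nm = tr$samples$moment)
    utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     fn, row.names = FALSE, quote = FALSE)
    files <- c(files, fn)
  }
  if (!is.null(truths)) {
    tj <- file.path(out_path, "ground_truth.json")
    rec <- do.call(rbind, lapply(truths, function(x)
      data.frame(subject_id = x$subject_id, speed = x$speed,
                 M_c = x$M_c, M_d = x$M_d,
                 Gamma_df = x$Gamma_df, Gamma_dl_signed = x$Gamma_dl_signed,
                 Gamma_pf = x$Gamma_pf, K_df = x$K_df, K_dl = x$K_dl,
                 K_pf = x$K_pf, E = x$E)))
    jsonlite::write_json(rec, tj, digits = NA, dataframe = "rows")
    files <- c(files, tj)
  }
  invisible(files)
}

#' Read a dataset from disk
#'
#' Reads `cohort.json` and every `<subject>_<speed>.csv` trial file in
#' the directory, validating the schema, strict `gait_pct`
#' monotonicity (reported with the offending line) and subject ids.
#'
#' @param path dataset directory.
#' @return List with `cohort` (an `"ankle_cohort"`, derived speeds
#'   recomputed) and `trials` (list of `"gait_trial"`s).
#' @export
read_trials <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  cj <- file.path(path, "cohort.json")
  if (!file.exists(cj)) stop("missing cohort.json in ", path)
  crec <- jsonlite::fromJSON(cj)
  if (length(crec) == 0 || is.null(nrow(crec)) || nrow(crec) == 0) {
    cohort <- data.frame(subject_id = character(0), weight = numeric(0),
                         height = numeric(0), preferred_speed = numeric(0),
                         singular_speed = numeric(0))
  } else {
    need <- c("subject_id", "weight_kg", "height_m")
    if (!all(need %in% names(crec)))
      stop("cohort.json must have fields ", paste(need, collapse = ", "))
    cohort <- data.frame(subject_id = crec$subject_id,
                         weight = crec$weight_kg, height = crec$height_m,
                         preferred_speed = optimal_speed(crec$height_m),
                         singular_speed = NA_real_,
                         stringsAsFactors = FALSE)
  }
  class(cohort) <- c("ankle_cohort", "data.frame")

  fns <- sort(list.files(path, pattern = "^.+_[0-9.]+\\.csv$"))
  if (!length(fns)) warning("no trial files found in ", path)
  trials <- lapply(fns, function(fn) {
    m <- regmatches(fn, regexec("^(.+)_([0-9.]+)\\.csv$", fn))[[1]]
    sid <- m[2]; speed <- as.numeric(m[3])
    if (nrow(cohort) && !(sid %in% cohort$subject_id))
      stop("parse error in ", fn, ": unknown subject id '", sid, "'")
    df <- utils::read.csv(file.path(path, fn))
    need <- c("gait_pct", "angle_rad", "moment_Nm")
    if (!all(need %in% names(df)))
      stop("parse error in ", fn, ": missing column(s) ",
           paste(setdiff(need, names(df)), collapse = ", "))
    bad <- which(diff(df$gait_pct) <= 0)
    if (length(bad))
      stop("parse error in ", fn, ": gait_pct not strictly increasing at line ",
           bad[1] + 2L)  # +1 for header, +1 for the second row of the pair
    gait_trial(sid, speed,
               data.frame(gait_pct = df$gait_pct, angle = df$angle_rad,
                          moment = df$moment_Nm))
  })
  list(cohort = cohort, trials = trials)
}
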