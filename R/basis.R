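#' Define one predictor-basis term
#'
#' A term is a monomial in body and gait parameters:
#' \eqn{W^{w} H^{h} V^{v} \Gamma_{df}^{g_{df}} \Gamma_{dl}^{g_{dl}}
#'      \Gamma_{pf}^{g_{pf}}}.
#' Excursion exponents are typically -1 (quasi-stiffness bases, where
#' the transition moment is divided by the phase excursion) or +1 (work
#' basis).  The dual-flexion excursion enters **signed**, so that the
#' dual-flexion quasi-stiffness sign flip at the singular speed is
#' representable.
#'
#' @param name unique term label.
#' @param w,h,v,g_df,g_dl,g_pf exponents of weight, height, speed and
#'   the three phase excursions.
#' @return A list of class `"basis_term"`.
#' @export
basis_term <- function(name, w = 0, h = 0, v = 0,
                       g_df = 0, g_dl = 0, g_pf = 0) {
  structure(list(name = name, w = w, h = h, v = v,
                 g_df = g_df, g_dl = g_dl, g_pf = g_pf),
            class = "basis_term")
}

#' Predictor basis specification for one response
#'
#' @param response one of `"K_df"`, `"K_dl"`, `"K_pf"`, `"E"`.
#' @param terms list of [basis_term()]s with unique names.
#' @param include_intercept add an intercept column.
#' @return A list of class `"basis_spec"`.
#' @export
basis_spec <- function(response, terms, include_intercept = TRUE) {
  response <- match.arg(response, c("K_df", "K_dl", "K_pf", "E"))
  nms <- vapply(terms, function(t) t$name, "")
  if (anyDuplicated(nms)) stop("term names must be unique")
  structure(list(response = response, terms = terms,
                 include_intercept = include_intercept),
            class = "basis_spec")
}

#' Default reconstructed bases for the four responses
#'
#' Quasi-stiffness bases follow from the transition-moment polynomials
#' divided by the phase excursion, plus the undivided polynomial
#' terms and (dual/plantar) a bare speed term; the work basis is the
#' 9-term family \eqn{W H \Gamma_x V^k} (x in df, dl, pf; k = 0, 1, 2)
#' without intercept.
#'
#' @return Named list of four [basis_spec()]s.
#' @export
default_basis_specs <- function() {
  t_k <- function(gname) {
    function(name, v, over) {
      args <- list(name = name, w = 1, h = 1, v = v)
      if (over) args[[gname]] <- -1
      do.call(basis_term, args)
    }
  }
  mk_df <- t_k("g_df")
  mk_dl <- t_k("g_dl")
  mk_pf <- t_k("g_pf")
  list(
    K_df = basis_spec("K_df", list(
      mk_df("WH/G_df", 0, TRUE), mk_df("WH.V/G_df", 1, TRUE),
      mk_df("WH", 0, FALSE), mk_df("WH.V", 1, FALSE)
    ), include_intercept = TRUE),
    K_dl = basis_spec("K_dl", list(
      mk_dl("WH/G_dl", 0, TRUE), mk_dl("WH.V/G_dl", 1, TRUE),
      mk_dl("WH.V2/G_dl", 2, TRUE),
      mk_dl("WH", 0, FALSE), mk_dl("WH.V", 1, FALSE),
      mk_dl("WH.V2", 2, FALSE), basis_term("V", v = 1)
    ), include_intercept = TRUE),
    K_pf = basis_spec("K_pf", list(
      mk_pf("WH/G_pf", 0, TRUE), mk_pf("WH.V/G_pf", 1, TRUE),
      mk_pf("WH.V2/G_pf", 2, TRUE),
      mk_pf("WH", 0, FALSE), mk_pf("WH.V", 1, FALSE),
      mk_pf("WH.V2", 2, FALSE), basis_term("V", v = 1)
    ), include_intercept = TRUE),
    E = basis_spec("E", local({
      terms <- list()
      for (gx in c("g_df", "g_dl", "g_pf")) {
        lab <- sub("g_", "G_", gx)
        for (k in 0:2) {
          nm <- if (k == 0) sprintf("WH.%s", lab) else sprintf("WH.%s.V%d", lab, k)
          args <- list(name = nm, w = 1, h = 1, v = k)
          args[[gx]] <- 1
          terms[[length(terms) + 1L]] <- do.call(basis_term, args)
        }
      }
      terms
    }), include_intercept = FALSE)
  )
}

eval_terms <- function(terms, data) {
  # data: data.frame with W, H, V, G_df, G_dl (signed), G_pf
  X <- vapply(terms, function(t) {
    data$W^t$w * data$H^t$h * data$V^t$v *
      data$G_df^t$g_df * data$G_dl^t$g_dl * data$G_pf^t$g_pf
  }, numeric(nrow(data)))
  if (nrow(data) == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- vapply(terms, function(t) t$name, "")
  X
}

#' Build a design matrix and response vector for one basis
#'
#' Joins trial summaries with cohort stature, evaluates each basis term,
#' and drops rows where a required excursion denominator is (near) zero
#' or — for the dual-flexion response — the trial is singularity
#' flagged.  The dual-flexion excursion enters signed.
#'
#' @param summaries a `"joint_summary"` data frame.
#' @param cohort an `"ankle_cohort"` (needs `subject_id`, `weight`,
#'   `height`).
#' @param spec a [basis_spec()].
#' @param zero_tol excursion magnitude below which a division by it
#'   drops the row.
#' @return List: `X` (design matrix, intercept column first when
#'   requested), `y` (response), `groups` (subject ids), `rows` (row
#'   indices into `summaries`), `dropped` (data frame of dropped rows
#'   and reasons).
#' @export
build_basis <- function(summaries, cohort, spec, zero_tol = 1e-4) {
  if (nrow(summaries) == 0L) {
    return(list(X = matrix(numeric(0), 0, length(spec$terms) +
                             spec$include_intercept),
                y = numeric(0), groups = character(0),
                rows = integer(0),
                dropped = data.frame(row = integer(0), reason = character(0))))
  }
  miss <- setdiff(unique(summaries$subject_id), cohort$subject_id)
  if (length(miss))
    stop("subjects missing from cohort: ", paste(miss, collapse = ", "))
  idx <- match(summaries$subject_id, cohort$subject_id)
  data <- data.frame(W = cohort$weight[idx], H = cohort$height[idx],
                     V = summaries$speed,
                     G_df = summaries$Gamma_df,
                     G_dl = summaries$Gamma_dl_signed,
                     G_pf = summaries$Gamma_pf)

  keep <- rep(TRUE, nrow(summaries))
  reason <- rep(NA_character_, nrow(summaries))
  if (spec$response == "K_dl" && "singular_dl" %in% names(summaries)) {
    sing <- summaries$singular_dl
    reason[keep & sing] <- "singular dual-flexion trial"
    keep <- keep & !sing
  }
  for (t in spec$terms) {
    for (gn in c("g_df", "g_dl", "g_pf")) {
      if (t[[gn]] < 0) {
        col <- sub("g_", "G_", gn)
        near0 <- abs(data[[col]]) < zero_tol
        reason[keep & near0] <- paste0("near-zero ", col, " in term ", t$name)
        keep <- keep & !near0
      }
    }
  }
  y <- switch(spec$response,
              K_df = summaries$K_df, K_dl = summaries$K_dl,
              K_pf = summaries$K_pf, E = summaries$E_loop)
  bad <- !is.finite(y)
  reason[keep & bad] <- "non-finite response"
  keep <- keep & !bad

  X <- eval_terms(spec$terms, data[keep, , drop = FALSE])
  if (spec$include_intercept)
    X <- cbind(`(Intercept)` = rep(1, sum(keep)), X)
  dropped <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped)) {
    message("build_basis(", spec$response, "): dropped ", nrow(dropped),
            " row(s): ", paste(unique(dropped$reason), collapse = "; "))
  }
  list(X = X, y = y[keep], groups = summaries$subject_id[keep],
       rows = which(keep), dropped = dropped)
}
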