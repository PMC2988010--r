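#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates `G(t) = P(C > t)` by reversing the roles of events and
#' censorings: censoring is the "event" and all true failures are treated
#' as censored observations of the censoring time. At tied times the
#' failure-first convention applies, so subjects failing at `t` remain in
#' the censoring risk set there. `G` is estimated unconditionally on the
#' whole cohort (no covariate adjustment), matching the assumption that
#' censoring is independent of disease progression.
#'
#' @param x a `cr_cohort`.
#' @return A [cr_stepfun()] for `G(t)`.
#' @export
censoring_km <- function(x) {
  suppressWarnings(kaplan_meier(x$time, x$event == 0))
}

#' Fine-Gray risk-set expansion with IPCW weights
#'
#' Builds the counting-process rows of the proportional
#' subdistribution-hazards model for a target cause k. Subjects censored
#' or failing from cause k contribute a single `(0, T_i]` row with their
#' status and weight 1. A subject failing from a competing cause at `T_i`
#' stays in the risk set afterwards: their `(0, T_i]` row has status 0,
#' and follow-on rows — one per target-cause event time in
#' `(T_i, t_max]` — keep them at risk with the
#' inverse-probability-of-censoring weight `w_i(t) = G(t-) / G(T_i-)`,
#' where `G` is [censoring_km()]. With no censoring all weights are 1 and
#' the construction is equivalent to recoding competing events as censored
#' beyond the last observed time.
#'
#' @param x a `cr_cohort`.
#' @param cause target cause in `1..K`.
#' @param X optional design matrix from [encode()] (row order = cohort
#'   order); omit for a null model.
#' @return A [cp_rows()] object; `subject` keys rows back to cohort ids.
#' @export
expand_fg_rows <- function(x, cause, X = NULL) {
  K <- n_causes(x)
  if (!(cause %in% seq_len(K))) stop("cause must be in 1..", K)
  if (sum(x$event == cause) == 0)
    stop("expand_fg_rows: no events of cause ", cause)
  n <- nrow(x)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  G <- censoring_km(x)
  te <- sort(unique(x$time[x$event == cause]))     # target-cause event times
  comp <- which(x$event != 0 & x$event != cause)

  start <- rep(0, n)
  stopt <- x$time
  status <- as.integer(x$event == cause)
  weight <- rep(1, n)
  subj <- x$id
  ridx <- seq_len(n)

  if (length(comp) && length(te)) {
    pos <- findInterval(x$time[comp], te)          # #{te <= T_i}
    cnt <- length(te) - pos
    keep <- cnt > 0
    if (any(keep)) {
      comp <- comp[keep]; pos <- pos[keep]; cnt <- cnt[keep]
      jidx <- sequence(cnt) + rep(pos, cnt)
      rep_i <- rep(comp, cnt)
      Gleft_te <- sf_left(G, te)
      Gleft_T <- sf_left(G, x$time)
      w <- Gleft_te[jidx] / Gleft_T[rep_i]
      first <- jidx == rep(pos, cnt) + 1L
      st <- ifelse(first, x$time[rep_i], c(NA_real_, te)[jidx])
      bad <- !is.finite(w)
      if (any(bad)) {
        warning("expand_fg_rows: dropped ", sum(bad),
                " follow-on row(s) with undefined IPCW weight (G = 0)")
        st <- st[!bad]; w <- w[!bad]; rep_i <- rep_i[!bad]
        jidx <- jidx[!bad]
      }
      start <- c(start, st)
      stopt <- c(stopt, te[jidx])
      status <- c(status, integer(length(jidx)))
      weight <- c(weight, w)
      subj <- c(subj, x$id[rep_i])
      ridx <- c(ridx, rep_i)
    }
  }
  cp_rows(stop = stopt, status = status, x = X[ridx, , drop = FALSE],
          start = start, weight = weight, subject = subj)
}

#' Fit the Fine-Gray proportional subdistribution-hazards model
#'
#' Weighted Cox fit (Breslow ties) on the expanded rows of
#' [expand_fg_rows()]. The covariance is the robust sandwich clustered on
#' subject — the model-based variance is not valid under IPCW weighting.
#' The baseline subdistribution cumulative hazard comes from the weighted
#' Breslow estimator.
#'
#' @param x a `cr_cohort`.
#' @param cause target cause.
#' @param covariates covariate names (may be empty for a null model).
#' @return An object of class `fg_fit`: `cause`, `cox` (`cox_fit`),
#'   `baseline` ([cr_stepfun()] for `Lambda*_0k`), `censoring_km`,
#'   `weight_scheme`, `covariates`, `schema`.
#' @export
fit_fine_gray <- function(x, cause, covariates = character(0)) {
  X <- encode(x, covariates)
  rows <- expand_fg_rows(x, cause, X)
  fit <- fit_cox(rows, ties = "breslow", robust = ncol(X) > 0)
  structure(list(cause = cause, cox = fit,
                 baseline = breslow_baseline(fit, rows)[[1]],
                 censoring_km = censoring_km(x),
                 weight_scheme = "ipcw: G(t-)/G(min(T,t)-), unconditional G",
                 covariates = covariates, schema = cohort_schema(x)),
            class = "fg_fit")
}

#' @export
print.fg_fit <- function(x, ...) {
  cat(sprintf("<fg_fit> cause %d, %s\n", x$cause, x$weight_scheme))
  if (length(x$cox$beta)) print(hazard_ratio_table(x$cox))
  invisible(x)
}

#' CIF prediction on the subdistribution scale
#'
#' `I_k(t; z) = 1 - exp(-Lambda*_0k(t) exp(beta' z))`: under the Fine-Gray
#' model covariates act directly on the cumulative incidence of the target
#' cause.
#'
#' @param fit an `fg_fit`.
#' @param profile named list of raw covariate values.
#' @param grid optional evaluation times (step semantics, as in
#'   [predict_cif_cs()]).
#' @return A [cr_stepfun()], non-decreasing and in `[0, 1)`.
#' @export
predict_cif_fg <- function(fit, profile = list(), grid = NULL) {
  if (!fit$cox$converged)
    warning("predict_cif_fg: underlying fit did not converge")
  zv <- encode_profile(fit$schema, fit$covariates, profile)
  lp <- if (length(zv)) sum(fit$cox$beta * zv) else 0
  cif <- 1 - exp(-fit$baseline$values * exp(lp))
  sf <- cr_stepfun(fit$baseline$times, cif, 0)
  if (!is.null(grid)) {
    grid <- sort(unique(as.numeric(grid)))
    sf <- cr_stepfun(grid, sf_at(sf, grid), 0)
  }
  sf
}
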