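#' Kaplan-Meier product-limit estimator
#'
#' Standard product-limit estimate of the survival function with Greenwood
#' standard errors. Tied events at one time are processed together;
#' censorings tied with an event time leave the risk set after the event
#' (the usual convention), so a subject censored at an event time is still
#' counted at risk there.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return A [cr_stepfun()] for `S(t)` with extra fields `n_risk`,
#'   `n_event` and `se` (Greenwood).
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(!is.finite(times) | times <= 0)) stop("times must be positive")
  events <- as.integer(events != 0)
  if (!any(events == 1)) {
    warning("no events: survival curve is constant at 1")
    return(cr_stepfun(numeric(0), numeric(0), 1,
                      extra = list(n_risk = numeric(0), n_event = numeric(0),
                                   se = numeric(0))))
  }
  tj <- sort(unique(times[events == 1]))
  nj <- vapply(tj, function(t) sum(times >= t), numeric(1))
  dj <- vapply(tj, function(t) sum(times == t & events == 1), numeric(1))
  s <- cumprod(1 - dj / nj)
  gw <- cumsum(dj / (nj * (nj - dj)))
  se <- s * sqrt(ifelse(is.finite(gw), gw, NA))
  cr_stepfun(tj, s, 1, extra = list(n_risk = nj, n_event = dj, se = se))
}

#' Naive per-cause 1 - KM curve
#'
#' Treats every competing cause as censoring and returns `1 - S_KM`. This
#' estimator overstates the probability of the target event whenever
#' competing events occur, and is provided purposely for bias
#' demonstrations; outputs are labelled "naive".
#'
#' @param x a `cr_cohort`.
#' @param cause target cause in `1..K`.
#' @return A [cr_stepfun()] (starts at 0, non-decreasing) with attribute
#'   `method = "naive"`.
#' @export
naive_one_minus_km <- function(x, cause) {
  K <- n_causes(x)
  if (!(cause %in% seq_len(K))) stop("cause must be in 1..", K)
  km <- kaplan_meier(x$time, x$event == cause)
  out <- cr_stepfun(km$times, 1 - km$values, 0,
                    extra = list(se = km$se, n_risk = km$n_risk,
                                 n_event = km$n_event))
  attr(out, "method") <- "naive"
  out
}

#' Aalen-Johansen cumulative incidence estimator
#'
#' Nonparametric plug-in estimate of the per-cause cumulative incidence
#' functions `I_k(t) = P(T <= t, D = k)`: at each event time the cause-k
#' increment is `S(t-) d_k / n`, with `S` the all-cause product-limit
#' survival. Because the same `S` and risk sets are shared across causes,
#' the conservation identity `sum_k I_k(t) + S(t) = 1` holds exactly at
#' every event time.
#'
#' Variances use the standard delta-method (counting-process) estimator.
#'
#' @param x a `cr_cohort`.
#' @return A list of class `cif_estimate`: `per_cause` (list of
#'   [cr_stepfun()]s indexed by cause), `overall_survival`, `at_risk`
#'   (risk-set size at each event time), `event_times`.
#' @export
aalen_johansen <- function(x) {
  if (nrow(x) == 0) stop("empty cohort")
  K <- n_causes(x)
  tj <- sort(unique(x$time[x$event > 0]))
  nj <- vapply(tj, function(t) sum(x$time >= t), numeric(1))
  dkj <- vapply(seq_len(K), function(k)
    vapply(tj, function(t) sum(x$time == t & x$event == k), numeric(1)),
    numeric(length(tj)))
  dkj <- matrix(dkj, nrow = length(tj), ncol = K)
  dj <- rowSums(dkj)
  s <- cumprod(1 - dj / nj)                       # S(t_j)
  s_left <- c(1, s[-length(s)])                   # S(t_j -)
  per_cause <- vector("list", K)
  for (k in seq_len(K)) {
    inc <- s_left * dkj[, k] / nj
    cif <- cumsum(inc)
    se <- aj_variance(tj, nj, dj, dkj[, k], s_left, cif)
    per_cause[[k]] <- cr_stepfun(tj, cif, 0, extra = list(se = se))
  }
  structure(list(per_cause = per_cause,
                 overall_survival = cr_stepfun(tj, s, 1),
                 at_risk = nj, event_times = tj),
            class = "cif_estimate")
}

# Delta-method variance of the Aalen-Johansen CIF (Marubini-Valsecchi form).
aj_variance <- function(tj, nj, dj, dk, s_left, cif) {
  m <- length(tj)
  if (m == 0) return(numeric(0))
  a <- ifelse(nj > dj, dj / (nj * (nj - dj)), NA)      # Greenwood increments
  b <- s_left * dk / nj^2
  cvec <- s_left^2 * dk * (nj - dk) / nj^3
  v <- numeric(m)
  for (j in seq_len(m)) {
    diff <- cif[j] - cif[seq_len(j)]
    v[j] <- sum(diff^2 * a[seq_len(j)], na.rm = TRUE) +
      sum(cvec[seq_len(j)]) - 2 * sum(diff * b[seq_len(j)])
  }
  sqrt(pmax(v, 0))
}

#' @export
print.cif_estimate <- function(x, ...) {
  K <- length(x$per_cause)
  cat(sprintf("<cif_estimate> %d cause(s), %d event times\n", K,
              length(x$event_times)))
  for (k in seq_len(K)) {
    sf <- x$per_cause[[k]]
    fin <- if (length(sf$values)) sf$values[length(sf$values)] else 0
    cat(sprintf("  cause %d: CIF at last event time %.4f\n", k, fin))
  }
  invisible(x)
}

#' Tidy curve export
#'
#' @param x a `cif_estimate`.
#' @return data.frame (`time`, `cause`, `estimate`, `se`) with cause 0 used
#'   for overall survival.
#' @export
cif_as_table <- function(x) {
  out <- list()
  for (k in seq_along(x$per_cause)) {
    sf <- x$per_cause[[k]]
    out[[k]] <- data.frame(time = sf$times, cause = k, estimate = sf$values,
                           se = if (length(sf$se)) sf$se else NA)
  }
  sv <- x$overall_survival
  out[[length(out) + 1L]] <- data.frame(time = sv$times, cause = 0,
                                        estimate = sv$values, se = NA)
  do.call(rbind, out)
}
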