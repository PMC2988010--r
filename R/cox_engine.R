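#' Counting-process rows
#'
#' The Cox machinery operates on `(start, stop]` intervals with an event
#' indicator at `stop`, a non-negative case weight, a stratum label and a
#' design row. Plain right-censored data are the special case `start = 0`.
#' The cause-specific, Fine-Gray and Lunn-McNeil models all reduce to such
#' rows; the Fine-Gray expansion additionally uses time-varying weights via
#' multiple rows per subject.
#'
#' @param stop interval endpoints (event/censoring times), `stop > start`.
#' @param status 0/1 event indicator at `stop`.
#' @param x design matrix (n x p), a vector (p = 1) or `NULL` (null model).
#' @param start interval open endpoints, default 0.
#' @param weight non-negative case weights, default 1.
#' @param stratum stratum labels, default a single stratum.
#' @param subject subject identifiers for clustering of robust variances;
#'   defaults to one subject per row.
#' @return A list of class `cp_rows`.
#' @export
cp_rows <- function(stop, status, x = NULL, start = 0, weight = 1,
                    stratum = 1L, subject = NULL) {
  n <- length(stop)
  if (is.null(x)) x <- matrix(numeric(0), n, 0)
  if (is.vector(x) && !is.matrix(x)) x <- matrix(x, ncol = 1,
                                                 dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  start <- rep_len(as.numeric(start), n)
  weight <- rep_len(as.numeric(weight), n)
  stratum <- rep_len(stratum, n)
  if (is.null(subject)) subject <- seq_len(n)
  subject <- rep_len(subject, n)
  if (any(start >= stop)) stop("cp_rows: start must be < stop")
  if (any(weight < 0)) stop("cp_rows: negative weights")
  structure(list(start = start, stop = as.numeric(stop),
                 status = as.integer(status != 0), weight = weight,
                 stratum = stratum, subject = subject, x = x),
            class = "cp_rows")
}

#' @export
print.cp_rows <- function(x, ...) {
  cat(sprintf("<cp_rows> %d rows, %d events, %d column(s), %d stratum(s)\n",
              length(x$stop), sum(x$status * (x$weight > 0)), ncol(x$x),
              length(unique(x$stratum))))
  invisible(x)
}

# sum of `vals` (matrix) over rows in the risk set {start < t <= stop},
# evaluated at each t in `tj`; O((n + m) log n) via sorted prefix sums.
risk_sums <- function(start, stop, vals, tj) {
  vals <- as.matrix(vals)
  tot <- colSums(vals)
  pref <- function(key) {
    o <- order(key)
    cs <- apply(vals[o, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, matrix(cs, ncol = ncol(vals)))
    pos <- findInterval(tj, key[o], left.open = TRUE)   # #{key < t}
    # sum over key >= t:
    sweep(-cs[pos + 1L, , drop = FALSE], 2, tot, "+")
  }
  pref(stop) - pref(start)
}

# per-stratum partial-likelihood quantities at coefficient vector `beta`
pl_stratum <- function(st, beta, ties) {
  p <- ncol(st$x)
  eta <- if (p) drop(st$x %*% beta) else numeric(length(st$stop))
  r <- st$weight * exp(eta)
  ev <- which(st$status == 1L & st$weight > 0)
  if (!length(ev))
    return(list(ll = 0, U = numeric(p), I = matrix(0, p, p),
                tj = numeric(0), dW = numeric(0), S0 = numeric(0),
                xbar = matrix(0, 0, p)))
  tj <- sort(unique(st$stop[ev]))
  m <- length(tj)
  grp <- match(st$stop[ev], tj)
  dW <- as.vector(rowsum(st$weight[ev], grp))
  sete <- as.vector(rowsum(st$weight[ev] * eta[ev], grp))
  sxe <- if (p) matrix(rowsum(st$weight[ev] * st$x[ev, , drop = FALSE], grp),
                       ncol = p) else matrix(0, m, 0)
  S0 <- drop(risk_sums(st$start, st$stop, r, tj))
  S1 <- if (p) risk_sums(st$start, st$stop, r * st$x, tj) else matrix(0, m, 0)
  if (p) {
    xx <- matrix(0, length(r), p * p)
    for (a in seq_len(p)) for (b in seq_len(p))
      xx[, (a - 1) * p + b] <- st$x[, a] * st$x[, b]
    S2 <- risk_sums(st$start, st$stop, r * xx, tj)
  } else S2 <- matrix(0, m, 0)

  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  if (ties == "breslow" || p == 0) {
    ll <- sum(sete - dW * log(S0))
    if (p) {
      xbar <- S1 / S0
      U <- colSums(sxe - dW * xbar)
      for (j in seq_len(m)) {
        v <- matrix(S2[j, ], p, p, byrow = TRUE) / S0[j] -
          tcrossprod(xbar[j, ])
        I <- I + dW[j] * v
      }
    } else xbar <- matrix(0, m, 0)
  } else {                                        # Efron
    xbar <- if (p) S1 / S0 else matrix(0, m, 0)   # used only for residuals
    S0e <- drop(rowsum(r[ev], grp))
    S1e <- if (p) matrix(rowsum(r[ev] * st$x[ev, , drop = FALSE], grp),
                         ncol = p) else matrix(0, m, 0)
    cnt <- drop(rowsum(rep(1, length(ev)), grp))
    for (j in seq_len(m)) {
      mj <- cnt[j]; wbar <- dW[j] / mj
      s2j <- matrix(S2[j, ], p, p, byrow = TRUE)
      s2e <- matrix(0, p, p)
      if (p) {
        ej <- ev[grp == j]
        for (i in ej) s2e <- s2e + r[i] * tcrossprod(st$x[i, ])
      }
      ll <- ll + sete[j]
      for (k in seq_len(mj) - 1L) {
        den <- S0[j] - (k / mj) * S0e[j]
        ll <- ll - wbar * log(den)
        if (p) {
          xb <- (S1[j, ] - (k / mj) * S1e[j, ]) / den
          U <- U - wbar * xb
          I <- I + wbar * ((s2j - (k / mj) * s2e) / den - tcrossprod(xb))
        }
      }
    }
    if (p) U <- U + colSums(sxe)
  }
  list(ll = ll, U = U, I = I, tj = tj, dW = dW, S0 = S0, xbar = xbar)
}

pl_all <- function(strata_list, beta, ties) {
  p <- ncol(strata_list[[1]]$x)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (st in strata_list) {
    q <- pl_stratum(st, beta, ties)
    ll <- ll + q$ll; U <- U + q$U; I <- I + q$I
  }
  list(ll = ll, U = U, I = I)
}

split_strata <- function(rows) {
  idx <- split(seq_along(rows$stop), rows$stratum)
  lapply(idx, function(i)
    list(start = rows$start[i], stop = rows$stop[i], status = rows$status[i],
         weight = rows$weight[i], subject = rows$subject[i],
         x = rows$x[i, , drop = FALSE], rows_idx = i))
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the (weighted) log partial likelihood over counting-process
#' rows by Newton-Raphson with step-halving. Breslow tie handling is the
#' default (it keeps exact weight/replication invariance and is the
#' convention of the subdistribution-hazards literature); Efron is
#' available. Convergence is declared when the relative change in the log
#' partial likelihood falls below `eps` (default 1e-9), with at most
#' `max_iter` iterations and up to 5 step-halvings per iteration.
#'
#' A coefficient diverging beyond `|beta| > 15` flags a monotone partial
#' likelihood: the fit is returned with a warning and `flagged = TRUE`.
#' The model-based covariance is the inverse observed information; with
#' `robust = TRUE` a sandwich estimate from score residuals aggregated by
#' `subject` is added (mandatory for IPCW-weighted fits, where the
#' model-based variance is not valid).
#'
#' @param rows a [cp_rows()] object.
#' @param init initial coefficient vector (default zeros).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param robust also compute the sandwich covariance, clustering on
#'   `rows$subject`.
#' @param eps relative log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `cox_fit`: `beta`, `var` (model-based),
#'   `var_robust` (or `NULL`), `loglik` (`c(null, final)`), `score` (at the
#'   solution), `iterations`, `converged`, `flagged`, `n`, `n_events`,
#'   `ties`, `use_robust`.
#' @export
fit_cox <- function(rows, init = NULL, ties = c("breslow", "efron"),
                    robust = FALSE, eps = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  p <- ncol(rows$x)
  n_events <- sum(rows$status == 1L & rows$weight > 0)
  if (n_events == 0) stop("fit_cox: no events")
  strata_list <- split_strata(rows)
  beta <- if (is.null(init)) numeric(p) else rep_len(as.numeric(init), p)

  q0 <- pl_all(strata_list, numeric(p), ties)
  ll_null <- q0$ll
  flagged <- FALSE; converged <- FALSE; iter <- 0L
  if (p == 0) {
    beta <- numeric(0); var <- matrix(0, 0, 0); converged <- TRUE
    ll <- ll_null; U <- numeric(0)
  } else {
    # collinearity check on the null-model information
    if (rcond_sym(q0$I) < 1e-12) {
      bad <- singular_columns(q0$I, colnames(rows$x))
      stop("fit_cox: singular information matrix; offending column(s): ",
           paste(bad, collapse = ", "))
    }
    q <- if (all(beta == 0)) q0 else pl_all(strata_list, beta, ties)
    ll <- q$ll
    repeat {
      iter <- iter + 1L
      step <- solve(q$I, q$U)
      cand <- beta + step
      qc <- pl_all(strata_list, cand, ties)
      h <- 0
      while (qc$ll < ll - 1e-12 && h < 5) {
        h <- h + 1
        cand <- beta + step / 2^h
        qc <- pl_all(strata_list, cand, ties)
      }
      delta <- abs(qc$ll - ll) / (abs(qc$ll) + 0.1)
      beta <- cand; ll <- qc$ll; q <- qc
      if (any(abs(beta) > 15)) {
        flagged <- TRUE
        warning("fit_cox: monotone partial likelihood suspected ",
                "(|beta| > 15); estimates unreliable")
        break
      }
      if (delta < eps) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    if (rcond_sym(q$I) < 1e-12) {
      bad <- singular_columns(q$I, colnames(rows$x))
      stop("fit_cox: singular information at solution; column(s): ",
           paste(bad, collapse = ", "))
    }
    var <- solve(q$I)
    U <- q$U
  }
  names(beta) <- colnames(rows$x)
  if (p) dimnames(var) <- list(colnames(rows$x), colnames(rows$x))
  fit <- structure(list(beta = beta, var = var, var_robust = NULL,
                        loglik = c(null = ll_null, final = ll), score = U,
                        iterations = iter, converged = converged,
                        flagged = flagged, n = length(rows$stop),
                        n_events = n_events, ties = ties,
                        use_robust = robust),
                   class = "cox_fit")
  if (robust && p > 0)
    fit$var_robust <- sandwich_var(fit, rows, strata_list)
  fit
}

rcond_sym <- function(m) {
  if (!nrow(m)) return(1)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(ev) / max(abs(ev))
}

singular_columns <- function(I, nms) {
  qr_ <- qr(I)
  if (qr_$rank == ncol(I)) return(character(0))
  nms[qr_$pivot[(qr_$rank + 1):ncol(I)]]
}

# score residuals per row, aggregated by subject -> sandwich covariance
sandwich_var <- function(fit, rows, strata_list = NULL) {
  if (is.null(strata_list)) strata_list <- split_strata(rows)
  p <- length(fit$beta)
  resid <- matrix(0, length(rows$stop), p)
  for (st in strata_list) {
    q <- pl_stratum(st, fit$beta, "breslow")
    if (!length(q$tj)) next
    eta <- drop(st$x %*% fit$beta)
    r <- st$weight * exp(eta)
    dL <- q$dW / q$S0                              # baseline increments
    H <- cumsum(dL)
    G <- apply(q$xbar * dL, 2, cumsum)
    G <- matrix(G, ncol = p)
    look <- function(cum, t) {
      idx <- findInterval(t, q$tj)
      out <- matrix(0, length(t), ncol(cum))
      out[idx > 0, ] <- cum[idx[idx > 0], , drop = FALSE]
      out
    }
    Hs <- look(cbind(H), st$stop); Ha <- look(cbind(H), st$start)
    Gs <- look(G, st$stop); Ga <- look(G, st$start)
    rr <- -r * (st$x * drop(Hs - Ha) - (Gs - Ga))
    ev <- which(st$status == 1L & st$weight > 0)
    if (length(ev)) {
      j <- match(st$stop[ev], q$tj)
      rr[ev, ] <- rr[ev, ] +
        st$weight[ev] * (st$x[ev, , drop = FALSE] - q$xbar[j, , drop = FALSE])
    }
    resid[st$rows_idx, ] <- rr
  }
  U_sub <- rowsum(resid, rows$subject)
  v <- fit$var %*% crossprod(U_sub) %*% fit$var
  dimnames(v) <- dimnames(fit$var)
  v
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, %s in %d iter\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (length(x$beta)) print(hazard_ratio_table(x))
  invisible(x)
}

#' Active covariance of a Cox fit
#'
#' Robust sandwich covariance when the fit requested it (as IPCW-weighted
#' fits must), otherwise the model-based inverse information.
#' @param fit a `cox_fit`.
#' @return p x p covariance matrix.
#' @export
cox_vcov <- function(fit) {
  if (isTRUE(fit$use_robust) && !is.null(fit$var_robust)) fit$var_robust
  else fit$var
}

#' Breslow baseline cumulative hazard
#'
#' Step-function estimate of the baseline cumulative hazard of a fitted
#' model, one curve per stratum, with increment `d_j / sum_{risk} w e^{x'b}`
#' at each event time.
#'
#' @param fit a `cox_fit`.
#' @param rows the [cp_rows()] the model was fitted to.
#' @return Named list of [cr_stepfun()] (initial value 0), one per stratum.
#' @export
breslow_baseline <- function(fit, rows) {
  strata_list <- split_strata(rows)
  out <- lapply(strata_list, function(st) {
    q <- pl_stratum(st, fit$beta, "breslow")
    cr_stepfun(q$tj, cumsum(q$dW / q$S0), 0,
               extra = list(increments = q$dW / q$S0))
  })
  names(out) <- names(strata_list)
  out
}

#' Hazard-ratio table
#'
#' Exponentiates coefficients into hazard ratios with Wald confidence
#' intervals and p-values, plus the percent-change reading
#' `(HR - 1) x 100` used in narrative summaries ("51% higher hazard").
#'
#' @param fit a `cox_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame (`term`, `beta`, `se`, `hr`, `lcl`, `ucl`, `p`,
#'   `pct_change`). Emitted with a warning when the fit did not converge.
#' @export
hazard_ratio_table <- function(fit, level = 0.95) {
  if (!fit$converged)
    warning("hazard_ratio_table: fit did not converge; interpret with care")
  se <- sqrt(pmax(diag(cox_vcov(fit)), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$beta
  data.frame(term = names(b), beta = unname(b), se = unname(se),
             hr = exp(unname(b)),
             lcl = exp(unname(b) - z * se), ucl = exp(unname(b) + z * se),
             p = ifelse(se > 0, 2 * stats::pnorm(-abs(unname(b)) / se), 1),
             pct_change = (exp(unname(b)) - 1) * 100,
             row.names = NULL)
}

# cut counting-process rows at the given times (piecewise-constant
# time-dependent covariates); status stays on the final piece of each row
split_rows_at <- function(rows, cut_times) {
  ct <- sort(unique(cut_times))
  a <- findInterval(rows$start, ct)                 # #{ct <= start}
  b <- findInterval(rows$stop, ct, left.open = TRUE)  # #{ct < stop}
  npiece <- pmax(b - a, 0L) + 1L
  idx <- rep(seq_along(rows$stop), npiece)
  ends <- unlist(Map(function(ai, bi, s) {
    if (bi > ai) c(ct[(ai + 1):bi], s) else s
  }, a, b, rows$stop))
  starts <- unlist(Map(function(ai, bi, s0) {
    if (bi > ai) c(s0, ct[(ai + 1):bi]) else s0
  }, a, b, rows$start))
  last <- cumsum(npiece)
  status <- integer(length(idx))
  status[last] <- rows$status
  cp_rows(stop = ends, status = status, x = rows$x[idx, , drop = FALSE],
          start = starts, weight = rows$weight[idx],
          stratum = rows$stratum[idx], subject = rows$subject[idx])
}

#' Proportional-hazards diagnostics
#'
#' Two complementary checks of proportionality for each design column:
#' (a) for columns with few distinct values, group-wise
#' `log(-log S_KM(t))` curves are exported for plotting (parallel curves
#' support proportionality); (b) the model is refitted adding, one column
#' at a time, the time-dependent interaction `x * log(t)` evaluated at
#' event times, and the Wald p-value of the interaction is reported (small
#' p flags non-proportionality).
#'
#' @param fit a converged `cox_fit`.
#' @param rows the [cp_rows()] the model was fitted to.
#' @return data.frame (`term`, `beta_tt`, `se_tt`, `p_tt`) with attribute
#'   `cloglog`: per eligible column, a list of [cr_stepfun()] cloglog
#'   curves by group.
#' @export
check_proportionality <- function(fit, rows) {
  p <- length(fit$beta)
  if (!p) stop("check_proportionality: model has no covariates")
  tj <- sort(unique(rows$stop[rows$status == 1L]))
  srows <- split_rows_at(rows, tj)
  out <- data.frame(term = names(fit$beta), beta_tt = NA_real_,
                    se_tt = NA_real_, p_tt = NA_real_)
  for (j in seq_len(p)) {
    xz <- cbind(srows$x, srows$x[, j] * log(srows$stop))
    colnames(xz) <- c(colnames(srows$x),
                      paste0(names(fit$beta)[j], ":log(t)"))
    rj <- cp_rows(stop = srows$stop, status = srows$status, x = xz,
                  start = srows$start, weight = srows$weight,
                  stratum = srows$stratum, subject = srows$subject)
    fj <- fit_cox(rj, ties = fit$ties, robust = fit$use_robust)
    k <- p + 1L
    se <- sqrt(diag(cox_vcov(fj)))[k]
    out$beta_tt[j] <- fj$beta[k]
    out$se_tt[j] <- se
    out$p_tt[j] <- 2 * stats::pnorm(-abs(fj$beta[k]) / se)
  }
  cl <- list()
  base <- which(rows$start == 0)
  for (j in seq_len(p)) {
    vals <- rows$x[base, j]
    if (length(unique(vals)) > 5) next
    curves <- lapply(split(base, vals), function(i) {
      km <- suppressWarnings(kaplan_meier(rows$stop[i], rows$status[i]))
      keep <- km$values > 0 & km$values < 1
      cr_stepfun(km$times[keep], log(-log(km$values[keep])), NA)
    })
    cl[[names(fit$beta)[j]]] <- curves
  }
  attr(out, "cloglog") <- cl
  out
}
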