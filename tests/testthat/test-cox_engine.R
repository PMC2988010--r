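test_that("fit_cox solves the toy stationary point and symmetric null", {
  # (1,event,z=1), (2,event,z=0), (3,cens,z=1): beta = -ln(2)/2
  fit <- fit_cox(cp_rows(c(1, 2, 3), c(1, 1, 0), c(1, 0, 1)))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), -log(2) / 2, tolerance = 1e-8)
  expect_lt(sqrt(sum(fit$score^2)), 1e-6)
  # exactly balanced groups: beta = 0 by symmetry
  fit0 <- fit_cox(cp_rows(c(1, 2, 1, 2), c(1, 1, 1, 1), c(0, 0, 1, 1)))
  expect_equal(unname(fit0$beta), 0, tolerance = 1e-10)
  expect_error(fit_cox(cp_rows(c(1, 2), c(0, 0), c(0, 1))), "no events")
})

test_that("Newton-Raphson agrees with the grid-search oracle on n <= 8", {
  fixtures <- list(
    list(time = c(1, 2, 3), status = c(1, 1, 0), x = c(1, 0, 1)),
    list(time = c(1, 1, 2, 3), status = c(1, 1, 1, 0), x = c(1, 0, 0, 1)),
    list(time = c(2, 4, 4, 5, 7, 9), status = c(1, 0, 1, 1, 1, 0),
         x = c(0, 1, 1, 0, 1, 0)),
    list(time = c(1, 2, 3, 4, 5, 6, 7, 8), status = c(1, 1, 0, 1, 1, 0, 1, 1),
         x = c(0.2, -1, 0.5, 1.3, 0, -0.4, 2, 1)))
  for (fx in fixtures) {
    b_grid <- pl_grid_max(fx$time, fx$status, fx$x)
    fit <- fit_cox(cp_rows(fx$time, fx$status, fx$x))
    expect_equal(unname(fit$beta), b_grid, tolerance = 1e-6)
    # and the oracle log-likelihood agrees with the engine's
    expect_equal(unname(fit$loglik["final"]),
                 pl_oracle(fx$time, fx$status, fx$x, fit$beta),
                 tolerance = 1e-9)
  }
})

test_that("fit_cox matches coxph across tie methods, weights, strata", {
  skip_if_not_installed("survival")
  set.seed(5)
  n <- 150
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  t <- round(rexp(n, exp(0.4 * x[, 1])), 1) + 0.1    # forces ties
  status <- rbinom(n, 1, 0.7)
  w <- runif(n, 0.5, 2)
  s <- rep(1:3, length.out = n)
  st <- runif(n, 0, t * 0.4)
  d <- data.frame(t, status, a = x[, 1], b = x[, 2], w, s, st)
  cases <- list(
    list(rows = cp_rows(t, status, x), ties = "breslow",
         fml = survival::Surv(t, status) ~ a + b, w = NULL, rb = FALSE),
    list(rows = cp_rows(t, status, x), ties = "efron",
         fml = survival::Surv(t, status) ~ a + b, w = NULL, rb = FALSE),
    list(rows = cp_rows(t, status, x, weight = w), ties = "breslow",
         fml = survival::Surv(t, status) ~ a + b, w = w, rb = TRUE),
    list(rows = cp_rows(t, status, x, stratum = s), ties = "breslow",
         fml = survival::Surv(t, status) ~ a + b + survival::strata(s),
         w = NULL, rb = FALSE),
    list(rows = cp_rows(t, status, x, start = st), ties = "breslow",
         fml = survival::Surv(st, t, status) ~ a + b, w = NULL, rb = FALSE))
  for (cs in cases) {
    fit <- fit_cox(cs$rows, ties = cs$ties, robust = cs$rb)
    ref <- survival::coxph(cs$fml, data = d, ties = cs$ties,
                           weights = cs$w, robust = cs$rb)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-8)
    v <- if (cs$rb) fit$var_robust else fit$var
    expect_equal(unname(v), unname(vcov(ref)), tolerance = 1e-8)
  }
})

test_that("weight invariance and stratum-copy invariance hold exactly", {
  ch <- random_cohort(60, 17)
  X <- encode(ch, "z")
  # duplicating a row == doubling its weight (Breslow)
  dup <- fit_cox(cp_rows(c(ch$time, ch$time[1]), c(ch$event == 1, ch$event[1] == 1),
                         rbind(X, X[1, , drop = FALSE])))
  wt <- fit_cox(cp_rows(ch$time, ch$event == 1, X,
                        weight = c(2, rep(1, nrow(ch) - 1))))
  expect_equal(dup$beta, wt$beta, tolerance = 1e-12)
  b1 <- breslow_baseline(dup, cp_rows(c(ch$time, ch$time[1]),
                                      c(ch$event == 1, ch$event[1] == 1),
                                      rbind(X, X[1, , drop = FALSE])))[[1]]
  b2 <- breslow_baseline(wt, cp_rows(ch$time, ch$event == 1, X,
                                     weight = c(2, rep(1, nrow(ch) - 1))))[[1]]
  expect_equal(b1$values, b2$values, tolerance = 1e-12)

  # disjoint stratum copies of one dataset == the single dataset
  single <- fit_cox(cp_rows(ch$time, ch$event == 1, X))
  copies <- fit_cox(cp_rows(rep(ch$time, 2), rep(ch$event == 1, 2),
                            rbind(X, X), stratum = rep(1:2, each = nrow(ch))))
  expect_equal(single$beta, copies$beta, tolerance = 1e-10)
})

test_that("breslow_baseline: null reduction, toy plug-in, strata isolation", {
  ch <- random_cohort(80, 23, K = 1)
  rows <- cp_rows(ch$time, ch$event)
  fit <- fit_cox(rows)
  bl <- breslow_baseline(fit, rows)[[1]]
  # null model: Nelson-Aalen increments d_j / n_j
  km <- kaplan_meier(ch$time, ch$event)
  expect_equal(bl$increments, km$n_event / km$n_risk, tolerance = 1e-12)

  # toy: increments 1/(2x+1) at t=1 and 1/(1+x) at t=2, x = exp(beta)
  rows3 <- cp_rows(c(1, 2, 3), c(1, 1, 0), c(1, 0, 1))
  f3 <- fit_cox(rows3)
  x <- exp(unname(f3$beta))
  b3 <- breslow_baseline(f3, rows3)[[1]]
  expect_equal(b3$increments, c(1 / (2 * x + 1), 1 / (1 + x)),
               tolerance = 1e-8)

  # one stratum's jumps are unaffected by the other's event times
  ch2 <- random_cohort(40, 29, K = 1)
  rows_a <- cp_rows(ch$time, ch$event, stratum = 1)
  rows_ab <- cp_rows(c(ch$time, ch2$time), c(ch$event, ch2$event),
                     stratum = rep(1:2, c(nrow(ch), nrow(ch2))))
  f_ab <- fit_cox(rows_ab)
  bl_ab <- breslow_baseline(f_ab, rows_ab)
  expect_equal(bl_ab[["1"]]$times, bl$times)
  expect_equal(bl_ab[["1"]]$increments, bl$increments, tolerance = 1e-12)
})

test_that("hazard_ratio_table: percent-change readings and degenerate fit", {
  mk <- function(beta, se) structure(
    list(beta = c(z = beta), var = matrix(se^2, 1, 1), var_robust = NULL,
         converged = TRUE, use_robust = FALSE), class = "cox_fit")
  tab <- hazard_ratio_table(mk(log(1.513), 0.14))
  expect_equal(tab$hr, 1.513)
  expect_equal(round(tab$pct_change), 51)
  expect_equal(round(hazard_ratio_table(mk(log(1.323), 0.1))$pct_change), 32)
  expect_equal(round(hazard_ratio_table(mk(log(2.65), 0.1))$pct_change), 165)
  t0 <- hazard_ratio_table(mk(0, 0.2))
  expect_equal(t0$hr, 1)
  expect_equal(t0$pct_change, 0)
  expect_equal(t0$p, 1)
  # CI contains HR
  expect_true(tab$lcl < tab$hr && tab$hr < tab$ucl)
  bad <- mk(0.5, 0.1); bad$converged <- FALSE
  expect_warning(hazard_ratio_table(bad), "converge")
})

test_that("degenerate designs are reported, not silently fitted", {
  ch <- random_cohort(50, 41)
  X <- cbind(a = ch$z, b = ch$z)           # collinear
  expect_error(fit_cox(cp_rows(ch$time, ch$event == 1, X)), "singular")
  # perfectly separating covariate -> monotone likelihood flag
  tmono <- c(1, 2, 3, 4, 5, 6)
  xmono <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fmono <- fit_cox(cp_rows(tmono, rep(1, 6), xmono)),
                 "monotone")
  expect_true(fmono$flagged)
})

test_that("proportionality diagnostics: null p's healthy, violation caught", {
  # single-covariate toy: cloglog curves step with the group-wise KM
  ch <- random_cohort(80, 51, K = 1)
  rows <- cp_rows(ch$time, ch$event, encode(ch, "z"))
  fit <- fit_cox(rows)
  pr <- check_proportionality(fit, rows)
  cl <- attr(pr, "cloglog")[["z"]]
  for (g in c("0", "1")) {
    kmg <- kaplan_meier(ch$time[ch$z == as.numeric(g)],
                        ch$event[ch$z == as.numeric(g)])
    keep <- kmg$values > 0 & kmg$values < 1
    expect_equal(cl[[g]]$times, kmg$times[keep])
    expect_equal(cl[[g]]$values, log(-log(kmg$values[keep])),
                 tolerance = 1e-12)
  }

  # proportional world: interaction p not systematically small (10 reps)
  ps <- vapply(1:10, function(i) {
    ch <- random_cohort(300, 600 + i, K = 1, cens_rate = 0.03)
    rows <- cp_rows(ch$time, ch$event, encode(ch, "z"))
    check_proportionality(fit_cox(rows), rows)$p_tt
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.35)
  expect_gt(median(ps), 0.1)

  # effect reversing sign at t = 5: interaction flagged
  set.seed(77)
  n <- 2000
  z <- rbinom(n, 1, 0.5)
  # baseline 0.15, covariate effect +1 before t = 5 and -1 after:
  # invert the piecewise-exponential cumulative hazard
  b <- 0.15
  e <- rexp(n)
  H5 <- 5 * b * exp(z)
  tt <- ifelse(e < H5, e / (b * exp(z)), 5 + (e - H5) / (b * exp(-z)))
  cc <- runif(n, 2, 12)
  rows <- cp_rows(pmin(tt, cc), tt <= cc, matrix(z, ncol = 1))
  pr2 <- check_proportionality(fit_cox(rows), rows)
  expect_lt(pr2$p_tt, 0.05)
})
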