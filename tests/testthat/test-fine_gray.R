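test_that("censoring KM: duality, single censoring atom, no censoring", {
  ch <- toy3()
  G <- censoring_km(ch)
  expect_equal(G$times, 3)
  expect_equal(sf_at(G, 3), 0)
  expect_equal(sf_left(G, 3), 1)

  # no censored subjects: G == 1
  chn <- make_cohort(c(1, 2, 3), c(1, 2, 1))
  expect_equal(sf_at(censoring_km(chn), 100), 1)

  # swap events <-> censorings: censoring_km == kaplan_meier of original
  ch2 <- random_cohort(80, 19, K = 1, cens_rate = 0.08)
  swapped <- make_cohort(ch2$time, 1 - ch2$event)
  expect_equal(censoring_km(swapped)$values,
               kaplan_meier(ch2$time, ch2$event)$values)
})

test_that("FG expansion builds the modified risk set", {
  # {(1,c2),(2,c1),(3,cens)}, target cause 1: subject 1 stays at risk at t=2
  ch <- make_cohort(c(1, 2, 3), c(2, 1, 0))
  rows <- expand_fg_rows(ch, 1)
  at2 <- sum(rows$start < 2 & 2 <= rows$stop)
  expect_equal(at2, 3)                      # vs 2 under cause-specific
  # follow-on row for subject 1 spans (1, 2] with weight G(2-)/G(1-) = 1
  fo <- which(rows$start > 0)
  expect_equal(rows$start[fo], 1)
  expect_equal(rows$stop[fo], 2)
  expect_equal(rows$weight[fo], 1)
  expect_error(expand_fg_rows(ch, 3), "cause")
  expect_error(expand_fg_rows(make_cohort(c(1, 2), c(2, 0)), 1), "no events")

  # modified risk set contains the cause-specific risk set at every
  # target-cause event time; equality iff no prior competing events
  for (seed in 1:6) {
    chr <- random_cohort(70, 300 + seed)
    rows <- expand_fg_rows(chr, 1)
    te <- sort(unique(chr$time[chr$event == 1]))
    for (t in te) {
      fg_n <- sum(rows$start < t & t <= rows$stop)
      cs_n <- sum(chr$time >= t)
      expect_gte(fg_n, cs_n)
      prior_comp <- sum(chr$time < t & chr$event == 2)
      if (prior_comp == 0) expect_equal(fg_n, cs_n)
      else expect_gt(fg_n, cs_n)
    }
  }
})

test_that("IPCW weights follow G(t-)/G(T_i-) and K=1 expansion is identity", {
  chr <- random_cohort(60, 37, cens_rate = 0.1)
  G <- censoring_km(chr)
  rows <- expand_fg_rows(chr, 1)
  fo <- which(rows$start > 0)
  ids <- rows$subject[fo]
  Ti <- chr$time[match(ids, chr$id)]
  expect_equal(rows$weight[fo],
               sf_left(G, rows$stop[fo]) / sf_left(G, Ti),
               tolerance = 1e-12)
  expect_true(all(rows$weight[fo] <= 1 + 1e-12))   # G is non-increasing

  ch1 <- random_cohort(50, 43, K = 1)
  r1 <- expand_fg_rows(ch1, 1)
  expect_equal(length(r1$stop), nrow(ch1))
  expect_true(all(r1$weight == 1))
  f_fg <- fit_fine_gray(ch1, 1, "z")
  f_cx <- fit_cox(cp_rows(ch1$time, ch1$event, encode(ch1, "z")))
  expect_equal(f_fg$cox$beta, f_cx$beta, tolerance = 1e-12)
})

test_that("no-censoring FG equals the recode-at-max oracle", {
  for (seed in c(3, 9)) {
    ch <- random_cohort(100, 500 + seed, cens_rate = 1e-9)
    ch <- ch[ch$event > 0, ]                  # drop the (rare) censored
    ch <- make_cohort(ch$time, ch$event, z = ch$z)
    f <- fit_fine_gray(ch, 1, "z")
    # oracle: competing events recoded censored past the largest time
    tmax <- max(ch$time)
    t2 <- ifelse(ch$event == 2, tmax + 1, ch$time)
    s2 <- as.integer(ch$event == 1)
    f2 <- fit_cox(cp_rows(t2, s2, encode(ch, "z")))
    expect_equal(f$cox$beta, f2$beta, tolerance = 1e-8)
  }
})

test_that("FG fit matches the survival package's finegray construction", {
  skip_if_not_installed("survival")
  ch <- random_cohort(250, 61, cens_rate = 0.06)
  f <- fit_fine_gray(ch, 1, "z")
  ev <- factor(ch$event, 0:2, labels = c("cens", "c1", "c2"))
  d <- data.frame(id = ch$id, time = ch$time, ev = ev, z = ch$z)
  fgd <- survival::finegray(survival::Surv(time, ev) ~ z + id, data = d,
                            etype = "c1", id = id)
  ref <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ z, data = fgd,
    weights = fgwt, ties = "breslow", cluster = id)
  expect_equal(unname(f$cox$beta), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(f$cox$var_robust), unname(vcov(ref)),
               tolerance = 1e-8)
})

test_that("subdistribution CIF prediction", {
  ch <- random_cohort(200, 67, cens_rate = 0.05)
  f <- fit_fine_gray(ch, 1, "z")
  # reference profile: 1 - exp(-Lambda*)
  p0 <- predict_cif_fg(f, list(z = 0))
  expect_equal(p0$values, 1 - exp(-f$baseline$values), tolerance = 1e-12)
  # monotone, within [0, 1)
  p1 <- predict_cif_fg(f, list(z = 1))
  expect_true(all(diff(c(0, p1$values)) >= -1e-15))
  expect_true(all(p1$values >= 0 & p1$values < 1))
  # beta'z -> -inf: CIF -> 0 (forced positive coefficient)
  f_forced <- f
  f_forced$cox$beta <- c(z = 1)
  pneg <- predict_cif_fg(f_forced, list(z = -50))
  expect_lt(max(pneg$values), 1e-6)
  # K=1 null model: 1 - exp(-Lambda*) approaches 1 - KM as n grows
  # (compared away from the sparse tail, where Breslow and product-limit
  # legitimately disagree)
  err <- vapply(c(100, 1600), function(n) {
    ch1 <- random_cohort(n, 71, K = 1, cens_rate = 0.05)
    f1 <- fit_fine_gray(ch1, 1, character(0))
    p <- predict_cif_fg(f1)
    km <- kaplan_meier(ch1$time, ch1$event)
    g <- seq(0, stats::quantile(ch1$time, 0.8), length.out = 50)
    max(abs(sf_at(p, g) - (1 - sf_at(km, g))))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("FG beta recovery and CI coverage on FG-simulated data", {
  reps <- 40
  res <- t(vapply(seq_len(reps), function(i) {
    sp <- sim_spec(n = 1000,
      covariates = list(z = list(kind = "bernoulli", p = 0.5)),
      mechanism = "fine_gray",
      fg = list(p = 0.3, beta1 = c(z = 0.5), base2 = 1,
                beta2 = c(z = 0.2)),
      censoring = list(rate = 0.3, admin = 10), seed = 7000 + i)
    ch <- simulate_fine_gray(sp)
    f <- fit_fine_gray(ch, 1, "z")
    se <- sqrt(diag(cox_vcov(f$cox)))
    c(unname(f$cox$beta), unname(se))
  }, numeric(2)))
  se_rep <- sd(res[, 1]) / sqrt(reps)
  expect_lt(abs(mean(res[, 1]) - 0.5), 3 * se_rep)
  cover <- mean(abs(res[, 1] - 0.5) <= 1.959964 * res[, 2])
  expect_gte(cover, 0.85)                    # loose bound at 40 reps
})
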