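test_that("augmentation layout: n x K rows, indicators, interactions", {
  ch <- make_cohort(c(5.2, 3, 7), c(1, 0, 2), male = c(1, 0, 1))
  rows <- lm_augment(ch, "male", "unstratified")
  expect_equal(length(rows$stop), 3 * 2)
  expect_equal(sum(rows$status), sum(ch$event > 0))
  lay <- attr(rows, "lm_layout")
  expect_equal(colnames(rows$x),
               c("riskType2", "male_type1", "male_type2"))
  # subject 1 (t=5.2, D=1, male=1): type-1 row has status 1, male_type1=1
  i1 <- which(rows$subject == 1)
  r1 <- i1[rows$x[i1, "riskType2"] == 0]
  r2 <- i1[rows$x[i1, "riskType2"] == 1]
  expect_equal(rows$status[r1], 1L)
  expect_equal(rows$status[r2], 0L)
  expect_equal(unname(rows$x[r1, ]), c(0, 1, 0))
  expect_equal(unname(rows$x[r2, ]), c(1, 0, 1))
  expect_equal(rows$stop[i1], c(5.2, 5.2))
  # censored subject: both rows status 0
  i2 <- which(rows$subject == 2)
  expect_equal(rows$status[i2], c(0L, 0L))
  # per subject at most one event row
  expect_true(all(tapply(rows$status, rows$subject, sum) <= 1))

  # stratified mode: type is a stratum, no bare indicator columns
  srows <- lm_augment(ch, "male", "stratified")
  expect_equal(colnames(srows$x), c("male_type1", "male_type2"))
  expect_equal(sort(unique(srows$stratum)), c(1L, 2L))

  expect_error(lm_augment(random_cohort(20, 1, K = 1), "z", "stratified"),
               "K = 1")
})

test_that("stratified LM reproduces separate cause-specific fits", {
  for (seed in c(5, 12)) {
    ch <- random_cohort(150, seed)
    cs <- fit_cause_specific(ch, "z")
    lm <- fit_lm(ch, "z", "stratified")
    expect_equal(unname(lm$cox$beta["z_type1"]),
                 unname(cs$per_cause[[1]]$beta), tolerance = 1e-6)
    expect_equal(unname(lm$cox$beta["z_type2"]),
                 unname(cs$per_cause[[2]]$beta), tolerance = 1e-6)
    # covariance blocks agree too
    expect_equal(lm$cox$var["z_type1", "z_type1"],
                 unname(cs$per_cause[[1]]$var[1, 1]), tolerance = 1e-6)
    expect_equal(lm$cox$var["z_type1", "z_type2"], 0, tolerance = 1e-6)
    # and the per-stratum baselines match the per-cause baselines
    for (k in 1:2) {
      bl <- lm$baselines[[as.character(k)]]
      expect_equal(bl$values, cs$baselines[[k]]$values, tolerance = 1e-6)
    }
    # coefficient count contracts
    expect_equal(length(lm$cox$beta), 2 * 1)
    expect_equal(length(fit_lm(ch, "z", "unstratified")$cox$beta),
                 (2 - 1) + 2 * 1)
  }
})

test_that("risk-type HR recovers a true baseline ratio", {
  reps <- 12
  est <- vapply(seq_len(reps), function(i) {
    sp <- sim_spec(n = 4000, covariates = list(),
      mechanism = "cause_specific",
      causes = list(list(base = 0.02), list(base = 0.05)),
      censoring = list(admin = 20), seed = 900 + i)
    ch <- simulate_cause_specific(sp)
    f <- fit_lm(ch, character(0), "unstratified")
    exp(unname(f$cox$beta["riskType2"]))
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 2.5), 3 * se)
})

test_that("non-proportional type baselines are flagged by the diagnostic", {
  # type-2 hazard rises steeply with time while type-1 is flat
  sp <- sim_spec(n = 1500, covariates = list(),
    mechanism = "cause_specific",
    causes = list(list(base = 0.05, shape = 1),
                  list(base = 0.002, shape = 3)),
    censoring = list(admin = 12), seed = 55)
  ch <- simulate_cause_specific(sp)
  rows <- lm_augment(ch, character(0), "unstratified")
  fit <- fit_cox(rows)
  pr <- check_proportionality(fit, rows)
  expect_lt(pr$p_tt[pr$term == "riskType2"], 0.05)
})

test_that("LM CIF predictions: stratified == cause-specific; conservation", {
  ch <- random_cohort(200, 27)
  cs <- fit_cause_specific(ch, "z")
  lms <- fit_lm(ch, "z", "stratified")
  for (zv in c(0, 1)) {
    # z = 1 pushes a late pooled increment above 1 here; both plug-ins
    # renormalize it (with a warning) and must still agree and conserve
    a <- suppressWarnings(predict_cif_cs(cs, list(z = zv)))
    b <- suppressWarnings(predict_cif_lm(lms, list(z = zv)))
    for (k in 1:2)
      expect_stepfun_equal(a$per_cause[[k]], b$per_cause[[k]],
                           a$event_times, 1e-8)
  }
  lmu <- fit_lm(ch, "z", "unstratified")
  pu <- suppressWarnings(predict_cif_lm(lmu, list(z = 1)))
  tj <- pu$event_times
  tot <- Reduce(`+`, lapply(pu$per_cause, sf_at, t = tj)) +
    sf_at(pu$overall_survival, tj)
  expect_lt(max(abs(tot - 1)), 1e-12)

  # with truly proportional type baselines the unstratified curves
  # approach the cause-specific curves as n grows
  errs <- vapply(c(300, 2500), function(n) {
    sp <- sim_spec(n = n, covariates = list(),
      mechanism = "cause_specific",
      causes = list(list(base = 0.02), list(base = 0.05)),
      censoring = list(admin = 20), seed = 81)
    chp <- simulate_cause_specific(sp)
    a <- predict_cif_cs(fit_cause_specific(chp, character(0)))
    b <- predict_cif_lm(fit_lm(chp, character(0), "unstratified"))
    g <- seq(1, 18, by = 1)
    max(abs(sf_at(a$per_cause[[1]], g) - sf_at(b$per_cause[[1]], g)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})
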