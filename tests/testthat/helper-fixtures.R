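# fixtures and independent oracles shared across the suite

make_cohort <- function(time, event, ..., n_causes = NULL, schema = NULL) {
  df <- data.frame(id = seq_along(time), time = time, event = event, ...)
  cohort(df, n_causes = n_causes, schema = schema)
}

# the three-subject toy used throughout: (1, cause1), (2, cause2), (3, cens)
toy3 <- function() make_cohort(c(1, 2, 3), c(1, 2, 0))

# independent partial-likelihood oracle: direct risk-set scan, Breslow ties
pl_oracle <- function(time, status, x, beta) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  tj <- sort(unique(time[status == 1]))
  ll <- 0
  for (t in tj) {
    ev <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(eta[ev]) - length(ev) * log(sum(exp(eta[risk])))
  }
  ll
}

# grid search (step 1e-4 over +-5) refined by optimize(); one covariate
pl_grid_max <- function(time, status, x) {
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) pl_oracle(time, status, x, b), numeric(1))
  b0 <- grid[which.max(ll)]
  opt <- stats::optimize(function(b) pl_oracle(time, status, x, b),
                         c(b0 - 2e-4, b0 + 2e-4), maximum = TRUE,
                         tol = 1e-10)
  opt$maximum
}

# small deterministic competing-risks cohort generator for property loops
random_cohort <- function(n, seed, K = 2, cens_rate = 0.05) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  lat <- sapply(seq_len(K), function(k) rexp(n, 0.05 * k * exp(0.3 * z)))
  lat <- matrix(lat, ncol = K)
  T_lat <- apply(lat, 1, min)
  cause <- apply(lat, 1, which.min)
  C <- rexp(n, cens_rate)
  make_cohort(pmin(T_lat, C), ifelse(T_lat <= C, cause, 0L), z = z,
              n_causes = K)
}

expect_stepfun_equal <- function(a, b, grid, tol = 1e-12) {
  expect_lt(max(abs(sf_at(a, grid) - sf_at(b, grid))), tol)
}
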