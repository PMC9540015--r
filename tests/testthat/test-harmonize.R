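# Simulated-truth checks for the empirical-Bayes center harmonization.

make_batched <- function(seed, n_per = 200, p = 30, shift = 0, scale = 1,
                         dx_effect = 0) {
  set.seed(seed)
  n <- 2 * n_per
  center <- rep(c("A", "B"), each = n_per)
  group <- rep(c("control", "case"), n)[1:n]
  X <- matrix(rnorm(n * p), n, p)
  X[group == "case", ] <- X[group == "case", ] + dx_effect
  X[center == "B", ] <- X[center == "B", ] * scale + shift
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, center = center, group = group)
}

test_that("no bias means no correction", {
  d <- make_batched(1)
  fit <- combat_fit(d$X, d$center)
  expect_lt(max(abs(fit$gamma_star)), 0.05)
  expect_lt(max(abs(fit$delta2_star - 1)), 0.2)
})

test_that("a known additive center shift is recovered and removed", {
  d <- make_batched(2, shift = 5)
  fit <- combat_fit(d$X, d$center)
  # gamma is on the standardized scale; B's location estimate recovers the
  # shift after multiplying back by the pooled SD
  est_shift <- (fit$gamma_star["B", ] - fit$gamma_star["A", ]) *
    sqrt(fit$var_pooled)
  expect_equal(mean(est_shift), 5, tolerance = 0.1)
  H <- combat_apply(d$X, fit, d$center)
  mean_gap <- colMeans(H[d$center == "B", ]) - colMeans(H[d$center == "A", ])
  expect_lt(mean(abs(mean_gap)), 0.1)  # residual gap ~ sampling noise
})

test_that("diagnosis-linked differences survive harmonization", {
  # no center bias: harmonizing must not erode the case-control effect
  d <- make_batched(3, dx_effect = 1)
  cov <- data.frame(diagnosis = d$group)
  fit <- combat_fit(d$X, d$center, cov)
  H <- combat_apply(d$X, fit, d$center, cov)
  d_before <- vapply(seq_len(ncol(d$X)), function(j) {
    robust_cohen_d(d$X[d$group == "case", j], d$X[d$group == "control", j])
  }, 0)
  d_after <- vapply(seq_len(ncol(H)), function(j) {
    robust_cohen_d(H[d$group == "case", j], H[d$group == "control", j])
  }, 0)
  expect_lt(max(abs(d_after - d_before) / abs(d_before)), 0.05)
})

test_that("center F-statistics drop for essentially all features", {
  co <- simulate_cohort(sim_config(n_controls = 200, n_cases_left = 100,
                                   n_cases_right = 100, n_centers = 4,
                                   center_shift_sd = 1, center_scale_sd = 0.2,
                                   missing_rate = 0, n_heavy_missing = 0,
                                   seed = 8))
  reg <- feature_registry()
  X <- as.matrix(co$data[, reg$name])
  ctr <- co$data$center
  covs <- data.frame(age = co$data$age, sex = co$data$sex,
                     icv = co$data$icv, diagnosis = co$data$group)
  fit <- combat_fit(X, ctr, covs)
  H <- combat_apply(X, fit, ctr, covs)
  f_stat <- function(M) vapply(seq_len(ncol(M)), function(j) {
    summary(stats::aov(M[, j] ~ factor(ctr)))[[1]]$`F value`[1]
  }, 0)
  expect_gt(mean(f_stat(H) < f_stat(X)), 0.95)
})

test_that("single-center apply is the identity and refits are idempotent", {
  d <- make_batched(4, n_per = 100)
  one <- d$center == "A"
  fit1 <- combat_fit(d$X[one, ], d$center[one])
  expect_lt(max(abs(combat_apply(d$X[one, ], fit1, d$center[one]) -
                      d$X[one, ])), 1e-8)

  d2 <- make_batched(5, shift = 3)
  fitA <- combat_fit(d2$X, d2$center)
  H1 <- combat_apply(d2$X, fitA, d2$center)
  fitB <- combat_fit(H1, d2$center)
  H2 <- combat_apply(H1, fitB, d2$center)
  expect_lt(max(abs(H2 - H1)), 0.05 * stats::sd(H1))
})

test_that("errors: tiny centers, unseen labels, confounded design", {
  d <- make_batched(6, n_per = 50)
  expect_error(combat_fit(d$X[c(1:50, 51), ], d$center[c(1:50, 51)]),
               ">= 2 subjects")
  fit <- combat_fit(d$X, d$center)
  expect_error(combat_apply(d$X, fit, rep("C", nrow(d$X))), "unseen")
  expect_error(combat_fit(d$X, d$center,
                          data.frame(same_as_batch = d$center)),
               "confounded")
})

test_that("harmonized values agree with the reference ComBat implementation", {
  d <- make_batched(7, n_per = 60, p = 20, shift = 2, scale = 1.4,
                    dx_effect = 0.8)
  cov <- data.frame(diagnosis = d$group)
  fit <- combat_fit(d$X, d$center, cov)
  ours <- combat_apply(d$X, fit, d$center, cov)
  mod <- stats::model.matrix(~ diagnosis, data = cov)
  ref <- t(suppressMessages(
    sva::ComBat(t(d$X), batch = d$center, mod = mod)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})
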