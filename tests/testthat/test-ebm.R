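# The event-based model: mixtures, sequence likelihood, search, PVD, staging.

test_that("mixture components are proper densities", {
  set.seed(1)
  ctrl <- rnorm(200)
  cases <- c(rnorm(100), rnorm(100, -2.5))
  fit <- fit_mixture(ctrl, cases, direction = -1)
  grid <- seq(-8, 6, length.out = 4001)
  d <- mixture_densities(fit, grid)
  dx <- diff(grid)[1]
  expect_equal(sum(d$normal) * dx, 1, tolerance = 1e-3)
  expect_equal(sum(d$abnormal) * dx, 1, tolerance = 1e-3)
  expect_true(fit$theta >= 0.01 && fit$theta <= 0.99)
})

test_that("mixture weight recovers the abnormal fraction when separated", {
  set.seed(2)
  ctrl <- rnorm(500)
  frac <- 0.3
  cases <- c(rnorm(350), rnorm(150, -4))  # components 4 SD apart
  fit <- fit_mixture(ctrl, cases, direction = -1)
  expect_equal(fit$theta, frac, tolerance = 0.05)
})

test_that("cases drawn from the control distribution give a null fit", {
  set.seed(3)
  ctrl <- rnorm(400)
  cases <- rnorm(400)
  fit <- fit_mixture(ctrl, cases, direction = -1)
  expect_lt(fit$theta, 0.25)
  # posterior abnormality is forbidden on the healthy side of the median
  d <- mixture_densities(fit, 2)   # clearly healthy-side value
  post <- fit$theta * d$abnormal / (fit$theta * d$abnormal +
                                      (1 - fit$theta) * d$normal)
  expect_lt(post, 0.5)
})

test_that("sequence likelihood matches the hand-enumerated toy", {
  toy <- toy_two_event()
  ll_12 <- sequence_log_likelihood(toy$X, toy$fits, c(1, 2))
  ll_21 <- sequence_log_likelihood(toy$X, toy$fits, c(2, 1))
  # stages (0,1,2): (0.1*0.8 + 0.9*0.8 + 0.9*0.2)/3 and
  #                 (0.1*0.8 + 0.2*0.1 + 0.9*0.2)/3
  expect_equal(exp(ll_12), 0.98 / 3, tolerance = 1e-5)
  expect_equal(exp(ll_21), 0.28 / 3, tolerance = 1e-5)
})

test_that("likelihood is exchangeable over subjects and flat when uninformative", {
  set.seed(4)
  co <- simulate_cohort(clean_sim_config(seed = 4, n_controls = 60,
                                         n_cases = 60,
                                         ground_truth_sequence =
                                           c("hippocampus_vol", "thalamus_vol",
                                             "precuneus_thick")))
  prep <- ebm_ready(co)
  fits <- lapply(seq_len(3), function(j) {
    fit_mixture(prep$X_controls[, j], prep$X_cases[, j], prep$directions[[j]])
  })
  X <- prep$X_cases
  ll <- sequence_log_likelihood(X, fits, 1:3)
  ll_perm <- sequence_log_likelihood(X[sample(nrow(X)), ], fits, 1:3)
  expect_equal(ll, ll_perm, tolerance = 1e-12)

  # identical component densities make every ordering equally likely
  flat <- list(fixed_density_fit(0, 0.4, 0.4), fixed_density_fit(0, 0.4, 0.4),
               fixed_density_fit(0, 0.4, 0.4))
  Xf <- matrix(0, 5, 3)
  lls <- apply(all_perms(3), 1, function(S)
    sequence_log_likelihood(Xf, flat, S))
  expect_lt(diff(range(lls)), 1e-12)
})

test_that("greedy ascent handles N = 1 and solves the toy", {
  toy <- toy_two_event()
  lp <- ebmstage:::mixture_log_probs(toy$fits, toy$X)
  ga <- greedy_ascent(lp$lpE, lp$lpN, n_iter = 50, n_init = 2, seed = 1)
  expect_equal(ga$sequence, c(1L, 2L))

  one <- ebmstage:::mixture_log_probs(toy$fits[1], toy$X[, 1, drop = FALSE])
  ga1 <- greedy_ascent(one$lpE, one$lpN, seed = 1)
  expect_equal(ga1$sequence, 1L)
})

test_that("MCMC never loses the initial likelihood and explores a flat target", {
  toy <- toy_two_event()
  lp <- ebmstage:::mixture_log_probs(toy$fits, toy$X)
  mc <- mcmc_sequences(lp$lpE, lp$lpN, init = c(1L, 2L), n_samples = 500,
                       seed = 2)
  expect_gte(mc$ml_loglik, sequence_log_likelihood(toy$X, toy$fits, c(1, 2)))

  # flat likelihood: each event visits each position uniformly
  N <- 4
  lpE <- matrix(log(0.3), 20, N); lpN <- matrix(log(0.3), 20, N)
  mc2 <- mcmc_sequences(lpE, lpN, init = 1:N, n_samples = 20000, seed = 3)
  freq <- vapply(seq_len(N), function(p)
    tabulate(mc2$chain[, p], nbins = N) / nrow(mc2$chain), numeric(N))
  se3 <- 3 * sqrt(0.25 * 0.75 / 20000) + 0.02  # binomial SE + mixing slack
  expect_lt(max(abs(freq - 1 / N)), se3)
  expect_gt(mc2$acceptance_rate, 0.99)
})

test_that("search attains the exhaustive optimum on a strong 4-event problem", {
  co <- simulate_cohort(clean_sim_config(
    seed = 6, n_controls = 200, n_cases = 200,
    ground_truth_sequence = c("hippocampus_vol", "thalamus_vol",
                              "precuneus_thick", "lateralventricle_vol")))
  prep <- ebm_ready(co)
  fit <- ebm_fit(prep$X_controls, prep$X_cases, prep$directions,
                 greedy_iter = 300, greedy_init = 3, mcmc_samples = 2000,
                 seed = 6)
  oracle <- exhaustive_ml(prep$X_cases, fit$fits)
  expect_equal(fit$log_likelihood, oracle$loglik, tolerance = 1e-10)
  expect_equal(fit$sequence_idx, unname(oracle$sequence))
})

test_that("bootstrap PVD is doubly stochastic and a permutation matrix at 1 repeat", {
  co <- simulate_cohort(clean_sim_config(
    seed = 7, n_controls = 150, n_cases = 150,
    ground_truth_sequence = c("hippocampus_vol", "thalamus_vol",
                              "precuneus_thick")))
  prep <- ebm_ready(co)
  pvd1 <- bootstrap_pvd(prep$X_controls, prep$X_cases, prep$directions,
                        n_boot = 1, greedy_iter = 200, greedy_init = 2,
                        mcmc_samples = 500, seed = 7)
  expect_true(all(pvd1 %in% c(0, 1)))
  expect_equal(unname(rowSums(pvd1)), rep(1, 3))
  expect_equal(unname(colSums(pvd1)), rep(1, 3))

  pvd5 <- bootstrap_pvd(prep$X_controls, prep$X_cases, prep$directions,
                        n_boot = 5, greedy_iter = 200, greedy_init = 2,
                        mcmc_samples = 500, seed = 8)
  expect_equal(unname(rowSums(pvd5)), rep(1, 3))
  expect_equal(unname(colSums(pvd5)), rep(1, 3))
})

test_that("staging reproduces the toy and is monotone in accumulated events", {
  toy <- toy_two_event()
  st <- stage_subjects(toy$X, toy$fits, c("m1", "m2"))
  expect_equal(exp(as.numeric(st[1, c("loglik_0", "loglik_1", "loglik_2")])),
               c(0.08, 0.72, 0.18), tolerance = 1e-10)
  expect_equal(st$stage, 1L)

  set.seed(9)
  co <- simulate_cohort(clean_sim_config(seed = 9, n_controls = 300,
                                         n_cases = 300))
  prep <- ebm_ready(co)
  fits <- lapply(seq_len(7), function(j)
    fit_mixture(prep$X_controls[, j], prep$X_cases[, j], prep$directions[[j]]))
  names(fits) <- colnames(prep$X_cases)
  S <- colnames(prep$X_cases)

  # subject at the normal modes -> stage 0; at the abnormal modes -> stage N
  normal_modes <- vapply(fits, function(f)
    f$support0[which.max(kde_pdf_at(f, "normal"))], 0)
  abnormal_modes <- vapply(fits, function(f)
    f$support1[which.max(kde_pdf_at(f, "abnormal"))], 0)
  probe <- rbind(normal_modes, abnormal_modes)
  colnames(probe) <- S
  st2 <- stage_subjects(probe, fits, S)
  expect_equal(st2$stage, c(0L, 7L))

  # flipping events to abnormal one at a time in order never lowers the stage
  walk <- matrix(rep(normal_modes, 8), 8, 7, byrow = TRUE)
  for (k in 1:7) walk[(k + 1):8, k] <- abnormal_modes[k]
  colnames(walk) <- S
  st3 <- stage_subjects(walk, fits, S)
  expect_true(all(diff(st3$stage) >= 0))
})
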