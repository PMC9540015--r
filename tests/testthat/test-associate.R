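test_that("Spearman correlation handles ties as average ranks", {
  expect_equal(spearman_assoc(0:9, 0:9)$rho, 1)
  expect_equal(spearman_assoc(0:3, 3:0)$rho, -1)
  # {0,0,1,2} vs {1,2,3,4}: tied ranks (1.5,1.5,3,4) vs (1,2,3,4)
  s <- spearman_assoc(c(0, 0, 1, 2), c(1, 2, 3, 4))
  expect_equal(s$rho, 0.9487, tolerance = 1e-4)
  # oracle identity: Pearson on ranks
  set.seed(41)
  x <- sample(1:100); y <- x + rnorm(100, 0, 20)
  expect_equal(spearman_assoc(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_warning(s0 <- spearman_assoc(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s0$rho))
})

test_that("Mann-Whitney AUC equals the all-pairs estimate", {
  expect_equal(mannwhitney_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(mannwhitney_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  r <- mannwhitney_auc(c(1, 2), c(0, 3))
  expect_equal(r$U, 2)
  expect_equal(r$auc, 0.5)

  set.seed(43)
  for (i in 1:25) {
    a <- sample(0:7, sample(5:200, 1), replace = TRUE)
    b <- sample(0:7, sample(5:200, 1), replace = TRUE)
    expect_equal(mannwhitney_auc(a, b)$auc, auc_brute(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis reproduces the closed-form tie-free value", {
  expect_equal(kruskal_assoc(c(1, 1, 1, 1), rep(c("a", "b"), 2))$H, 0)
  expect_equal(kruskal_assoc(c(1, 1, 1, 1), rep(c("a", "b"), 2))$p, 1)
  # ranks 1..6: H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 3.857
  k <- kruskal_assoc(c(1, 2, 3, 4, 5, 6), rep(c("L", "R"), each = 3))
  expect_equal(k$H, 27 / 7, tolerance = 1e-10)
  expect_equal(k$df, 1)
})

test_that("stage-0 contrasts detect a duration gap and skip degenerate strata", {
  set.seed(47)
  n <- 400
  stage <- sample(0:7, n, replace = TRUE)
  stages <- data.frame(subject_id = sprintf("s%03d", 1:n), stage = stage)
  clinical <- data.frame(subject_id = stages$subject_id,
                         duration = 15 + 2 * stage + rnorm(n, 0, 5),
                         age_at_onset = 30 - stage + rnorm(n, 0, 6))
  res <- stage0_contrasts(stages, clinical)
  dur <- res$tests[res$tests$contrast == "duration_stage0_vs_non0", ]
  expect_lt(dur$p, 0.01)
  expect_lt(dur$mean_stage0, dur$mean_non0)

  all0 <- data.frame(subject_id = stages$subject_id, stage = 0L)
  res0 <- stage0_contrasts(all0, clinical)
  expect_null(res0$tests)
  expect_true(any(grepl("skipped", res0$log)))
})

test_that("stage-0 duration contrast holds its type-I error under the null", {
  set.seed(53)
  p_vals <- vapply(1:400, function(i) {
    n <- 120
    stage <- sample(0:7, n, replace = TRUE)
    stages <- data.frame(subject_id = sprintf("s%03d", 1:n), stage = stage)
    clinical <- data.frame(subject_id = stages$subject_id,
                           duration = rnorm(n, 20, 5),
                           age_at_onset = rnorm(n, 25, 8))
    res <- stage0_contrasts(stages, clinical)
    res$tests$p[res$tests$contrast == "duration_stage0_vs_non0"]
  }, 0)
  rate <- mean(p_vals < 0.05)
  expect_gt(rate, 0.017)  # 0.05 +/- 3 binomial SE at 400 replicates
  expect_lt(rate, 0.083)
})

test_that("the full association report wires every analysis together", {
  set.seed(59)
  n <- 300
  stage <- sample(0:7, n, replace = TRUE)
  ids <- sprintf("s%03d", 1:n)
  stages <- data.frame(subject_id = ids, group = "case", stage = stage)
  clinical <- data.frame(
    subject_id = ids,
    duration = 15 + 2 * stage + rnorm(n, 0, 5),
    age_at_onset = pmax(30 - stage + rnorm(n, 0, 6), 1),
    drug_resistant = runif(n) < plogis(1.4 + 0.25 * stage))
  lat <- stats::setNames(sample(c("left", "right"), n, TRUE), ids)
  rep <- associate_stages(stages, clinical, laterality = lat)
  expect_s3_class(rep, "association_report")
  rho_all <- rep$correlations$rho[rep$correlations$test == "stage_vs_duration_all"]
  expect_gt(rho_all, 0.3)
  expect_gt(rep$resistance$auc, 0.5)
  expect_true(rep$resistance$auc <= 1 && rep$resistance$auc >= 0)
  expect_gte(rep$lateralization$H, 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_association_report(rep, path)
  out <- utils::read.csv(path)
  expect_true(all(c("stage_vs_duration_all", "resistance_auc",
                    "left_vs_right_kruskal_H") %in% out$test))
})
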