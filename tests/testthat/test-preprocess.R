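test_that("missingness filter is strict at the threshold", {
  co <- simulate_cohort(clean_sim_config(seed = 1, n_controls = 30,
                                         n_cases = 30))
  reg <- feature_registry()
  df <- co$data
  df[1, reg$name[1:10]] <- NA   # exactly 10 missing: kept
  df[2, reg$name[1:11]] <- NA   # 11 missing: dropped
  fm <- filter_missing(df)
  expect_true(df$subject_id[1] %in% fm$kept$subject_id)
  expect_identical(fm$dropped$subject_id, df$subject_id[2])
  expect_true(any(grepl("11 missing", fm$log)))

  fm0 <- filter_missing(co$data)
  expect_equal(nrow(fm0$dropped), 0)
})

test_that("SVD completion recovers low-rank structure exactly", {
  set.seed(42)
  u <- rnorm(30); v <- rnorm(8)
  M <- u %*% t(v)
  M_missing <- M
  M_missing[7, 3] <- NA
  out <- impute_svd(M_missing, rank = 1, tol = 1e-12)
  expect_lt(abs(out[7, 3] - M[7, 3]), 1e-8)
  expect_identical(out[-7, ], M[-7, ])  # observed cells untouched
  expect_identical(out[7, -3], M[7, -3])

  # a complete matrix passes through unchanged
  expect_identical(unname(impute_svd(M)[, ]), unname(M))
})

test_that("imputation runs independently within centers", {
  set.seed(7)
  X <- matrix(rnorm(40 * 6), 40, 6)
  X[X > 2] <- NA
  centers <- rep(c("A", "B"), each = 20)
  # rank 2 on this small noisy block converges slowly; the comparison only
  # needs both calls to follow the identical iteration path
  joint <- suppressWarnings(impute_svd(X, center = centers, rank = 2))
  solo <- suppressWarnings(impute_svd(X[centers == "B", ], rank = 2))
  expect_equal(unname(joint[centers == "B", ]), unname(solo[, ]),
               tolerance = 1e-12)
})

test_that("ipsi/contra relabeling maps the focus hemisphere correctly", {
  co <- simulate_cohort(clean_sim_config(seed = 3, n_controls = 100,
                                         n_cases = 40))
  df <- co$data
  left_case <- which(df$laterality == "left")[1]
  right_case <- which(df$laterality == "right")[1]
  df$lh_hippocampus_vol[c(left_case, right_case)] <- 3000
  df$rh_hippocampus_vol[c(left_case, right_case)] <- 4000
  rel <- relabel_ipsi_contra(df, seed = 5)
  expect_equal(rel$data$ipsi_hippocampus_vol[left_case], 3000)
  expect_equal(rel$data$contra_hippocampus_vol[left_case], 4000)
  expect_equal(rel$data$ipsi_hippocampus_vol[right_case], 4000)
  expect_equal(rel$data$contra_hippocampus_vol[right_case], 3000)

  # seeded control split: exactly half each way, reproducibly
  side <- rel$pseudo_laterality[df$subject_id[df$group == "control"]]
  expect_equal(sum(side == "left"), 50)
  rel2 <- relabel_ipsi_contra(df, seed = 5)
  expect_identical(rel$pseudo_laterality, rel2$pseudo_laterality)
  rel3 <- relabel_ipsi_contra(df, seed = 6)
  expect_false(identical(rel$pseudo_laterality, rel3$pseudo_laterality))

  # hemisphere-role involution: mapping back reproduces the originals
  reg <- feature_registry()
  lat <- rel$pseudo_laterality[df$subject_id]
  for (pid in c("hippocampus_vol", "precuneus_thick", "hemisphere_mean_thick")) {
    lh <- reg$name[reg$pair_id == pid & reg$hemisphere == "left"]
    back <- ifelse(lat == "left", rel$data[[paste0("ipsi_", pid)]],
                   rel$data[[paste0("contra_", pid)]])
    expect_equal(unname(back), df[[lh]])
  }
})

test_that("asymmetry index matches its definition and symmetries", {
  expect_equal(compute_basi(2.5, 2.5), 0)
  expect_equal(compute_basi(1, 3), -1)
  expect_equal(compute_basi(3, 1), 1)
  expect_true(is.na(compute_basi(2, -2)))

  set.seed(99)
  i <- rlnorm(10000); c <- rlnorm(10000); k <- rlnorm(10000)
  expect_equal(compute_basi(i, c), -compute_basi(c, i), tolerance = 1e-12)
  expect_equal(compute_basi(k * i, k * c), compute_basi(i, c),
               tolerance = 1e-12)
})

test_that("analysis matrix has the 78+78+78 layout", {
  co <- simulate_cohort(clean_sim_config(seed = 4, n_controls = 40,
                                         n_cases = 40))
  am <- build_analysis_matrix(relabel_ipsi_contra(co$data, seed = 1))
  expect_equal(nrow(am$features), 234)
  expect_equal(as.integer(table(am$features$role)[c("basi", "contra", "ipsi")]),
               c(78L, 78L, 78L))
  expect_true(all(am$features$name %in% names(am$data)))
  # BASI columns are exact functions of the side columns
  expect_equal(am$data$basi_hippocampus_vol,
               compute_basi(am$data$ipsi_hippocampus_vol,
                            am$data$contra_hippocampus_vol))
})

test_that("residualization removes covariates and is idempotent", {
  set.seed(21)
  n <- 200
  cov <- data.frame(age = runif(n, 20, 60),
                    sex = sample(c("F", "M"), n, TRUE),
                    icv = rnorm(n, 1.5e6, 1e5))
  X <- cbind(pure_age = 2 * cov$age,
             indep = rnorm(n),
             mixed = 0.1 * cov$age + rnorm(n))
  adj <- residualize(X, cov)
  # exactly covariate-driven feature collapses to its intercept
  expect_lt(diff(range(adj[, "pure_age"])), 1e-9)
  # orthogonality to each covariate
  for (v in list(cov$age, as.numeric(cov$sex == "M"), cov$icv)) {
    expect_lt(abs(cor(adj[, "mixed"] - mean(adj[, "mixed"]), v)), 1e-10)
  }
  # independent feature barely moves
  expect_gt(cor(adj[, "indep"], X[, "indep"]), 0.99)
  # idempotence
  adj2 <- residualize(adj, cov)
  expect_lt(max(abs(adj2 - adj)), 1e-8)
  # constant covariate dropped with a warning
  cov2 <- cov; cov2$sex <- "F"
  expect_warning(residualize(X, cov2), "constant")
})
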