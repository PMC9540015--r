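# Synthetic multicenter cohort generator.
#
# Emulates the statistical structure the pipeline must handle: a ground-truth
# sequence of biomarker "events" (normal -> abnormal transitions applied to
# the seizure-focus hemisphere), per-center additive and multiplicative
# biases, linear age/sex/ICV effects, sparse missingness, and clinical
# variables linked to the latent disease stage. It does not simulate images,
# spatial correlation between regions, or longitudinal follow-up.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the package's canonical study conditions: cohort sizes and
#' center count mirroring a large multicenter epilepsy consortium (1625
#' controls, 446 left-lateralized and 358 right-lateralized cases across 25
#' centers), seven ground-truth events with a standardized case-control
#' separation of 2 SD, latent stages uniform over 0..N, duration of illness
#' increasing 2 years per stage from a 15-year base, and a drug-resistance
#' probability rising with stage from about 80%.
#'
#' @param n_controls,n_cases_left,n_cases_right group sizes.
#' @param n_centers number of acquisition centers (uniform assignment).
#' @param ground_truth_sequence character vector of pair identifiers from
#'   [feature_registry()] giving the true event order.
#' @param stage_distribution probability vector over latent stages `0..N`
#'   (`N = length(ground_truth_sequence)`); must sum to 1.
#' @param effect_size standardized mean separation between the normal and
#'   abnormal component of each event feature (SD units, > 0).
#' @param center_shift_sd,center_scale_sd dispersion of per-center additive
#'   shifts (SD units) and of log multiplicative scales.
#' @param beta_age,beta_icv,beta_sex covariate slopes in feature-SD units per
#'   standardized covariate (sex: male indicator).
#' @param missing_rate completely-at-random missingness fraction in `[0, 1)`.
#' @param n_heavy_missing number of subjects forced to carry more than 10
#'   missing values, to exercise the exclusion filter.
#' @param duration_base,duration_slope,duration_sd duration of illness model:
#'   `base + slope * stage + N(0, sd)` years, truncated at 0.5.
#' @param resistance_logit_intercept,resistance_logit_slope drug-resistance
#'   model: `P(resistant) = plogis(intercept + slope * stage)`.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_controls = 1625,
                       n_cases_left = 446,
                       n_cases_right = 358,
                       n_centers = 25,
                       ground_truth_sequence = c(
                         "hippocampus_vol", "superiorparietal_thick",
                         "precuneus_thick", "supramarginal_thick",
                         "superiorfrontal_thick", "thalamus_vol",
                         "lateralventricle_vol"),
                       stage_distribution = NULL,
                       effect_size = 2.0,
                       center_shift_sd = 0.3,
                       center_scale_sd = 0.1,
                       beta_age = -0.3,
                       beta_icv = 0.4,
                       beta_sex = 0.2,
                       missing_rate = 0.0002,
                       n_heavy_missing = 2,
                       duration_base = 15,
                       duration_slope = 2,
                       duration_sd = 5,
                       resistance_logit_intercept = 1.4,
                       resistance_logit_slope = 0.25,
                       seed = 1L) {
  reg <- feature_registry()
  if (!all(ground_truth_sequence %in% reg$pair_id)) {
    stop("ground_truth_sequence must contain pair identifiers from feature_registry()")
  }
  if (anyDuplicated(ground_truth_sequence)) {
    stop("ground_truth_sequence must be a permutation (no duplicates)")
  }
  n_events <- length(ground_truth_sequence)
  if (is.null(stage_distribution)) {
    stage_distribution <- rep(1 / (n_events + 1), n_events + 1)
  }
  if (length(stage_distribution) != n_events + 1) {
    stop("stage_distribution must have length N + 1 (stages 0..N)")
  }
  if (any(stage_distribution < 0) || abs(sum(stage_distribution) - 1) > 1e-8) {
    stop("stage_distribution must be a probability vector summing to 1")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multicenter cross-sectional cohort
#'
#' Draws a latent stage for every case from `stage_distribution`; features
#' whose pair occupies positions `1..stage` of the ground-truth sequence are
#' drawn from the abnormal component *on the seizure-focus hemisphere only*.
#' Controls draw every feature from the normal component. Covariate effects,
#' per-center location/scale biases, missingness, and stage-linked clinical
#' variables are then layered on top. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: list with `data` (wide
#'   subject-by-feature data.frame), `clinical` (cases only: `age_at_onset`,
#'   `duration`, `drug_resistant`), and `truth` (per-subject latent stage and
#'   laterality, the ground-truth sequence, per-center bias parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reg <- feature_registry()
  base <- .feature_baselines(reg)
  p <- nrow(reg)
  n_events <- length(config$ground_truth_sequence)

  n <- config$n_controls + config$n_cases_left + config$n_cases_right
  group <- c(rep("control", config$n_controls),
             rep("case", config$n_cases_left + config$n_cases_right))
  laterality <- c(rep("none", config$n_controls),
                  rep("left", config$n_cases_left),
                  rep("right", config$n_cases_right))
  subject_id <- sprintf("sub-%05d", seq_len(n))
  center <- paste0("center", sprintf("%02d",
                   sample.int(config$n_centers, n, replace = TRUE)))

  age <- pmin(pmax(stats::rnorm(n, 35, 12), 18), 70)
  sex <- ifelse(stats::runif(n) < 0.56, "F", "M")
  icv <- stats::rnorm(n, 1.5e6, 1.5e5) + ifelse(sex == "M", 1e5, 0)

  stage <- integer(n)
  is_case <- group == "case"
  stage[is_case] <- sample(0:n_events, sum(is_case), replace = TRUE,
                           prob = config$stage_distribution)

  # per-center, per-feature biases (ComBat's generative model)
  centers <- paste0("center", sprintf("%02d", seq_len(config$n_centers)))
  gamma <- matrix(stats::rnorm(config$n_centers * p, 0, config$center_shift_sd),
                  config$n_centers, p, dimnames = list(centers, reg$name))
  delta <- matrix(exp(stats::rnorm(config$n_centers * p, 0, config$center_scale_sd)),
                  config$n_centers, p, dimnames = list(centers, reg$name))

  # abnormality indicator: subject x feature
  event_pos <- match(reg$pair_id, config$ground_truth_sequence)  # NA if no event
  z_age <- (age - 35) / 12
  z_icv <- (icv - 1.55e6) / 1.5e5
  male <- as.numeric(sex == "M")

  eps <- matrix(stats::rnorm(n * p), n, p)
  shift <- matrix(0, n, p)
  for (j in which(!is.na(event_pos))) {
    hit <- is_case & stage >= event_pos[j] & laterality == reg$hemisphere[j]
    shift[hit, j] <- reg$direction[j] * config$effect_size
  }
  cov_eff <- outer(z_age, rep(config$beta_age, p)) +
    outer(z_icv, rep(config$beta_icv, p)) +
    outer(male, rep(config$beta_sex, p))
  ci <- match(center, centers)
  std <- cov_eff + gamma[ci, , drop = FALSE] +
    delta[ci, , drop = FALSE] * (eps + shift)
  X <- sweep(sweep(std, 2, base$sd, "*"), 2, base$mu, "+")
  dimnames(X) <- list(NULL, reg$name)

  # missingness: MCAR plus a handful of heavy-missing subjects
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    X[mask] <- NA_real_
  }
  if (config$n_heavy_missing > 0) {
    heavy <- sample.int(n, min(config$n_heavy_missing, n))
    for (s in heavy) {
      k <- sample(11:15, 1)
      X[s, sample.int(p, k)] <- NA_real_
    }
  }

  data <- data.frame(subject_id = subject_id, center = center, group = group,
                     laterality = laterality, age = age, sex = sex, icv = icv,
                     stringsAsFactors = FALSE)
  data <- cbind(data, as.data.frame(X))

  # clinical variables for cases, linked to the latent stage
  ncase <- sum(is_case)
  duration <- pmax(config$duration_base +
                     config$duration_slope * stage[is_case] +
                     stats::rnorm(ncase, 0, config$duration_sd), 0.5)
  onset <- pmax(age[is_case] - duration, 1)
  p_res <- stats::plogis(config$resistance_logit_intercept +
                           config$resistance_logit_slope * stage[is_case])
  resistant <- stats::runif(ncase) < p_res
  clinical <- data.frame(subject_id = subject_id[is_case],
                         age_at_onset = onset, duration = duration,
                         drug_resistant = resistant, stringsAsFactors = FALSE)

  truth <- list(
    stage = stats::setNames(stage, subject_id),
    laterality = stats::setNames(laterality, subject_id),
    sequence = config$ground_truth_sequence,
    center_shift = gamma,
    center_scale = delta,
    config = config
  )
  structure(list(data = data, clinical = clinical, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$data$group)
  cat("Synthetic cohort:", nrow(x$data), "subjects (",
      tab[["control"]], "controls,", sum(x$data$group == "case"), "cases ),",
      length(unique(x$data$center)), "centers,",
      length(x$truth$sequence), "ground-truth events\n")
  invisible(x)
}
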