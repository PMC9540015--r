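# Stage-clinical association statistics: rank correlations with duration of
# illness and age at onset, drug-resistance discrimination (Mann-Whitney U /
# AUC), left-vs-right stage comparison (Kruskal-Wallis), and the Stage-0
# versus non-0 contrasts. No multiple-testing correction is applied across
# these tests (documented; they are reported individually).

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p via the asymptotic t approximation
#' (as in `cor.test`).
#'
#' @param x,y paired numeric vectors (pairs with any NA are dropped;
#'   n >= 3 required).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U with AUC
#'
#' `U` counts pairs in which `group_a` exceeds `group_b` (ties count 0.5),
#' so `AUC = U / (n_a * n_b)` is the probability that a random member of
#' `group_a` outranks a random member of `group_b`. p-value from the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors (the "positive" group first; for
#'   drug-response analyses this is the resistant group).
#' @return list with `U`, `auc`, `p`, `n_a`, `n_b`.
#' @export
mannwhitney_auc <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = FALSE,
                                            correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, auc = U / (length(group_a) * length(group_b)), p = wt$p.value,
       n_a = length(group_a), n_b = length(group_b))
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H with a chi-square p-value on `groups - 1` degrees of
#' freedom. When every value is identical across groups, `H = 0`, `p = 1`.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 nonempty groups).
#' @return list with `H`, `df`, `p`, `n`.
#' @export
kruskal_assoc <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 nonempty groups")
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1, n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       n = length(values))
}

#' Stage-0 versus later-stage contrasts
#'
#' Splits staged cases at stage 0 vs stage >= 1 and reports two-sample
#' t-tests (Welch by default) for duration of illness, age at onset, and
#' ipsilateral hippocampal volume, plus robust effect sizes of hippocampal
#' volume against controls within stage strata (stage 0, non-0; and for the
#' contralateral hippocampus: stages 1-2 and 3-N). A stratum with fewer
#' than 2 subjects skips its contrast (logged).
#'
#' @param stages `stage_assignment` rows for cases (must contain
#'   `subject_id` and `stage`).
#' @param clinical clinical data.frame (`subject_id`, `duration`,
#'   `age_at_onset`).
#' @param hippo_ipsi,hippo_contra named numeric vectors of (adjusted)
#'   hippocampal volume per subject (names = subject_id) covering cases and
#'   controls; `control_ids` marks which belong to controls.
#' @param control_ids character vector of control subject IDs.
#' @param var_equal use the pooled-variance classical t-test instead of
#'   Welch.
#' @return list with `tests` (data.frame of contrasts), `effects`
#'   (data.frame of stratified robust d), and `log`.
#' @export
stage0_contrasts <- function(stages, clinical, hippo_ipsi = NULL,
                             hippo_contra = NULL, control_ids = NULL,
                             var_equal = FALSE) {
  log <- character(0)
  m <- merge(stages[, c("subject_id", "stage")], clinical, by = "subject_id")
  zero <- m$stage == 0
  tests <- list()
  run_t <- function(v0, v1, label) {
    if (sum(!is.na(v0)) < 2 || sum(!is.na(v1)) < 2) {
      log <<- log_event(log, "contrast %s skipped: stratum with n < 2", label)
      return(NULL)
    }
    tt <- stats::t.test(v0, v1, var.equal = var_equal)
    data.frame(contrast = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_stage0 = mean(v0, na.rm = TRUE),
               mean_non0 = mean(v1, na.rm = TRUE),
               n_stage0 = sum(!is.na(v0)), n_non0 = sum(!is.na(v1)))
  }
  tests$duration <- run_t(m$duration[zero], m$duration[!zero],
                          "duration_stage0_vs_non0")
  tests$onset <- run_t(m$age_at_onset[zero], m$age_at_onset[!zero],
                       "onset_stage0_vs_non0")

  effects <- NULL
  if (!is.null(hippo_ipsi)) {
    hi0 <- hippo_ipsi[m$subject_id[zero]]
    hi1 <- hippo_ipsi[m$subject_id[!zero]]
    tests$hippo <- run_t(hi0, hi1, "ipsi_hippocampus_stage0_vs_non0")
    ctrl <- hippo_ipsi[intersect(names(hippo_ipsi), control_ids)]
    eff <- list()
    strat_d <- function(v, label, side) {
      if (sum(!is.na(v)) < 2 || length(ctrl_side) < 2) {
        log <<- log_event(log, "effect %s skipped: stratum with n < 2", label)
        return(NULL)
      }
      data.frame(stratum = label, side = side,
                 d = suppressWarnings(robust_cohen_d(v, ctrl_side)),
                 n_cases = sum(!is.na(v)))
    }
    ctrl_side <- ctrl
    eff$a <- strat_d(hi0, "stage0", "ipsi")
    eff$b <- strat_d(hi1, "non0", "ipsi")
    if (!is.null(hippo_contra)) {
      ctrl_side <- hippo_contra[intersect(names(hippo_contra), control_ids)]
      lo <- m$stage >= 1 & m$stage <= 2
      hi <- m$stage >= 3
      eff$c <- strat_d(hippo_contra[m$subject_id[zero]], "stage0", "contra")
      eff$d <- strat_d(hippo_contra[m$subject_id[lo]], "stage1_2", "contra")
      eff$e <- strat_d(hippo_contra[m$subject_id[hi]], "stage3_N", "contra")
    }
    effects <- do.call(rbind, Filter(Negate(is.null), eff))
  }
  list(tests = do.call(rbind, Filter(Negate(is.null), tests)),
       effects = effects, log = log)
}

#' Full stage-clinical association report
#'
#' Runs every association analysis on staged cases: Spearman correlations
#' of stage with duration and age at onset (all cases and restricted to
#' stages >= 1), the resistant-vs-responsive Mann-Whitney/AUC, the
#' left-vs-right Kruskal-Wallis, and the Stage-0 contrasts.
#'
#' @param stages `stage_assignment` data.frame for cases.
#' @param clinical clinical data.frame.
#' @param laterality named character vector (left/right) per case.
#' @param ... passed to [stage0_contrasts()] (`hippo_ipsi`, `hippo_contra`,
#'   `control_ids`, `var_equal`).
#' @return list of class `association_report`: `correlations`,
#'   `resistance`, `lateralization`, `stage0`, `log`.
#' @export
associate_stages <- function(stages, clinical, laterality = NULL, ...) {
  m <- merge(stages[, c("subject_id", "stage")], clinical, by = "subject_id")
  nz <- m$stage >= 1
  corr <- function(v, label, sub) {
    s <- spearman_assoc(m$stage[sub], v[sub])
    data.frame(test = label, rho = s$rho, p = s$p, n = s$n)
  }
  correlations <- rbind(
    corr(m$duration, "stage_vs_duration_all", rep(TRUE, nrow(m))),
    corr(m$duration, "stage_vs_duration_nonzero", nz),
    corr(m$age_at_onset, "stage_vs_onset_all", rep(TRUE, nrow(m))),
    corr(m$age_at_onset, "stage_vs_onset_nonzero", nz)
  )
  res <- NULL
  if (!is.null(m$drug_resistant) && any(m$drug_resistant, na.rm = TRUE) &&
      any(!m$drug_resistant, na.rm = TRUE)) {
    res <- mannwhitney_auc(m$stage[m$drug_resistant %in% TRUE],
                           m$stage[m$drug_resistant %in% FALSE])
  }
  lat <- NULL
  if (!is.null(laterality)) {
    side <- laterality[m$subject_id]
    lat <- kruskal_assoc(m$stage, side)
  }
  s0 <- stage0_contrasts(stages, clinical, ...)
  structure(list(correlations = correlations, resistance = res,
                 lateralization = lat, stage0 = s0,
                 log = s0$log), class = "association_report")
}

#' Write an association report as a flat CSV
#'
#' One row per test: name, statistic, p, n.
#'
#' @param report an [associate_stages()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(report, path) {
  rows <- list()
  for (i in seq_len(nrow(report$correlations))) {
    r <- report$correlations[i, ]
    rows[[length(rows) + 1]] <- data.frame(test = r$test, statistic = r$rho,
                                           p = r$p, n = r$n)
  }
  if (!is.null(report$resistance)) {
    rows[[length(rows) + 1]] <- data.frame(
      test = "resistance_auc", statistic = report$resistance$auc,
      p = report$resistance$p,
      n = report$resistance$n_a + report$resistance$n_b)
  }
  if (!is.null(report$lateralization)) {
    rows[[length(rows) + 1]] <- data.frame(
      test = "left_vs_right_kruskal_H", statistic = report$lateralization$H,
      p = report$lateralization$p, n = report$lateralization$n)
  }
  if (!is.null(report$stage0$tests)) {
    for (i in seq_len(nrow(report$stage0$tests))) {
      r <- report$stage0$tests[i, ]
      rows[[length(rows) + 1]] <- data.frame(
        test = r$contrast, statistic = r$t, p = r$p,
        n = r$n_stage0 + r$n_non0)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
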