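# End-to-end orchestration: filter -> impute -> harmonize -> residualize ->
# relabel -> asymmetry -> select -> EBM fit -> stage -> associate, with a
# run manifest and a structured log of every filtering decision.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter, overridable by a YAML file or a
#' partial list. Search settings default to the full-scale fit (10 random
#' greedy initializations of 10000 iterations, 500000 MCMC samples, 100
#' bootstrap repeats with shortened per-replicate chains).
#'
#' @param ... named overrides, e.g. `ebm = list(mcmc_samples = 50000)`
#'   (merged recursively).
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(cohort = NULL, clinical = NULL),
    filter = list(max_missing = 10),
    impute = list(rank = 5, tol = 1e-6, max_iter = 500),
    combat = list(parametric = TRUE, tol = 1e-4, max_iter = 100),
    residualize = list(fit_on = "all"),
    split = list(seed = 42),
    basi = list(order = "after_adjust"),
    select = list(threshold = 0.5, mad_center = "median"),
    ebm = list(greedy_iter = 10000, greedy_init = 10,
               mcmc_samples = 500000, likelihood_subjects = "cases",
               bootstrap_repeats = 100, bootstrap_mcmc = 10000,
               bootstrap_greedy_iter = 2000, bootstrap_greedy_init = 4,
               min_n = 20, seed = 1),
    associate = list(var_equal = FALSE),
    out = list(dir = "ebm_results", render = FALSE)
  )
  modify_list_deep(cfg, list(...))
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' @param x `NULL` (defaults), a YAML file path, or a partial list of
#'   overrides.
#' @return full configuration list.
#' @export
load_config <- function(x = NULL) {
  if (is.null(x)) return(default_config())
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("config file not found: ", x)
    return(do.call(default_config, yaml::read_yaml(x)))
  }
  if (is.list(x)) return(do.call(default_config, x))
  stop("config must be NULL, a file path, or a list")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in the fixed order (missingness filter, within-center
#' SVD imputation, ComBat harmonization, covariate residualization,
#' ipsi/contra relabeling with the seeded control split, asymmetry indices,
#' robust effect-size selection, event-based model fit, bootstrap PVD,
#' staging, stage-clinical associations) and writes all artifacts plus a run
#' manifest to `config$out$dir`. Fully deterministic given the input files,
#' configuration, and seeds.
#'
#' @param config see [load_config()].
#' @param cohort optional in-memory cohort data.frame (otherwise read from
#'   `config$input$cohort`).
#' @param clinical optional in-memory clinical data.frame.
#' @return invisible list with all intermediate and final objects
#'   (`selected`, `ebm`, `pvd`, `stages`, `associations`, `manifest`, ...).
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, clinical = NULL) {
  cfg <- load_config(config)
  t0 <- Sys.time()
  log <- character(0)
  reg <- feature_registry()

  if (is.null(cohort)) {
    if (is.null(cfg$input$cohort)) stop("[stage: input] no cohort supplied")
    cohort <- with_stage("input", read_cohort(cfg$input$cohort))
  } else {
    with_stage("input", validate_cohort(cohort))
  }
  if (is.null(clinical) && !is.null(cfg$input$clinical)) {
    clinical <- with_stage("input", read_clinical(cfg$input$clinical))
  }
  n_input <- nrow(cohort)

  fm <- with_stage("filter", filter_missing(cohort, cfg$filter$max_missing))
  log <- c(log, fm$log)
  cohort <- fm$kept

  X <- as.matrix(cohort[, reg$name])
  X <- with_stage("impute", impute_svd(X, center = cohort$center,
                                       rank = cfg$impute$rank,
                                       tol = cfg$impute$tol,
                                       max_iter = cfg$impute$max_iter))
  log <- log_event(log, "imputation converged: %s", attr(X, "converged"))

  diagnosis <- ifelse(cohort$group == "control", "control",
                      paste0("case_", cohort$laterality))
  covs <- data.frame(age = cohort$age, sex = cohort$sex, icv = cohort$icv,
                     diagnosis = diagnosis)
  cb <- with_stage("harmonize", combat_fit(X, cohort$center, covs,
                                           tol = cfg$combat$tol,
                                           max_iter = cfg$combat$max_iter))
  X <- with_stage("harmonize", combat_apply(X, cb, cohort$center, covs))
  log <- log_event(log, "harmonized %d features across %d centers",
                   ncol(X), length(cb$batches))

  X <- with_stage("residualize",
                  residualize(X, cohort[, c("age", "sex", "icv")],
                              fit_on = cfg$residualize$fit_on,
                              group = cohort$group))
  adj <- cohort
  adj[, reg$name] <- X

  rel <- with_stage("relabel", relabel_ipsi_contra(adj, cfg$split$seed))
  am <- with_stage("basi", build_analysis_matrix(rel))
  log <- c(log, am$log)

  tab <- with_stage("select", effect_table(am, mad_center = cfg$select$mad_center))
  selected <- with_stage("select", select_features(tab, cfg$select$threshold))
  log <- log_event(log, "selected %d of %d features at |d| >= %.2f",
                   nrow(selected), nrow(tab), cfg$select$threshold)

  feats <- selected$feature
  dirs <- stats::setNames(selected$direction, feats)
  is_case <- am$data$group == "case"
  Xc <- as.matrix(am$data[!is_case, feats, drop = FALSE])
  Xp <- as.matrix(am$data[is_case, feats, drop = FALSE])
  rownames(Xc) <- am$data$subject_id[!is_case]
  rownames(Xp) <- am$data$subject_id[is_case]

  e <- cfg$ebm
  fit <- with_stage("ebm", ebm_fit(Xc, Xp, dirs,
                                   greedy_iter = e$greedy_iter,
                                   greedy_init = e$greedy_init,
                                   mcmc_samples = e$mcmc_samples,
                                   likelihood_subjects = e$likelihood_subjects,
                                   seed = e$seed, min_n = e$min_n))
  pvd <- with_stage("ebm", bootstrap_pvd(Xc, Xp, dirs,
                                         n_boot = e$bootstrap_repeats,
                                         greedy_iter = e$bootstrap_greedy_iter,
                                         greedy_init = e$bootstrap_greedy_init,
                                         mcmc_samples = e$bootstrap_mcmc,
                                         seed = e$seed, min_n = e$min_n))
  log <- c(log, attr(pvd, "log"))

  Xall <- rbind(Xp, Xc)
  grp <- c(rep("case", nrow(Xp)), rep("control", nrow(Xc)))
  stages <- with_stage("stage", stage_subjects(Xall, fit$fits, fit$sequence,
                                               group = grp))

  assoc <- NULL
  if (!is.null(clinical)) {
    hip_i <- stats::setNames(am$data$ipsi_hippocampus_vol, am$data$subject_id)
    hip_c <- stats::setNames(am$data$contra_hippocampus_vol, am$data$subject_id)
    lat <- stats::setNames(adj$laterality, adj$subject_id)
    assoc <- with_stage("associate",
      associate_stages(stages[stages$group == "case", ], clinical,
                       laterality = lat, hippo_ipsi = hip_i,
                       hippo_contra = hip_c,
                       control_ids = adj$subject_id[adj$group == "control"],
                       var_equal = cfg$associate$var_equal))
    log <- c(log, assoc$log)
  }

  out_dir <- cfg$out$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(fit, pvd, stages, out_dir)
  mix <- data.frame(feature = names(fit$fits),
                    theta = vapply(fit$fits, function(f) f$theta, 0),
                    bw_normal = vapply(fit$fits, function(f) f$bw0, 0),
                    bw_abnormal = vapply(fit$fits, function(f) f$bw1, 0),
                    converged = vapply(fit$fits, function(f) f$converged, TRUE))
  utils::write.csv(mix, file.path(out_dir, "mixtures.csv"), row.names = FALSE)
  utils::write.csv(tab, file.path(out_dir, "effect_table.csv"),
                   row.names = FALSE)
  mcmc_pvd_out <- data.frame(event = rownames(fit$mcmc_pvd), fit$mcmc_pvd,
                             check.names = FALSE)
  utils::write.csv(mcmc_pvd_out, file.path(out_dir, "pvd_mcmc.csv"),
                   row.names = FALSE)
  if (!is.null(assoc)) {
    write_association_report(assoc, file.path(out_dir, "associations.csv"))
  }
  write_feature_registry(file.path(out_dir, "feature_registry.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ebmstage")),
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    config = cfg,
    seeds = list(split = cfg$split$seed, ebm = cfg$ebm$seed),
    input_hashes = if (is.character(cfg$input$cohort))
      as.list(tools::md5sum(unlist(cfg$input[!vapply(cfg$input, is.null, TRUE)])))
      else NULL,
    counts = list(input = n_input, kept = nrow(cohort),
                  dropped = n_input - nrow(cohort),
                  cases = sum(grp == "case"), controls = sum(grp == "control"),
                  features_selected = nrow(selected))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  writeLines(log, file.path(out_dir, "run.log"))

  invisible(list(cohort = adj, analysis = am, effect_table = tab,
                 selected = selected, ebm = fit, pvd = pvd, stages = stages,
                 associations = assoc, manifest = manifest, log = log,
                 out_dir = out_dir))
}

#' Render summary tables (and optionally figures) from a completed run
#'
#' Always writes the tabular summaries: a stage histogram by group
#' (`stage_histogram.csv`) and the distribution of duration of illness per
#' stage (`duration_by_stage.csv`, if a clinical table is given). With
#' `render = TRUE` additionally draws a PVD heatmap to `pvd_heatmap.png`.
#'
#' @param dir results directory from [run_pipeline()].
#' @param clinical optional clinical data.frame for the duration table.
#' @param render draw the PNG heatmap (default `FALSE`).
#' @return invisible list with `histogram` and `duration_by_stage`.
#' @export
render_report <- function(dir, clinical = NULL, render = FALSE) {
  stages_path <- file.path(dir, "stages.csv")
  if (!file.exists(stages_path)) stop("missing artifact: ", stages_path)
  stages <- read_stages(stages_path)
  n_events <- sum(grepl("^loglik_", names(stages))) - 1L
  hist <- as.data.frame(table(stage = factor(stages$stage, levels = 0:n_events),
                              group = stages$group))
  names(hist)[3] <- "count"
  utils::write.csv(hist, file.path(dir, "stage_histogram.csv"),
                   row.names = FALSE)
  dur <- NULL
  if (!is.null(clinical)) {
    m <- merge(stages[, c("subject_id", "stage")], clinical, by = "subject_id")
    dur <- do.call(rbind, lapply(split(m$duration, m$stage), function(v) {
      data.frame(n = length(v), mean = mean(v), median = stats::median(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 q75 = unname(stats::quantile(v, 0.75)))
    }))
    dur <- cbind(stage = as.integer(rownames(dur)), dur)
    utils::write.csv(dur, file.path(dir, "duration_by_stage.csv"),
                     row.names = FALSE)
  }
  if (render) {
    pvd_path <- file.path(dir, "pvd.csv")
    if (file.exists(pvd_path)) {
      pvd <- utils::read.csv(pvd_path, check.names = FALSE)
      m <- as.matrix(pvd[, -1])
      grDevices::png(file.path(dir, "pvd_heatmap.png"), width = 720,
                     height = 540)
      graphics::par(mar = c(4, 12, 2, 1))
      graphics::image(t(m[rev(seq_len(nrow(m))), ]),
                      col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                      axes = FALSE, main = "Positional variance diagram")
      graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                     labels = seq_len(ncol(m)))
      graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                     labels = rev(pvd[[1]]), las = 2, cex.axis = 0.7)
      grDevices::dev.off()
    }
  }
  invisible(list(histogram = hist, duration_by_stage = dur))
}
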