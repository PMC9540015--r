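# Shared fixtures, all generated in code.

# Small multicenter cohort with every nuisance term active.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_controls = 120, n_cases_left = 60, n_cases_right = 60,
             n_centers = 3, missing_rate = 0.001, n_heavy_missing = 1,
             seed = seed, ...)
}

# Bias-free single-center cohort: the canonical conditions for testing the
# event-based model itself.
clean_sim_config <- function(seed = 1L, n_controls = 500, n_cases = 500, ...) {
  sim_config(n_controls = n_controls, n_cases_left = ceiling(n_cases / 2),
             n_cases_right = floor(n_cases / 2), n_centers = 1,
             center_shift_sd = 0, center_scale_sd = 0,
             beta_age = 0, beta_icv = 0, beta_sex = 0,
             missing_rate = 0, n_heavy_missing = 0, seed = seed, ...)
}

# Biomarker matrices (ipsilateral event features) + truth, ready for ebm_fit.
ebm_ready <- function(cohort, split_seed = 1L) {
  cfg <- cohort$truth$config
  rel <- relabel_ipsi_contra(cohort$data, seed = split_seed)
  feats <- paste0("ipsi_", cfg$ground_truth_sequence)
  reg <- feature_registry()
  dirs <- stats::setNames(
    reg$direction[match(cfg$ground_truth_sequence, reg$pair_id)], feats)
  is_case <- rel$data$group == "case"
  Xc <- as.matrix(rel$data[!is_case, feats, drop = FALSE])
  Xp <- as.matrix(rel$data[is_case, feats, drop = FALSE])
  rownames(Xc) <- rel$data$subject_id[!is_case]
  rownames(Xp) <- rel$data$subject_id[is_case]
  list(X_controls = Xc, X_cases = Xp, directions = dirs, truth = feats,
       latent_stage = cohort$truth$stage)
}

# A "mixture fit" whose component densities take prescribed values at x0:
# a single-support-point Gaussian KDE centred at x0 has density
# 1 / (bw * sqrt(2*pi)) there, so the bandwidth pins the density exactly.
fixed_density_fit <- function(x0, p_normal, p_abnormal, direction = -1) {
  structure(list(
    support0 = x0, w0 = 1, bw0 = 1 / (sqrt(2 * pi) * p_normal),
    support1 = x0, w1 = 1, bw1 = 1 / (sqrt(2 * pi) * p_abnormal),
    theta = 0.5, direction = direction, iterations = 0L,
    converged = TRUE, degenerate = FALSE), class = "kde_mixture_fit")
}

# Toy two-biomarker problem used throughout: one subject at x = 0 with
# p(x1|E) = 0.9, p(x1|!E) = 0.1, p(x2|E) = 0.2, p(x2|!E) = 0.8.
toy_two_event <- function() {
  fits <- list(m1 = fixed_density_fit(0, 0.1, 0.9),
               m2 = fixed_density_fit(0, 0.8, 0.2))
  X <- matrix(0, 1, 2, dimnames = list("s1", c("m1", "m2")))
  list(X = X, fits = fits)
}

# Exhaustive maximum-likelihood sequence (oracle for small N).
exhaustive_ml <- function(X, fits) {
  N <- ncol(X)
  perms <- all_perms(N)
  ll <- apply(perms, 1, function(S) sequence_log_likelihood(X, fits, S))
  list(sequence = perms[which.max(ll), ], loglik = max(ll), all = ll)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Component density evaluated at the component's own support points
# (used to locate a component's mode).
kde_pdf_at <- function(fit, comp) {
  if (comp == "normal") {
    ebmstage:::kde_pdf(fit$support0, fit$support0, fit$bw0, fit$w0)
  } else {
    ebmstage:::kde_pdf(fit$support1, fit$support1, fit$bw1, fit$w1)
  }
}

# All-pairs AUC oracle (ties count one half).
auc_brute <- function(a, b) {
  s <- 0
  for (x in a) s <- s + sum(x > b) + 0.5 * sum(x == b)
  s / (length(a) * length(b))
}
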