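# The event-based model proper: stage-marginalized sequence likelihood,
# greedy-ascent initialization, Metropolis MCMC over permutations, bootstrap
# positional variance diagrams, and per-subject staging.
#
# Model: all patients traverse one fixed ordering S of N biomarker events.
# A subject at stage k has events S(1)..S(k) abnormal and the rest normal.
# With a uniform prior over stages 0..N, the data likelihood of subject j is
#   P(x_j | S) = 1/(N+1) * sum_k  prod_{i<=k} p(x_{j,S(i)} | E)
#                               * prod_{i>k}  p(x_{j,S(i)} | not E).

# Closure returning the log-likelihood of any permutation, precomputing what
# does not depend on the ordering. The stage cumulative sums are done with
# one (subjects x N) %*% (N x N upper-triangular) product so the MCMC inner
# loop stays in BLAS.
make_seq_loglik <- function(lpE, lpN) {
  D <- unname(lpE - lpN)
  base <- rowSums(lpN)
  n <- nrow(D); N <- ncol(D)
  U <- upper.tri(matrix(0, N, N), diag = TRUE) * 1
  sum_base <- sum(base)
  const <- sum_base - n * log(N + 1)
  rows <- seq_len(n)
  # log-sum-exp over stages {0, cd_1, .., cd_N}: this closure runs ~150k
  # times inside greedy ascent + MCMC, so it sticks to max.col/.rowSums and
  # whole-matrix exp() rather than generic pmax/rowSums dispatch.
  function(S) {
    cd <- D[, S, drop = FALSE] %*% U
    mx <- cd[cbind(rows, max.col(cd, ties.method = "first"))]
    mx <- mx * (mx > 0)  # the stage-0 term is exp(0)
    s <- exp(-mx) + .rowSums(exp(cd - mx), n, N)
    const + sum(mx) + sum(log(s))
  }
}

#' Log-likelihood of an event sequence
#'
#' Stage-marginalized likelihood of the data under ordering `S`, with a
#' uniform prior over stages 0..N and log-sum-exp accumulation.
#'
#' @param X numeric matrix (subjects x N biomarkers), complete; columns in
#'   the same order as `fits`.
#' @param fits list of [fit_mixture()] objects, one per biomarker.
#' @param S integer permutation of `1..N` (or biomarker names matching
#'   `colnames(X)`).
#' @return scalar log-likelihood.
#' @export
sequence_log_likelihood <- function(X, fits, S) {
  if (is.character(S)) S <- match(S, colnames(X))
  stopifnot(!anyNA(S), length(S) == ncol(as.matrix(X)))
  lp <- mixture_log_probs(fits, X)
  make_seq_loglik(lp$lpE, lp$lpN)(as.integer(S))
}

#' Greedy-ascent search for a high-likelihood sequence
#'
#' From each of `n_init` random starting permutations, proposes `n_iter`
#' transpositions of two uniformly chosen positions, accepting only strict
#' likelihood increases; returns the best sequence across initializations.
#' Deterministic given `seed`.
#'
#' @param lpE,lpN log density matrices from the fitted mixtures
#'   (subjects x N).
#' @param n_iter proposals per initialization (default 10000).
#' @param n_init number of random initializations (default 10).
#' @param seed integer seed.
#' @return list with `sequence` (integer permutation), `log_likelihood`,
#'   and `init_loglik` (best value per initialization).
#' @export
greedy_ascent <- function(lpE, lpN, n_iter = 10000, n_init = 10, seed = 1L) {
  N <- ncol(lpE)
  ll_fun <- make_seq_loglik(lpE, lpN)
  if (N == 1L) {
    return(list(sequence = 1L, log_likelihood = ll_fun(1L),
                init_loglik = ll_fun(1L)))
  }
  set.seed(derive_seed(seed, 17L))
  best_S <- NULL; best_ll <- -Inf
  init_ll <- numeric(n_init)
  for (i in seq_len(n_init)) {
    S <- sample.int(N)
    ll <- ll_fun(S)
    for (it in seq_len(n_iter)) {
      sw <- sample.int(N, 2L)
      S2 <- S
      S2[sw] <- S2[rev(sw)]
      ll2 <- ll_fun(S2)
      if (ll2 > ll) { S <- S2; ll <- ll2 }
    }
    init_ll[i] <- ll
    if (ll > best_ll) { best_ll <- ll; best_S <- S }
  }
  list(sequence = best_S, log_likelihood = best_ll, init_loglik = init_ll)
}

#' Metropolis MCMC over event sequences
#'
#' Symmetric transposition proposals accepted with probability
#' `min(1, exp(delta logL))`; every sample is recorded. Returns the chain
#' and the maximum-likelihood sequence visited (which always attains at
#' least the initial value). Deterministic given `seed`.
#'
#' @param lpE,lpN log density matrices (subjects x N).
#' @param init integer permutation to start from (use [greedy_ascent()]).
#' @param n_samples chain length (default 500000).
#' @param seed integer seed.
#' @return list with `chain` (n_samples x N integer matrix), `loglik`
#'   (per-sample), `ml_sequence`, `ml_loglik`, `acceptance_rate`.
#' @export
mcmc_sequences <- function(lpE, lpN, init, n_samples = 500000, seed = 1L) {
  N <- ncol(lpE)
  stopifnot(length(init) == N)
  ll_fun <- make_seq_loglik(lpE, lpN)
  set.seed(derive_seed(seed, 29L))
  S <- as.integer(init)
  ll <- ll_fun(S)
  ml_S <- S; ml_ll <- ll
  chain <- matrix(NA_integer_, n_samples, N)
  lls <- numeric(n_samples)
  n_acc <- 0L
  if (N == 1L) {
    chain[] <- 1L; lls[] <- ll
    return(list(chain = chain, loglik = lls, ml_sequence = S, ml_loglik = ll,
                acceptance_rate = 0))
  }
  u_swap <- matrix(sample.int(N, 2L * n_samples, replace = TRUE), ncol = 2L)
  # reject self-swaps by redrawing the second index
  same <- u_swap[, 1L] == u_swap[, 2L]
  while (any(same)) {
    u_swap[same, 2L] <- sample.int(N, sum(same), replace = TRUE)
    same <- u_swap[, 1L] == u_swap[, 2L]
  }
  u_acc <- stats::runif(n_samples)
  for (t in seq_len(n_samples)) {
    S2 <- S
    S2[u_swap[t, ]] <- S2[u_swap[t, c(2L, 1L)]]
    ll2 <- ll_fun(S2)
    if (ll2 >= ll || u_acc[t] < exp(ll2 - ll)) {
      S <- S2; ll <- ll2; n_acc <- n_acc + 1L
      if (ll > ml_ll) { ml_ll <- ll; ml_S <- S }
    }
    chain[t, ] <- S
    lls[t] <- ll
  }
  list(chain = chain, loglik = lls, ml_sequence = ml_S, ml_loglik = ml_ll,
       acceptance_rate = n_acc / n_samples)
}

#' Fit the full event-based model for one biomarker set
#'
#' Fits per-biomarker KDE mixtures (controls vs cases, with per-feature
#' abnormality directions), then estimates the maximum-likelihood event
#' sequence by greedy ascent followed by MCMC. The sequence likelihood uses
#' cases only by default; the mixtures already use the controls.
#'
#' @param X_controls,X_cases numeric matrices (subjects x N), complete,
#'   with identical column names.
#' @param directions named (-1/+1) vector per biomarker.
#' @param greedy_iter,greedy_init greedy-ascent settings (defaults 10000/10).
#' @param mcmc_samples MCMC chain length (default 500000).
#' @param likelihood_subjects `"cases"` (default) or `"all"`.
#' @param seed integer seed.
#' @param min_n minimum group size for the mixtures.
#' @return object of class `ebm_fit`: `sequence` (ordered biomarker names),
#'   `log_likelihood`, `fits`, `greedy`, `mcmc` (chain omitted from print),
#'   `mcmc_pvd` (event x position frequencies over the chain).
#' @export
ebm_fit <- function(X_controls, X_cases, directions,
                    greedy_iter = 10000, greedy_init = 10,
                    mcmc_samples = 500000,
                    likelihood_subjects = c("cases", "all"),
                    seed = 1L, min_n = 20) {
  likelihood_subjects <- match.arg(likelihood_subjects)
  X_controls <- as.matrix(X_controls); X_cases <- as.matrix(X_cases)
  stopifnot(identical(colnames(X_controls), colnames(X_cases)))
  nm <- colnames(X_controls)
  if (!is.null(names(directions))) directions <- directions[nm]
  stopifnot(length(directions) == length(nm), !anyNA(directions))
  fits <- lapply(seq_along(nm), function(j) {
    fit_mixture(X_controls[, j], X_cases[, j], directions[[j]], min_n = min_n)
  })
  names(fits) <- nm
  Xlik <- if (likelihood_subjects == "cases") X_cases else
    rbind(X_cases, X_controls)
  lp <- mixture_log_probs(fits, Xlik)
  ga <- greedy_ascent(lp$lpE, lp$lpN, n_iter = greedy_iter,
                      n_init = greedy_init, seed = seed)
  mc <- mcmc_sequences(lp$lpE, lp$lpN, ga$sequence,
                       n_samples = mcmc_samples, seed = seed)
  N <- length(nm)
  pvd_mcmc <- matrix(0, N, N, dimnames = list(nm, paste0("pos", seq_len(N))))
  for (p in seq_len(N)) {
    tab <- tabulate(mc$chain[, p], nbins = N)
    pvd_mcmc[, p] <- tab / nrow(mc$chain)
  }
  structure(list(sequence = nm[mc$ml_sequence],
                 sequence_idx = mc$ml_sequence,
                 log_likelihood = mc$ml_loglik,
                 fits = fits, greedy = ga,
                 mcmc = mc, mcmc_pvd = pvd_mcmc,
                 directions = directions), class = "ebm_fit")
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat("Event-based model fit:", length(x$sequence), "events\n")
  cat("  ML sequence:", paste(x$sequence, collapse = " -> "), "\n")
  cat("  log-likelihood:", format(x$log_likelihood), "\n")
  cat("  MCMC acceptance rate:", round(x$mcmc$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Bootstrap positional variance diagram
#'
#' Resamples subjects with replacement within group strata (cases and
#' controls separately), refits the mixtures and reruns greedy ascent + a
#' (typically shortened) MCMC on each replicate, and tabulates how often
#' each event lands at each sequence position among the per-replicate
#' maximum-likelihood sequences. Rows and columns both sum to 1: every
#' replicate contributes one permutation matrix. A replicate in which some
#' biomarker is constant within a group is redrawn (and logged).
#'
#' @param X_controls,X_cases biomarker matrices as in [ebm_fit()].
#' @param directions named direction vector.
#' @param n_boot bootstrap repeats (default 100).
#' @param greedy_iter,greedy_init,mcmc_samples per-replicate search
#'   settings; defaults (2000/4/10000) are deliberately lighter than the
#'   primary fit.
#' @param seed integer seed.
#' @param min_n minimum group size for the mixtures.
#' @return object of class `ebm_pvd`: the N x N frequency matrix with
#'   attributes `n_boot` and `log`.
#' @export
bootstrap_pvd <- function(X_controls, X_cases, directions, n_boot = 100,
                          greedy_iter = 2000, greedy_init = 4,
                          mcmc_samples = 10000, seed = 1L, min_n = 20) {
  X_controls <- as.matrix(X_controls); X_cases <- as.matrix(X_cases)
  nm <- colnames(X_cases)
  N <- length(nm)
  counts <- matrix(0, N, N, dimnames = list(nm, paste0("pos", seq_len(N))))
  log <- character(0)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, 1000L + b))
    repeat {
      ico <- sample.int(nrow(X_controls), replace = TRUE)
      ica <- sample.int(nrow(X_cases), replace = TRUE)
      ok <- all(apply(X_controls[ico, , drop = FALSE], 2, stats::sd) > 0) &&
        all(apply(X_cases[ica, , drop = FALSE], 2, stats::sd) > 0)
      if (ok) break
      log <- log_event(log, "bootstrap %d: degenerate draw, redrawn", b)
    }
    fit <- ebm_fit(X_controls[ico, , drop = FALSE],
                   X_cases[ica, , drop = FALSE], directions,
                   greedy_iter = greedy_iter, greedy_init = greedy_init,
                   mcmc_samples = mcmc_samples,
                   seed = derive_seed(seed, 2000L + b), min_n = min_n)
    counts[cbind(fit$sequence_idx, seq_len(N))] <-
      counts[cbind(fit$sequence_idx, seq_len(N))] + 1
  }
  structure(counts / n_boot, n_boot = n_boot, log = log, class = "ebm_pvd")
}

#' Assign disease stages to subjects
#'
#' For each subject computes the log-likelihood of every stage `k = 0..N`
#' under the fitted sequence (events `S(1)..S(k)` abnormal, the rest
#' normal) and assigns the argmax stage, breaking ties toward the lower
#' stage ("no abnormality" is the conservative default). Applied to cases
#' and controls alike.
#'
#' @param X numeric matrix (subjects x N biomarkers), complete; rownames
#'   are used as subject IDs when present.
#' @param fits list of per-biomarker mixture fits (named as `colnames(X)`).
#' @param sequence ordered biomarker names (or integer permutation).
#' @param group optional group label per subject, carried through.
#' @return data.frame of class `stage_assignment`: `subject_id`, `group`,
#'   `stage`, and `loglik_0` .. `loglik_N`.
#' @export
stage_subjects <- function(X, fits, sequence, group = NULL) {
  X <- as.matrix(X)
  S <- if (is.character(sequence)) match(sequence, colnames(X)) else
    as.integer(sequence)
  stopifnot(!anyNA(S), length(S) == ncol(X))
  lp <- mixture_log_probs(fits, X)
  D <- (lp$lpE - lp$lpN)[, S, drop = FALSE]
  N <- ncol(X)
  U <- upper.tri(matrix(0, N, N), diag = TRUE) * 1
  stage_ll <- cbind(0, D %*% U) + rowSums(lp$lpN)
  colnames(stage_ll) <- paste0("loglik_", 0:N)
  stage <- max.col(stage_ll, ties.method = "first") - 1L
  out <- data.frame(
    subject_id = if (!is.null(rownames(X))) rownames(X) else
      sprintf("sub-%05d", seq_len(nrow(X))),
    group = if (is.null(group)) NA_character_ else as.character(group),
    stage = stage
  )
  out <- cbind(out, as.data.frame(stage_ll))
  class(out) <- c("stage_assignment", "data.frame")
  out
}
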