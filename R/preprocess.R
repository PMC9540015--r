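# Missing-data handling, covariate residualization, ipsi/contra relabeling
# and asymmetry indices: everything between the raw 156-feature table and
# the 234-feature analysis matrix.

#' Drop subjects with too many missing feature values
#'
#' Subjects with strictly more than `max_missing` missing feature values are
#' removed (">10" is strict: 10 missing is kept, 11 dropped).
#'
#' @param df cohort data.frame.
#' @param max_missing maximum tolerated missing count (default 10).
#' @return list with `kept`, `dropped` (data.frames) and `log` (character).
#' @export
filter_missing <- function(df, max_missing = 10) {
  reg <- feature_registry()
  nmiss <- rowSums(is.na(df[, reg$name, drop = FALSE]))
  drop <- nmiss > max_missing
  log <- character(0)
  for (i in which(drop)) {
    log <- log_event(log, "dropped subject %s: %d missing values (> %d)",
                     df$subject_id[i], nmiss[i], max_missing)
  }
  log <- log_event(log, "filter_missing: kept %d, dropped %d",
                   sum(!drop), sum(drop))
  if (all(drop)) warning("all subjects dropped by the missingness filter")
  list(kept = df[!drop, , drop = FALSE], dropped = df[drop, , drop = FALSE],
       log = log)
}

#' Iterative SVD-based matrix completion
#'
#' Imputes missing cells by alternating between a rank-`rank` truncated SVD
#' of the filled matrix and replacement of the missing cells with the
#' low-rank reconstruction, starting from column means, until the RMS change
#' of the imputed cells drops below `tol` (in units of the column SD).
#' Columns are scaled to unit observed SD for the completion and scaled back
#' afterwards -- morphometric features span four orders of magnitude, and a
#' diagonal rescaling preserves the rank structure exactly while keeping the
#' truncated SVD from chasing the large-scale columns. When `center` is
#' given the completion runs independently within each center, so center
#' biases never leak across sites. Observed cells are never altered.
#'
#' @param X numeric matrix (subjects x features) with `NA` for missing.
#' @param center optional grouping vector (length `nrow(X)`).
#' @param rank truncated-SVD rank (default 5).
#' @param tol convergence threshold on the RMS change of imputed cells,
#'   on the column-standardized scale.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning and `converged = FALSE` attribute.
#' @return completed matrix with attribute `converged`.
#' @export
impute_svd <- function(X, center = NULL, rank = 5, tol = 1e-6,
                       max_iter = 500) {
  X <- as.matrix(X)
  if (!anyNA(X)) {
    attr(X, "converged") <- TRUE
    return(X)
  }
  if (!is.null(center)) {
    stopifnot(length(center) == nrow(X))
    conv <- TRUE
    for (g in unique(center)) {
      idx <- which(center == g)
      sub <- impute_svd(X[idx, , drop = FALSE], center = NULL, rank = rank,
                        tol = tol, max_iter = max_iter)
      X[idx, ] <- sub
      conv <- conv && isTRUE(attr(sub, "converged"))
    }
    attr(X, "converged") <- conv
    return(X)
  }
  miss <- is.na(X)
  col_frac <- colMeans(miss)
  if (any(col_frac >= 0.5)) {
    stop("impute_svd: some columns are >= 50% missing; cannot impute reliably")
  }
  r <- min(rank, nrow(X) - 1L, ncol(X))
  col_sd <- apply(X, 2, stats::sd, na.rm = TRUE)
  col_sd[!is.finite(col_sd) | col_sd == 0] <- 1
  Z <- sweep(X, 2, col_sd, "/")
  # column-mean initialization
  mu <- colMeans(Z, na.rm = TRUE)
  filled <- Z
  filled[miss] <- mu[col(Z)[miss]]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- svd(filled, nu = r, nv = r)
    recon <- s$u %*% (s$d[seq_len(r)] * t(s$v))
    new_vals <- recon[miss]
    delta <- sqrt(mean((new_vals - filled[miss])^2))
    filled[miss] <- new_vals
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("impute_svd did not converge in ", max_iter, " iterations")
  }
  out <- X
  out[miss] <- filled[miss] * col_sd[col(X)[miss]]
  attr(out, "converged") <- converged
  out
}

#' Residualize features on age, sex, and ICV
#'
#' Per feature, fits ordinary least squares of the feature on age, sex
#' (binary-coded) and intracranial volume with an intercept, and replaces
#' the feature by residual + fitted intercept, so adjusted values stay on
#' the original scale. A constant covariate is dropped with a warning.
#'
#' @param X numeric matrix (subjects x features), complete.
#' @param covariates data.frame with `age`, `sex` (`"F"`/`"M"`), `icv`.
#' @param fit_on `"all"` (default) to estimate slopes on every subject, or
#'   `"controls"` to estimate on controls only and apply everywhere (then
#'   `group` must be supplied).
#' @param group optional group labels, required for `fit_on = "controls"`.
#' @return adjusted matrix, same dimensions.
#' @export
residualize <- function(X, covariates, fit_on = c("all", "controls"),
                        group = NULL) {
  fit_on <- match.arg(fit_on)
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(covariates))
  design <- cbind(intercept = 1,
                  age = covariates$age,
                  sex = as.numeric(covariates$sex == "M"),
                  icv = covariates$icv)
  keep <- c(TRUE, apply(design[, -1, drop = FALSE], 2,
                        function(v) stats::var(v) > 0))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(design)[!keep], collapse = ", "))
    design <- design[, keep, drop = FALSE]
  }
  rows <- seq_len(nrow(X))
  if (fit_on == "controls") {
    if (is.null(group)) stop("fit_on='controls' requires `group`")
    rows <- which(group == "control")
  }
  beta <- qr.coef(qr(design[rows, , drop = FALSE]), X[rows, , drop = FALSE])
  fitted <- design %*% beta
  resid <- X - fitted
  sweep(resid, 2, beta["intercept", ], "+")
}

#' Relabel hemispheres as ipsilateral/contralateral
#'
#' For left-lateralized cases left-hemisphere features become ipsilateral;
#' for right-lateralized cases the right hemisphere does. Controls are
#' randomly split in half (deterministically given `seed`): one half is
#' treated as left-lateralized, the other as right-lateralized; with an odd
#' control count the larger half goes to the left assignment (logged).
#'
#' @param df cohort data.frame (features may already be harmonized/adjusted).
#' @param seed integer seed for the control split.
#' @return list with `data` (metadata plus 78 `ipsi_*` and 78 `contra_*`
#'   columns), `pseudo_laterality` (the side treated as ipsilateral for every
#'   subject), `pairs` (the pair table used), and `log`.
#' @export
relabel_ipsi_contra <- function(df, seed) {
  reg <- feature_registry()
  validate_cohort(df)
  log <- character(0)

  side <- df$laterality
  ctrl <- which(df$group == "control")
  if (length(ctrl)) {
    set.seed(derive_seed(seed, 101L))
    n_left <- ceiling(length(ctrl) / 2)
    if (length(ctrl) %% 2 == 1) {
      log <- log_event(log,
        "odd control count (%d): larger half (%d) assigned left",
        length(ctrl), n_left)
    }
    left_ctrl <- sample(ctrl, n_left)
    side[ctrl] <- "right"
    side[left_ctrl] <- "left"
    log <- log_event(log, "control split: %d as left-lateralized, %d as right",
                     n_left, length(ctrl) - n_left)
  }

  pairs <- unique(reg[, c("pair_id", "kind", "region", "direction")])
  lnames <- stats::setNames(reg$name[reg$hemisphere == "left"],
                            reg$pair_id[reg$hemisphere == "left"])
  rnames <- stats::setNames(reg$name[reg$hemisphere == "right"],
                            reg$pair_id[reg$hemisphere == "right"])
  L <- as.matrix(df[, lnames[pairs$pair_id], drop = FALSE])
  R <- as.matrix(df[, rnames[pairs$pair_id], drop = FALSE])
  is_left <- side == "left"
  ipsi <- ifelse(matrix(is_left, nrow(df), nrow(pairs)), L, R)
  contra <- ifelse(matrix(is_left, nrow(df), nrow(pairs)), R, L)
  colnames(ipsi) <- paste0("ipsi_", pairs$pair_id)
  colnames(contra) <- paste0("contra_", pairs$pair_id)

  meta <- df[, .meta_cols, drop = FALSE]
  list(data = cbind(meta, as.data.frame(ipsi), as.data.frame(contra)),
       pseudo_laterality = stats::setNames(side, df$subject_id),
       pairs = pairs, log = log)
}

#' Brain asymmetry index
#'
#' `BASI = (ipsi - contra) / ((ipsi + contra) / 2)`: the ipsilateral minus
#' contralateral difference normalized by the pair mean. Antisymmetric in
#' its arguments and invariant to common positive rescaling. Undefined when
#' `ipsi + contra == 0` (returned as `NA`).
#'
#' @param ipsi,contra numeric vectors (recycled as usual).
#' @return numeric vector of asymmetry indices in which `NA` marks
#'   undefined entries.
#' @export
#' @examples
#' compute_basi(1, 3)  # -1
#' compute_basi(3, 1)  # +1
compute_basi <- function(ipsi, contra) {
  denom <- (ipsi + contra) / 2
  out <- (ipsi - contra) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Build the 234-feature analysis matrix
#'
#' Appends the 78 BASI columns to a relabeled table from
#' [relabel_ipsi_contra()], yielding 78 ipsilateral + 78 contralateral +
#' 78 asymmetry features with group/center labels retained.
#'
#' @param relabeled output of [relabel_ipsi_contra()].
#' @return list with `data` (metadata + 234 feature columns), `features`
#'   (per-column attribute table: `name`, `role`, `pair_id`, `kind`,
#'   `direction`), and `log`.
#' @export
build_analysis_matrix <- function(relabeled) {
  df <- relabeled$data
  pairs <- relabeled$pairs
  log <- relabeled$log
  ipsi <- as.matrix(df[, paste0("ipsi_", pairs$pair_id), drop = FALSE])
  contra <- as.matrix(df[, paste0("contra_", pairs$pair_id), drop = FALSE])
  basi <- matrix(compute_basi(ipsi, contra), nrow(df), nrow(pairs))
  colnames(basi) <- paste0("basi_", pairs$pair_id)
  n_undef <- sum(is.na(basi) & !is.na(ipsi) & !is.na(contra))
  if (n_undef > 0) {
    log <- log_event(log, "BASI undefined (ipsi + contra = 0) for %d cells",
                     n_undef)
  }
  features <- rbind(
    data.frame(name = colnames(ipsi), role = "ipsi", pairs,
               row.names = NULL),
    data.frame(name = colnames(contra), role = "contra", pairs,
               row.names = NULL),
    data.frame(name = colnames(basi), role = "basi", pairs,
               row.names = NULL)
  )
  list(data = cbind(df, as.data.frame(basi)), features = features, log = log)
}
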