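# Parametric empirical-Bayes ComBat harmonization of per-center biases.
#
# Removes per-center additive (location) and multiplicative (scale) effects
# from every feature while preserving variance attributable to covariates of
# interest (age, sex, ICV, diagnosis). The fit/apply split keeps the
# estimated center parameters serializable for audit and lets the same fit
# be applied to held-out data from the same centers.

#' Fit ComBat center-bias parameters
#'
#' Standard parametric empirical-Bayes ComBat: (1) per-feature OLS with
#' center indicators and covariates; (2) standardization by the grand mean,
#' covariate effects and pooled SD; (3) per-center location/scale estimates;
#' (4) empirical-Bayes shrinkage of locations toward a normal prior and of
#' squared scales toward an inverse-gamma prior via the standard iterative
#' conditional updates.
#'
#' @param X numeric matrix (subjects x features), complete.
#' @param center factor-like vector of center labels (>= 2 centers, each
#'   with >= 2 subjects).
#' @param covariates data.frame of covariates to protect; factors/characters
#'   are expanded to treatment-coded dummies (e.g. a 3-level diagnosis).
#'   May be `NULL`.
#' @param tol convergence tolerance of the EB iterations (default 1e-4).
#' @param max_iter EB iteration cap.
#' @return object of class `combat_fit` holding the standardization model,
#'   shrunk per-center locations (`gamma_star`) and scales (`delta2_star`),
#'   and the prior hyperparameters.
#' @export
combat_fit <- function(X, center, covariates = NULL, tol = 1e-4,
                       max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  center <- as.character(center)
  stopifnot(length(center) == n)
  if (anyNA(X)) stop("combat_fit requires a complete matrix")
  batches <- sort(unique(center))
  n_batch <- length(batches)
  counts <- table(factor(center, levels = batches))
  if (any(counts < 2)) {
    stop("every center must have >= 2 subjects; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  single <- n_batch < 2
  batch_design <- outer(center, batches, "==") * 1
  colnames(batch_design) <- batches

  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (j in seq_along(covariates)) {
      if (is.character(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
    }
    mod <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  design <- cbind(batch_design, mod)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("confounded design: covariates are collinear with center labels")
  }
  B_hat <- qr.coef(qrd, X)  # (n_batch + q) x p

  # per-center zero-variance features break the scale model
  for (b in batches) {
    v <- apply(X[center == b, , drop = FALSE], 2, stats::var)
    if (any(v == 0)) {
      stop("zero-variance feature(s) within center ", b, ": ",
           paste(utils::head(colnames(X)[v == 0], 3), collapse = ", "))
    }
  }

  grand_mean <- crossprod(as.numeric(counts) / n,
                          B_hat[seq_len(n_batch), , drop = FALSE])[1, ]
  # ML pooled residual variance (divisor n), matching the reference algorithm
  var_pooled <- colSums((X - design %*% B_hat)^2) / n
  if (any(var_pooled == 0)) stop("zero pooled variance feature")

  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  if (!is.null(mod)) {
    stand_mean <- stand_mean + mod %*% B_hat[-seq_len(n_batch), , drop = FALSE]
  }
  Z <- (X - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_hat <- matrix(0, n_batch, p, dimnames = list(batches, colnames(X)))
  delta2_hat <- matrix(1, n_batch, p, dimnames = list(batches, colnames(X)))
  for (i in seq_len(n_batch)) {
    zi <- Z[center == batches[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(zi)
    delta2_hat[i, ] <- apply(zi, 2, stats::var)
  }

  # EB hyperparameters (method of moments across features)
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }
  a_prior <- apply(delta2_hat, 1, aprior)
  b_prior <- apply(delta2_hat, 1, bprior)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (!single) {
    for (i in seq_len(n_batch)) {
      ni <- as.numeric(counts[i])
      zi <- Z[center == batches[i], , drop = FALSE]
      g_new <- gamma_hat[i, ]; d_new <- delta2_hat[i, ]
      change <- 1
      it <- 0
      while (change > tol && it < max_iter) {
        g_old <- g_new; d_old <- d_new
        g_new <- (ni * tau2[i] * gamma_hat[i, ] + d_new * gamma_bar[i]) /
          (ni * tau2[i] + d_new)
        sse <- colSums((zi - matrix(g_new, ni, p, byrow = TRUE))^2)
        d_new <- (b_prior[i] + 0.5 * sse) / (ni / 2 + a_prior[i] - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
        it <- it + 1
      }
      gamma_star[i, ] <- g_new
      delta2_star[i, ] <- d_new
    }
  } else {
    gamma_star[] <- 0
    delta2_star[] <- 1
  }

  structure(list(
    batches = batches, single_center = single,
    grand_mean = grand_mean, var_pooled = var_pooled,
    beta_cov = if (is.null(mod)) NULL else B_hat[-seq_len(n_batch), , drop = FALSE],
    mod_names = if (is.null(mod)) NULL else colnames(mod),
    cov_template = covariates,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                 a_prior = a_prior, b_prior = b_prior)
  ), class = "combat_fit")
}

#' Apply a fitted ComBat adjustment
#'
#' Standardizes each value with the fit's grand/covariate model, removes the
#' shrunk center location, de-scales by the shrunk center scale, and adds
#' grand and covariate effects back. With a single-center fit the data are
#' returned unchanged (there is nothing to remove).
#'
#' @param X matrix to harmonize (subjects x features, same features as fit).
#' @param fit a [combat_fit()] object.
#' @param center center label per row; all labels must be known to the fit.
#' @param covariates covariates per row, same columns as used in the fit
#'   (required if the fit used covariates).
#' @return harmonized matrix, same shape as `X`.
#' @export
combat_apply <- function(X, fit, center, covariates = NULL) {
  stopifnot(inherits(fit, "combat_fit"))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  center <- as.character(center)
  unseen <- setdiff(unique(center), fit$batches)
  if (length(unseen)) stop("unseen center label(s): ", paste(unseen, collapse = ", "))

  stand_mean <- matrix(fit$grand_mean, n, p, byrow = TRUE)
  if (!is.null(fit$beta_cov)) {
    if (is.null(covariates)) stop("fit used covariates; supply them to combat_apply")
    covariates <- as.data.frame(covariates)
    for (j in seq_along(covariates)) {
      tpl <- fit$cov_template[[j]]
      if (is.factor(tpl)) {
        covariates[[j]] <- factor(covariates[[j]], levels = levels(tpl))
      }
    }
    mod <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    stand_mean <- stand_mean + mod %*% fit$beta_cov
  }
  sdp <- matrix(sqrt(fit$var_pooled), n, p, byrow = TRUE)
  Z <- (X - stand_mean) / sdp
  ci <- match(center, fit$batches)
  Zadj <- (Z - fit$gamma_star[ci, , drop = FALSE]) /
    sqrt(fit$delta2_star[ci, , drop = FALSE])
  Zadj * sdp + stand_mean
}
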