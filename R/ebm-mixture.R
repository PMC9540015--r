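# Per-biomarker KDE mixture model separating the "normal" and "abnormal"
# component of a biomarker's distribution. Nonparametric on purpose: event
# features need not be Gaussian (ventricular volumes are skewed), and the
# stage-marginalized likelihood only needs pointwise density evaluations.

# Weighted Gaussian KDE evaluated at x. Small problems evaluate the kernel
# sum exactly; large ones go through an FFT-binned density on a 2048-point
# grid (cut = 4 bandwidths past the support range) with linear
# interpolation, which is accurate to well below the mixture-fit tolerance
# and orders of magnitude faster inside the EM loop and the bootstrap.
kde_pdf <- function(x, support, bw, w = NULL) {
  if (is.null(w)) w <- rep(1, length(support))
  wn <- w / sum(w)
  if (length(x) * length(support) <= 250000) {
    K <- outer(x, support, function(a, b) stats::dnorm(a, b, bw))
    return(as.vector(K %*% wn))
  }
  d <- stats::density(support, bw = bw, weights = wn, n = 2048, cut = 4)
  y <- stats::approx(d$x, d$y, xout = x, yleft = 0, yright = 0)$y
  pmax(y, 0)
}

# Silverman's rule on a weighted sample (effective n), floored to avoid
# bandwidth collapse when a component shrinks to a few points.
silverman_bw <- function(v, floor_sd, w = NULL) {
  if (is.null(w)) w <- rep(1, length(v))
  sw <- sum(w)
  n_eff <- sw^2 / sum(w^2)
  m <- sum(w * v) / sw
  s <- sqrt(sum(w * (v - m)^2) / sw)
  iqr <- diff(weighted_quantile(v, w, c(0.25, 0.75)))
  a <- min(s, iqr / 1.349)
  if (a == 0) a <- s
  bw <- 0.9 * a * n_eff^(-1 / 5)
  max(bw, 1e-3 * floor_sd)
}

weighted_quantile <- function(v, w, probs) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) v[which(cw >= p)[1]], 0)
}

weighted_median <- function(v, w) weighted_quantile(v, w, 0.5)

#' Fit a two-component KDE mixture for one biomarker
#'
#' Constrained iterative fit. Component memberships start from the
#' diagnosis labels (controls -> normal, cases -> abnormal) and are then
#' refined: each iteration (a) refits Gaussian-kernel KDEs for both
#' components from their currently weighted members -- controls always
#' carry weight 1 in the normal component, cases contribute to both
#' components with their posterior membership weights -- using Silverman
#' bandwidths floored at `1e-3` of the overall SD; (b) sets the mixture
#' weight `theta` to the fraction of case mass in the abnormal component;
#' (c) recomputes each case's posterior `P(abnormal | x)`, subject to the
#' directionality constraint that values on the healthy side of the normal
#' component's median can never be abnormal. Iterations stop when
#' memberships are stable. `theta` is clipped to `[0.01, 0.99]`; hitting a
#' clip flags the fit as degenerate.
#'
#' @param controls,cases numeric vectors of the biomarker in each group.
#' @param direction `-1` if abnormality means a decrease, `+1` an increase.
#' @param max_iter membership-update cap (default 100).
#' @param min_n minimum group size (default 20).
#' @param tol membership-stability threshold (max absolute change of the
#'   posterior weights).
#' @return object of class `kde_mixture_fit`: support points, weights and
#'   bandwidth of each component, `theta`, `direction`, `iterations`,
#'   `converged`, `degenerate`.
#' @export
fit_mixture <- function(controls, cases, direction, max_iter = 100,
                        min_n = 20, tol = 1e-4) {
  controls <- controls[!is.na(controls)]
  cases <- cases[!is.na(cases)]
  if (length(controls) < min_n || length(cases) < min_n) {
    stop("fit_mixture needs >= ", min_n, " values per group")
  }
  stopifnot(direction %in% c(-1, 1))
  all_sd <- stats::sd(c(controls, cases))
  if (all_sd == 0) stop("degenerate biomarker: zero variance")

  nca <- length(cases)
  w_ab <- rep(1, nca)  # init by diagnosis label: cases -> abnormal
  theta <- 1
  converged <- FALSE
  degenerate <- FALSE
  it <- 0
  sup0 <- w0 <- bw0 <- sup1 <- w1 <- bw1 <- NULL
  for (it in seq_len(max_iter)) {
    sup0 <- c(controls, cases)
    w0 <- c(rep(1, length(controls)), 1 - w_ab)
    sup1 <- cases
    w1 <- w_ab
    if (sum(w1) < 2) {
      # keep the abnormal component identifiable: anchor on the most
      # extreme cases in the abnormal direction
      ord <- order(direction * cases, decreasing = TRUE)
      w1 <- numeric(nca)
      w1[ord[seq_len(min(5, nca))]] <- 1
      degenerate <- TRUE
    }
    bw0 <- silverman_bw(sup0, all_sd, w0)
    bw1 <- silverman_bw(sup1, all_sd, w1)
    theta <- mean(w_ab)
    if (theta <= 0.01 || theta >= 0.99) {
      theta <- min(max(theta, 0.01), 0.99)
      degenerate <- TRUE
    }
    f0 <- kde_pdf(cases, sup0, bw0, w0)
    f1 <- kde_pdf(cases, sup1, bw1, w1)
    post <- theta * f1 / (theta * f1 + (1 - theta) * f0)
    med0 <- weighted_median(sup0, w0)
    healthy <- if (direction < 0) cases > med0 else cases < med0
    post[healthy] <- 0
    if (max(abs(post - w_ab)) < tol) { converged <- TRUE; w_ab <- post; break }
    w_ab <- post
  }
  structure(list(support0 = sup0, w0 = w0, bw0 = bw0,
                 support1 = sup1, w1 = w1, bw1 = bw1,
                 theta = theta, direction = direction,
                 iterations = it, converged = converged,
                 degenerate = degenerate), class = "kde_mixture_fit")
}

#' Evaluate a fitted mixture's component densities
#'
#' @param fit a [fit_mixture()] object.
#' @param x numeric vector of evaluation points.
#' @return list with `normal` and `abnormal` density values at `x`.
#' @export
mixture_densities <- function(fit, x) {
  stopifnot(inherits(fit, "kde_mixture_fit"))
  list(normal = kde_pdf(x, fit$support0, fit$bw0, fit$w0),
       abnormal = kde_pdf(x, fit$support1, fit$bw1, fit$w1))
}

# Log p(x | event) and log p(x | no event) matrices for a set of fitted
# biomarkers; densities floored at 1e-300 before taking logs.
mixture_log_probs <- function(fits, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(fits))
  lpE <- lpN <- matrix(NA_real_, nrow(X), ncol(X),
                       dimnames = dimnames(X))
  for (j in seq_along(fits)) {
    if (anyNA(X[, j])) stop("missing biomarker values; impute upstream")
    d <- mixture_densities(fits[[j]], X[, j])
    lpE[, j] <- log(pmax(d$abnormal, 1e-300))
    lpN[, j] <- log(pmax(d$normal, 1e-300))
  }
  list(lpE = lpE, lpN = lpN)
}
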