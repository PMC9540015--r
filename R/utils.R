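# Internal numeric helpers shared across modules.

#' Row-wise log-sum-exp of a numeric matrix
#'
#' Stable computation of `log(rowSums(exp(m)))`, used by the stage-marginalized
#' sequence likelihood. Loops over columns (few stages) rather than rows
#' (many subjects) so it stays vectorized over subjects.
#'
#' @param m numeric matrix (subjects x stages).
#' @return numeric vector of length `nrow(m)`.
#' @keywords internal
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2:nc) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

#' Kendall rank correlation between two permutations
#'
#' Measures how well an estimated event sequence recovers a ground-truth
#' ordering: +1 for identical orderings, -1 for exact reversal.
#'
#' @param estimated character or integer vector: a permutation of the event set.
#' @param truth the reference permutation over the same events.
#' @return Kendall's tau in \[-1, 1\].
#' @export
#' @examples
#' truth_kendall_tau(c("a", "b", "c"), c("c", "b", "a"))
truth_kendall_tau <- function(estimated, truth) {
  if (length(estimated) != length(truth) ||
      !setequal(as.character(estimated), as.character(truth))) {
    stop("`estimated` and `truth` must be permutations of the same event set")
  }
  pos_est <- match(as.character(truth), as.character(estimated))
  unname(stats::cor(pos_est, seq_along(truth), method = "kendall"))
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream * 7919) %% 2147483647)
}

# Minimal structured run log: list of timestamped messages.
log_event <- function(log, ...) {
  c(log, paste0(format(Sys.time(), "%H:%M:%S"), " | ", sprintf(...)))
}
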