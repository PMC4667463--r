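#' Storey bootstrap estimate of the null proportion pi0
#'
#' Computes `pi0_hat(lambda) = #\{p > lambda\} / (m (1 - lambda))` over a
#' grid of tuning values and selects `lambda` by Storey's bootstrap: for
#' each of `B` resamples of the p-values the mean squared error of
#' `pi0_hat^b(lambda)` around the plug-in minimum `min_lambda pi0_hat` is
#' estimated, and the `lambda` with the smallest estimated MSE wins. The
#' result is clipped to `[0, 1]`.
#'
#' P-values exactly 1 (the point mass of the boundary RLRT null) enter
#' unmodified: the mixture null is uniform-dominated, so the estimator
#' stays conservative.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @param lambda grid of tuning values in `(0, 1)`.
#' @param B number of bootstrap resamples.
#' @return `pi0_hat` in `[0, 1]`.
#' @export
estimate_pi0_bootstrap <- function(pvals,
                                   lambda = seq(0.05, 0.95, by = 0.05),
                                   B = 100L) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  pi0_lambda <- vapply(lambda, function(l) mean(pvals > l) / (1 - l),
                       numeric(1))
  pi0_min <- min(pi0_lambda)
  mse <- numeric(length(lambda))
  for (b in seq_len(B)) {
    pb <- sample(pvals, m, replace = TRUE)
    pi0_b <- vapply(lambda, function(l) mean(pb > l) / (1 - l), numeric(1))
    mse <- mse + (pi0_b - pi0_min)^2
  }
  pi0 <- pi0_lambda[which.min(mse)]
  min(max(pi0, 0), 1)
}

#' q-values from p-values and an estimated null proportion
#'
#' `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j` on the sorted p-values,
#' mapped back to input order and clipped at 1. With `pi0 = 1` this is the
#' Benjamini-Hochberg adjusted p-value.
#'
#' @param pvals p-values.
#' @param pi0 estimated proportion of true nulls in `[0, 1]`.
#' @return q-values aligned with `pvals`.
#' @export
qvalues <- function(pvals, pi0 = 1) {
  stopifnot(pi0 >= 0, pi0 <= 1)
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pvals[o] / (m:1)))[ro]
  q
}

#' FDR-threshold a p-value family
#'
#' Estimates pi0 (Storey bootstrap by default), converts to q-values, and
#' flags the significant set at level `alpha`.
#'
#' @param pvals p-values (NAs allowed; excluded from estimation, returned
#'   as NA q-values).
#' @param alpha FDR level.
#' @param pi0_method `"bootstrap"` (Storey) or `"one"` (plain BH, pi0 = 1).
#' @param ... passed to [estimate_pi0_bootstrap()].
#' @return list of class `fdr_result`: `pi0_hat`, `pi1_hat`, `q_values`,
#'   `significant` (logical), `alpha`.
#' @export
fdr_adjust <- function(pvals, alpha = 0.05,
                       pi0_method = c("bootstrap", "one"), ...) {
  pi0_method <- match.arg(pi0_method)
  ok <- !is.na(pvals)
  pi0 <- if (pi0_method == "bootstrap")
    estimate_pi0_bootstrap(pvals[ok], ...) else 1
  q <- rep(NA_real_, length(pvals))
  q[ok] <- qvalues(pvals[ok], pi0)
  structure(list(pi0_hat = pi0, pi1_hat = 1 - pi0, q_values = q,
                 significant = !is.na(q) & q <= alpha, alpha = alpha),
            class = "fdr_result")
}
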