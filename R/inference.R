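#' Residual likelihood ratio test for the blending variance component
#'
#' Tests `H0: sigma2^2 = 0` by comparing the REML log-likelihoods of the
#' nested fits m1 (without blending term) and m2 (with it). Because the
#' null value lies on the boundary of the parameter space, the statistic
#' `T = max(0, 2 (l2 - l1))` is referred to a half-half mixture of a
#' chi-square with one degree of freedom and a point mass at zero:
#' `p = 1` when `T = 0`, else `p = 0.5 P(chi2_1 >= T)`.
#'
#' A boundary m2 fit (`sigma2^2` estimated as 0) has `l2 = l1` exactly, so
#' `T = 0` and `p = 1`. Small negative differences from finite convergence
#' tolerance are truncated to 0.
#'
#' @param fit_m1,fit_m2 [em_reml_fit()] results for the reduced and full
#'   model on the same data and identical fixed-effect structure.
#' @return list of class `rlrt_result` with `statistic` and `p_value`.
#' @export
rlrt <- function(fit_m1, fit_m2) {
  stopifnot(inherits(fit_m1, "reml_fit"), inherits(fit_m2, "reml_fit"))
  if (fit_m1$n != fit_m2$n || fit_m1$p != fit_m2$p ||
      !isTRUE(all.equal(unname(fit_m1$X), unname(fit_m2$X))))
    stop("fits have different fixed-effect structures; ",
         "REML likelihoods are not comparable")
  T <- max(0, 2 * (fit_m2$loglik - fit_m1$loglik))
  if (!is.null(fit_m2$vc$sigma2) && fit_m2$vc$sigma2 == 0) T <- 0
  p <- if (T == 0) 1 else 0.5 * stats::pchisq(T, df = 1, lower.tail = FALSE)
  structure(list(statistic = T, p_value = p), class = "rlrt_result")
}

# p-value of the boundary mixture null for a given RLRT statistic
rlrt_pvalue <- function(T) {
  ifelse(T <= 0, 1, 0.5 * stats::pchisq(T, df = 1, lower.tail = FALSE))
}

# Kenward-Roger adjusted F test, reference R implementation.
# X: n x p, Alist: list of dV/dtheta for the random blocks (residual
# identity appended internally), sig: block variances, sige: residual,
# L: ell x p contrast.
kr_ftest_r <- function(y, X, Alist, sig, sige, L) {
  n <- length(y); p <- ncol(X)
  L <- matrix(L, ncol = p)
  ell <- nrow(L)
  V <- diag(sige, n)
  for (j in seq_along(Alist)) V <- V + sig[j] * Alist[[j]]
  Vinv <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vinv)
  Phi <- solve(XtVi %*% X)
  beta <- drop(Phi %*% XtVi %*% y)
  Pm <- Vinv - t(XtVi) %*% Phi %*% XtVi
  D <- c(Alist, list(diag(1, n)))
  K <- length(D)
  Bp <- lapply(D, function(M) XtVi %*% M)
  PM <- lapply(D, function(M) Pm %*% M)
  Info <- matrix(0, K, K)
  for (i in 1:K) for (j in i:K)
    Info[i, j] <- Info[j, i] <- 0.5 * sum(PM[[i]] * t(PM[[j]]))
  Wc <- solve(Info)
  Pi <- lapply(Bp, function(B) { M <- -(B %*% t(XtVi)); (M + t(M)) / 2 })
  Lam <- matrix(0, p, p)
  for (i in 1:K) for (j in 1:K) {
    Qij <- Bp[[i]] %*% Vinv %*% t(Bp[[j]])
    Lam <- Lam + Wc[i, j] * (Qij - Pi[[i]] %*% Phi %*% Pi[[j]])
  }
  PhiA <- Phi + 2 * Phi %*% Lam %*% Phi
  Fs <- drop(crossprod(L %*% beta, solve(L %*% PhiA %*% t(L), L %*% beta))) / ell
  Theta <- t(L) %*% solve(L %*% Phi %*% t(L)) %*% L
  Si <- lapply(Pi, function(P) Phi %*% P %*% Phi)
  A1 <- A2 <- 0
  for (i in 1:K) for (j in 1:K) {
    A1 <- A1 + Wc[i, j] * sum(diag(Theta %*% Si[[i]])) *
      sum(diag(Theta %*% Si[[j]]))
    A2 <- A2 + Wc[i, j] * sum(diag(Theta %*% Si[[i]] %*% Theta %*% Si[[j]]))
  }
  g <- ((ell + 1) * A1 - (ell + 4) * A2) / ((ell + 2) * A2)
  den <- 3 * ell + 2 * (1 - g)
  c1 <- g / den; c2 <- (ell - g) / den; c3 <- (ell + 2 - g) / den
  Bq <- (A1 + 6 * A2) / (2 * ell)
  Estar <- 1 / (1 - A2 / ell)
  Vstar <- (2 / ell) * (1 + c1 * Bq) /
    ((1 - c2 * Bq)^2 * (1 - c3 * Bq))
  rho <- Vstar / (2 * Estar^2)
  m <- if (ell * rho - 1 > 1e-10) 4 + (ell + 2) / (ell * rho - 1) else 1e7
  if (Estar > 0 && m > 2) lam <- m / (Estar * (m - 2)) else { lam <- 1; m <- n - p }
  Fstar <- lam * Fs
  list(statistic = Fstar, ndf = ell, ddf = m,
       p_value = stats::pf(Fstar, ell, m, lower.tail = FALSE))
}

#' Kenward-Roger adjusted F-test of a fixed-effect contrast
#'
#' Wald-type F-test of `L beta = 0` using the Kenward-Roger small-sample
#' adjusted covariance of the fixed-effect estimates and matching
#' denominator degrees of freedom; the covariance of the variance-component
#' estimates is taken from the expected REML information at the fitted
#' values. A variance component estimated on the boundary (reported 0) is
#' treated as a fixed zero and dropped from the adjustment.
#'
#' @param fit an [em_reml_fit()] result.
#' @param mats the [model_matrices()] the fit was computed from.
#' @param y the observation vector used for the fit.
#' @param contrast contrast matrix `L` (ell x p) or vector (length p); by
#'   default the treatment contrast columns of the fixed design.
#' @return list of class `ftest_result`: `statistic`, `ndf`, `ddf`
#'   (possibly non-integer), `p_value`, `model`.
#' @export
ftest_treatment <- function(fit, mats, y, contrast = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  p <- ncol(mats$X)
  if (is.null(contrast)) {
    tc <- mats$treatment_cols
    contrast <- matrix(0, length(tc), p)
    contrast[cbind(seq_along(tc), tc)] <- 1
  }
  L <- matrix(contrast, ncol = p)
  # estimability: rows of L must lie in the row space of X
  XtX <- crossprod(mats$X)
  proj <- L %*% pinv_sym(XtX) %*% XtX
  if (max(abs(proj - L)) > 1e-8)
    stop("contrast is not estimable (outside the row space of X)")
  if (all(abs(L) < 1e-14)) {
    out <- list(statistic = 0, ndf = nrow(L), ddf = fit$n - p, p_value = 1,
                model = fit$model)
    return(structure(out, class = "ftest_result"))
  }
  Alist <- list(); sig <- numeric(0)
  if (!is.na(fit$vc$sigma1) && fit$vc$sigma1 > 0 && ncol(mats$Z1) > 0) {
    Alist <- c(Alist, list(mats$Z1 %*% mats$G1 %*% t(mats$Z1)))
    sig <- c(sig, fit$vc$sigma1)
  }
  if (fit$model == "m2" && fit$vc$sigma2 > 0 && ncol(mats$Z2) > 0) {
    Alist <- c(Alist, list(mats$Z2 %*% mats$G2 %*% t(mats$Z2)))
    sig <- c(sig, fit$vc$sigma2)
  }
  out <- kr_ftest_r(y, mats$X, Alist, sig, fit$vc$sigmae, L)
  out$model <- fit$model
  structure(out, class = "ftest_result")
}

# minimal Moore-Penrose inverse (symmetric use only)
pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}
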