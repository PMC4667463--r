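#' EM-REML fitting configuration
#'
#' @param epsilon convergence tolerance on the relative change of the
#'   variance-component vector, `sqrt(|B[n-1]-B[n]|^2 / |B[n]|^2) < epsilon`.
#' @param max_iter iteration cap; non-convergence is reported, never an error.
#' @param init optional named list with starting values `sigma1`, `sigma2`,
#'   `sigmae`; by default `sigmae` starts at the OLS residual variance and
#'   the random-block variances at half of it.
#' @param boundary_floor_rel smallest admissible variance, relative to
#'   `var(y)`; estimates at the floor are reported as 0.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(epsilon = 1e-8, max_iter = 1000L, init = NULL,
                       boundary_floor_rel = 1e-10) {
  stopifnot(epsilon > 0, max_iter >= 1, boundary_floor_rel >= 0)
  structure(list(epsilon = epsilon, max_iter = as.integer(max_iter),
                 init = init, boundary_floor_rel = boundary_floor_rel),
            class = "fit_config")
}

# Reparameterize a random block (Z, G) -> (Z U D^{1/2}, I), dropping null
# eigen-directions, so that the MME stay well posed even for singular G
# (overlapping compositions).  The induced marginal covariance Z G Z' is
# unchanged and q becomes rank(G).
whiten_block <- function(Z, G, tol = 1e-10) {
  if (is.null(Z) || ncol(Z) == 0)
    return(list(Z = matrix(0, nrow(Z %||% matrix(0, 1, 0)), 0),
                L = matrix(0, 0, 0)))
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  L <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(Z = Z %*% L, L = L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve Henderson's mixed model equations
#'
#' Builds and solves the coefficient system with variance ratios
#' `lambda_j = sigmae^2 / sigma_j^2`, returning BLUE/BLUP solutions and the
#' diagonal blocks of the coefficient-matrix inverse (needed by the EM
#' updates and the Kenward-Roger adjustment).
#'
#' @param mats a [model_matrices()] object.
#' @param y observation vector (length n).
#' @param vc named list/vector with `sigma1`, `sigmae` and, unless the
#'   blending block is omitted, `sigma2`; `sigma2 = NULL` or `NA` drops the
#'   blending block (model m1).
#' @return list with `beta_hat`, `u1_hat`, `u2_hat`, the full inverse
#'   coefficient matrix `Cinv` and the block index map.
#' @export
solve_mme <- function(mats, y, vc) {
  vc <- as.list(vc)
  stopifnot(length(y) == mats$n, vc$sigma1 > 0, vc$sigmae > 0)
  use2 <- !is.null(vc$sigma2) && !is.na(vc$sigma2) && vc$sigma2 > 0 &&
    ncol(mats$Z2) > 0
  X <- mats$X
  blocks <- list(X)
  Ginvs <- list(NULL)
  if (ncol(mats$Z1) > 0) {
    g1inv <- tryCatch(solve(mats$G1), error = function(e)
      stop("G1 is singular; use the composition-whitened fitter ",
           "(em_reml_fit) for this design"))
    blocks <- c(blocks, list(mats$Z1))
    Ginvs <- c(Ginvs, list(g1inv * vc$sigmae / vc$sigma1))
  }
  if (use2) {
    blocks <- c(blocks, list(mats$Z2))
    Ginvs <- c(Ginvs, list(solve(mats$G2) * vc$sigmae / vc$sigma2))
  }
  W <- do.call(cbind, blocks)
  C <- crossprod(W)
  sizes <- vapply(blocks, ncol, 1L)
  offs <- cumsum(c(0, sizes))
  for (b in seq_along(blocks)[-1]) {
    idx <- (offs[b] + 1):offs[b + 1]
    C[idx, idx] <- C[idx, idx] + Ginvs[[b]]
  }
  Cinv <- tryCatch(solve(C), error = function(e) {
    d <- diag(qr.R(qr(C)))
    stop("singular MME coefficient matrix (confounded design); ",
         "aliased columns: ",
         paste(colnames(W)[abs(d) < 1e-8 * max(abs(d))], collapse = ", "))
  })
  sol <- drop(Cinv %*% crossprod(W, y))
  p <- ncol(X)
  out <- list(beta_hat = stats::setNames(sol[seq_len(p)], colnames(X)),
              u1_hat = NULL, u2_hat = NULL, Cinv = Cinv,
              blocks = list(p = p, q1 = if (length(sizes) > 1) sizes[2] else 0,
                            q2 = if (use2) sizes[3] else 0))
  if (length(sizes) > 1)
    out$u1_hat <- stats::setNames(sol[(offs[2] + 1):offs[3]],
                                  colnames(mats$Z1))
  if (use2)
    out$u2_hat <- stats::setNames(sol[(offs[3] + 1):offs[4]],
                                  colnames(mats$Z2))
  out
}

#' Restricted (REML) log-likelihood
#'
#' Evaluates `-1/2 [log|V| + log|X'V^-1X| + y'Py + (n - p) log 2pi]` with
#' `V` from [assemble_covariance()]. The additive constant is fixed at
#' `-(n - p)/2 log 2pi`, so differences between the nested models m1 and m2
#' (same fixed design) are directly comparable.
#'
#' @inheritParams solve_mme
#' @param vc named list/vector with `sigma1`, `sigma2`, `sigmae`
#'   (use `sigma2 = 0` for m1).
#' @return scalar log-likelihood.
#' @export
reml_loglik <- function(mats, y, vc) {
  vc <- as.list(vc)
  if (is.null(vc$sigma2) || is.na(vc$sigma2)) vc$sigma2 <- 0
  V <- assemble_covariance(mats, vc)
  n <- mats$n; X <- mats$X; p <- ncol(X)
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite"))
  Vinv <- chol2inv(ch)
  XtVi <- crossprod(X, Vinv)
  XtViX <- XtVi %*% X
  XtViy <- drop(XtVi %*% y)
  b <- solve(XtViX, XtViy)
  yPy <- drop(crossprod(y, Vinv %*% y)) - sum(XtViy * b)
  ldV <- 2 * sum(log(diag(ch)))
  ldX <- determinant(XtViX, logarithm = TRUE)$modulus
  -0.5 * (ldV + as.numeric(ldX) + yPy + (n - p) * log(2 * pi))
}

#' Fit the per-transcript mixed model by EM-REML
#'
#' Iterates the expectation-maximization REML updates through the mixed
#' model equations until the relative-change criterion falls below
#' `epsilon`, then solves for fixed and random effects at the converged
#' variance components. The full model (m2) carries biological, blending
#' and residual components; `include_blending = FALSE` fits the reduced
#' model m1.
#'
#' @inheritParams solve_mme
#' @param cfg a [fit_config()].
#' @param include_blending include the blending random term (model m2)?
#' @param trace_loglik record the REML log-likelihood at every iteration
#'   (slower; used by diagnostics and tests)?
#' @return object of class `reml_fit`: variance components `vc`
#'   (`sigma1`, `sigma2`, `sigmae`; boundary estimates reported as 0),
#'   `loglik`, solutions, iteration count, convergence flag and, if
#'   requested, the log-likelihood trace.
#' @examples
#' d <- mouse_like_design()
#' mats <- model_matrices(d)
#' sim <- simulate_experiment(sim_config(m = 2, seed = 1))
#' em_reml_fit(mats, sim$Y[1, ])
#' @export
em_reml_fit <- function(mats, y, cfg = fit_config(),
                        include_blending = TRUE, trace_loglik = FALSE) {
  stopifnot(inherits(mats, "model_matrices"), length(y) == mats$n)
  if (stats::var(y) == 0) stop("degenerate input: y is constant")
  w1 <- whiten_block(mats$Z1, mats$G1)
  blocks <- list()
  if (ncol(w1$Z) > 0) blocks <- c(blocks, list(w1$Z))
  use2 <- include_blending && ncol(mats$Z2) > 0
  if (use2) {
    w2 <- whiten_block(mats$Z2, mats$G2)
    blocks <- c(blocks, list(w2$Z))
  }
  X <- mats$X
  p <- ncol(X)
  r <- stats::lm.fit(X, y)$residuals
  v0 <- sum(r^2) / (mats$n - p)
  init <- cfg$init
  init_sige <- init$sigmae %||% v0
  init_sig <- numeric(0)
  if (ncol(w1$Z) > 0) init_sig <- c(init_sig, init$sigma1 %||% (init_sige / 2))
  if (use2) init_sig <- c(init_sig, init$sigma2 %||% (init_sige / 2))
  boundary2 <- FALSE
  if (use2) {
    # decide the sigma2^2 = 0 boundary from the REML score at zero,
    # evaluated at the reduced-model optimum (KKT condition); EM itself
    # approaches the boundary only sublinearly
    blocks_m1 <- blocks[-length(blocks)]
    init_m1 <- init_sig[-length(init_sig)]
    f1 <- cpp_em_single(y, X, blocks_m1, cfg$epsilon, cfg$max_iter,
                        cfg$boundary_floor_rel, init_m1, init_sige,
                        trace_loglik)
    n <- mats$n
    V1 <- diag(f1$sige, n)
    if (length(blocks_m1)) V1 <- V1 + f1$sig[1] * tcrossprod(blocks_m1[[1]])
    V1i <- chol2inv(chol(V1))
    XtVi <- crossprod(X, V1i)
    Pm <- V1i - t(XtVi) %*% solve(XtVi %*% X, XtVi)
    A2 <- tcrossprod(w2$Z)
    Py <- Pm %*% y
    score <- -0.5 * (sum(Pm * A2) - drop(crossprod(Py, A2 %*% Py)))
    if (score <= 0) { boundary2 <- TRUE; fit <- f1 }
  }
  if (!boundary2)
    fit <- cpp_em_single(y, X, blocks, cfg$epsilon, cfg$max_iter,
                         cfg$boundary_floor_rel, init_sig, init_sige,
                         trace_loglik)
  floorv <- cfg$boundary_floor_rel * stats::var(y)
  sig <- as.numeric(fit$sig)
  at_floor <- sig <= 1.5 * floorv
  vc <- list(sigma1 = NA_real_, sigma2 = 0, sigmae = fit$sige)
  j <- 1
  if (ncol(w1$Z) > 0) { vc$sigma1 <- if (at_floor[j]) 0 else sig[j]; j <- j + 1 }
  if (use2)
    vc$sigma2 <- if (boundary2 || at_floor[j]) 0 else sig[j]
  # solutions at the converged components (floored values kept positive so
  # the MME remain defined)
  sol_vc <- list(sigma1 = max(if (is.na(vc$sigma1)) 0 else vc$sigma1, floorv),
                 sigma2 = if (use2) max(vc$sigma2, floorv) else NULL,
                 sigmae = max(vc$sigmae, floorv))
  sol <- tryCatch(solve_mme(mats, y, sol_vc), error = function(e) NULL)
  structure(list(vc = vc, loglik = fit$loglik,
                 beta_hat = sol$beta_hat, u1_hat = sol$u1_hat,
                 u2_hat = sol$u2_hat,
                 iterations = fit$iterations, converged = fit$converged,
                 criterion = fit$criterion,
                 loglik_trace = as.numeric(fit$loglik_trace),
                 model = if (use2) "m2" else "m1",
                 n = mats$n, p = p, X = X),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("EM-REML fit (", x$model, "): sigma1^2 = ", signif(x$vc$sigma1, 4),
      ", sigma2^2 = ", signif(x$vc$sigma2, 4),
      ", sigmae^2 = ", signif(x$vc$sigmae, 4), "\n",
      " loglik = ", format(x$loglik), "; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}
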