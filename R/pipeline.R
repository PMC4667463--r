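#' Fit m1 and m2 to every transcript of an expression matrix
#'
#' Runs the EM-REML fitter over all rows of `Y` for the reduced model m1
#' (biological + residual variance) and the full model m2 (+ blending
#' variance), computes the boundary RLRT of `H0: sigma2^2 = 0` and
#' Kenward-Roger adjusted treatment F-tests under both models.
#'
#' The `sigma2^2` boundary is decided by the REML score at zero evaluated
#' at the m1 optimum; boundary transcripts have `sigma2^2 = 0`, an RLRT
#' statistic of exactly 0 (p-value 1) and identical m1/m2 F-tests. If the
#' biological block is aliased with the residual (every sample a distinct
#' single individual measured once, `Z1 G1 Z1' = I`), it is absorbed into
#' the residual variance.
#'
#' @param Y numeric matrix, transcripts x arrays (columns in design order).
#' @param mats a [model_matrices()] object.
#' @param cfg a [fit_config()].
#' @param contrast optional contrast matrix for the F-test; defaults to the
#'   treatment columns.
#' @param kr compute the Kenward-Roger F-tests (disable for variance-only
#'   studies)?
#' @return data.frame with one row per transcript: variance components,
#'   log-likelihoods, iteration/convergence diagnostics, RLRT statistic and
#'   p-value, F statistics with KR denominator df and p-values.
#' @export
fit_transcripts <- function(Y, mats, cfg = fit_config(), contrast = NULL,
                            kr = TRUE) {
  stopifnot(inherits(mats, "model_matrices"), ncol(Y) == mats$n)
  X <- mats$X
  p <- ncol(X)
  w1 <- whiten_block(mats$Z1, mats$G1)
  w2 <- whiten_block(mats$Z2, mats$G2)
  Z1 <- w1$Z; Z2 <- w2$Z
  absorbed <- FALSE
  if (ncol(Z1) > 0 &&
      max(abs(tcrossprod(Z1) - diag(1, mats$n))) < 1e-10) {
    Z1 <- matrix(0, mats$n, 0)  # biological term aliased with residual
    absorbed <- TRUE
  }
  if (is.null(contrast)) {
    tc <- mats$treatment_cols
    contrast <- matrix(0, length(tc), p)
    contrast[cbind(seq_along(tc), tc)] <- 1
  }
  L <- matrix(contrast, ncol = p)
  res <- cpp_fit_transcripts(Y, X, Z1, Z2, L, cfg$epsilon, cfg$max_iter,
                             cfg$boundary_floor_rel, kr)
  cn <- c("sigma1_m1", "sigmae_m1", "loglik_m1", "iter_m1", "converged_m1",
          "F_m1", "ddf_m1", "pF_m1",
          "sigma1_m2", "sigma2_m2", "sigmae_m2", "loglik_m2", "iter_m2",
          "converged_m2", "boundary_m2", "F_m2", "ddf_m2", "pF_m2",
          "score0_m2")
  colnames(res) <- cn
  out <- as.data.frame(res)
  out$transcript <- rownames(Y) %||% sprintf("t%05d", seq_len(nrow(Y)))
  # report floored variance estimates as zero
  floorv <- cfg$boundary_floor_rel * apply(Y, 1, stats::var)
  for (col in c("sigma1_m1", "sigma1_m2", "sigma2_m2"))
    out[[col]] <- ifelse(!is.na(out[[col]]) & out[[col]] <= 1.5 * floorv,
                         0, out[[col]])
  T <- pmax(0, 2 * (out$loglik_m2 - out$loglik_m1))
  T[out$boundary_m2 == 1] <- 0
  out$rlrt_T <- T
  out$rlrt_p <- rlrt_pvalue(T)
  out <- out[, c("transcript", setdiff(names(out), "transcript"))]
  attr(out, "absorbed_biological") <- absorbed
  out
}

#' Expression filter on group means
#'
#' Keeps a transcript when at least one treatment group's summary
#' log-expression reaches `threshold` (both groups below means exclusion).
#'
#' @param Y expression matrix (transcripts x arrays).
#' @param groups group label per column of `Y`.
#' @param threshold log-scale threshold.
#' @param summary group summary: mean (default), min or max over the
#'   group's arrays.
#' @return logical vector: transcript kept?
#' @export
filter_expressed <- function(Y, groups, threshold = 8,
                             summary = c("mean", "min", "max")) {
  summary <- match.arg(summary)
  if (any(is.na(groups)))
    stop("every array must be mapped to a group")
  fun <- match.fun(summary)
  gs <- vapply(unique(groups), function(g)
    apply(Y[, groups == g, drop = FALSE], 1, fun), numeric(nrow(Y)))
  gs <- matrix(gs, nrow = nrow(Y))
  apply(gs, 1, max) >= threshold
}

#' Kendall rank agreement of two p-value rankings
#'
#' Tie-corrected Kendall's tau between the two p-value vectors restricted
#' to the union of each ranking's top-`k` transcripts.
#'
#' @param p_m1,p_m2 aligned p-value vectors.
#' @param k list depth (>= 2).
#' @return Kendall's tau.
#' @export
rank_agreement <- function(p_m1, p_m2, k = 100L) {
  stopifnot(length(p_m1) == length(p_m2))
  if (k < 2 || k > length(p_m1))
    stop("k must lie in [2, number of transcripts]")
  top <- union(order(p_m1)[seq_len(k)], order(p_m2)[seq_len(k)])
  stats::cor(p_m1[top], p_m2[top], method = "kendall")
}

array_groups <- function(design) {
  trt <- pool_treatment(design)
  as.character(trt[as.character(design$measurements$sample)])
}

#' Run the full per-transcript study on one dataset
#'
#' Filters low-expressed transcripts, fits m1 and m2 per transcript, tests
#' the blending variance (RLRT) and the treatment contrast (KR F-test,
#' both models), estimates pi0 and q-values separately for the three
#' p-value families, and assembles a study report (counts of transcripts
#' with a significant blending variance and of differentially expressed
#' transcripts per model, mean variance components, truth intersections
#' when simulation ground truth is supplied).
#'
#' @param Y expression matrix (transcripts x arrays) or a
#'   [simulate_experiment()] result (in which case `design` and `truth`
#'   are taken from it).
#' @param design the [pool_design()]; ignored when `Y` is a simulation.
#' @param truth optional simulation truth (list with `de` flags).
#' @param alpha FDR level.
#' @param threshold expression filter threshold (log scale).
#' @param cfg a [fit_config()].
#' @param pi0_method pi0 estimator for all families: `"bootstrap"` or
#'   `"one"`.
#' @param parameterization biological-effect parameterization, see
#'   [build_biological_matrices()].
#' @param seed seed for the pi0 bootstrap resamples.
#' @return list of class `study_result` with `records` (per-transcript
#'   table) and `report`.
#' @examples
#' sim <- simulate_experiment(sim_config(m = 60, n_de = 20, seed = 1))
#' st <- run_study(sim, seed = 1)
#' st$report$de_m1; st$report$de_m2
#' @export
run_study <- function(Y, design = NULL, truth = NULL, alpha = 0.05,
                      threshold = 8, cfg = fit_config(),
                      pi0_method = c("bootstrap", "one"),
                      parameterization = "composition", seed = 1L) {
  pi0_method <- match.arg(pi0_method)
  if (inherits(Y, "pool_simulation")) {
    design <- Y$design; truth <- Y$truth; Y <- Y$Y
  }
  stopifnot(inherits(design, "pool_design"))
  mats <- model_matrices(design, parameterization)
  groups <- array_groups(design)
  keep <- filter_expressed(Y, groups, threshold)
  fits <- fit_transcripts(Y[keep, , drop = FALSE], mats, cfg)

  set.seed(seed)
  fam <- list(rlrt = fits$rlrt_p, f_m1 = fits$pF_m1, f_m2 = fits$pF_m2)
  fdr <- lapply(fam, fdr_adjust, alpha = alpha, pi0_method = pi0_method)
  fits$q_rlrt <- fdr$rlrt$q_values
  fits$q_m1 <- fdr$f_m1$q_values
  fits$q_m2 <- fdr$f_m2$q_values

  sig_vc <- fdr$rlrt$significant
  de1 <- fdr$f_m1$significant
  de2 <- fdr$f_m2$significant

  report <- list(
    m_total = nrow(Y), m_pass = sum(keep),
    n_fit_failed = sum(is.na(fits$loglik_m2)),
    sign_vc = sum(sig_vc, na.rm = TRUE),
    pi1_rlrt = fdr$rlrt$pi1_hat,
    de_m1 = sum(de1, na.rm = TRUE), de_m2 = sum(de2, na.rm = TRUE),
    de_both = sum(de1 & de2, na.rm = TRUE),
    de_m1_only = sum(de1 & !de2, na.rm = TRUE),
    de_m2_only = sum(de2 & !de1, na.rm = TRUE),
    mean_vc_m1 = c(sigma1 = mean(fits$sigma1_m1, na.rm = TRUE),
                   sigmae = mean(fits$sigmae_m1, na.rm = TRUE)),
    mean_vc_m2 = c(sigma1 = mean(fits$sigma1_m2, na.rm = TRUE),
                   sigma2 = mean(fits$sigma2_m2, na.rm = TRUE),
                   sigmae = mean(fits$sigmae_m2, na.rm = TRUE)))
  if (sum(keep) >= 200)
    report$tau_top100 <- rank_agreement(fits$pF_m1, fits$pF_m2, 100L)

  if (!is.null(truth)) {
    de_sim <- truth$de[keep]
    n_null <- sum(!de_sim)
    venn <- table(m1 = de1, m2 = de2, sim = de_sim)
    report <- c(report, list(
      n_de_sim = sum(de_sim), n_null = n_null,
      missed_m1 = sum(de_sim & !de1, na.rm = TRUE),
      missed_m2 = sum(de_sim & !de2, na.rm = TRUE),
      false_m1 = sum(de1 & !de_sim, na.rm = TRUE),
      false_m2 = sum(de2 & !de_sim, na.rm = TRUE),
      false_m1_vc = sum(de1 & !de_sim & sig_vc, na.rm = TRUE),
      false_m2_vc = sum(de2 & !de_sim & sig_vc, na.rm = TRUE),
      fdp_m1 = sum(de1 & !de_sim, na.rm = TRUE) / n_null,
      fdp_m2 = sum(de2 & !de_sim, na.rm = TRUE) / n_null))
    report$venn <- venn
  }
  structure(list(records = fits, report = report, keep = keep,
                 alpha = alpha),
            class = "study_result")
}

report_vector <- function(report) {
  keep <- vapply(report, function(x) is.numeric(x) && length(x) == 1, TRUE)
  unlist(report[keep])
}

#' Replicate the simulated study and average the report
#'
#' Runs [simulate_experiment()] + [run_study()] on `reps` fresh replicates
#' (seeds `seed`, `seed + 1`, ...), averaging all scalar report fields and
#' attaching Monte-Carlo standard errors.
#'
#' @param cfg a [sim_config()]; its seed is the base seed.
#' @param reps number of repetitions (>= 1).
#' @param ... passed to [run_study()].
#' @return list of class `study_replication`: `mean`, `se`, `reps`,
#'   `per_rep` (matrix of per-replicate report values).
#' @export
replicate_study <- function(cfg, reps = 100L, ...) {
  stopifnot(reps >= 1)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    sim <- simulate_experiment(cfg_r)
    st <- run_study(sim, seed = cfg_r$seed, ...)
    rows[[r]] <- report_vector(st$report)
  }
  per_rep <- do.call(rbind, rows)
  structure(list(mean = colMeans(per_rep),
                 se = apply(per_rep, 2, stats::sd) / sqrt(reps),
                 reps = reps, per_rep = per_rep),
            class = "study_replication")
}

#' @export
print.study_result <- function(x, ...) {
  r <- x$report
  cat("Study of", r$m_total, "transcripts (", r$m_pass, "pass filter )\n",
      " significant blending VC:", r$sign_vc,
      "| pi1 =", signif(r$pi1_rlrt, 3), "\n",
      " DE at", x$alpha, "FDR: m1 =", r$de_m1, ", m2 =", r$de_m2,
      ", shared =", r$de_both, "\n")
  invisible(x)
}
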