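#' Dirichlet aliquot weights for a pool
#'
#' Draws the proportions with which each individual's RNA enters a pool of
#' size `gamma` from a symmetric Dirichlet with parameters
#' `a_i = 1/sigma_z2 - 1/gamma`. Each weight has expectation `1/gamma` and
#' variance `a_i (a_0 - a_i) / (a_0^2 (a_0 + 1)) ~= (gamma-1)/gamma^3 *
#' sigma_z2`, so `sigma_z2` parameterizes the pooling technical variance.
#'
#' @param gamma pool size (>= 2).
#' @param sigma_z2 pooling technical variance; must satisfy
#'   `0 <= sigma_z2 < gamma` so that `a_i > 0`. Zero returns exactly
#'   uniform weights.
#' @param n number of independent weight vectors.
#' @return an `n x gamma` matrix of weights (rows sum to 1).
#' @export
draw_weights <- function(gamma, sigma_z2, n = 1L) {
  stopifnot(gamma >= 2, n >= 1)
  if (sigma_z2 == 0)
    return(matrix(1 / gamma, n, gamma))
  if (sigma_z2 < 0 || sigma_z2 >= gamma)
    stop("sigma_z2 must lie in [0, gamma) so that the Dirichlet ",
         "parameters a_i = 1/sigma_z2 - 1/gamma stay positive ",
         "(got sigma_z2 = ", sigma_z2, ", gamma = ", gamma, ")")
  a <- 1 / sigma_z2 - 1 / gamma
  g <- matrix(stats::rgamma(n * gamma, shape = a), n, gamma)
  g / rowSums(g)
}

#' Pooled log-signal of individual log-expressions
#'
#' `log(sum_i w_i exp(x_i))`, evaluated with an overflow-safe
#' log-sum-exp. By Jensen's inequality the result is at least `w'x`.
#'
#' @param x individual log-expressions.
#' @param w aliquot weights (same length, positive, summing to 1).
#' @return pooled log-expression (scalar).
#' @export
pool_signal <- function(x, w) {
  if (length(x) != length(w)) stop("x and w must have equal length")
  stopifnot(all(w > 0), abs(sum(w) - 1) < 1e-8)
  mx <- max(x)
  mx + log(sum(w * exp(x - mx)))
}

#' Simulation configuration
#'
#' Defines the stochastic structure of a simulated pooled one-color
#' experiment: per-transcript means uniform on `mean_range`, a random DE
#' subset with effects uniform on `effect_range` times a random sign
#' applied to the second treatment group, individual log-expressions
#' `N(mean, sigma_b2)`, pooled signals via Dirichlet aliquot weights with
#' pooling technical variance `sigma_z2` for the blending-affected
#' transcript fraction `f` (uniform weights otherwise), and independent
#' `N(0, sigma_t2)` technical errors per measurement.
#'
#' The variance presets are `"mouse"` (`sigma_b2 = 0.103`,
#' `sigma_t2 = 0.017`, `sigma_z2 = 2.7`; the default, matching the
#' variance-component estimates of the pooled mouse experiment whose
#' layout the default design copies), `"power_study"` (`sigma_b2 = 0.094`,
#' `sigma_t2 = 0.017`, `sigma_z2 = 2.7`; used for the replicated
#' model-comparison study of differential-expression detection) and
#' `"high_noise"` (`sigma_b2 = 0.103`, `sigma_t2 = 0.17`,
#' `sigma_z2 = 2.7`; a sensitivity setting in which the technical
#' variance dominates the per-mixture blending variance).
#'
#' @param design a one-color [pool_design()]; default [mouse_like_design()].
#' @param m number of transcripts.
#' @param n_de number of differentially expressed transcripts.
#' @param effect_range range of the uniform treatment-effect magnitude.
#' @param mean_range range of the uniform per-transcript mean.
#' @param sigma_b2,sigma_t2,sigma_z2 biological, technical and pooling
#'   technical variances; defaults from `preset`.
#' @param blending_fraction fraction `f` of transcripts affected by
#'   imperfect blending.
#' @param weights_mode `"per-transcript"` (fresh Dirichlet weights per pool
#'   and transcript; matches the variance model being validated) or
#'   `"per-mixture"` (one draw per physical mixture shared by all
#'   transcripts).
#' @param seed integer seed.
#' @param preset variance preset, see Details.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(design = mouse_like_design(), m = 9000L,
                       n_de = 3000L, effect_range = c(0.5, 1.5),
                       mean_range = c(8, 14),
                       sigma_b2 = NULL, sigma_t2 = NULL, sigma_z2 = NULL,
                       blending_fraction = 1,
                       weights_mode = c("per-transcript", "per-mixture"),
                       seed = 1L,
                       preset = c("mouse", "power_study", "high_noise")) {
  preset <- match.arg(preset)
  weights_mode <- match.arg(weights_mode)
  pv <- switch(preset,
               mouse = list(b = 0.103, t = 0.017, z = 2.7),
               power_study = list(b = 0.094, t = 0.017, z = 2.7),
               high_noise = list(b = 0.103, t = 0.17, z = 2.7))
  cfg <- structure(list(
    design = design, m = as.integer(m), n_de = as.integer(n_de),
    effect_range = effect_range, mean_range = mean_range,
    sigma_b2 = sigma_b2 %||% pv$b, sigma_t2 = sigma_t2 %||% pv$t,
    sigma_z2 = sigma_z2 %||% pv$z,
    blending_fraction = blending_fraction,
    weights_mode = weights_mode, seed = as.integer(seed)),
    class = "sim_config")
  stopifnot(cfg$sigma_b2 >= 0, cfg$sigma_t2 >= 0, cfg$sigma_z2 >= 0,
            cfg$blending_fraction >= 0, cfg$blending_fraction <= 1,
            cfg$n_de <= cfg$m)
  cfg
}

#' Scenario presets for the blending-affected fraction
#'
#' `s1`, `s2`, `s3`: none, one third, and all transcripts carry a non-zero
#' blending error (affected transcripts chosen uniformly at random under
#' the configuration seed).
#'
#' @param name one of `"s1"`, `"s2"`, `"s3"`.
#' @param base a [sim_config()] to modify.
#' @return the modified `sim_config`.
#' @export
scenario <- function(name, base = sim_config()) {
  f <- switch(name, s1 = 0, s2 = 1 / 3, s3 = 1,
              stop("unknown scenario '", name, "'"))
  base$blending_fraction <- f
  base
}

#' Simulate a pooled expression experiment with full ground truth
#'
#' Generates the expression matrix (transcripts x arrays) for the
#' configured design. Per transcript, individual log-expressions are drawn
#' once and reused wherever the individual appears (single-individual
#' arrays and pools alike); each physical mixture gets one pooled
#' log-signal (Dirichlet-weighted for blending-affected transcripts,
#' uniform otherwise) shared by its technical replicates, which then differ
#' only by independent technical errors.
#'
#' The returned truth records, per transcript, the DE flag and effect and
#' the blending flag, and per pooled mixture the decomposition
#' `u1 = xbar - mu`, `u2 = log(w' exp(x)) - log(mean(exp(x)))` and the
#' log-bias `log(mean(exp(x))) - xbar`, which sum (with the fixed effects
#' and technical error) exactly to the observation.
#'
#' @param cfg a [sim_config()].
#' @param store_detail also store the individual log-expression matrix,
#'   technical errors and aliquot weights (for exact conservation checks).
#' @return list of class `pool_simulation`: `Y` (m x n matrix), `design`,
#'   `truth`, `config`.
#' @examples
#' sim <- simulate_experiment(scenario("s2", sim_config(m = 20, seed = 1)))
#' dim(sim$Y)
#' sum(sim$truth$blending)
#' @export
simulate_experiment <- function(cfg, store_detail = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- cfg$design
  if (design$platform != "one-color")
    stop("the simulator emulates one-color pooled designs")
  gam <- pool_sizes(design)
  pooled_ids <- design$pools$id[gam >= 2]
  if (cfg$blending_fraction > 0 && length(pooled_ids) &&
      cfg$sigma_z2 >= min(gam[pooled_ids]))
    stop("Dirichlet validity violated: sigma_z2 = ", cfg$sigma_z2,
         " >= smallest pool size ", min(gam[pooled_ids]),
         " (a_i = 1/sigma_z2 - 1/gamma must be positive)")

  set.seed(cfg$seed)
  m <- cfg$m
  ind <- design$individuals
  n_ind <- nrow(ind)
  group2 <- ind$treatment == design$treatment_levels[2]

  mu <- stats::runif(m, cfg$mean_range[1], cfg$mean_range[2])
  de <- rep(FALSE, m); de[sample.int(m, cfg$n_de)] <- TRUE
  effect <- numeric(m)
  effect[de] <- stats::runif(cfg$n_de, cfg$effect_range[1],
                             cfg$effect_range[2]) *
    sample(c(-1, 1), cfg$n_de, replace = TRUE)
  n_bl <- round(cfg$blending_fraction * m)
  blending <- rep(FALSE, m)
  if (n_bl > 0) blending[sample.int(m, n_bl)] <- TRUE

  # individual log-expressions, one draw per individual per transcript
  Xi <- mu + outer(effect, as.numeric(group2)) +
    matrix(stats::rnorm(m * n_ind, 0, sqrt(cfg$sigma_b2)), m, n_ind)
  colnames(Xi) <- ind$id

  meas <- design$measurements
  n <- nrow(meas)
  members <- stats::setNames(design$pools$members, design$pools$id)
  blend_of <- stats::setNames(as.character(design$pools$blend_event),
                              design$pools$id)
  events <- unique(blend_of[pooled_ids])

  pooled_val <- u1p <- u2p <- lbp <- matrix(NA_real_, m, length(events),
                                            dimnames = list(NULL, events))
  wstore <- if (store_detail) stats::setNames(vector("list", length(events)),
                                              events) else NULL
  for (e in events) {
    p <- pooled_ids[match(e, blend_of[pooled_ids])]
    mem <- match(members[[p]], ind$id)
    g <- length(mem)
    E <- exp(Xi[, mem, drop = FALSE] - 12)  # shift for numerical headroom
    W <- matrix(1 / g, m, g)
    aff <- which(blending)
    if (length(aff)) {
      if (cfg$weights_mode == "per-transcript") {
        W[aff, ] <- draw_weights(g, cfg$sigma_z2, length(aff))
      } else {
        W[aff, ] <- matrix(draw_weights(g, cfg$sigma_z2, 1L),
                           length(aff), g, byrow = TRUE)
      }
    }
    unif <- log(rowMeans(E)) + 12
    pooled <- unif  # uniform weights: u2 identically zero
    if (length(aff))
      pooled[aff] <- log(rowSums(W[aff, , drop = FALSE] *
                                   E[aff, , drop = FALSE])) + 12
    xbar <- rowMeans(Xi[, mem, drop = FALSE])
    grp_mu <- mu + effect * as.numeric(group2[mem[1]])
    pooled_val[, e] <- pooled
    u1p[, e] <- xbar - grp_mu
    u2p[, e] <- pooled - unif
    lbp[, e] <- unif - xbar
    if (store_detail) wstore[[e]] <- W
  }

  eps <- matrix(stats::rnorm(m * n, 0, sqrt(cfg$sigma_t2)), m, n)
  Y <- matrix(NA_real_, m, n,
              dimnames = list(sprintf("t%05d", seq_len(m)),
                              as.character(meas$array)))
  for (j in seq_len(n)) {
    s <- as.character(meas$sample[j])
    if (gam[[s]] == 1) {
      Y[, j] <- Xi[, match(members[[s]], ind$id)] + eps[, j]
    } else {
      Y[, j] <- pooled_val[, blend_of[[s]]] + eps[, j]
    }
  }

  truth <- list(mu = mu, de = de, effect = effect, blending = blending,
                u1 = u1p, u2 = u2p, log_bias = lbp, events = events)
  if (store_detail) {
    truth$x <- Xi
    truth$eps <- eps
    truth$weights <- wstore
  }
  structure(list(Y = Y, design = design, truth = truth, config = cfg),
            class = "pool_simulation")
}
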