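# Small designs and generators shared across the test files.

# Two groups; per group: two singles plus two pools (sizes 3 and 2),
# pools in technical duplicate.  14 arrays, small enough for brute-force
# oracles.
small_pooled_design <- function() {
  ind <- data.frame(id = c(sprintf("a%d", 1:7), sprintf("b%d", 1:7)),
                    treatment = rep(c("ctl", "trt"), each = 7))
  pools <- data.frame(
    id = c("a1s", "a2s", "PA1", "PA2", "b1s", "b2s", "PB1", "PB2"),
    members = I(list("a1", "a2", c("a3", "a4", "a5"), c("a6", "a7"),
                     "b1", "b2", c("b3", "b4", "b5"), c("b6", "b7"))))
  samples <- c("a1s", "a2s", "PA1", "PA1", "PA2", "PA2",
               "b1s", "b2s", "PB1", "PB1", "PB2", "PB2")
  meas <- data.frame(array = sprintf("r%02d", seq_along(samples)),
                     channel = "single", sample = samples)
  pool_design(ind, pools, meas, platform = "one-color",
              treatment_levels = c("ctl", "trt"))
}

# all-singleton design: gamma = 1 everywhere, one measurement each
singleton_design <- function(n_per_group = 5) {
  ids <- c(sprintf("c%d", seq_len(n_per_group)),
           sprintf("t%d", seq_len(n_per_group)))
  ind <- data.frame(id = ids,
                    treatment = rep(c("ctl", "trt"), each = n_per_group))
  pools <- data.frame(id = paste0(ids, "s"), members = I(as.list(ids)))
  meas <- data.frame(array = paste0("arr_", ids), channel = "single",
                     sample = paste0(ids, "s"))
  pool_design(ind, pools, meas, platform = "one-color",
              treatment_levels = c("ctl", "trt"))
}

# hand-built model_matrices (for layouts outside the design grammar,
# e.g. a pure one-way random-effects model with intercept-only X)
make_mats <- function(X, Z1, G1, Z2 = NULL, G2 = NULL, treatment_cols = 2) {
  n <- nrow(X)
  if (is.null(Z2)) { Z2 <- matrix(0, n, 0); G2 <- matrix(0, 0, 0) }
  structure(list(X = X, treatment_cols = treatment_cols, Z1 = Z1, G1 = G1,
                 Z2 = Z2, G2 = G2, n = n, rows = seq_len(n),
                 parameterization = "manual"),
            class = "model_matrices")
}

# two-color layout echoing the bee experiment: 6 sample compositions
# (sizes 1, 2, 4 mixed across two behaviors), three tissues, 22 arrays
bee_like_design <- function() {
  ind <- data.frame(id = c(sprintf("h%d", 1:7), sprintf("c%d", 1:7)),
                    treatment = rep(c("hygienic", "control"), each = 7))
  pools <- data.frame(
    id = sprintf("S%d", 1:6),
    members = I(list("h1", c("h2", "h3"), c("h4", "h5", "h6", "h7"),
                     "c1", c("c2", "c3"), c("c4", "c5", "c6", "c7"))))
  tissues <- c("MB", "AL", "ANT")
  # arrays pair a hygienic with a control composition within one tissue
  pairs <- rbind(c(1, 4), c(2, 5), c(3, 6), c(2, 4), c(1, 5), c(3, 4),
                 c(2, 6))
  rows <- list()
  a <- 0
  for (ti in tissues) {
    np <- if (ti == "MB") 8 else 7
    for (k in seq_len(np)) {
      a <- a + 1
      pr <- pairs[((k - 1) %% nrow(pairs)) + 1, ]
      if (k %% 2 == 0) pr <- rev(pr)  # dye swap
      rows[[length(rows) + 1]] <- data.frame(
        array = sprintf("arr%02d", a),
        channel = c("red", "green"),
        sample = sprintf("S%d", pr), tissue = ti)
    }
  }
  meas <- do.call(rbind, rows)
  pool_design(ind, pools, meas, platform = "two-color",
              treatment_levels = c("control", "hygienic"),
              array_covariates = "tissue")
}

# exact Gaussian draws from the fitted model family
gaussian_transcripts <- function(mats, vc, m, mu = 10, delta = 0,
                                 seed = 1) {
  set.seed(seed)
  V <- assemble_covariance(mats, vc)
  R <- chol(V)
  mean_row <- drop(mats$X %*% c(mu, rep(delta, ncol(mats$X) - 1)))
  sweep(matrix(rnorm(m * mats$n), m, mats$n) %*% R, 2, mean_row, "+")
}
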