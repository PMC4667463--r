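#!/usr/bin/env Rscript
# Null calibration of the blending-variance RLRT (scenario s1).
#
# Simulates one 9000-transcript pooled experiment with perfectly blended
# pools (pooling technical variance zero for every transcript), fits both
# models per transcript and summarizes the RLRT p-value distribution: the
# fraction of exact ones (the boundary point mass), uniformity of the
# sub-unity p-values, the estimated non-null fraction pi1, and the number
# of transcripts called significant at a 5 % FDR.

suppressPackageStartupMessages(library(poolvar))
dir.create("results", showWarnings = FALSE)

design <- mouse_like_design()
mats <- model_matrices(design, "composition")
cfg <- scenario("s1", sim_config(m = 9000, seed = 1))
sim <- simulate_experiment(cfg)
ft <- fit_transcripts(sim$Y, mats, kr = FALSE)

set.seed(1)
f <- fdr_adjust(ft$rlrt_p)
u <- ft$rlrt_p[ft$rlrt_p < 0.5] * 2
out <- data.frame(
  frac_p_one = mean(ft$rlrt_p == 1),
  ks_p_uniform = stats::ks.test(u, "punif")$p.value,
  pi1_hat = f$pi1_hat,
  sign_vc = sum(f$significant),
  nonconverged_m2 = sum(ft$converged_m2 == 0))
write.table(out, "results/01_null_calibration.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Under the complete null,", round(100 * out$frac_p_one, 1),
    "% of transcripts sit on the p = 1 point mass;", out$sign_vc,
    "of 9000 are (wrongly) declared at 5 % FDR; pi1_hat =",
    signif(out$pi1_hat, 3), "\n")
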