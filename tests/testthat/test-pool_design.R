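test_that("the 44-array pooled layout builds the expected design matrices", {
  d <- mouse_like_design()
  mats <- model_matrices(d, "individual")
  expect_equal(dim(mats$Z1), c(44, 28))
  expect_equal(dim(mats$Z2), c(44, 12))
  expect_equal(dim(mats$X), c(44, 2))
  # first 10 rows: identity block for the individually measured animals
  expect_equal(unname(mats$Z1[1:10, 1:10]), diag(10))
  expect_true(all(mats$Z1[1:10, 11:28] == 0))
  # rows 11-14 (first two pools in duplicate): five entries of 0.2
  for (r in 11:14) {
    expect_equal(sum(mats$Z1[r, ] == 0.2), 5)
    expect_equal(sum(mats$Z1[r, ]), 1)
  }
  # pools three to six carry a composite effect of their own (single 1)
  for (r in 15:22) expect_equal(sum(mats$Z1[r, ] == 1), 1)
  # G1 diagonal: 1 for individual effects, 1/5 for composite pools
  expect_true(all(diag(mats$G1) %in% c(1, 0.2)))
  expect_equal(sum(diag(mats$G1) == 0.2), 8)
  # blending covariance: (gamma-1)/gamma^2 = 4/25 for every pool of five
  expect_equal(unname(diag(mats$G2)), rep(4 / 25, 12))
  # technical replicates of one mixture share one blending effect
  expect_equal(mats$Z2[11, ], mats$Z2[12, ])
  expect_true(all(mats$Z2[1:10, ] == 0))
})

test_that("blending covariance entries follow (gamma-1)/gamma^2", {
  # rat-style pool sizes
  sizes <- c(2, 3, 5, 12)
  ind <- data.frame(id = c(sprintf("i%02d", 1:22), "u1"),
                    treatment = c(rep("A", 22), "B"))
  pools <- data.frame(id = sprintf("P%d", 1:4),
                      members = I(split(sprintf("i%02d", 1:22),
                                        rep(1:4, times = sizes))))
  meas <- data.frame(array = sprintf("a%d", 1:4), channel = "single",
                     sample = sprintf("P%d", 1:4))
  # make pools treatment-homogeneous: all members drawn from group A
  d <- pool_design(ind, pools, meas, treatment_levels = c("A", "B"))
  bl <- build_blending_matrices(d)
  expect_equal(unname(diag(bl$G2)), c(1 / 4, 2 / 9, 4 / 25, 11 / 144))
  # single-individual samples contribute no blending effect
  d2 <- singleton_design()
  bl2 <- build_blending_matrices(d2)
  expect_equal(ncol(bl2$Z2), 0)
})

test_that("individual parameterization of fully-resolved designs gives identity G1", {
  # every individual used in several compositions (rat-style):
  # singles plus one pool of 2 and one of 3 reusing the same animals
  ind <- data.frame(id = sprintf("r%d", 1:3),
                    treatment = rep(c("A", "B"), length.out = 3))
  ind$treatment <- c("A", "A", "A")
  ind <- rbind(ind, data.frame(id = "z", treatment = "B"))
  pools <- data.frame(id = c("s1", "s2", "s3", "P2", "P3", "zs"),
                      members = I(list("r1", "r2", "r3", c("r1", "r2"),
                                       c("r1", "r2", "r3"), "z")))
  meas <- data.frame(array = sprintf("a%d", 1:6), channel = "single",
                     sample = c("s1", "s2", "s3", "P2", "P3", "zs"))
  d <- pool_design(ind, pools, meas, treatment_levels = c("A", "B"))
  bio <- build_biological_matrices(d, "individual")
  expect_equal(unname(bio$G1), diag(4))
  # rows carry reciprocal pool sizes
  expect_equal(unname(bio$Z1[4, 1:2]), c(1 / 2, 1 / 2))
  expect_equal(unname(bio$Z1[5, 1:3]), rep(1 / 3, 3))
  expect_equal(unname(bio$Z1[1, 1]), 1)
})

test_that("composition G1 encodes membership overlap", {
  ind <- data.frame(id = sprintf("i%d", 1:6),
                    treatment = rep(c("A", "B"), each = 3))
  ind$treatment <- "A"
  ind <- rbind(ind, data.frame(id = "w", treatment = "B"))
  pools <- data.frame(id = c("P1", "P2", "ws"),
                      members = I(list(c("i1", "i2", "i3"),
                                       c("i3", "i4", "i5"), "w")))
  meas <- data.frame(array = c("a1", "a2", "a3"), channel = "single",
                     sample = c("P1", "P2", "ws"))
  d <- pool_design(ind, pools, meas, treatment_levels = c("A", "B"))
  bio <- build_biological_matrices(d, "composition")
  # overlap of one individual between two pools of three: 1/(3*3)
  expect_equal(bio$G1[1, 2], 1 / 9)
  expect_equal(diag(bio$G1), c(1 / 3, 1 / 3, 1), ignore_attr = TRUE)
  # brute-force oracle: covariance of averages of iid unit-variance effects
  w1 <- c(1, 1, 1, 0, 0, 0, 0) / 3
  w2 <- c(0, 0, 1, 1, 1, 0, 0) / 3
  expect_equal(bio$G1[1, 2], sum(w1 * w2))
})

test_that("individual and composition parameterizations give identical Z1 G1 Z1'", {
  for (d in list(mouse_like_design(), small_pooled_design())) {
    a <- build_biological_matrices(d, "individual")
    b <- build_biological_matrices(d, "composition")
    Va <- a$Z1 %*% a$G1 %*% t(a$Z1)
    Vb <- b$Z1 %*% b$G1 %*% t(b$Z1)
    expect_lt(max(abs(Va - Vb)), 1e-12)
  }
})

test_that("assembled covariance matches the closed-form pool variance", {
  d <- small_pooled_design()
  mats <- model_matrices(d, "composition")
  s1 <- 0.4; s2 <- 0.25; se <- 0.1
  V <- assemble_covariance(mats, list(sigma1 = s1, sigma2 = s2, sigmae = se))
  expect_equal(V, t(V))
  expect_true(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) >
                -1e-12)
  # row 3 measures the pool of three: sigma1/3 + sigma2*2/9 + sigmae
  expect_equal(V[3, 3], s1 / 3 + s2 * 2 / 9 + se)
  # singles: sigma1 + sigmae, no blending
  expect_equal(V[1, 1], s1 + se)
  # technical replicates of one mixture covary via u1 and u2
  expect_equal(V[3, 4], s1 / 3 + s2 * 2 / 9)
  # zero variance components collapse to white noise
  V0 <- assemble_covariance(mats, list(sigma1 = 0, sigma2 = 0, sigmae = 2))
  expect_equal(V0, diag(2, mats$n))
})

test_that("two-color designs difference the channels", {
  d <- bee_like_design()
  fx <- build_fixed_design(d)
  expect_equal(dim(fx$X), c(22, 4))  # mean, behavior, two tissue contrasts
  bio <- build_biological_matrices(d, "composition")
  bl <- build_blending_matrices(d)
  # each array row: +1 on the red composition, -1 on the green one
  expect_true(all(rowSums(bio$Z1) == 0))
  expect_true(all(abs(bio$Z1) %in% c(0, 1)))
  expect_true(all(rowSums(abs(bio$Z1)) == 2))
  # blending rows sum to the red-minus-green count of pooled samples
  expect_true(all(bl$Z2 %in% c(-1, 0, 1)))
  # red and green samples from the same treatment level cancel
  ind <- data.frame(id = c("x1", "x2"), treatment = c("T", "T"))
  ind <- rbind(ind, data.frame(id = "y1", treatment = "C"))
  pools <- data.frame(id = c("xs1", "xs2", "ys"),
                      members = I(list("x1", "x2", "y1")))
  meas <- data.frame(array = c("a1", "a1", "a2", "a2"),
                     channel = c("red", "green", "red", "green"),
                     sample = c("xs1", "xs2", "xs1", "ys"))
  d2 <- pool_design(ind, pools, meas, platform = "two-color",
                    treatment_levels = c("C", "T"))
  X2 <- build_fixed_design(d2)$X
  expect_equal(unname(X2[1, "treatmentT"]), 0)
  expect_equal(unname(X2[2, "treatmentT"]), 1)
})

test_that("reference coding of a two-group one-color design", {
  d <- singleton_design(2)
  X <- build_fixed_design(d)$X
  expect_equal(unname(X), cbind(1, c(0, 0, 1, 1)))
})

test_that("invalid designs are rejected with informative errors", {
  ind <- data.frame(id = c("i1", "i2"), treatment = c("A", "B"))
  pools_bad <- data.frame(id = "P1", members = I(list(c("i1", "nope"))))
  meas <- data.frame(array = "a1", channel = "single", sample = "P1")
  expect_error(pool_design(ind, pools_bad, meas,
                           treatment_levels = c("A", "B")),
               "unknown individual")
  pools_empty <- data.frame(id = "P1", members = I(list(character())))
  expect_error(pool_design(ind, pools_empty, meas,
                           treatment_levels = c("A", "B")), "empty")
  pools_mixed <- data.frame(id = "P1", members = I(list(c("i1", "i2"))))
  expect_error(pool_design(ind, pools_mixed, meas,
                           treatment_levels = c("A", "B")), "mixes treatment")
  expect_error(pool_design(ind, data.frame(id = "P1",
                                           members = I(list("i1"))),
                           meas, treatment_levels = c("A")), "at least 2")
  # treatment confounded: only one group ever measured
  ind2 <- data.frame(id = c("i1", "i2"), treatment = c("A", "B"))
  pools2 <- data.frame(id = c("s1", "s2"), members = I(list("i1", "i1")))
  expect_error(pool_design(ind2, pools2,
                           data.frame(array = c("a1", "a2"),
                                      channel = "single",
                                      sample = c("s1", "s2")),
                           treatment_levels = c("A", "B")) |>
                 build_fixed_design(), "confounded")
})

test_that("designs survive a YAML round trip", {
  d <- small_pooled_design()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pool_design(d, path)
  d2 <- read_pool_design(path)
  m1 <- model_matrices(d, "composition")
  m2 <- model_matrices(d2, "composition")
  for (nm in c("X", "Z1", "G1", "Z2", "G2"))
    expect_equal(unname(m1[[nm]]), unname(m2[[nm]]))
  expect_error(read_pool_design(withr::local_tempfile(lines = "platform: x")),
               "misses section")
})

test_that("matrix export writes one TSV per matrix", {
  mats <- model_matrices(small_pooled_design())
  dir <- withr::local_tempdir()
  paths <- export_matrices(mats, dir)
  expect_true(all(file.exists(file.path(dir, c("X.tsv", "Z1.tsv", "G1.tsv",
                                               "Z2.tsv", "G2.tsv")))))
  Z1 <- as.matrix(utils::read.delim(file.path(dir, "Z1.tsv"),
                                    row.names = 1, check.names = FALSE))
  expect_equal(unname(Z1), unname(mats$Z1))
})
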