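#' Declarative description of a pooled expression experiment
#'
#' A pool design records which individuals were blended into which RNA pools,
#' which sample was hybridized on which array (and channel, for two-color
#' platforms), and the fixed-effect structure (treatment plus optional
#' nuisance factors). It is the single source from which all model matrices
#' are built.
#'
#' @param individuals data.frame with columns `id` (unique labels) and
#'   `treatment` (one of `treatment_levels`); further columns are kept as
#'   individual-level covariates.
#' @param pools data.frame with columns `id`, `members` (a list column of
#'   character vectors of individual ids) and optionally `blend_event`
#'   (label of the physical mixture; defaults to the pool id, i.e. every
#'   pool blended once). A pool of size one represents a single-individual
#'   sample.
#' @param measurements data.frame with columns `array`, `channel`
#'   (`"single"` for one-color platforms, `"red"`/`"green"` for two-color)
#'   and `sample` (a pool id); further columns are measurement-level
#'   covariates (e.g. tissue).
#' @param platform `"one-color"` or `"two-color"`.
#' @param treatment_levels character vector (length >= 2) of declared
#'   treatment levels; the first level is the reference.
#' @param array_covariates names of measurement columns entering the fixed
#'   design as array-level effects (two-color platforms only; sample-level
#'   treatment is always differenced between channels, array-level
#'   covariates enter undifferenced).
#'
#' @return An object of class `pool_design`.
#' @export
pool_design <- function(individuals, pools, measurements,
                        platform = c("one-color", "two-color"),
                        treatment_levels = NULL,
                        array_covariates = character()) {
  platform <- match.arg(platform)
  individuals <- as.data.frame(individuals)
  pools <- as.data.frame(pools)
  measurements <- as.data.frame(measurements)

  stopifnot(all(c("id", "treatment") %in% names(individuals)),
            all(c("id", "members") %in% names(pools)),
            all(c("array", "channel", "sample") %in% names(measurements)))
  if (anyDuplicated(individuals$id))
    stop("duplicated individual ids: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  if (anyDuplicated(pools$id))
    stop("duplicated pool ids: ",
         paste(unique(pools$id[duplicated(pools$id)]), collapse = ", "))
  if (is.null(treatment_levels))
    treatment_levels <- unique(as.character(individuals$treatment))
  if (length(treatment_levels) < 2)
    stop("a design needs at least 2 treatment levels for DE testing")
  bad_trt <- setdiff(unique(as.character(individuals$treatment)), treatment_levels)
  if (length(bad_trt))
    stop("undeclared treatment level(s): ", paste(bad_trt, collapse = ", "))

  if (!is.list(pools$members)) pools$members <- as.list(pools$members)
  if (is.null(pools$blend_event)) pools$blend_event <- pools$id
  for (i in seq_len(nrow(pools))) {
    mem <- pools$members[[i]]
    if (length(mem) < 1)
      stop("pool '", pools$id[i], "' is empty")
    unknown <- setdiff(mem, individuals$id)
    if (length(unknown))
      stop("pool '", pools$id[i], "' references unknown individual(s): ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(mem))
      stop("pool '", pools$id[i], "' lists an individual twice")
    trts <- unique(individuals$treatment[match(mem, individuals$id)])
    if (length(trts) > 1)
      stop("pool '", pools$id[i], "' mixes treatment levels: ",
           paste(trts, collapse = ", "))
  }

  unknown_s <- setdiff(unique(measurements$sample), pools$id)
  if (length(unknown_s))
    stop("measurement(s) reference unknown sample(s): ",
         paste(unknown_s, collapse = ", "))
  ch <- as.character(measurements$channel)
  if (platform == "one-color") {
    if (!all(ch == "single"))
      stop("one-color designs must use channel = 'single' for every measurement")
  } else {
    if (!all(ch %in% c("red", "green")))
      stop("two-color designs must use channel 'red' or 'green'")
    tab <- table(measurements$array, ch)
    if (!all(tab == 1) || ncol(tab) != 2)
      stop("each two-color array needs exactly one red and one green measurement")
  }
  missing_cov <- setdiff(array_covariates, names(measurements))
  if (length(missing_cov))
    stop("array covariate(s) not found among measurement columns: ",
         paste(missing_cov, collapse = ", "))

  structure(list(platform = platform,
                 treatment_levels = treatment_levels,
                 individuals = individuals,
                 pools = pools,
                 measurements = measurements,
                 array_covariates = array_covariates),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  gam <- vapply(x$pools$members, length, 1L)
  cat("pool_design:", x$platform, "platform\n",
      " individuals:", nrow(x$individuals),
      "| pools:", nrow(x$pools),
      paste0("(sizes ", paste(sort(unique(gam)), collapse = ","), ")"),
      "| measurements:", nrow(x$measurements), "\n",
      " treatment levels:", paste(x$treatment_levels, collapse = ", "), "\n")
  invisible(x)
}

pool_sizes <- function(design) {
  stats::setNames(vapply(design$pools$members, length, 1L), design$pools$id)
}

pool_treatment <- function(design) {
  stats::setNames(
    as.character(design$individuals$treatment[
      match(vapply(design$pools$members, `[`, "", 1), design$individuals$id)]),
    design$pools$id)
}

# rows of the design, one per response entry: measurements for one-color,
# arrays (red minus green) for two-color
design_rows <- function(design) {
  if (design$platform == "one-color") {
    list(n = nrow(design$measurements),
         labels = as.character(design$measurements$array))
  } else {
    arrays <- unique(as.character(design$measurements$array))
    list(n = length(arrays), labels = arrays)
  }
}

#' Fixed-effects design matrix
#'
#' Builds the fixed design `X` for a pool design. One-color platforms get an
#' intercept plus reference-coded treatment (plus any declared array
#' covariates). Two-color platforms are modeled on per-array log-ratio
#' differences: each row is the red sample's covariate row minus the green
#' sample's, with an intercept column of ones absorbing the dye effect and
#' array-level covariates entering undifferenced.
#'
#' @param design a [pool_design()].
#' @return list with `X` (n x p matrix, labeled columns), `treatment_cols`
#'   (indices of the treatment contrast columns), and `rows` (response row
#'   labels: arrays).
#' @export
build_fixed_design <- function(design) {
  trt <- factor(pool_treatment(design), levels = design$treatment_levels)
  lev <- design$treatment_levels
  trt_code <- function(pool_ids) {
    # reference coding: indicator columns for levels 2..k
    f <- trt[pool_ids]
    out <- vapply(lev[-1], function(l) as.numeric(f == l),
                  numeric(length(pool_ids)))
    matrix(out, nrow = length(pool_ids),
           dimnames = list(NULL, paste0("treatment", lev[-1])))
  }
  cov_code <- function(values, name) {
    f <- factor(values)
    if (nlevels(f) < 2) return(NULL)
    out <- vapply(levels(f)[-1], function(l) as.numeric(f == l),
                  numeric(length(f)))
    matrix(out, nrow = length(f),
           dimnames = list(NULL, paste0(name, levels(f)[-1])))
  }

  meas <- design$measurements
  if (design$platform == "one-color") {
    X <- cbind(`(Intercept)` = 1, trt_code(as.character(meas$sample)))
    for (cv in design$array_covariates)
      X <- cbind(X, cov_code(meas[[cv]], cv))
    rows <- as.character(meas$array)
  } else {
    arrays <- unique(as.character(meas$array))
    redm <- meas[meas$channel == "red", , drop = FALSE]
    greenm <- meas[meas$channel == "green", , drop = FALSE]
    red <- redm[match(arrays, as.character(redm$array)), , drop = FALSE]
    green <- greenm[match(arrays, as.character(greenm$array)), , drop = FALSE]
    X <- cbind(`(Intercept)` = 1,
               trt_code(as.character(red$sample)) -
                 trt_code(as.character(green$sample)))
    for (cv in design$array_covariates) {
      # array-level: red and green rows agree, take the red one
      X <- cbind(X, cov_code(red[[cv]], cv))
    }
    rows <- arrays
  }
  rownames(X) <- rows
  treatment_cols <- which(startsWith(colnames(X), "treatment"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    if (any(startsWith(aliased, "treatment")))
      stop("treatment is confounded with the intercept/other fixed effects ",
           "(aliased columns: ", paste(aliased, collapse = ", "), ")")
    stop("rank-deficient fixed design (aliased columns: ",
         paste(aliased, collapse = ", "), ")")
  }
  list(X = X, treatment_cols = treatment_cols, rows = rows)
}

# signed incidence of samples on response rows: one-color -> one +1 entry per
# row; two-color -> +1 red sample, -1 green sample
sample_incidence <- function(design) {
  meas <- design$measurements
  if (design$platform == "one-color") {
    rows <- as.character(meas$array)
    data.frame(row = seq_along(rows), sample = as.character(meas$sample),
               sign = 1)
  } else {
    arrays <- unique(as.character(meas$array))
    idx <- match(as.character(meas$array), arrays)
    data.frame(row = idx, sample = as.character(meas$sample),
               sign = ifelse(meas$channel == "red", 1, -1))
  }
}

#' Biological design and covariance matrices
#'
#' Builds `Z1` (incidence of biological effects on observations) and `G1`
#' (their covariance scaler) under one of two equivalent parameterizations.
#'
#' `"individual"`: one effect per individually-resolved individual (an
#' individual is resolved when it appears in a size-1 pool or in more than
#' one distinct composition) plus one composite effect per pool whose
#' members are never resolved. `Z1` carries `1/gamma` for each resolved
#' member of a measured sample (1 for singles and for composite-pool
#' measurements); `G1` is diagonal with 1 for individual effects and
#' `1/gamma` for composite-pool effects.
#'
#' `"composition"`: one effect per distinct sample composition (member set);
#' `Z1` entries are 1 (+1/-1 per channel for two-color) and
#' `G1[i, j] = |members_i intersect members_j| / (gamma_i * gamma_j)`,
#' so the diagonal is `1/gamma_i`.
#'
#' Both give identical marginal covariance contributions `Z1 G1 Z1'`.
#'
#' @param design a [pool_design()].
#' @param parameterization `"composition"` (default) or `"individual"`.
#' @return list with matrices `Z1`, `G1` and the effect labels.
#' @export
build_biological_matrices <- function(design,
                                      parameterization = c("composition",
                                                           "individual")) {
  parameterization <- match.arg(parameterization)
  inc <- sample_incidence(design)
  n <- design_rows(design)$n
  gam <- pool_sizes(design)
  members <- stats::setNames(design$pools$members, design$pools$id)

  if (parameterization == "composition") {
    key <- vapply(members, function(m) paste(sort(m), collapse = "|"), "")
    comp_keys <- unique(key)
    comp_members <- lapply(comp_keys,
                           function(k) sort(members[[match(k, key)]]))
    q1 <- length(comp_keys)
    Z1 <- matrix(0, n, q1,
                 dimnames = list(NULL, paste0("comp", seq_len(q1))))
    ci <- match(key[inc$sample], comp_keys)
    for (r in seq_len(nrow(inc)))
      Z1[inc$row[r], ci[r]] <- Z1[inc$row[r], ci[r]] + inc$sign[r]
    G1 <- matrix(0, q1, q1)
    sizes <- vapply(comp_members, length, 1L)
    for (i in seq_len(q1)) for (j in i:q1) {
      ov <- length(intersect(comp_members[[i]], comp_members[[j]]))
      G1[i, j] <- G1[j, i] <- ov / (sizes[i] * sizes[j])
    }
    dimnames(G1) <- list(colnames(Z1), colnames(Z1))
    return(list(Z1 = Z1, G1 = G1, effects = comp_members,
                parameterization = "composition"))
  }

  # individual parameterization
  key <- vapply(members, function(m) paste(sort(m), collapse = "|"), "")
  n_comp_of_ind <- table(unlist(lapply(unique(key), function(k)
    members[[match(k, key)]])))
  singles <- unlist(members[gam == 1])
  resolved <- union(singles,
                    names(n_comp_of_ind)[n_comp_of_ind > 1])
  resolved <- design$individuals$id[design$individuals$id %in% resolved]
  composite_pools <- design$pools$id[
    !vapply(members, function(m) any(m %in% resolved), TRUE)]
  # distinct composite compositions (re-blended pools share the effect)
  comp_key <- key[composite_pools]
  composite_eff <- composite_pools[!duplicated(comp_key)]
  eff_labels <- c(as.character(resolved),
                  if (length(composite_eff)) paste0("pool:", composite_eff))
  q1 <- length(eff_labels)
  Z1 <- matrix(0, n, q1, dimnames = list(NULL, eff_labels))
  g1 <- c(rep(1, length(resolved)),
          gam[composite_eff]^-1)
  eff_of_pool <- function(p) {
    m <- members[[p]]
    if (all(m %in% resolved)) {
      list(idx = match(m, eff_labels), w = rep(1 / length(m), length(m)))
    } else if (!any(m %in% resolved)) {
      k <- key[[p]]
      eff <- paste0("pool:", composite_eff[match(k, comp_key[!duplicated(comp_key)])])
      list(idx = match(eff, eff_labels), w = 1)
    } else {
      stop("pool '", p, "' mixes resolved and unresolved individuals; ",
           "use the composition parameterization")
    }
  }
  for (r in seq_len(nrow(inc))) {
    e <- eff_of_pool(inc$sample[r])
    Z1[inc$row[r], e$idx] <- Z1[inc$row[r], e$idx] + inc$sign[r] * e$w
  }
  G1 <- diag(g1, q1)
  dimnames(G1) <- list(eff_labels, eff_labels)
  list(Z1 = Z1, G1 = G1, effects = eff_labels,
       parameterization = "individual")
}

#' Blending design and covariance matrices
#'
#' One random effect per blend event of a pool with at least two members;
#' `G2` is diagonal with entries `(gamma - 1) / gamma^2` and `Z2` carries 1
#' (one-color; identical across technical replicates of the same mixture)
#' or +1/-1 per channel (two-color). Rows for single-individual samples are
#' zero.
#'
#' @inheritParams build_biological_matrices
#' @return list with matrices `Z2`, `G2` and the blend-event labels.
#' @export
build_blending_matrices <- function(design) {
  inc <- sample_incidence(design)
  n <- design_rows(design)$n
  gam <- pool_sizes(design)
  be <- as.character(design$pools$blend_event)
  keep <- gam >= 2
  events <- unique(be[keep])
  q2 <- length(events)
  Z2 <- matrix(0, n, q2, dimnames = list(NULL, events))
  g2 <- numeric(q2)
  event_of_pool <- stats::setNames(be, design$pools$id)
  for (p in design$pools$id[keep]) {
    e <- match(event_of_pool[[p]], events)
    gp <- (gam[[p]] - 1) / gam[[p]]^2
    if (g2[e] != 0 && abs(g2[e] - gp) > 1e-12)
      stop("blend event '", events[e], "' shared by pools of different sizes")
    g2[e] <- gp
  }
  pooled <- inc$sample %in% design$pools$id[keep]
  for (r in which(pooled)) {
    e <- match(event_of_pool[[inc$sample[r]]], events)
    Z2[inc$row[r], e] <- Z2[inc$row[r], e] + inc$sign[r]
  }
  G2 <- diag(g2, q2)
  dimnames(G2) <- list(events, events)
  list(Z2 = Z2, G2 = G2, events = events)
}

#' Realize all model matrices for a design
#'
#' @inheritParams build_biological_matrices
#' @return an object of class `model_matrices`: list with `X`,
#'   `treatment_cols`, `Z1`, `G1`, `Z2`, `G2`, `n`, and row labels.
#' @export
model_matrices <- function(design,
                           parameterization = c("composition", "individual")) {
  parameterization <- match.arg(parameterization)
  fx <- build_fixed_design(design)
  bio <- build_biological_matrices(design, parameterization)
  bl <- build_blending_matrices(design)
  structure(list(X = fx$X, treatment_cols = fx$treatment_cols,
                 Z1 = bio$Z1, G1 = bio$G1, Z2 = bl$Z2, G2 = bl$G2,
                 n = nrow(fx$X), rows = fx$rows,
                 parameterization = parameterization),
            class = "model_matrices")
}

#' Marginal covariance of the observations
#'
#' `V(y) = Z1 G1 Z1' sigma1^2 + Z2 G2 Z2' sigma2^2 + I sigmae^2`.
#'
#' @param mats a [model_matrices()] object.
#' @param vc named numeric vector or list with elements `sigma1`, `sigma2`,
#'   `sigmae` (variances, all non-negative).
#' @return n x n symmetric positive semidefinite matrix.
#' @export
assemble_covariance <- function(mats, vc) {
  vc <- as.list(vc)
  s1 <- vc$sigma1; s2 <- vc$sigma2; se <- vc$sigmae
  stopifnot(s1 >= 0, s2 >= 0, se >= 0)
  n <- mats$n
  if (nrow(mats$Z1) != n || nrow(mats$Z2) != n)
    stop("dimension mismatch between Z matrices and n")
  V <- diag(se, n)
  if (ncol(mats$Z1)) V <- V + s1 * mats$Z1 %*% mats$G1 %*% t(mats$Z1)
  if (ncol(mats$Z2)) V <- V + s2 * mats$Z2 %*% mats$G2 %*% t(mats$Z2)
  (V + t(V)) / 2
}

#' Export model matrices as TSV files for audit
#'
#' @param mats a [model_matrices()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_matrices <- function(mats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("X", "Z1", "G1", "Z2", "G2")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(mats[[nm]], p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' The 44-array pooled one-color reference layout
#'
#' Builds the design used throughout the simulation study: 60 individuals in
#' two treatment groups of 30; per group, individuals 1-10 are measured
#' individually (10 arrays), individuals 1-5 and 6-10 also form the first
#' two pools of five, and individuals 11-30 form four further pools of five;
#' every pool is blended once and measured in technical duplicate (12 pooled
#' arrays per group), for 22 arrays per group and 44 in total.
#'
#' @param treatment_levels labels of the two groups.
#' @return a [pool_design()].
#' @export
mouse_like_design <- function(treatment_levels = c("control", "selected")) {
  stopifnot(length(treatment_levels) == 2)
  ind <- data.frame(
    id = c(sprintf("A%02d", 1:30), sprintf("B%02d", 1:30)),
    treatment = rep(treatment_levels, each = 30))
  mk_pools <- function(pref) {
    ids <- sprintf("%s%02d", pref, 1:30)
    data.frame(id = sprintf("%s_P%d", pref, 1:6),
               members = I(split(ids, rep(1:6, each = 5))))
  }
  singles <- data.frame(
    id = c(sprintf("A%02d_s", 1:10), sprintf("B%02d_s", 1:10)),
    members = I(as.list(c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10)))))
  pools <- rbind(singles, mk_pools("A"), mk_pools("B"))
  meas_line <- function(pref) {
    c(sprintf("%s%02d_s", pref, 1:10),
      rep(sprintf("%s_P%d", pref, 1:6), each = 2))
  }
  samples <- c(meas_line("A"), meas_line("B"))
  meas <- data.frame(array = sprintf("arr%02d", seq_along(samples)),
                     channel = "single", sample = samples)
  pool_design(ind, pools, meas, platform = "one-color",
              treatment_levels = treatment_levels)
}
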