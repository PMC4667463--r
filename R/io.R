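#' Read / write expression matrices as TSV
#'
#' Plain TSV with the transcript id in the first column and one column per
#' array (for two-color platforms, one column per array holding the
#' log-ratio `M = log R - log G`).
#'
#' @param path file path.
#' @return numeric matrix with transcript rownames and array colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param Y expression matrix.
#' @export
write_expression <- function(Y, path) {
  df <- data.frame(transcript = rownames(Y) %||% seq_len(nrow(Y)), Y,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a pool design as YAML
#'
#' The schema has top-level keys `platform`, `treatment_levels`, optional
#' `array_covariates`, and lists `individuals` (`id`, `treatment`, extra
#' covariates), `pools` (`id`, `members`, optional `blend_event`) and
#' `measurements` (`array`, `channel`, `sample`, extra covariates).
#' Validation errors name the offending entry.
#'
#' @param path file path.
#' @return a [pool_design()].
#' @export
read_pool_design <- function(path) {
  d <- yaml::read_yaml(path)
  for (k in c("platform", "individuals", "pools", "measurements"))
    if (is.null(d[[k]])) stop("design file misses section '", k, "'")
  to_df <- function(lst, section, required) {
    for (i in seq_along(lst))
      for (r in required)
        if (is.null(lst[[i]][[r]]))
          stop("design file: ", section, " entry ", i,
               " misses field '", r, "'")
    keys <- unique(unlist(lapply(lst, names)))
    out <- lapply(keys, function(k)
      lapply(lst, function(e) e[[k]] %||% NA))
    names(out) <- keys
    out
  }
  ind <- to_df(d$individuals, "individuals", c("id", "treatment"))
  ind <- data.frame(lapply(ind, unlist), stringsAsFactors = FALSE)
  pl <- to_df(d$pools, "pools", c("id", "members"))
  pools <- data.frame(id = unlist(pl$id), stringsAsFactors = FALSE)
  pools$members <- I(lapply(pl$members, unlist))
  if (!is.null(pl$blend_event))
    pools$blend_event <- unlist(lapply(pl$blend_event, function(x)
      if (is.na(x[1])) NA_character_ else as.character(x)))
  if (!is.null(pools$blend_event) && anyNA(pools$blend_event))
    pools$blend_event <- ifelse(is.na(pools$blend_event), pools$id,
                                pools$blend_event)
  ms <- to_df(d$measurements, "measurements", c("array", "channel", "sample"))
  meas <- data.frame(lapply(ms, unlist), stringsAsFactors = FALSE)
  pool_design(ind, pools, meas, platform = d$platform,
              treatment_levels = d$treatment_levels,
              array_covariates = d$array_covariates %||% character())
}

#' @rdname read_pool_design
#' @param design a [pool_design()].
#' @export
write_pool_design <- function(design, path) {
  row_list <- function(df) lapply(seq_len(nrow(df)), function(i) {
    e <- as.list(df[i, , drop = FALSE])
    lapply(e, function(x) if (is.list(x)) unlist(x[[1]]) else unname(x))
  })
  yaml::write_yaml(list(
    platform = design$platform,
    treatment_levels = design$treatment_levels,
    array_covariates = design$array_covariates,
    individuals = row_list(design$individuals),
    pools = row_list(design$pools),
    measurements = row_list(design$measurements)), path)
  invisible(path)
}

#' Write per-transcript study records and the study report
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- study$records
  num <- vapply(rec, is.numeric, TRUE)
  rec[num] <- lapply(rec[num], signif, digits = 6)
  p1 <- file.path(dir, "records.tsv")
  utils::write.table(rec, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "report.json")
  rep <- study$report
  rep$venn <- NULL
  jsonlite::write_json(rep, p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
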