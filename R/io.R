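#' Tabular I/O for pipeline artifacts
#'
#' Every artifact is written as TSV with a one-line header so runs diff
#' cleanly; column schemas ship in \code{inst/extdata/schemas.md}.
#'
#' @param cohort cohort table.
#' @param path file path.
#' @name artifact_io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' @rdname artifact_io
#' @export
write_cohort <- function(cohort, path) write_tsv(cohort, path)

#' @rdname artifact_io
#' @export
read_cohort <- function(path) {
  df <- read_tsv(path)
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df
}

#' @rdname artifact_io
#' @param m measure matrix.
#' @export
write_measure_matrix <- function(m, path) {
  df <- data.frame(participant_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  tr <- attr(m, "truth")
  if (!is.null(tr))
    write_tsv(tr, sub("\\.tsv$", "_truth.tsv", path))
  invisible(path)
}

#' @rdname artifact_io
#' @param metric,smoothing_fwhm metadata restored on the matrix.
#' @export
read_measure_matrix <- function(path, metric = NA, smoothing_fwhm = 0) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$participant_id
  truth_path <- sub("\\.tsv$", "_truth.tsv", path)
  if (file.exists(truth_path)) attr(m, "truth") <- read_tsv(truth_path)
  attr(m, "metric") <- metric
  attr(m, "smoothing_fwhm") <- smoothing_fwhm
  m
}

#' @rdname artifact_io
#' @param design a \code{sample_design}.
#' @export
write_design <- function(design, path) {
  if (is.null(design$pairing)) {
    df <- data.frame(member_id = design$member_ids, male_id = NA,
                     female_id = NA, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(member_id = design$member_ids,
                     male_id = c(design$pairing$male_id,
                                 design$pairing$male_id),
                     female_id = c(design$pairing$female_id,
                                   design$pairing$female_id),
                     stringsAsFactors = FALSE)
  }
  df$label <- design$label
  df$tolerance <- design$tolerance
  write_tsv(df, path)
}

#' @rdname artifact_io
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  pairing <- NULL
  if (!all(is.na(df$male_id))) {
    half <- df[seq_len(nrow(df) / 2), ]
    pairing <- data.frame(male_id = half$male_id,
                          female_id = half$female_id,
                          stringsAsFactors = FALSE)
  }
  new_sample_design(df$label[1], df$member_id, pairing, df$tolerance[1])
}

#' @rdname artifact_io
#' @param fit a \code{trajectory_fit}.
#' @export
write_estimates <- function(fit, path) {
  terms <- colnames(fit$estimates)
  long <- do.call(rbind, lapply(terms, function(tm) {
    data.frame(unit = rownames(fit$estimates), term = tm,
               estimate = fit$estimates[, tm], se = fit$se[, tm],
               p = fit$p[, tm],
               adj_r2 = fit$adj_r2, n = fit$n,
               sample = fit$sample, method = fit$method, model = fit$model,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  write_tsv(long, path)
}

#' @rdname artifact_io
#' @export
read_estimates <- function(path) {
  long <- read_tsv(path)
  units <- unique(long$unit)
  terms <- unique(long$term)
  shape <- function(col) {
    m <- matrix(NA_real_, length(units), length(terms),
                dimnames = list(units, terms))
    m[cbind(match(long$unit, units), match(long$term, terms))] <- long[[col]]
    m
  }
  first <- long[match(units, long$unit), ]
  structure(list(estimates = shape("estimate"), se = shape("se"),
                 p = shape("p"), adj_r2 = first$adj_r2, n = first$n,
                 skipped = is.na(first$adj_r2),
                 model = long$model[1], sample = long$sample[1],
                 method = long$method[1], global_var = NA),
            class = "trajectory_fit")
}

#' Read / write a simulation or pipeline configuration as key: value text
#'
#' Uses Debian-control-style \code{key: value} records (one field per line).
#'
#' @param config a \code{sim_config} or plain named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  flat <- vapply(config, function(v) paste(v, collapse = " "), character(1))
  writeLines(paste0(names(flat), ": ", flat), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  dcf <- read.dcf(path)
  vals <- as.list(dcf[1, ])
  num <- suppressWarnings(lapply(vals, function(v) {
    parts <- strsplit(v, " ")[[1]]
    n <- as.numeric(parts)
    if (anyNA(n)) parts else n
  }))
  num$include_globals <- isTRUE(num$include_globals == "TRUE")
  cfg <- do.call(sim_config, num[names(num) %in% names(formals(sim_config))])
  cfg
}
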