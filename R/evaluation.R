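#' Compare trajectory estimates against a gold standard
#'
#' For each model term, computes the Pearson correlation between the
#' reference (gold-standard) and test estimate vectors across units, the
#' OLS slope of the test estimates regressed on the reference (an ideal
#' correction gives r near 1 and slope near 1; slope below 1 indicates
#' systematic underestimation), a paired t-test over the per-unit
#' differences, the paired Cohen's d (mean difference / sd of differences),
#' and Benjamini-Hochberg FDR-adjusted p-values across all terms in the
#' report.
#'
#' @param ref,test \code{trajectory_fit} objects on the same unit set.
#' @param terms model terms to compare (default age, sexM, age:sexM).
#' @param slope_direction \code{"test_on_ref"} (default) or
#'   \code{"ref_on_test"}.
#' @return an \code{estimate_comparison}: data.frame with one row per term
#'   (\code{r}, \code{slope}, \code{t}, \code{p}, \code{p_fdr}, \code{d},
#'   \code{n_units}).
#' @export
compare_estimates <- function(ref, test,
                              terms = c("age", "sexM", "age:sexM"),
                              slope_direction = c("test_on_ref",
                                                  "ref_on_test")) {
  slope_direction <- match.arg(slope_direction)
  er <- if (inherits(ref, "trajectory_fit")) ref$estimates else as.matrix(ref)
  et <- if (inherits(test, "trajectory_fit")) test$estimates else
    as.matrix(test)
  if (!setequal(rownames(er), rownames(et))) {
    d1 <- setdiff(rownames(er), rownames(et))
    d2 <- setdiff(rownames(et), rownames(er))
    stop("unit sets differ; only in ref: ",
         paste(utils::head(d1, 5), collapse = ", "),
         "; only in test: ", paste(utils::head(d2, 5), collapse = ", "),
         call. = FALSE)
  }
  et <- et[rownames(er), , drop = FALSE]
  if (nrow(er) < 3L) stop("need at least 3 units", call. = FALSE)
  stopifnot(all(terms %in% colnames(er)), all(terms %in% colnames(et)))
  rows <- lapply(terms, function(tm) {
    x <- er[, tm]; y <- et[, tm]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (var(x) == 0 && slope_direction == "test_on_ref")
      stop("zero variance in reference estimates for term ", tm,
           call. = FALSE)
    if (var(y) == 0 && slope_direction == "ref_on_test")
      stop("zero variance in test estimates for term ", tm, call. = FALSE)
    slope <- if (slope_direction == "test_on_ref")
      cov(x, y) / var(x) else cov(x, y) / var(y)
    dif <- y - x
    n <- length(dif)
    sdd <- sd(dif)
    if (sdd == 0) {                # identical vectors: no evidence, not NaN
      tt <- 0; pp <- 1; dd <- 0
    } else {
      tt <- mean(dif) / (sdd / sqrt(n))
      pp <- 2 * pt(abs(tt), df = n - 1, lower.tail = FALSE)
      dd <- mean(dif) / sdd
    }
    data.frame(term = tm, r = cor(x, y), slope = slope, t = tt, p = pp,
               d = dd, n_units = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- benjamini_hochberg(out$p)
  out <- out[, c("term", "r", "slope", "t", "p", "p_fdr", "d", "n_units")]
  class(out) <- c("estimate_comparison", "data.frame")
  attr(out, "ref") <- if (inherits(ref, "trajectory_fit"))
    paste(ref$sample, ref$method) else "matrix"
  attr(out, "test") <- if (inherits(test, "trajectory_fit"))
    paste(test$sample, test$method) else "matrix"
  out
}

#' @export
print.estimate_comparison <- function(x, ...) {
  cat("estimate_comparison: ref =", attr(x, "ref"),
      "| test =", attr(x, "test"), "\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1).
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Summarize adjusted R-squared across units
#'
#' @param fits a \code{trajectory_fit} or a list of them.
#' @return data.frame keyed by sample/method/model with mean, sd, min and
#'   max adjusted R^2 across units.
#' @export
fit_summary <- function(fits) {
  if (inherits(fits, "trajectory_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  do.call(rbind, lapply(fits, function(f) {
    r2 <- f$adj_r2[!f$skipped]
    if (!length(r2)) stop("fit contains no usable units", call. = FALSE)
    data.frame(sample = f$sample, method = f$method, model = f$model,
               mean = mean(r2), sd = sd(r2), min = min(r2), max = max(r2),
               n_units = length(r2), stringsAsFactors = FALSE)
  }))
}

#' Adjusted R-squared after partialling out the global variable
#'
#' Detects global-measure signal injected by an adjustment (notably the
#' proportions method on weakly TIV-coupled metrics): the adjusted outcome
#' is residualized on the global variable by OLS within the design sample,
#' the residuals are re-z-scored, the trajectory model is refitted, and the
#' per-unit adjusted R^2 is returned.  If the adjusted outcome was already
#' orthogonal to the global variable, these match the unpartialled values.
#'
#' @param adjusted adjusted measure matrix.
#' @param cohort cohort table.
#' @param design a \code{sample_design}.
#' @param global_var cohort column to partial out (default \code{"tiv"}).
#' @return named numeric vector of per-unit adjusted R^2.
#' @export
partial_r2_control <- function(adjusted, cohort, design,
                               global_var = "tiv") {
  ids <- design$member_ids
  if (!all(ids %in% rownames(adjusted)))
    stop("design members missing from the matrix", call. = FALSE)
  sub <- cohort[match(ids, cohort$participant_id), , drop = FALSE]
  g <- sub[[global_var]]
  Y <- adjusted[ids, , drop = FALSE]
  X <- cbind(1, g)
  res <- Y
  for (j in seq_len(ncol(Y))) {
    keep <- !is.na(Y[, j])
    cf <- stats::.lm.fit(X[keep, , drop = FALSE], Y[keep, j])$coefficients
    res[keep, j] <- Y[keep, j] - X[keep, , drop = FALSE] %*% cf
  }
  for (a in c("metric", "smoothing_fwhm", "truth"))
    attr(res, a) <- attr(adjusted, a)
  fit <- fit_trajectory(res, cohort, design, include_covariate = FALSE,
                        method_label = "partialled")
  setNames(fit$adj_r2, rownames(fit$estimates))
}
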