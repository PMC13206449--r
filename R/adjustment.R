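#' Fit the allometric power exponent of one unit
#'
#' Ordinary least-squares slope of \code{log(moi)} on \code{log(g)}
#' (intercept included): the exponent \eqn{b} of the power-corrected
#' proportions method.
#'
#' @param moi positive measure values for one unit.
#' @param g positive global-measure values (e.g. TIV).
#' @return the fitted exponent (slope) as a single number.
#' @export
fit_power_exponent <- function(moi, g) {
  keep <- !is.na(moi) & !is.na(g)
  moi <- moi[keep]; g <- g[keep]
  if (any(moi <= 0))
    stop("log-log fit undefined: non-positive measure values at indices ",
         paste(utils::head(which(moi <= 0), 5), collapse = ", "),
         call. = FALSE)
  if (any(g <= 0))
    stop("log-log fit undefined: non-positive global values", call. = FALSE)
  fit <- stats::.lm.fit(cbind(1, log(g)), log(moi))
  unname(fit$coefficients[2])
}

#' Apply a head-size adjustment to a measure matrix
#'
#' Implements the value-transforming correction methods, per unit:
#' \describe{
#'   \item{proportions}{\eqn{MOI_{adj} = MOI / g} (assumes strict
#'     proportionality, \eqn{\beta = 1}).}
#'   \item{pcp}{\eqn{MOI_{adj} = MOI / g^{b_j}} with \eqn{b_j} the log-log
#'     OLS slope of the unit on \code{fitting_sample}.}
#'   \item{residuals}{\eqn{MOI_{adj} = MOI - b_j (g - \bar g)} with
#'     \eqn{b_j} the linear OLS slope and \eqn{\bar g} the mean of \code{g}
#'     over \code{fitting_sample}.}
#'   \item{none}{returns the matrix unchanged.}
#' }
#' Slopes and means are estimated on the pooled (both-sex) fitting sample;
#' per-group normalization is known to bias sex comparisons.  The covariate
#' method is not a value transform: it is realized by
#' \code{\link{fit_trajectory}(include_covariate = TRUE)}.
#'
#' @param m measure matrix (participants x units).
#' @param cohort cohort table supplying the global variable.
#' @param method one of \code{"none"}, \code{"proportions"}, \code{"pcp"},
#'   \code{"residuals"}.
#' @param global_var cohort column used as the adjusting variable
#'   (default \code{"tiv"}).
#' @param fitting_sample participant ids used to estimate the per-unit
#'   slopes and the global mean; default: all rows of \code{m}.
#' @param b optional fixed per-unit exponent/slope (single value or one per
#'   unit), bypassing estimation; \code{b = 1} makes pcp identical to
#'   proportions.
#' @return the adjusted matrix, with an \code{adjustment} attribute (an
#'   \code{adjustment_spec}: method, global_var, per-unit \code{b},
#'   \code{global_mean}, fitting ids).  Missing entries propagate.
#' @export
apply_adjustment <- function(m, cohort,
                             method = c("none", "proportions", "pcp",
                                        "residuals"),
                             global_var = "tiv",
                             fitting_sample = NULL, b = NULL) {
  method <- match.arg(method)
  stopifnot(global_var %in% names(cohort))
  g_all <- cohort[[global_var]][match(rownames(m), cohort$participant_id)]
  if (anyNA(g_all))
    stop("matrix rows missing from cohort (or NA ", global_var, ")",
         call. = FALSE)
  if (is.null(fitting_sample)) fitting_sample <- rownames(m)
  if (!all(fitting_sample %in% rownames(m)))
    stop("fitting_sample must be a subset of the matrix rows", call. = FALSE)
  fit_idx <- match(fitting_sample, rownames(m))
  spec <- list(method = method, global_var = global_var,
               b = NULL, global_mean = NULL, fitting_sample = fitting_sample)
  out <- m
  if (method %in% c("proportions", "pcp")) {
    if (any(g_all <= 0))
      stop(global_var, " must be positive for ", method, call. = FALSE)
  }
  if (method == "proportions") {
    out <- m / g_all
  } else if (method == "pcp") {
    b <- if (!is.null(b)) rep_len(b, ncol(m)) else
      vapply(seq_len(ncol(m)), function(j)
        fit_power_exponent(m[fit_idx, j], g_all[fit_idx]), numeric(1))
    out <- m / outer(g_all, b, `^`)
    spec$b <- setNames(b, colnames(m))
  } else if (method == "residuals") {
    gm <- mean(g_all[fit_idx])
    b <- if (!is.null(b)) rep_len(b, ncol(m)) else
      vapply(seq_len(ncol(m)), function(j) {
        x <- g_all[fit_idx]; y <- m[fit_idx, j]
        keep <- !is.na(y)
        cov(x[keep], y[keep]) / var(x[keep])
      }, numeric(1))
    out <- m - outer(g_all - gm, b)
    spec$b <- setNames(b, colnames(m))
    spec$global_mean <- gm
  }
  for (a in c("metric", "smoothing_fwhm", "truth"))
    attr(out, a) <- attr(m, a)
  class(spec) <- "adjustment_spec"
  attr(out, "adjustment") <- spec
  out
}

#' @export
print.adjustment_spec <- function(x, ...) {
  cat("adjustment_spec: method", x$method, "on", x$global_var)
  if (!is.null(x$b))
    cat(sprintf(" (b: %d units, median %.3f)", length(x$b),
                stats::median(x$b)))
  cat("\n")
  invisible(x)
}
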