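#' Fit standardized aging-trajectory models per unit
#'
#' For every measurement unit, fits the linear model
#' \deqn{MOI ~ 1 + age + sex + age:sex}
#' (optionally \code{+ global}, the covariate method) by OLS on the members
#' of one sample design.  Continuous predictors (age, and the global
#' covariate when included) are z-scored within the design sample; the
#' outcome is z-scored within the design sample \emph{after} any adjustment
#' has been applied to the matrix; sex enters as an unscaled 0/1 indicator
#' with female as reference, and the interaction is the product of the
#' z-scored age and the sex indicator.
#'
#' Units with zero outcome variance within the sample are skipped (flagged
#' in the result, with a warning), not imputed.  Units are fitted on their
#' complete cases.
#'
#' @param m measure matrix (raw or adjusted).
#' @param cohort cohort table.
#' @param design a \code{sample_design}; its members must be rows of
#'   \code{m}.
#' @param include_covariate add the z-scored global variable as a regressor
#'   (the covariate method).
#' @param global_var cohort column used as the covariate.
#' @param method_label label stored on the fit (defaults to the matrix's
#'   adjustment method, or \code{"none"}).
#' @return a \code{trajectory_fit}: per-unit standardized coefficients,
#'   standard errors, p-values and adjusted R^2, with \code{print},
#'   \code{summary} and \code{coef} methods.  Terms are
#'   \code{(Intercept)}, \code{age}, \code{sexM}, \code{age:sexM} and,
#'   when included, \code{global}.
#' @export
fit_trajectory <- function(m, cohort, design, include_covariate = FALSE,
                           global_var = "tiv", method_label = NULL) {
  stopifnot(inherits(design, "sample_design"))
  ids <- design$member_ids
  if (!all(ids %in% rownames(m)))
    stop("design members missing from the measure matrix", call. = FALSE)
  ci <- match(ids, cohort$participant_id)
  if (anyNA(ci)) stop("design members missing from the cohort", call. = FALSE)
  sub <- cohort[ci, , drop = FALSE]
  Y <- m[ids, , drop = FALSE]
  za <- as.numeric(scale(sub$age_months))
  male <- as.numeric(sub$sex == "M")
  X <- cbind("(Intercept)" = 1, age = za, sexM = male, "age:sexM" = za * male)
  if (include_covariate) {
    g <- sub[[global_var]]
    if (is.null(g)) stop("no column '", global_var, "' in cohort",
                         call. = FALSE)
    X <- cbind(X, global = as.numeric(scale(g)))
  }
  p <- ncol(X)
  n_all <- nrow(X)
  if (n_all <= p)
    stop(sprintf("n (%d) must exceed the number of parameters (%d)",
                 n_all, p), call. = FALSE)
  nu <- ncol(Y)
  terms <- colnames(X)
  est <- se <- matrix(NA_real_, nu, p, dimnames = list(colnames(Y), terms))
  adj_r2 <- rep(NA_real_, nu)
  nvec <- integer(nu)
  skipped <- logical(nu)
  complete <- !is.na(Y)
  all_complete <- all(complete)
  if (all_complete) {
    qx <- qr(X)
    xtxi <- chol2inv(qr.R(qx))
  }
  for (j in seq_len(nu)) {
    if (all_complete) {
      y <- Y[, j]; Xj <- X; qj <- qx; xj <- xtxi
    } else {
      keep <- complete[, j]
      y <- Y[keep, j]; Xj <- X[keep, , drop = FALSE]
      if (nrow(Xj) <= p) { skipped[j] <- TRUE; next }
      qj <- qr(Xj)
      xj <- chol2inv(qr.R(qj))
    }
    sdy <- sd(y)
    if (!is.finite(sdy) || sdy == 0) { skipped[j] <- TRUE; next }
    yz <- (y - mean(y)) / sdy
    cf <- qr.coef(qj, yz)
    res <- yz - Xj %*% cf
    nj <- length(yz)
    rss <- sum(res^2)
    s2 <- rss / (nj - p)
    est[j, ] <- cf
    se[j, ] <- sqrt(pmax(diag(xj) * s2, 0))
    r2 <- 1 - rss / (nj - 1)          # var(yz) = 1 by construction
    # p - 1 predictors beside the intercept
    adj_r2[j] <- 1 - (1 - r2) * (nj - 1) / (nj - p)
    nvec[j] <- nj
  }
  if (any(skipped))
    warning(sum(skipped), " unit(s) skipped (zero variance or too few ",
            "complete cases): ",
            paste(utils::head(colnames(Y)[skipped], 5), collapse = ", "),
            call. = FALSE)
  tval <- est / se
  pval <- 2 * pt(abs(tval), df = pmax(nvec - p, 1), lower.tail = FALSE)
  ml <- method_label
  if (is.null(ml)) {
    adj <- attr(m, "adjustment")
    ml <- if (is.null(adj)) "none" else adj$method
  }
  structure(list(estimates = est, se = se, p = pval, adj_r2 = adj_r2,
                 n = nvec, skipped = skipped,
                 model = if (include_covariate) "eq5" else "eq1",
                 sample = design$label, method = ml,
                 global_var = if (include_covariate) global_var else NA),
            class = "trajectory_fit")
}

#' @export
coef.trajectory_fit <- function(object, ...) object$estimates

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "trajectory_fit (%s): %d units, sample '%s', method '%s', n = %d\n",
    x$model, nrow(x$estimates), x$sample, x$method, max(x$n)))
  cat("standardized estimates (mean across units):\n")
  print(round(colMeans(x$estimates, na.rm = TRUE), 4))
  invisible(x)
}

#' @export
summary.trajectory_fit <- function(object, ...) {
  qs <- apply(object$estimates, 2, quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE)
  out <- list(model = object$model, sample = object$sample,
              method = object$method, quantiles = t(qs),
              adj_r2 = c(mean = mean(object$adj_r2, na.rm = TRUE),
                         sd = sd(object$adj_r2, na.rm = TRUE),
                         min = min(object$adj_r2, na.rm = TRUE),
                         max = max(object$adj_r2, na.rm = TRUE)),
              n_units = nrow(object$estimates),
              n_skipped = sum(object$skipped))
  class(out) <- "summary.trajectory_fit"
  out
}

#' @export
print.summary.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit summary (%s; sample '%s', method '%s')\n",
              x$model, x$sample, x$method))
  cat("estimate quantiles across", x$n_units, "units:\n")
  print(round(x$quantiles, 4))
  cat(sprintf("adjusted R^2: mean %.3f (sd %.3f), range [%.3f, %.3f]\n",
              x$adj_r2["mean"], x$adj_r2["sd"], x$adj_r2["min"],
              x$adj_r2["max"]))
  if (x$n_skipped) cat(x$n_skipped, "unit(s) skipped\n")
  invisible(x)
}

#' Scatter of test-sample estimates against gold-standard estimates
#'
#' @param x a \code{trajectory_fit} used as the reference (gold standard).
#' @param test a second \code{trajectory_fit} on the same units.
#' @param term model term to plot.
#' @param ... passed to \code{plot}.
#' @export
plot.trajectory_fit <- function(x, test = NULL, term = "sexM", ...) {
  if (is.null(test)) {
    graphics::hist(x$estimates[, term], breaks = 20,
                   main = paste("standardized", term, "estimates"),
                   xlab = term)
    return(invisible(x))
  }
  r <- x$estimates[, term]
  t2 <- test$estimates[rownames(x$estimates), term]
  graphics::plot(r, t2, xlab = paste("reference", term),
                 ylab = paste("test", term), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
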