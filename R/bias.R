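#' Residual-bias map: orthogonal distance from the identity line
#'
#' For each unit, the point (reference estimate, test estimate) is compared
#' with the ideal line \eqn{y = x}; the signed orthogonal distance
#' \eqn{(test - ref)/\sqrt{2}} is the residual bias of the correction.
#' Positive bias means undercorrection (the test estimate is shifted toward
#' the male direction relative to the gold standard).
#'
#' @param ref,test \code{trajectory_fit} objects (or estimate matrices) on
#'   the same units.
#' @param term model term (default \code{"sexM"}).
#' @return data.frame with columns \code{unit}, \code{bias}, plus the term
#'   and method labels as attributes.
#' @export
bias_map <- function(ref, test, term = "sexM") {
  er <- if (inherits(ref, "trajectory_fit")) ref$estimates else as.matrix(ref)
  et <- if (inherits(test, "trajectory_fit")) test$estimates else
    as.matrix(test)
  if (!setequal(rownames(er), rownames(et)))
    stop("unit sets differ between ref and test", call. = FALSE)
  et <- et[rownames(er), , drop = FALSE]
  b <- (et[, term] - er[, term]) / sqrt(2)
  structure(data.frame(unit = rownames(er), bias = unname(b),
                       stringsAsFactors = FALSE),
            term = term,
            method = if (inherits(test, "trajectory_fit")) test$method else
              "matrix")
}

#' Quasi-uniform unit coordinates on the sphere
#'
#' Places \code{n} unit centroids on the unit sphere with a Fibonacci
#' lattice; a synthetic stand-in for real parcel centroids, sufficient for
#' spin-test nulls.
#'
#' @param n number of units.
#' @param hemisphere label applied to all units (default \code{"L"}).
#' @param unit_ids optional ids (default \code{unit001}, ...).
#' @return data.frame with columns \code{unit}, \code{x}, \code{y},
#'   \code{z}, \code{hemisphere}; each (x, y, z) has unit norm.
#' @export
fibonacci_coordinates <- function(n, hemisphere = "L", unit_ids = NULL) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  if (is.null(unit_ids)) unit_ids <- sprintf("unit%03d", seq_len(n))
  data.frame(unit = unit_ids, x = r * cos(phi), y = r * sin(phi), z = z,
             hemisphere = hemisphere, stringsAsFactors = FALSE)
}

# uniform random rotation matrix (QR of a Gaussian matrix with sign fix,
# reflected to det +1): Stewart's construction
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spatial permutation ("spin") test for map correlation
#'
#' Tests the correlation between two unit maps against a null that respects
#' spatial structure: each permutation draws a uniform random 3D rotation,
#' rotates the unit centroids on the sphere (the mirrored rotation is
#' applied to right-hemisphere units), reassigns each unit the value of the
#' nearest rotated unit within its hemisphere, and recomputes the
#' correlation.  The empirical p-value is
#' \eqn{(\#\{null \ge observed\} + 1)/(n_{perm} + 1)} (one-sided
#' "exceeding" rule; \code{two_sided = TRUE} uses absolute values).
#'
#' @param map_a,map_b named numeric vectors on the same units (\code{map_a}
#'   is the one being spun).
#' @param coords coordinates from \code{\link{fibonacci_coordinates}} (or
#'   same schema) covering all units.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param two_sided compare |null| against |observed| instead.
#' @return a \code{spin_result}: list with \code{observed_r},
#'   \code{n_perm}, \code{p}, and \code{null_r} (the null correlations).
#' @export
spin_test <- function(map_a, map_b, coords, n_perm = 1000L, seed = 1L,
                      two_sided = FALSE) {
  stopifnot(n_perm >= 1)
  units <- names(map_a)
  if (is.null(units) || is.null(names(map_b)))
    stop("maps must be named by unit id", call. = FALSE)
  if (!setequal(units, names(map_b)))
    stop("maps are defined on different unit sets", call. = FALSE)
  map_b <- map_b[units]
  if (!all(units %in% coords$unit))
    stop("coordinates missing for units: ",
         paste(utils::head(setdiff(units, coords$unit), 5), collapse = ", "),
         call. = FALSE)
  if (sd(map_a) == 0 || sd(map_b) == 0)
    stop("correlation undefined for a constant map", call. = FALSE)
  co <- coords[match(units, coords$unit), , drop = FALSE]
  C <- as.matrix(co[, c("x", "y", "z")])
  hemi <- co$hemisphere
  obs <- cor(map_a, map_b)
  set.seed(substream_seed(seed, "spin"))
  mir <- diag(c(-1, 1, 1))
  null_r <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    R <- random_rotation()
    spun <- map_a
    for (h in unique(hemi)) {
      idx <- which(hemi == h)
      Rh <- if (h == hemi[1]) R else mir %*% R %*% mir
      Crot <- C[idx, , drop = FALSE] %*% t(Rh)
      # nearest rotated unit = max dot product on the unit sphere
      nn <- max.col(C[idx, , drop = FALSE] %*% t(Crot), ties.method = "first")
      spun[idx] <- map_a[idx][nn]
    }
    null_r[k] <- cor(spun, map_b)
  }
  p <- if (two_sided) (sum(abs(null_r) >= abs(obs)) + 1) / (n_perm + 1) else
    (sum(null_r >= obs) + 1) / (n_perm + 1)
  structure(list(observed_r = obs, n_perm = n_perm, p = p,
                 null_r = null_r, two_sided = two_sided),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf(
    "spin_test: observed r = %.3f, p = %.4g (%d permutations%s)\n",
    x$observed_r, x$p, x$n_perm,
    if (x$two_sided) ", two-sided" else ""))
  cat(sprintf("null r: mean %.3f, sd %.3f\n", mean(x$null_r), sd(x$null_r)))
  invisible(x)
}
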