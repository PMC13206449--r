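# minimal trajectory_fit stub for comparison tests
stub_fit <- function(est, sample = "s", method = "m", adj_r2 = NULL) {
  est <- as.matrix(est)
  structure(list(estimates = est,
                 se = est * 0, p = est * 0 + 0.5,
                 adj_r2 = if (is.null(adj_r2))
                   rep(0.3, nrow(est)) else adj_r2,
                 n = rep(100L, nrow(est)),
                 skipped = rep(FALSE, nrow(est)),
                 model = "eq1", sample = sample, method = method,
                 global_var = NA),
            class = "trajectory_fit")
}

rand_est <- function(n = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(2 * n), n, 2,
         dimnames = list(sprintf("u%02d", 1:n), c("age", "sexM")))
}

test_that("comparing a fit with itself gives the identity report", {
  f <- stub_fit(rand_est())
  cmp <- compare_estimates(f, f, terms = c("age", "sexM"))
  expect_equal(cmp$r, c(1, 1))
  expect_equal(cmp$slope, c(1, 1))
  expect_equal(cmp$t, c(0, 0))
  expect_equal(cmp$p, c(1, 1))
  expect_equal(cmp$d, c(0, 0))
})

test_that("a proportionally shrunken test vector keeps r = 1 at half slope", {
  e <- rand_est()
  cmp <- compare_estimates(stub_fit(e), stub_fit(e * 0.5),
                           terms = c("age", "sexM"))
  expect_equal(cmp$r, c(1, 1), tolerance = 1e-12)
  expect_equal(cmp$slope, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("r, slope, paired t and paired d match closed-form oracles", {
  for (s in 1:50) {
    e1 <- rand_est(10, seed = s)
    e2 <- rand_est(10, seed = s + 1000) * 0.8 + e1
    cmp <- compare_estimates(stub_fit(e1), stub_fit(e2),
                             terms = c("age", "sexM"))
    for (k in 1:2) {
      x <- e1[, k]; y <- e2[, k]; n <- length(x)
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      r_o <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      slope_o <- sxy / sum((x - mean(x))^2)
      dif <- y - x
      sd_o <- sqrt(sum((dif - mean(dif))^2) / (n - 1))
      t_o <- mean(dif) / (sd_o / sqrt(n))
      d_o <- mean(dif) / sd_o
      p_o <- 2 * (1 - pt(abs(t_o), n - 1))
      expect_equal(cmp$r[k], r_o, tolerance = 1e-10)
      expect_equal(cmp$slope[k], slope_o, tolerance = 1e-10)
      expect_equal(cmp$t[k], t_o, tolerance = 1e-10)
      expect_equal(cmp$d[k], d_o, tolerance = 1e-10)
      expect_equal(cmp$p[k], p_o, tolerance = 1e-10)
    }
  }
})

test_that("slope direction flag and error reporting behave", {
  e1 <- rand_est(8, seed = 3); e2 <- rand_est(8, seed = 4)
  a <- compare_estimates(stub_fit(e1), stub_fit(e2), terms = "age")
  b <- compare_estimates(stub_fit(e1), stub_fit(e2), terms = "age",
                         slope_direction = "ref_on_test")
  expect_equal(b$slope, cov(e1[, 1], e2[, 1]) / var(e2[, 1]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$slope, b$slope)))
  e3 <- e2; rownames(e3)[1] <- "zz"
  expect_error(compare_estimates(stub_fit(e1), stub_fit(e3), terms = "age"),
               "unit sets differ")
  expect_error(compare_estimates(stub_fit(e1[1:2, ]), stub_fit(e2[1:2, ]),
                                 terms = "age"), "at least 3")
  e4 <- e1; e4[, 1] <- 7
  expect_error(compare_estimates(stub_fit(e4), stub_fit(e2), terms = "age"),
               "zero variance")
})

test_that("benjamini_hochberg reproduces hand-computed step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(c(1, 1)), c(1, 1))
  # step-up with monotonicity: hand computation
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  adj <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(benjamini_hochberg(p), pmin(adj, 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted never below raw
  set.seed(9)
  pr <- runif(20)
  expect_true(all(benjamini_hochberg(pr) >= pr))
})

test_that("fit_summary aggregates adjusted R-squared correctly", {
  f1 <- stub_fit(rand_est(), adj_r2 = rep(0.3, 10))
  s1 <- fit_summary(f1)
  expect_equal(s1$mean, 0.3)
  expect_equal(s1$sd, 0)
  expect_equal(c(s1$min, s1$max), c(0.3, 0.3))
  f2 <- stub_fit(rand_est(2), adj_r2 = c(0.1, 0.5))
  s2 <- fit_summary(list(f1, f2))
  expect_equal(s2$mean[2], 0.3)
  expect_equal(c(s2$min[2], s2$max[2]), c(0.1, 0.5))
  set.seed(4)
  r2 <- runif(10)
  s3 <- fit_summary(stub_fit(rand_est(), adj_r2 = r2))
  expect_equal(s3$sd, sqrt(sum((r2 - mean(r2))^2) / 9), tolerance = 1e-12)
})

test_that("partialling the global out removes exactly its share of R2", {
  set.seed(6)
  n <- 300
  co <- toy_cohort(age_f = sample(560:960, n / 2, TRUE),
                   tiv_f = rnorm(n / 2, 1.34e6, 1e5),
                   age_m = sample(560:960, n / 2, TRUE),
                   tiv_m = rnorm(n / 2, 1.52e6, 1.2e5))
  design <- build_subsample(co, "not_matched", n / 2, seed = 6)
  # unit 1: orthogonal to TIV; unit 2: pure linear function of TIV
  y1 <- rnorm(n)
  y1 <- y1 - cov(y1, co$tiv) / var(co$tiv) * (co$tiv - mean(co$tiv))
  y2 <- 2 + 3e-6 * co$tiv + rnorm(n, 0, 0.05)
  m <- cbind(u1 = y1, u2 = y2)
  rownames(m) <- co$participant_id
  base <- fit_trajectory(m, co, design)
  pr2 <- partial_r2_control(m, co, design)
  expect_equal(unname(pr2["u1"]), base$adj_r2[1], tolerance = 1e-10)
  expect_lt(abs(unname(pr2["u2"])), 0.05)  # all signal removed
})

test_that("partialling exposes proportions-injected TIV signal in
           thickness-like data", {
  cfg <- sim_config(n_per_sex = 500L, seed = 14L, n_units = 10L,
                    metric = "cortical_thickness", ct_beta = 0.02,
                    alpha_range = c(2, 3), noise_cv = 0.05)
  co <- simulate_cohort(cfg)
  m <- simulate_measures(co, cfg)
  design <- build_subsample(co, "not_matched", 500L, seed = 14)
  prop <- apply_adjustment(m, co, "proportions")
  fit_prop <- fit_trajectory(prop, co, design)
  pr2 <- partial_r2_control(prop, co, design)
  # dividing a TIV-free measure by TIV injects TIV signal; partialling it
  # back out collapses the apparent fit
  expect_gt(mean(fit_prop$adj_r2), mean(pr2) + 0.1)
})
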