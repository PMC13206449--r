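traj_fixture <- function(n_per_sex = 150, seed = 21) {
  set.seed(seed)
  co <- toy_cohort(age_f = sample(560:960, n_per_sex, TRUE),
                   tiv_f = rnorm(n_per_sex, 1.34e6, 1e5),
                   age_m = sample(560:960, n_per_sex, TRUE),
                   tiv_m = rnorm(n_per_sex, 1.52e6, 1.2e5))
  design <- build_subsample(co, "not_matched", n_per_sex, seed = seed)
  list(co = co, design = design)
}

as_mat <- function(co, ...) {
  cols <- list(...)
  m <- vapply(cols, rep_len, numeric(nrow(co)), length.out = nrow(co))
  dimnames(m) <- list(co$participant_id, names(cols))
  m
}

test_that("an outcome equal to z-scored age is fitted perfectly", {
  fx <- traj_fixture()
  ids <- fx$design$member_ids
  za <- as.numeric(scale(fx$co$age_months[match(ids,
                                                fx$co$participant_id)]))
  m <- as_mat(fx$co, u1 = rep(0, nrow(fx$co)))
  m[ids, 1] <- za
  fit <- fit_trajectory(m, fx$co, fx$design)
  expect_equal(unname(fit$estimates[1, "age"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$estimates[1, "sexM"]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$estimates[1, "age:sexM"]), 0, tolerance = 1e-8)
  expect_equal(fit$adj_r2[1], 1, tolerance = 1e-10)
})

test_that("a pure sex contrast matches the standardized group-difference
           oracle", {
  fx <- traj_fixture()
  ids <- fx$design$member_ids
  male <- as.numeric(fx$co$sex[match(ids, fx$co$participant_id)] == "M")
  y <- 3.7 * male
  m <- as_mat(fx$co, u1 = NA_real_)
  m[ids, 1] <- y
  fit <- fit_trajectory(m, fx$co, fx$design)
  # oracle: with a noiseless group indicator outcome, the standardized sex
  # coefficient is the group mean difference in outcome-sd units
  oracle <- (mean(y[male == 1]) - mean(y[male == 0])) / sd(y)
  expect_equal(unname(fit$estimates[1, "sexM"]), oracle, tolerance = 1e-8)
  expect_equal(unname(fit$estimates[1, "age"]), 0, tolerance = 1e-8)
})

test_that("the covariate term recovers its weight and absorbs TIV-driven
           sex signal", {
  fx <- traj_fixture(n_per_sex = 400, seed = 33)
  ids <- fx$design$member_ids
  sub <- fx$co[match(ids, fx$co$participant_id), ]
  set.seed(1)
  y <- 0.5 * as.numeric(scale(sub$tiv)) + rnorm(length(ids), 0, 0.1)
  m <- as_mat(fx$co, u1 = NA_real_)
  m[ids, 1] <- y
  fit5 <- fit_trajectory(m, fx$co, fx$design, include_covariate = TRUE)
  fit1 <- fit_trajectory(m, fx$co, fx$design)
  expect_equal(unname(fit5$estimates[1, "global"]) * sd(y), 0.5,
               tolerance = 0.05)
  expect_lt(abs(fit5$estimates[1, "sexM"]),
            abs(fit1$estimates[1, "sexM"]))
  expect_equal(fit5$model, "eq5")
})

test_that("covariate and residuals methods coincide when the global is
           orthogonal to the design (Frisch-Waugh)", {
  fx <- traj_fixture(n_per_sex = 200, seed = 55)
  ids <- fx$design$member_ids
  n <- length(ids)
  sub <- fx$co[match(ids, fx$co$participant_id), ]
  za <- as.numeric(scale(sub$age_months))
  male <- as.numeric(sub$sex == "M")
  X <- cbind(1, za, male, za * male)
  set.seed(2)
  graw <- rnorm(n)
  g <- graw - X %*% qr.coef(qr(X), graw)       # exactly orthogonal to X
  co2 <- fx$co
  co2$gvar <- 0
  co2$gvar[match(ids, co2$participant_id)] <- as.numeric(g) + 10
  y <- 0.4 * za + 0.3 * male + 0.6 * as.numeric(scale(g)) + rnorm(n, 0, 0.2)
  m <- as_mat(fx$co, u1 = NA_real_)
  m[ids, 1] <- y
  fit5 <- fit_trajectory(m, co2, fx$design, include_covariate = TRUE,
                         global_var = "gvar")
  adj <- apply_adjustment(m[ids, , drop = FALSE], co2, "residuals",
                          global_var = "gvar")
  fit1 <- fit_trajectory(adj, co2, fx$design)
  # identical up to the outcome-sd rescaling induced by removing the
  # orthogonal global variance before z-scoring
  ratio <- sd(y) / sd(adj[, 1])
  for (tm in c("age", "sexM", "age:sexM"))
    expect_equal(unname(fit1$estimates[1, tm]),
                 unname(fit5$estimates[1, tm]) * ratio, tolerance = 1e-10)
})

test_that("degenerate units are skipped and small samples rejected", {
  fx <- traj_fixture(n_per_sex = 20)
  m <- as_mat(fx$co, u1 = rep(5, nrow(fx$co)),
              u2 = rnorm(nrow(fx$co)))
  expect_warning(fit <- fit_trajectory(m, fx$co, fx$design), "skipped")
  expect_true(fit$skipped[1])
  expect_false(fit$skipped[2])
  expect_true(all(is.na(fit$estimates[1, ])))
  tiny <- toy_cohort(age_f = c(700, 710), tiv_f = c(1.3e6, 1.31e6),
                     age_m = c(700, 712), tiv_m = c(1.5e6, 1.51e6))
  td <- build_subsample(tiny, "not_matched", 2, seed = 1)
  tm <- as_mat(tiny, u1 = rnorm(4))
  expect_error(fit_trajectory(tm, tiny, td), "exceed")
})

test_that("standard errors and p-values agree with lm on a random unit", {
  fx <- traj_fixture(n_per_sex = 80, seed = 77)
  ids <- fx$design$member_ids
  set.seed(3)
  m <- as_mat(fx$co, u1 = rnorm(nrow(fx$co), 100, 5))
  fit <- fit_trajectory(m, fx$co, fx$design)
  sub <- fx$co[match(ids, fx$co$participant_id), ]
  za <- as.numeric(scale(sub$age_months))
  male <- as.numeric(sub$sex == "M")
  ref <- summary(lm(scale(m[ids, 1]) ~ za + male + I(za * male)))
  expect_equal(unname(fit$estimates[1, ]),
               unname(coef(ref)[, "Estimate"]), tolerance = 1e-9)
  expect_equal(unname(fit$se[1, ]), unname(coef(ref)[, "Std. Error"]),
               tolerance = 1e-9)
  expect_equal(unname(fit$p[1, -1]), unname(coef(ref)[-1, "Pr(>|t|)"]),
               tolerance = 1e-9)
  expect_equal(fit$adj_r2[1], ref$adj.r.squared, tolerance = 1e-9)
})
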