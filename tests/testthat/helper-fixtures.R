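# shared fixture builders; everything is generated in code at test time

# a hand-built cohort with fully controlled ages/TIVs
toy_cohort <- function(age_f, tiv_f, age_m, tiv_m) {
  nf <- length(age_f); nm <- length(age_m)
  data.frame(
    participant_id = c(sprintf("F%03d", seq_len(nf)),
                       sprintf("M%03d", seq_len(nm))),
    sex = factor(rep(c("F", "M"), c(nf, nm)), levels = c("F", "M")),
    age_months = as.integer(c(age_f, age_m)),
    tiv = c(tiv_f, tiv_m),
    stringsAsFactors = FALSE)
}

# small default config for fast unit tests
quick_config <- function(...) {
  args <- list(n_per_sex = 200L, seed = 42L, n_units = 8L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# brute-force maximum bipartite matching size (Kuhn's augmenting paths)
# over an admissibility matrix A[male, female]; independent oracle for the
# greedy matcher
max_bipartite <- function(A) {
  nm <- nrow(A); nf <- ncol(A)
  match_f <- rep(0L, nf)
  augment <- function(m, seen) {
    for (f in which(A[m, ])) {
      if (!seen[f]) {
        seen[f] <- TRUE
        if (match_f[f] == 0L || augment(match_f[f], seen)) {
          match_f[f] <<- m
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (m in seq_len(nm))
    if (augment(m, rep(FALSE, nf))) size <- size + 1L
  size
}

# admissibility of each (male, female) pair under the relative tolerance
admissible_matrix <- function(cohort, tolerance,
                              match_on = c("age_months", "tiv")) {
  f <- cohort[cohort$sex == "F", ]
  m <- cohort[cohort$sex == "M", ]
  A <- matrix(TRUE, nrow(m), nrow(f))
  for (vn in match_on)
    A <- A & abs(outer(m[[vn]], f[[vn]], `-`)) <=
      tolerance * abs(m[[vn]])
  A
}
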