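#' End-to-end simulation-and-evaluation pipeline
#'
#' Runs the full comparison on one synthetic cohort: simulate, build the
#' four subsamples (matched gold standard, age-matched, not-matched,
#' extreme), apply every requested adjustment method, fit the standardized
#' trajectory models per (sample x method), compare each against the
#' matched-sample gold standard (raw values), and compute sex-term bias
#' maps.  All artifacts are written as TSV under \code{out_dir} together
#' with a manifest sufficient to reproduce the bundle bit-exactly.
#'
#' The matched design is thinned to \code{n_per_sex} pairs and the other
#' designs drawn at \code{n_per_sex} per sex, so all samples share one
#' statistical power; the simulated cohort must therefore be large enough
#' for the greedy matcher to yield at least \code{n_per_sex} pairs at the
#' 0.02\% tolerance (the yield grows roughly quadratically in cohort size;
#' 42,000 per sex gives ~2,300 pairs).
#'
#' @param config a \code{\link{sim_config}} describing the cohort.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   writing and returns the bundle only.
#' @param n_per_sex analysis-sample size per sex (pairs for the paired
#'   designs).
#' @param tolerance matching tolerance (default 0.0002).
#' @param methods adjustment methods to evaluate.
#' @param terms model terms compared against the gold standard.
#' @param global_var adjusting variable.
#' @param seed seed for sampling stages (defaults to \code{config$seed}).
#' @return invisibly, a list: \code{cohort}, \code{measures},
#'   \code{designs}, \code{fits} (per sample x method),
#'   \code{comparisons}, \code{bias_maps}, \code{gold}, \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_per_sex = 2000L,
                         tolerance = 2e-4,
                         methods = c("none", "proportions", "pcp",
                                     "residuals", "covariate"),
                         terms = c("age", "sexM", "age:sexM"),
                         global_var = "tiv", seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  methods <- match.arg(methods, several.ok = TRUE)
  cohort <- simulate_cohort(config)
  measures <- simulate_measures(cohort, config)
  measures <- filter_units(measures)

  matched_full <- match_by_age_tiv(cohort, tolerance, seed = seed)
  if (nrow(matched_full$pairing) < n_per_sex)
    stop(sprintf(
      "matching yielded %d pairs; %d requested - enlarge the cohort",
      nrow(matched_full$pairing), n_per_sex), call. = FALSE)
  designs <- list(
    matched = thin_pairs(matched_full, n_per_sex, seed = seed),
    age_matched = thin_pairs(
      match_by_age_tiv(cohort, tolerance, seed = seed,
                       match_on = "age_months", label = "age_matched"),
      n_per_sex, seed = seed),
    not_matched = build_subsample(cohort, "not_matched", n_per_sex,
                                  seed = seed),
    extreme = build_subsample(cohort, "extreme", n_per_sex,
                              matched = matched_full, seed = seed))

  gold <- fit_trajectory(measures, cohort, designs$matched,
                         method_label = "none")
  fits <- list()
  comparisons <- list()
  bias_maps <- list()
  for (dn in names(designs)) {
    for (me in methods) {
      fit <- if (me == "covariate") {
        fit_trajectory(measures, cohort, designs[[dn]],
                       include_covariate = TRUE, global_var = global_var,
                       method_label = "covariate")
      } else {
        adj <- apply_adjustment(measures, cohort, method = me,
                                global_var = global_var,
                                fitting_sample = designs[[dn]]$member_ids)
        fit_trajectory(adj, cohort, designs[[dn]], method_label = me)
      }
      key <- paste(dn, me, sep = ".")
      fits[[key]] <- fit
      if (!(dn == "matched" && me == "none")) {
        comparisons[[key]] <- compare_estimates(gold, fit, terms = terms)
        bias_maps[[key]] <- bias_map(gold, fit, term = "sexM")
      }
    }
  }

  manifest <- c(
    package_version = as.character(utils::packageVersion("allomatch")),
    r_version = as.character(getRversion()),
    seed = seed, n_per_sex = n_per_sex, tolerance = tolerance,
    methods = paste(methods, collapse = ","),
    global_var = global_var,
    unlist(lapply(unclass(config), paste, collapse = " ")))

  bundle <- list(cohort = cohort, measures = measures, designs = designs,
                 gold = gold, fits = fits, comparisons = comparisons,
                 bias_maps = bias_maps, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_cohort(bundle$cohort, fp("cohort.tsv"))
  write_measure_matrix(bundle$measures, fp("measures.tsv"))
  for (dn in names(bundle$designs))
    write_design(bundle$designs[[dn]], fp(paste0("design_", dn, ".tsv")))
  for (key in names(bundle$fits))
    write_estimates(bundle$fits[[key]],
                    fp(paste0("estimates_", key, ".tsv")))
  comp <- do.call(rbind, lapply(names(bundle$comparisons), function(k) {
    df <- as.data.frame(bundle$comparisons[[k]])
    df$comparison <- k
    df
  }))
  if (!is.null(comp)) write_tsv(comp, fp("comparisons.tsv"))
  bm <- do.call(rbind, lapply(names(bundle$bias_maps), function(k) {
    df <- bundle$bias_maps[[k]]
    df$comparison <- k
    df
  }))
  if (!is.null(bm)) write_tsv(bm, fp("bias_maps.tsv"))
  writeLines(paste0(names(bundle$manifest), ": ", bundle$manifest),
             fp("manifest.txt"))
  invisible(out_dir)
}
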