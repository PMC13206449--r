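#' Exact male-female matching on age and TIV
#'
#' Builds the gold-standard matched design: the cohort is split by sex, the
#' order within each group is randomized, and a single greedy pass over the
#' males claims, for each male, the first female (in randomized order) whose
#' values on every \code{match_on} variable lie within \code{tolerance}
#' relative to the male's.  Claimed females are removed from the pool;
#' males with no admissible female are dropped.  Tolerance denominators are
#' the male's values (females are matched to their male counterparts).
#'
#' With the default 0.02\% tolerance applied to age in months, only females
#' with the same integer age in months are admissible.
#'
#' @param cohort a cohort table (see \code{\link{simulate_cohort}}).
#' @param tolerance relative tolerance (default 0.0002, i.e. 0.02\%).
#' @param seed integer seed controlling the randomized orders.
#' @param match_on variables matched on: \code{c("age_months", "tiv")} for
#'   the matched design, \code{"age_months"} for the age-matched design.
#' @param label design label stored on the result.
#' @return a \code{sample_design}: list with \code{label},
#'   \code{member_ids}, \code{pairing} (data.frame \code{male_id},
#'   \code{female_id}), and \code{tolerance}.
#' @export
match_by_age_tiv <- function(cohort, tolerance = 2e-4, seed = 1L,
                             match_on = c("age_months", "tiv"),
                             label = "matched") {
  stopifnot(tolerance > 0, length(match_on) >= 1,
            all(match_on %in% names(cohort)))
  f <- cohort[cohort$sex == "F", , drop = FALSE]
  m <- cohort[cohort$sex == "M", , drop = FALSE]
  if (nrow(f) == 0L || nrow(m) == 0L)
    stop("cohort must contain both sexes", call. = FALSE)
  set.seed(substream_seed(seed, "match"))
  scan_rank <- sample.int(nrow(f))      # position of each female in the scan
  male_order <- sample.int(nrow(m))
  # age-sorted female index to restrict each male's scan to the admissible
  # age window; within the window the female with the smallest scan rank is
  # "the first in randomized order"
  a1 <- match_on[1]
  o <- order(f[[a1]])
  fv1 <- f[[a1]][o]
  rank_o <- scan_rank[o]
  other <- setdiff(match_on, a1)
  avail <- rep(TRUE, nrow(f))
  pair_m <- integer(0); pair_f <- integer(0)
  nearest_miss <- Inf
  for (i in male_order) {
    v <- m[[a1]][i]
    lo <- findInterval(v * (1 - tolerance) - 1e-9, fv1) + 1L
    hi <- findInterval(v * (1 + tolerance) + 1e-9, fv1)
    if (lo > hi) {
      nearest_miss <- min(nearest_miss,
                          min(abs(fv1 - v)) / abs(v))
      next
    }
    sl <- lo:hi
    ok <- avail[sl]
    for (vn in other) {
      w <- m[[vn]][i]
      ok <- ok & abs(f[[vn]][o][sl] - w) <= tolerance * abs(w)
    }
    cand <- sl[ok]
    if (!length(cand)) {
      nearest_miss <- min(nearest_miss, tolerance)  # age admissible, rest not
      next
    }
    pick <- cand[which.min(rank_o[cand])]
    avail[pick] <- FALSE
    pair_m <- c(pair_m, i)
    pair_f <- c(pair_f, pick)
  }
  if (!length(pair_m))
    stop(sprintf(
      "no admissible pairs at tolerance %g (nearest relative miss on %s: %g)",
      tolerance, a1, nearest_miss), call. = FALSE)
  pairing <- data.frame(male_id = m$participant_id[pair_m],
                        female_id = f$participant_id[o][pair_f],
                        stringsAsFactors = FALSE)
  new_sample_design(label, c(pairing$female_id, pairing$male_id),
                    pairing, tolerance)
}

new_sample_design <- function(label, member_ids, pairing = NULL,
                              tolerance = NA_real_) {
  structure(list(label = label, member_ids = member_ids,
                 pairing = pairing, tolerance = tolerance),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design '", x$label, "': ", length(x$member_ids),
      " members", sep = "")
  if (!is.null(x$pairing))
    cat(" (", nrow(x$pairing), " F-M pairs, tolerance ", x$tolerance, ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Thin a paired design to a fixed number of pairs
#'
#' Randomly keeps \code{n_pairs} of the male-female pairs, so that paired
#' designs can be sized like the other subsamples.
#'
#' @param design a paired \code{sample_design}.
#' @param n_pairs pairs to keep (must not exceed the available pairs).
#' @param seed integer seed.
#' @return a \code{sample_design} with \code{n_pairs} pairs.
#' @export
thin_pairs <- function(design, n_pairs, seed = 1L) {
  stopifnot(inherits(design, "sample_design"), !is.null(design$pairing))
  if (n_pairs > nrow(design$pairing))
    stop(sprintf("requested %d pairs but only %d available", n_pairs,
                 nrow(design$pairing)), call. = FALSE)
  set.seed(substream_seed(seed, "thin"))
  keep <- sample.int(nrow(design$pairing), n_pairs)
  pairing <- design$pairing[keep, , drop = FALSE]
  new_sample_design(design$label,
                    c(pairing$female_id, pairing$male_id),
                    pairing, design$tolerance)
}

#' Build the not-matched and extreme comparison subsamples
#'
#' \code{not_matched} draws a simple random sample of \code{n_per_sex}
#' participants per sex from the full cohort, so its age and TIV
#' distributions mimic the cohort's.  \code{extreme} removes every member
#' of the matched design first (exaggerating the female-male TIV gap, since
#' matching consumes high-TIV females and low-TIV males) and then samples
#' per sex stratified on the full-cohort age deciles, preserving the age
#' distribution.
#'
#' @param cohort a cohort table.
#' @param kind \code{"not_matched"} or \code{"extreme"}.
#' @param n_per_sex members per sex to draw.
#' @param matched the matched \code{sample_design} (required for
#'   \code{extreme}).
#' @param seed integer seed.
#' @return a \code{sample_design}.
#' @export
build_subsample <- function(cohort, kind = c("not_matched", "extreme"),
                            n_per_sex, matched = NULL, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(substream_seed(seed, paste0("subsample_", kind)))
  pool <- cohort
  if (kind == "extreme") {
    if (is.null(matched))
      stop("extreme subsample requires the matched design", call. = FALSE)
    pool <- cohort[!(cohort$participant_id %in% matched$member_ids), ,
                   drop = FALSE]
  }
  brk <- unique(quantile(cohort$age_months, probs = seq(0, 1, 0.1)))
  take <- function(sex) {
    p <- pool[pool$sex == sex, , drop = FALSE]
    if (nrow(p) < n_per_sex)
      stop(sprintf("requested %d per sex but only %d %s available",
                   n_per_sex, nrow(p), sex), call. = FALSE)
    if (kind == "not_matched") return(p$participant_id[
      sample.int(nrow(p), n_per_sex)])
    # extreme: stratify on full-cohort age deciles; largest-remainder
    # apportionment keeps every stratum count non-negative
    full <- cohort[cohort$sex == sex, , drop = FALSE]
    dec_full <- cut(full$age_months, brk, include.lowest = TRUE)
    exact <- n_per_sex * as.numeric(table(dec_full)) / nrow(full)
    want <- floor(exact)
    rem <- n_per_sex - sum(want)
    if (rem > 0) {
      up <- order(exact - want, decreasing = TRUE)[seq_len(rem)]
      want[up] <- want[up] + 1L
    }
    names(want) <- levels(dec_full)
    dec_pool <- cut(p$age_months, brk, include.lowest = TRUE)
    ids <- character(0)
    for (lev in levels(dec_pool)) {
      cand <- p$participant_id[dec_pool == lev]
      k <- want[[lev]]
      if (k > length(cand))
        stop(sprintf("age stratum %s exhausted (%d needed, %d left)",
                     lev, k, length(cand)), call. = FALSE)
      ids <- c(ids, cand[sample.int(length(cand), k)])
    }
    ids
  }
  new_sample_design(kind, c(take("F"), take("M")))
}

#' Verify the pairing constraints of a matched design
#'
#' @param design a paired \code{sample_design}.
#' @param cohort the cohort the design was built from.
#' @param match_on variables to check.
#' @return logical vector, one entry per pair: does the pair satisfy the
#'   relative tolerance on every variable (denominator: the male's value)?
#' @export
check_pairs <- function(design, cohort, match_on = c("age_months", "tiv")) {
  stopifnot(!is.null(design$pairing))
  fi <- match(design$pairing$female_id, cohort$participant_id)
  mi <- match(design$pairing$male_id, cohort$participant_id)
  ok <- rep(TRUE, nrow(design$pairing))
  for (vn in match_on) {
    ok <- ok & abs(cohort[[vn]][fi] - cohort[[vn]][mi]) <=
      design$tolerance * abs(cohort[[vn]][mi])
  }
  ok
}
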