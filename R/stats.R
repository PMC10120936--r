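#' Longitudinal comparison of voice parameters
#'
#' Recording dates contribute unequal squeal counts, so phases are compared
#' on date-balanced subsamples: an equal number of squeals is drawn at
#' random from every date inside each phase window before testing. Phase
#' contrasts use one-sided Wilcoxon rank-sum tests in a per-feature
#' direction (the expected worsening direction for pre vs early
#' post-surgery; the inverted, improvement direction when later windows are
#' compared against the early post-surgery window), with Bonferroni control
#' over the feature family.
#'
#' @name longitudinal_stats
NULL

#' Date-balanced subsample of a squeal table
#'
#' @param squeal_table Data frame with columns `recording_date` and
#'   `days_from_surgery` (one row per squeal).
#' @param phase Phase name (see [recovery_phases()]).
#' @param per_date_count Squeals to draw per date; default is the minimum
#'   per-date count across dates in the phase (the largest balanced
#'   sample).
#' @param seed Integer seed for reproducible draws.
#' @param allow_fewer If TRUE, dates with fewer than `per_date_count`
#'   squeals contribute all their squeals instead of erroring.
#' @return Row-subset of `squeal_table`.
#' @export
balanced_sample <- function(squeal_table, phase, per_date_count = NULL,
                            seed = 1L, allow_fewer = FALSE) {
  ph <- squeal_table[!is.na(squeal_table$days_from_surgery) &
                       phase_of_day(squeal_table$days_from_surgery) == phase, ,
                     drop = FALSE]
  ph <- ph[!is.na(ph$recording_date), , drop = FALSE]
  if (nrow(ph) == 0) stop("no squeals in phase ", phase)
  counts <- table(as.character(ph$recording_date))
  if (is.null(per_date_count)) per_date_count <- min(counts)
  if (!allow_fewer && any(counts < per_date_count))
    stop("some dates have fewer than ", per_date_count,
         " squeals; set allow_fewer = TRUE to keep them")
  rng <- local_rng(seed)
  idx <- unlist(lapply(names(counts), function(d) {
    rows <- which(as.character(ph$recording_date) == d)
    if (length(rows) <= per_date_count) rows
    else rows[rng$sample_int(length(rows), per_date_count)]
  }))
  ph[sort(idx), , drop = FALSE]
}

# seeded RNG stream that does not disturb the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, k) with_state(function() sample.int(n, k)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_state(function() stats::rpois(n, lambda))
  )
}

#' One-sided Wilcoxon rank-sum test
#'
#' Returns the rank-sum statistic of group `a` (midranks under ties) and a
#' one-sided p-value: exact by complete enumeration when the pooled sample
#' has at most 16 tie-free observations, otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param direction `"a_greater"` tests whether `a` is stochastically
#'   greater than `b`; `"a_less"` the opposite.
#' @return List with `rank_sum_statistic`, `p_one_sided`, `exact`
#'   (logical), `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b, direction = c("a_greater", "a_less")) {
  direction <- match.arg(direction)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  n_a <- length(a); n_b <- length(b)
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(n_a)])
  ties <- any(duplicated(c(a, b)))
  use_exact <- (n_a + n_b) <= 16 && !ties
  alt <- if (direction == "a_greater") "greater" else "less"
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                            exact = use_exact,
                                            correct = TRUE))
  list(rank_sum_statistic = w, p_one_sided = unname(ht$p.value),
       exact = use_exact, n_a = n_a, n_b = n_b)
}

#' Bonferroni family-wise correction
#'
#' @param p_values Numeric vector of one-sided p-values.
#' @param family_size Number of tests in the family (>= number of
#'   p-values): 2 for the evaluation-A parameter pair, 36 for the screened
#'   evaluation-B set.
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame with `p`, `p_corrected = min(1, family_size * p)` and
#'   `significant` flags.
#' @export
bonferroni <- function(p_values, family_size, alpha = 0.05) {
  stopifnot(family_size >= length(p_values), family_size >= 1)
  pc <- pmin(1, family_size * p_values)
  data.frame(p = p_values, p_corrected = pc, significant = pc <= alpha)
}

#' Default test directions for the six parameters
#'
#' Expected direction of change from pre-surgery to early post-surgery:
#' the energy-quantile parameters Q50 and P60 drop (loss of high-frequency
#' energy), the flux measures and Spread rise (increased instability and
#' noise), and LPC8 rises toward zero from negative values.
#'
#' @return Data frame with columns `feature`, `post_change`
#'   (`"down"`/`"up"`) and `description`.
#' @export
default_directions <- function() {
  data.frame(
    feature = c("q50", "flux1", "flux2", "spread", "p60", "lpc8"),
    post_change = c("down", "up", "up", "up", "down", "up"),
    description = c(
      "50% energy spectrum quantile (Hz)",
      "mean absolute inter-frame spectral difference",
      "RMS inter-frame spectral distance",
      "Mel spectral deviation about the centroid",
      "Mel 60% cumulative-energy frequency",
      "8th of 16 linear predictive coding coefficients"
    ),
    stringsAsFactors = FALSE
  )
}

#' Load a test-direction table from CSV
#'
#' @param path CSV with at least columns `feature` and `post_change`.
#' @return Direction data frame.
#' @export
load_directions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("feature", "post_change") %in% names(d)))
    stop("direction table needs 'feature' and 'post_change' columns")
  if (!all(d$post_change %in% c("down", "up")))
    stop("post_change must be 'down' or 'up'")
  d
}

#' Compare two recovery phases for one feature
#'
#' Draws date-balanced samples from both phases and runs the one-sided
#' rank-sum test. For a pre-surgery baseline phase (`phase_a = "PRE"`), the
#' test direction is the feature's expected worsening direction; for
#' comparisons of later windows against the early post-surgery window the
#' direction is inverted to test for improvement.
#'
#' @param feature_table Data frame with squeal metadata plus feature
#'   columns.
#' @param feature Feature column name.
#' @param phase_a,phase_b Phase names; `phase_a` is the earlier phase.
#' @param family_size Bonferroni family size (2 or 36).
#' @param directions Direction table (see [default_directions()]).
#' @param per_date_count,seed,allow_fewer Passed to [balanced_sample()].
#' @param alpha Family-wise level (default 0.05).
#' @return One-row data frame: feature, phases, group sizes, rank-sum
#'   statistic, one-sided p, corrected p, significance flag and the tested
#'   direction.
#' @export
compare_phases <- function(feature_table, feature, phase_a, phase_b,
                           family_size, directions = default_directions(),
                           per_date_count = NULL, seed = 1L,
                           allow_fewer = TRUE, alpha = 0.05) {
  dirrow <- directions[directions$feature == feature, , drop = FALSE]
  if (nrow(dirrow) != 1)
    stop("no test direction specified for feature ", feature)
  post_change <- dirrow$post_change

  # Worsening direction for PRE -> POST_EARLY; improvement (inverted) when
  # later windows are compared against POST_EARLY.
  improvement <- !identical(phase_a, "PRE")
  a_is_greater <- if (!improvement) post_change == "down" else post_change == "up"
  direction <- if (a_is_greater) "a_greater" else "a_less"

  sa <- balanced_sample(feature_table, phase_a, per_date_count,
                        seed = seed, allow_fewer = allow_fewer)
  sb <- balanced_sample(feature_table, phase_b, per_date_count,
                        seed = seed + 1L, allow_fewer = allow_fewer)
  ht <- wilcoxon_rank_sum(sa[[feature]], sb[[feature]], direction)
  corr <- bonferroni(ht$p_one_sided, family_size, alpha)
  data.frame(
    feature = feature, phase_a = phase_a, phase_b = phase_b,
    n_a = ht$n_a, n_b = ht$n_b,
    rank_sum_statistic = ht$rank_sum_statistic,
    direction = direction,
    p_one_sided = ht$p_one_sided,
    p_corrected = corr$p_corrected,
    significant = corr$significant,
    stringsAsFactors = FALSE
  )
}

#' Run a full phase contrast over a feature family
#'
#' @inheritParams compare_phases
#' @param features Character vector of feature columns; `family_size`
#'   defaults to its length.
#' @return Data frame with one row per feature.
#' @export
compare_phases_family <- function(feature_table, features, phase_a, phase_b,
                                  family_size = length(features),
                                  directions = default_directions(),
                                  per_date_count = NULL, seed = 1L,
                                  allow_fewer = TRUE, alpha = 0.05) {
  do.call(rbind, lapply(features, function(f) {
    compare_phases(feature_table, f, phase_a, phase_b, family_size,
                   directions, per_date_count, seed, allow_fewer, alpha)
  }))
}
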