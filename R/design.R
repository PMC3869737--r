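#' Inverse design questions
#'
#' Instead of fixing a significance threshold, the ranking approach fixes
#' the number of top hits `u` (or the sample size) and asks how large it
#' must be for a desired yield of true discoveries. Both searches exploit
#' monotonicity: \eqn{P_{t,u}} is nondecreasing in `u`, and \eqn{E(T)} is
#' nondecreasing in sample size (the noncentrality grows linearly with
#' it). Unattainable targets return a tagged result with
#' `attained = FALSE` rather than an error, so design-exploration
#' pipelines can branch on the outcome.
#'
#' @name design_queries
NULL

.design_result <- function(...) structure(list(...), class = "design_result")

#' @export
print.design_result <- function(x, ...) {
  if (isTRUE(x$attained)) {
    if (!is.null(x$u))
      cat(sprintf("<design_result> smallest u = %d (P_{%d,u} = %.4g >= %.4g)\n",
                  x$u, x$t, x$prob, x$target))
    else
      cat(sprintf(
        "<design_result> smallest n = %d per-group (E(T) = %.4g >= %.4g)\n",
        x$n, x$e_t, x$target))
  } else {
    cat(sprintf("<design_result> target %.4g not attainable (best %.4g)\n",
                x$target, if (!is.null(x$prob)) x$prob else x$e_t))
  }
  invisible(x)
}

#' Smallest number of top hits reaching a target ranking probability
#'
#' Finds the smallest `u` with \eqn{P_{t,u} \ge} `target_prob` by integer
#' bisection over the monotone sequence \eqn{u \mapsto P_{t,u}}.
#'
#' @param target_prob Desired ranking probability in \eqn{(0, 1)}.
#' @param t Required number of true signals, integer \eqn{\ge 1}.
#' @param study A [study_spec()].
#' @param correlated Passed to [ranking_prob()].
#' @return A `design_result` with fields `attained`, `u`, `prob`,
#'   `target`, `t`. When the target is not attainable even at `u = K`,
#'   `attained` is `FALSE` and `prob` holds \eqn{P_{t,K}}.
#' @examples
#' gwas <- study_spec(2e6, 75, effect_point(7.8))
#' find_top_u(0.95, t = 1, gwas)   # u = 11
#' @export
find_top_u <- function(target_prob, t, study, correlated = FALSE) {
  stopifnot(is_study_spec(study))
  .check_count(t, "t")
  if (length(target_prob) != 1L || target_prob <= 0 || target_prob >= 1)
    stop("`target_prob` must lie strictly inside (0, 1)", call. = FALSE)
  prob_at <- function(u) ranking_prob(t, u, study, correlated)$prob
  p_max <- prob_at(study$K)
  if (p_max < target_prob)
    return(.design_result(attained = FALSE, u = NA_integer_, prob = p_max,
                          target = target_prob, t = t))
  lo <- t  # P_{t,u} = 0 for u < t
  if (prob_at(lo) >= target_prob)
    return(.design_result(attained = TRUE, u = as.integer(lo),
                          prob = prob_at(lo), target = target_prob, t = t))
  hi <- study$K
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (prob_at(mid) >= target_prob) hi <- mid else lo <- mid
  }
  .design_result(attained = TRUE, u = as.integer(hi), prob = prob_at(hi),
                 target = target_prob, t = t)
}

#' Smallest sample size reaching a target yield of true discoveries
#'
#' The noncentrality of each true signal scales linearly with sample
#' size: \eqn{\lambda(n) = c \, \tilde n(n)}, where `c` is the per-allele
#' effect term ([per_allele_effect()]) and, for equal groups of `n` cases
#' and `n` controls, \eqn{\tilde n(n) = n}. The search finds the smallest
#' per-group size `n` on a grid with
#' \eqn{E(T \mid \mathrm{top}\ u) \ge} `target_e_t`, by bisection over
#' the grid (the yield is monotone in `n`). A grid rather than continuous
#' root-finding is used because group sizes are integers; the result is
#' exact on the grid.
#'
#' @param target_e_t Desired expected number of true signals among the
#'   top `u`, \eqn{\ge 0} (capped by `M`).
#' @param u Number of top hits.
#' @param K,M Total tests and true signals.
#' @param per_unit_effect Per-allele effect term \eqn{c = \lambda /
#'   \tilde n}.
#' @param n_grid Increasing grid of per-group sample sizes (default 500
#'   to 250000 in steps of 500).
#' @param df Degrees of freedom of the test statistic.
#' @param correlated Passed to [expected_true_in_top()].
#' @return A `design_result` with fields `attained`, `n` (per-group
#'   size), `e_t`, `target`.
#' @examples
#' find_sample_size(20, u = 200, K = 1e6, M = 50,
#'                  per_unit_effect = 0.0024,
#'                  n_grid = seq(1000, 20000, by = 1000))
#' @export
find_sample_size <- function(target_e_t, u, K, M, per_unit_effect,
                             n_grid = seq(500L, 250000L, by = 500L),
                             df = 1L, correlated = FALSE) {
  if (length(target_e_t) != 1L || !is.finite(target_e_t) || target_e_t < 0)
    stop("`target_e_t` must be a single value >= 0", call. = FALSE)
  if (per_unit_effect <= 0)
    stop("`per_unit_effect` must be > 0", call. = FALSE)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (length(n_grid) < 1L || any(n_grid < 1))
    stop("`n_grid` must contain positive group sizes", call. = FALSE)
  et_at <- function(n) {
    s <- study_spec(K, M, effect_point(per_unit_effect * n, df = df))
    expected_true_in_top(u, s, correlated)
  }
  et_max <- et_at(n_grid[length(n_grid)])
  if (et_max < target_e_t)
    return(.design_result(attained = FALSE, n = NA_integer_, e_t = et_max,
                          target = target_e_t))
  lo <- 1L; hi <- length(n_grid)
  if (et_at(n_grid[lo]) >= target_e_t) hi <- lo
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (et_at(n_grid[mid]) >= target_e_t) hi <- mid else lo <- mid
  }
  .design_result(attained = TRUE, n = n_grid[hi], e_t = et_at(n_grid[hi]),
                 target = target_e_t)
}

#' Yield table: expected true discoveries among top hits
#'
#' For each `u` supplied, the expected number of true signals among the
#' `u` smallest P-values and the expected proportion
#' (\eqn{1 - \mathrm{rFDR}(u)}).
#'
#' @param u_values Integer vector of top-hit counts, each \eqn{\le K}.
#' @param study A [study_spec()].
#' @param correlated Passed to [expected_true_in_top()].
#' @return A data frame with columns `u`, `e_t`, `prop_true`, rows in
#'   input order.
#' @examples
#' gwas <- study_spec(2e6, 75, effect_point(7.8))
#' yield_table(c(50, 600, 1150), gwas)
#' @export
yield_table <- function(u_values, study, correlated = FALSE) {
  stopifnot(is_study_spec(study))
  if (any(u_values < 1) || any(u_values > study$K) ||
      any(u_values != round(u_values)))
    stop("`u_values` must be integers between 1 and K", call. = FALSE)
  e_t <- vapply(u_values, expected_true_in_top, numeric(1),
                study = study, correlated = correlated)
  data.frame(u = as.integer(u_values), e_t = e_t,
             prop_true = e_t / u_values)
}
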