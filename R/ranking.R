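#' Multiple-testing study specification
#'
#' The testing universe of an experiment: `K` tests in total, of which
#' `M` are true signals whose noncentralities follow `effect`. The null
#' fraction is \eqn{\pi_0 = (K - M)/K}; the remaining \eqn{K - M} tests
#' produce Uniform(0,1) P-values.
#'
#' @param K Total number of tests, integer \eqn{\ge 1}.
#' @param M Number of true signals, integer with \eqn{0 \le M \le K}.
#' @param effect An [effect_model] for the true signals. May be omitted
#'   when `M = 0`.
#' @return An object of class `study_spec` with fields `K`, `M`,
#'   `effect`, and `pi0`.
#' @examples
#' study_spec(2e6, 75, effect_point(7.8))
#' study_spec(1000, 10, effect_gamma(0.5, 15))
#' @export
study_spec <- function(K, M, effect = NULL) {
  .check_count(K, "K")
  .check_count(M, "M", min = 0L)
  if (M > K) stop("`M` cannot exceed `K`", call. = FALSE)
  if (is.null(effect)) {
    if (M > 0) stop("`effect` is required when M > 0", call. = FALSE)
    effect <- effect_point(0)
  }
  stopifnot(is_effect_model(effect))
  structure(list(K = as.numeric(K), M = as.numeric(M), effect = effect,
                 pi0 = (K - M) / K),
            class = "study_spec")
}

#' @export
print.study_spec <- function(x, ...) {
  cat(sprintf("<study_spec> K = %g tests, M = %g true signals (pi0 = %.4g)\n",
              x$K, x$M, x$pi0))
  print(x$effect)
  invisible(x)
}

is_study_spec <- function(x) inherits(x, "study_spec")

#' CDF of the j-th ordered true-signal P-value
#'
#' With `M` independent true signals whose P-values share the marginal
#' CDF \eqn{\bar G}, the j-th smallest true-signal P-value has CDF
#' \deqn{P(p_{(j)}^{true} \le p) = 1 - \mathrm{Bin}\{j - 1;\, M,\,
#'       \bar G(p)\},}
#' the probability that at least `j` of the `M` true-signal P-values fall
#' at or below `p`.
#'
#' @param j Rank among the true signals, \eqn{1 \le j \le M}.
#' @param p P-value threshold(s) in \eqn{[0, 1]}.
#' @param study A [study_spec()].
#' @return Probability, same length as `p`.
#' @examples
#' s <- study_spec(1000, 10, effect_point(5))
#' ordered_true_cdf(3, 0.01, s)
#' @export
ordered_true_cdf <- function(j, p, study) {
  stopifnot(is_study_spec(study))
  .check_count(j, "j")
  if (j > study$M) stop("`j` must be between 1 and M", call. = FALSE)
  G <- marginal_cdf(p, study$effect)
  stats::pbinom(j - 1, study$M, G, lower.tail = FALSE)
}

.rank_result <- function(t, u, q, prob) {
  structure(list(t = t, u = u, q = q, prob = prob), class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf(
    "<rank_result> P(at least %d true signals among top %d) = %.6g\n",
    x$t, x$u, x$prob))
  invisible(x)
}

# plug-in positions of the (u-t+1)-th null order statistic for a vector
# of t values; the 1/2 continuity term is dropped under correlation
.q_plugin <- function(t, u, study, correlated) {
  off <- if (correlated) 1 else 0.5
  q <- (u - t + off) / (study$K - study$M + 1)
  pmin(pmax(q, 1e-300), 1)
}

#' Ranking probability: at least t true signals among the top u P-values
#'
#' The central quantity of the package:
#' \eqn{P_{t,u}}, the probability that when all `K` P-values of the
#' experiment are sorted, at least `t` of the `u` smallest belong to true
#' signals. It is approximated by evaluating the ordered-true-signal CDF
#' at a plug-in position of the \eqn{(u - t + 1)}-th null order
#' statistic:
#' \deqn{P_{t,u} \approx 1 - \mathrm{Bin}\{t - 1;\, M,\,
#'       \bar G(q_{t,u})\}, \qquad
#'       q_{t,u} = \frac{u - t + 1/2}{K - M + 1},}
#' where \eqn{\bar G} is the marginal true-signal P-value CDF
#' ([marginal_cdf()]). The approximation error is around 1--3% even at
#' `K` as small as 10 and vanishes as `K` and the rank grow.
#'
#' With `correlated = TRUE` the 1/2 continuity term is dropped
#' (\eqn{q_{t,u} = (u - t + 1)/(K - M + 1)}), which raises the plug-in
#' position and the probability -- the appropriate direction when strong
#' local correlation among the (mostly null) tests reduces the effective
#' number of tests.
#'
#' The binomial tail is evaluated through `pbinom(..., lower.tail =
#' FALSE)` (regularized incomplete beta), stable for large `M`.
#'
#' @param t Required number of true signals, integer \eqn{\ge 0}.
#'   `t = 0` gives probability 1; `t > min(u, M)` gives 0.
#' @param u Number of top hits considered, \eqn{1 \le u \le K}.
#' @param study A [study_spec()].
#' @param correlated Drop the continuity term for locally correlated
#'   tests? Default `FALSE` (independence).
#' @return A `rank_result` with fields `t`, `u`, `q` (plug-in position,
#'   `NA` in the degenerate cases), and `prob`.
#' @examples
#' gwas <- study_spec(2e6, 75, effect_point(7.8))
#' ranking_prob(1, 1, gwas)    # about 0.49: the best hit is a true signal
#' ranking_prob(1, 11, gwas)   # about 0.95
#' @seealso [expected_true_in_top()], [rfdr_expected()], [find_top_u()]
#' @export
ranking_prob <- function(t, u, study, correlated = FALSE) {
  stopifnot(is_study_spec(study))
  .check_count(t, "t", min = 0L)
  .check_count(u, "u")
  if (u > study$K) stop("`u` cannot exceed the total number of tests K",
                        call. = FALSE)
  if (t == 0) return(.rank_result(t, u, NA_real_, 1))
  if (t > min(u, study$M)) return(.rank_result(t, u, NA_real_, 0))
  q <- .q_plugin(t, u, study, correlated)
  G <- marginal_cdf(q, study$effect)
  .rank_result(t, u, q, stats::pbinom(t - 1, study$M, G, lower.tail = FALSE))
}

#' Expected number of true signals among the top u P-values
#'
#' \eqn{E(T) = \sum_{t \ge 1} P(T \ge t) = \sum_{t=1}^{\min(u, M)}
#' P_{t,u}}, the expected count of true signals among the `u` smallest
#' P-values of the experiment.
#'
#' @inheritParams ranking_prob
#' @return A single expectation in \eqn{[0, \min(u, M)]}.
#' @examples
#' gwas <- study_spec(2e6, 75, effect_point(7.8))
#' expected_true_in_top(50, gwas)     # about 5.5
#' @export
expected_true_in_top <- function(u, study, correlated = FALSE) {
  stopifnot(is_study_spec(study))
  .check_count(u, "u")
  if (u > study$K) stop("`u` cannot exceed the total number of tests K",
                        call. = FALSE)
  tmax <- min(u, study$M)
  if (tmax < 1) return(0)
  t <- seq_len(tmax)
  q <- .q_plugin(t, u, study, correlated)
  G <- marginal_cdf(q, study$effect)
  sum(stats::pbinom(t - 1, study$M, G, lower.tail = FALSE))
}

#' Expected ranking false discovery rate among the top u hits
#'
#' The ranking FDR, \eqn{\mathrm{rFDR}(u)}, is the expected proportion of
#' null signals among the `u` smallest P-values; its complement
#' `true_discovery_proportion()` is \eqn{E(T)/u}, the expected proportion
#' of true signals. Unlike threshold-based FDR procedures, the rank `u`
#' -- not a P-value cutoff -- is held fixed.
#'
#' @inheritParams ranking_prob
#' @return A proportion in \eqn{[0, 1]}.
#' @examples
#' gwas <- study_spec(2e6, 75, effect_point(7.8))
#' rfdr_expected(11, gwas)              # about 0.77
#' true_discovery_proportion(11, gwas)  # about 0.23
#' @export
rfdr_expected <- function(u, study, correlated = FALSE) {
  1 - true_discovery_proportion(u, study, correlated)
}

#' @rdname rfdr_expected
#' @export
true_discovery_proportion <- function(u, study, correlated = FALSE) {
  expected_true_in_top(u, study, correlated) / u
}

#' Posterior probability of the null hypothesis given a P-value
#'
#' Under the two-group model with null fraction \eqn{\pi_0 = (K - M)/K},
#' uniform null P-values, and true-signal marginal density `g`
#' ([marginal_density()]),
#' \deqn{\Pr(H_0 \mid p) = \frac{\pi_0}{\pi_0 + (1 - \pi_0) g(p)}.}
#' The posterior depends only on the P-value itself, not on its rank
#' among the K tests, so it is unaffected by selection of the smallest
#' P-values.
#'
#' @param p P-value(s) strictly inside \eqn{(0, 1)}.
#' @param study A [study_spec()].
#' @return Posterior probabilities, same length as `p`.
#' @examples
#' s <- study_spec(10000, 100, effect_point(5))
#' posterior_null(c(1e-6, 1e-3, 0.5), s)
#' @export
posterior_null <- function(p, study) {
  stopifnot(is_study_spec(study))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  pi0 <- study$pi0
  if (pi0 >= 1) return(rep.int(1, length(p)))
  if (pi0 <= 0) return(rep.int(0, length(p)))
  g <- marginal_density(p, study$effect)
  pi0 / (pi0 + (1 - pi0) * g)
}

#' Study-specific ranking FDR from observed P-values
#'
#' Averages the posterior null probability over the `u` smallest observed
#' P-values:
#' \deqn{\mathrm{rFDR}(u) = \frac{1}{u} \sum_{i=1}^{u}
#'       \Pr(H_0 \mid p_{(i)}).}
#' Input P-values are expected in ascending order; unsorted input is
#' sorted defensively with a warning (P-value files arrive unsorted in
#' practice).
#'
#' @param pvalues Numeric vector of observed P-values in \eqn{(0, 1)}.
#' @param u Number of top hits, \eqn{1 \le u \le} `length(pvalues)`.
#' @param study A [study_spec()] describing the assumed testing universe.
#' @return The study-specific rFDR, a proportion in \eqn{[0, 1]}.
#' @examples
#' s <- study_spec(1000, 10, effect_point(8))
#' pv <- sort(simulate_experiment(s, seed = 1)$pvalues)
#' rfdr_study(pv, 10, s)
#' @export
rfdr_study <- function(pvalues, u, study) {
  stopifnot(is_study_spec(study))
  .check_count(u, "u")
  if (u > length(pvalues))
    stop("`u` cannot exceed the number of P-values", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues >= 1))
    stop("P-values must lie strictly inside (0, 1)", call. = FALSE)
  if (is.unsorted(pvalues)) {
    warning("`pvalues` were not sorted; sorting ascending")
    pvalues <- sort(pvalues)
  }
  mean(posterior_null(pvalues[seq_len(u)], study))
}

#' Read a plain-text P-value list
#'
#' One P-value per line; blank lines and `#` comments are ignored.
#'
#' @param file Path to the file.
#' @return Numeric vector of P-values.
#' @export
read_pvalues <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- suppressWarnings(as.numeric(lines))
  if (any(is.na(p)))
    stop(sprintf("non-numeric entries in P-value file '%s'", file),
         call. = FALSE)
  p
}

#' Power of a single test at a significance level
#'
#' Evaluating the P-value CDF at a significance threshold \eqn{\alpha}
#' gives the power of a single test with noncentrality \eqn{\lambda}:
#' `power_at_level(alpha, lam) == pvalue_cdf(alpha, lam)`.
#'
#' @param alpha Significance level in \eqn{(0, 1)}.
#' @param lam Noncentrality \eqn{\lambda \ge 0}.
#' @param df Degrees of freedom, integer \eqn{\ge 1}.
#' @return Power, a probability.
#' @examples
#' power_at_level(2.5e-8, 7.8)   # about 0.003
#' @export
power_at_level <- function(alpha, lam, df = 1L) {
  if (any(alpha <= 0) || any(alpha >= 1))
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  pvalue_cdf(alpha, lam, df)
}

#' Power to detect at least one of M independent true signals
#'
#' \deqn{1 - \{1 - \bar G(\alpha)\}^M,} with \eqn{\bar G} the marginal
#' true-signal P-value CDF of the study. At
#' \eqn{\alpha = \frac{1/2}{K - M + 1}} this coincides exactly with the
#' ranking probability \eqn{P_{1,1}} that the smallest P-value of the
#' experiment is a true signal -- roughly power at ten times the
#' Bonferroni-adjusted 0.05 level.
#'
#' @param alpha Significance level in \eqn{(0, 1)}.
#' @param study A [study_spec()].
#' @return A probability, nondecreasing in both `alpha` and `M`.
#' @examples
#' gwas <- study_spec(2e6, 75, effect_point(7.8))
#' power_any(0.05 / 2e6, gwas)   # about 0.18
#' @export
power_any <- function(alpha, study) {
  stopifnot(is_study_spec(study))
  if (any(alpha <= 0) || any(alpha >= 1))
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  if (study$M == 0) return(rep.int(0, length(alpha)))
  1 - (1 - marginal_cdf(alpha, study$effect))^study$M
}

#' Probability that a true-signal P-value beats the r-th smallest null
#'
#' For a single true signal competing against the \eqn{K - M} null tests
#' of the study, the probability that its P-value falls below the r-th
#' smallest null P-value is
#' \deqn{\int_0^1 \{1 - F_{B(r,\, K-M-r+1)}(p)\}\, g(p)\, dp,}
#' where \eqn{F_{B}} is the Beta CDF of the r-th null order statistic
#' (independent continuous tests) and `g` the true-signal marginal
#' density. With a single null test (\eqn{K - M = 1}, `r = 1`) this
#' reduces to \eqn{1 - E(P_{true})}, the classical expected-P-value
#' comparison of one true against one false signal.
#'
#' @param r Rank among the null P-values, \eqn{1 \le r \le K - M}.
#' @param study A [study_spec()].
#' @return A probability.
#' @examples
#' s <- study_spec(101, 1, effect_point(5))
#' prob_true_beats_null_rank(3, s)
#' @export
prob_true_beats_null_rank <- function(r, study) {
  stopifnot(is_study_spec(study))
  .check_count(r, "r")
  n_null <- study$K - study$M
  if (r > n_null)
    stop("`r` must be between 1 and K - M", call. = FALSE)
  integrand <- function(p)
    stats::pbeta(p, r, n_null - r + 1, lower.tail = FALSE) *
      marginal_density(p, study$effect)
  res <- stats::integrate(integrand, 0, 1, abs.tol = 1e-9, rel.tol = 1e-7,
                          subdivisions = 1000L)
  min(max(res$value, 0), 1)
}
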