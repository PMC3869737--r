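#' Simulate one multiple-testing experiment
#'
#' Draws one noncentrality per true signal from the study's effect-size
#' model, generates the `M` true-signal P-values by the inverse-CDF
#' transform of uniforms, adds `K - M` Uniform(0,1) null P-values, and
#' sorts. Ties (a probability-zero event for these continuous
#' generators) are broken by the stable order of generation: true signals
#' first, in draw order.
#'
#' @param study A [study_spec()].
#' @param seed Optional integer seed (global RNG state restored on exit).
#' @return An object of class `sim_experiment`: a list with `pvalues`
#'   (ascending), `is_true` (parallel logical labels), and `lams_drawn`
#'   (the `M` sampled noncentralities, in draw order).
#' @examples
#' s <- study_spec(1000, 10, effect_gamma(0.5, 15))
#' ex <- simulate_experiment(s, seed = 1)
#' head(ex$pvalues); head(ex$is_true)
#' @export
simulate_experiment <- function(study, seed = NULL) {
  stopifnot(is_study_spec(study))
  with_seed(seed, {
    M <- study$M; K <- study$K
    lams <- draw_noncentralities(study$effect, M)
    p_true <- .pvalues_from_uniforms(stats::runif(M), lams, study$effect$df)
    p_null <- stats::runif(K - M)
    pv <- c(p_true, p_null)
    lab <- rep(c(TRUE, FALSE), c(M, K - M))
    o <- order(pv)
    structure(list(pvalues = pv[o], is_true = lab[o], lams_drawn = lams),
              class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d P-values, %d true signals; smallest p = %.3g (%s)\n",
    length(x$pvalues), sum(x$is_true), x$pvalues[1],
    if (x$is_true[1]) "true" else "null"))
  invisible(x)
}

# m smallest of n i.i.d. uniforms for each of `reps` rows, ascending, by
# the descending-records construction on 1 - U: exact order statistics
# without generating all n uniforms
.uniform_top_m <- function(reps, n, m) {
  X <- matrix(0, reps, m)
  acc <- rep.int(1, reps)
  for (j in seq_len(m)) {
    acc <- acc * stats::runif(reps)^(1 / (n - j + 1))
    X[, j] <- acc
  }
  1 - X
}

#' Counts of true signals among the top u P-values, across replicates
#'
#' Monte Carlo engine behind [empirical_rfdr()] and the validation of the
#' closed-form ranking approximations. For each replicate it simulates
#' one experiment and records, for every requested `u`, how many of the
#' `u` smallest P-values are true signals.
#'
#' Two generation strategies produce distributionally identical counts:
#' `"full"` materializes all `K` P-values per replicate, while `"topm"`
#' generates only the `max(u)` smallest null order statistics (via the
#' records construction of uniform order statistics) -- much faster when
#' `K` is large and only top-`u` summaries are needed. `"auto"` picks
#' `"topm"` for `K >= 10^4`.
#'
#' @param study A [study_spec()].
#' @param u Integer vector of top-hit counts.
#' @param n_reps Number of replicate experiments.
#' @param seed Optional integer seed.
#' @param method `"auto"`, `"full"`, or `"topm"`.
#' @return An `n_reps` by `length(u)` integer matrix of counts, columns
#'   named by `u`.
#' @examples
#' s <- study_spec(1000, 10, effect_gamma(0.5, 15))
#' cnt <- simulate_top_counts(s, u = c(1, 10), n_reps = 200, seed = 1)
#' colMeans(cnt)
#' @export
simulate_top_counts <- function(study, u, n_reps, seed = NULL,
                                method = c("auto", "full", "topm")) {
  stopifnot(is_study_spec(study))
  method <- match.arg(method)
  .check_count(n_reps, "n_reps")
  if (any(u < 1) || any(u > study$K) || any(u != round(u)))
    stop("`u` must be integers between 1 and K", call. = FALSE)
  M <- study$M; K <- study$K
  n_null <- K - M
  m <- max(u)
  if (method == "auto")
    method <- if (K >= 1e4 && n_null >= m && m > 0) "topm" else "full"
  if (method == "topm" && n_null < m)
    stop("`topm` requires max(u) <= K - M", call. = FALSE)
  with_seed(seed, {
    if (method == "full") {
      counts <- matrix(0L, n_reps, length(u))
      lab <- rep(c(TRUE, FALSE), c(M, n_null))
      for (r in seq_len(n_reps)) {
        lams <- draw_noncentralities(study$effect, M)
        pv <- c(.pvalues_from_uniforms(stats::runif(M), lams,
                                       study$effect$df),
                stats::runif(n_null))
        cs <- cumsum(lab[order(pv)])
        counts[r, ] <- cs[u]
      }
    } else {
      if (M > 0) {
        lams <- matrix(draw_noncentralities(study$effect, n_reps * M),
                       n_reps, M)
        p_true <- matrix(.pvalues_from_uniforms(stats::runif(n_reps * M),
                                                as.vector(lams),
                                                study$effect$df),
                         n_reps, M)
      } else {
        p_true <- matrix(numeric(0), n_reps, 0)
      }
      p_null <- .uniform_top_m(n_reps, n_null, m)
      combined <- cbind(p_true, p_null)
      counts <- matrix(0L, n_reps, length(u))
      for (r in seq_len(n_reps)) {
        row <- combined[r, ]
        thr <- sort.int(row, method = "quick")[u]
        counts[r, ] <- vapply(thr, function(th)
          sum(p_true[r, ] <= th), integer(1))
      }
    }
    colnames(counts) <- as.character(u)
    counts
  })
}

#' Monte Carlo estimate of 1 - rFDR(u)
#'
#' Average proportion of true signals among the `u` smallest P-values
#' over `n_reps` simulated experiments, with its Monte Carlo standard
#' error. Noncentralities are redrawn every replicate from the study's
#' effect-size model. This is the simulation estimate that the
#' closed-form [true_discovery_proportion()] approximates.
#'
#' @param study A [study_spec()].
#' @param u Number of top hits (single integer).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @param method Generation strategy, see [simulate_top_counts()].
#' @return A list with `estimate` (mean proportion of true signals among
#'   the top `u`), `se`, `n_reps`, and `u`.
#' @examples
#' s <- study_spec(10000, 100, effect_gamma(1, 5))
#' empirical_rfdr(s, u = 100, n_reps = 200, seed = 1)
#' @export
empirical_rfdr <- function(study, u, n_reps = 1000L, seed = NULL,
                           method = c("auto", "full", "topm")) {
  .check_count(u, "u")
  counts <- simulate_top_counts(study, u, n_reps, seed, method)
  prop <- counts[, 1] / u
  list(estimate = mean(prop),
       se = stats::sd(prop) / sqrt(n_reps),
       n_reps = as.integer(n_reps), u = as.integer(u))
}

#' Exact expectation of -log of an ordered null P-value
#'
#' Under the global null with `K` independent continuous tests, the i-th
#' smallest P-value follows Beta(i, K - i + 1), and
#' \deqn{E\{-\log_b p_{(i)}\} = \frac{\psi(K + 1) - \psi(i)}{\ln b},}
#' with \eqn{\psi} the digamma function. The naive plug-in line
#' \eqn{-\log_b\{i/(K + 1)\}} is biased by Jensen's inequality
#' (it lies strictly below this expectation), which makes the smallest
#' null P-values appear inflated on a QQ plot drawn against it.
#'
#' @param i Order-statistic rank(s), \eqn{1 \le i \le K}.
#' @param K Total number of tests.
#' @param log_base Logarithm base \eqn{b > 1} (default 10).
#' @return Expected value(s) of \eqn{-\log_b p_{(i)}}.
#' @examples
#' expected_neglog_null_order(1, 1, log_base = exp(1))   # exactly 1
#' expected_neglog_null_order(1:5, 1000)
#' @export
expected_neglog_null_order <- function(i, K, log_base = 10) {
  .check_count(K, "K")
  if (any(i < 1) || any(i > K) || any(i != round(i)))
    stop("`i` must be integers between 1 and K", call. = FALSE)
  if (length(log_base) != 1L || !is.finite(log_base) || log_base <= 1)
    stop("`log_base` must be > 1", call. = FALSE)
  (digamma(K + 1) - digamma(i)) / log(log_base)
}

#' Expected null line for a -log P-value QQ plot
#'
#' The exact expected \eqn{-\log_b} ordered null P-values for ranks
#' 1..K, suitable as the reference line of a QQ plot of observed
#' \eqn{-\log_b} P-values.
#'
#' @param K Total number of tests.
#' @param log_base Logarithm base (default 10).
#' @return A data frame of class `qq_line` with columns `rank` and
#'   `expected` (strictly decreasing in rank); the base is stored in
#'   `attr(, "log_base")`.
#' @examples
#' head(qq_line(1000))
#' @export
qq_line <- function(K, log_base = 10) {
  out <- data.frame(rank = seq_len(K),
                    expected = expected_neglog_null_order(seq_len(K), K,
                                                          log_base))
  attr(out, "log_base") <- log_base
  class(out) <- c("qq_line", "data.frame")
  out
}
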