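#' P-value CDF under a noncentral chi-square alternative
#'
#' For a chi-square test statistic with `df` degrees of freedom, the
#' P-value of a test with noncentrality \eqn{\lambda} has CDF
#' \deqn{G(p; \lambda) = 1 - F_\lambda\{F_0^{-1}(1 - p)\},}
#' where \eqn{F_0} and \eqn{F_\lambda} are the central and noncentral
#' chi-square CDFs. Under the null (\eqn{\lambda = 0}) this is the
#' identity: P-values are Uniform(0,1).
#'
#' The central quantile is evaluated through the upper tail
#' (`lower.tail = FALSE`) so that tiny P-values (far below `1e-12`) do not
#' lose precision to cancellation in `1 - p`.
#'
#' @param p P-value(s) in \eqn{[0, 1]}.
#' @param lam Noncentrality \eqn{\lambda \ge 0}; recycled against `p`.
#' @param df Degrees of freedom of the statistic, integer \eqn{\ge 1}.
#' @return `P(P-value <= p)`, same length as the longer of `p`, `lam`.
#' @examples
#' pvalue_cdf(0.05, 0)            # 0.05: uniform under the null
#' pvalue_cdf(2.5e-8, 7.8)        # power-like tail probability
#' @seealso [pvalue_density()], [marginal_cdf()], [power_at_level()]
#' @export
pvalue_cdf <- function(p, lam, df = 1L) {
  df <- .check_df(df)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("`lam` must be >= 0", call. = FALSE)
  n <- max(length(p), length(lam))
  p <- rep_len(p, n); lam <- rep_len(lam, n)
  out <- p
  alt <- lam > 0 & p > 0 & p < 1
  if (any(alt)) {
    x <- stats::qchisq(p[alt], df, lower.tail = FALSE)
    out[alt] <- stats::pchisq(x, df, ncp = lam[alt], lower.tail = FALSE)
  }
  out
}

#' P-value density under a noncentral chi-square alternative
#'
#' Derivative of [pvalue_cdf()]:
#' \deqn{g(p; \lambda) = f_\lambda(x) / f_0(x), \quad
#'       x = F_0^{-1}(1 - p),}
#' the likelihood ratio of the noncentral to the central chi-square
#' density at the statistic value corresponding to `p`. Evaluated on the
#' open interval (0, 1); the ratio is computed on the log scale to remain
#' stable at extreme `p`.
#'
#' @inheritParams pvalue_cdf
#' @param p P-value(s) in the open interval \eqn{(0, 1)}.
#' @return Density value(s), nonnegative; integrates to one over (0, 1).
#' @examples
#' pvalue_density(0.3, 0)   # 1: uniform density
#' pvalue_density(0.01, 7.8)
#' @export
pvalue_density <- function(p, lam, df = 1L) {
  df <- .check_df(df)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("`lam` must be >= 0", call. = FALSE)
  n <- max(length(p), length(lam))
  p <- rep_len(p, n); lam <- rep_len(lam, n)
  out <- rep.int(1, n)
  alt <- lam > 0
  if (any(alt)) {
    x <- stats::qchisq(p[alt], df, lower.tail = FALSE)
    out[alt] <- exp(stats::dchisq(x, df, ncp = lam[alt], log = TRUE) -
                    stats::dchisq(x, df, log = TRUE))
  }
  out
}

# Inverse-CDF transform of uniforms to P-values, one signal per draw.
# Solves G(p; lam) = u. For df = 1 the noncentral chi-square is a squared
# shifted normal, giving the exact closed form
#   p = 2 * pnorm(-|qnorm(u) + sqrt(lam)|);
# general df falls back to the (slow) noncentral chi-square quantile.
.pvalues_from_uniforms <- function(u, lam, df) {
  n <- max(length(u), length(lam))
  u <- rep_len(u, n); lam <- rep_len(lam, n)
  out <- u
  alt <- lam > 0
  if (!any(alt)) return(out)
  if (df == 1L) {
    z <- stats::qnorm(u[alt])
    out[alt] <- 2 * stats::pnorm(-abs(z + sqrt(lam[alt])))
  } else {
    x <- stats::qchisq(u[alt], df, ncp = lam[alt], lower.tail = FALSE)
    out[alt] <- stats::pchisq(x, df, lower.tail = FALSE)
  }
  out
}

#' Sample P-values from an effect-size model
#'
#' Generates i.i.d. P-values for true signals: a fresh noncentrality is
#' drawn per sample from the model (for tabulated and Gamma models), and
#' each uniform draw is pushed through the inverse P-value CDF. Under the
#' null (\eqn{\lambda = 0}) the P-values are exactly the uniform draws.
#'
#' @param model An [effect_model] object.
#' @param n Number of samples, \eqn{\ge 1}.
#' @param seed Optional integer seed; when supplied, the global RNG state
#'   is saved and restored, so the call is reproducible and side-effect
#'   free.
#' @return Numeric vector of `n` P-values.
#' @examples
#' sample_pvalues(effect_point(7.8), 5, seed = 1)
#' @export
sample_pvalues <- function(model, n, seed = NULL) {
  stopifnot(is_effect_model(model))
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  with_seed(seed, {
    u <- stats::runif(n)
    lam <- if (model$kind == "point") model$lam else draw_noncentralities(model, n)
    .pvalues_from_uniforms(u, lam, model$df)
  })
}

# adaptive quadrature of fn(lambda) against the Gamma(shape, scale)
# density over (0, upper], upper chosen so the truncated tail mass is
# below 1e-12 (the integrand is bounded for the CDF case, so the
# truncation error is below the quadrature tolerance)
.gamma_mix_quad <- function(model, fn, abs.tol = 1e-10) {
  upper <- stats::qgamma(1e-12, model$shape, scale = model$scale,
                         lower.tail = FALSE)
  integrand <- function(l) fn(l) * stats::dgamma(l, model$shape, scale = model$scale)
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = upper,
                     abs.tol = abs.tol, rel.tol = 1e-8,
                     subdivisions = 1000L),
    error = function(e) e)
  if (inherits(res, "error"))
    stop(sprintf(
      "quadrature over the Gamma(%g, %g) noncentrality distribution failed: %s",
      model$shape, model$scale, conditionMessage(res)), call. = FALSE)
  res$value
}

#' Marginal P-value CDF over an effect-size model
#'
#' CDF of a true-signal P-value averaged over the noncentrality
#' distribution:
#' \deqn{\bar G(p) = \int G(p; \lambda)\, d\gamma(\lambda),}
#' a finite mixture for point/tabulated models and an adaptive quadrature
#' (absolute tolerance `1e-10`) for the Gamma model. Replacing the model
#' by [to_mean_model()] gives the first-order (mean-noncentrality)
#' approximation; [to_tabulated()] gives the binned approximation.
#'
#' @param p P-value(s) in \eqn{[0, 1]}.
#' @param model An [effect_model] object.
#' @return `P(true-signal P-value <= p)`, same length as `p`.
#' @examples
#' marginal_cdf(0.001, effect_gamma(1, 5))
#' marginal_cdf(0.001, to_mean_model(effect_gamma(1, 5)))
#' @export
marginal_cdf <- function(p, model) {
  stopifnot(is_effect_model(model))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  switch(model$kind,
    point = pvalue_cdf(p, model$lam, model$df),
    tabulated = vapply(p, function(pi)
      sum(model$weights * pvalue_cdf(pi, model$lams, model$df)), numeric(1)),
    gamma = vapply(p, function(pi) {
      if (pi <= 0) return(0)
      if (pi >= 1) return(1)
      .gamma_mix_quad(model, function(l) pvalue_cdf(pi, l, model$df))
    }, numeric(1)))
}

#' Marginal P-value density over an effect-size model
#'
#' Density companion to [marginal_cdf()]: the P-value density of a true
#' signal averaged over the noncentrality distribution. Evaluated on the
#' open interval (0, 1).
#'
#' @inheritParams marginal_cdf
#' @param p P-value(s) in \eqn{(0, 1)}.
#' @return Density value(s), same length as `p`.
#' @examples
#' marginal_density(0.01, effect_tabulated(c(2, 8)))
#' @export
marginal_density <- function(p, model) {
  stopifnot(is_effect_model(model))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  switch(model$kind,
    point = pvalue_density(p, model$lam, model$df),
    tabulated = vapply(p, function(pi)
      sum(model$weights * pvalue_density(pi, model$lams, model$df)),
      numeric(1)),
    gamma = vapply(p, function(pi)
      .gamma_mix_quad(model, function(l) pvalue_density(pi, l, model$df)),
      numeric(1)))
}
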