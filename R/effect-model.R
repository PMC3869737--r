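#' Effect-size (noncentrality) models for true signals
#'
#' In a study with many tests, each true signal carries a noncentrality
#' parameter \eqn{\lambda} -- a standardized effect size scaled by sample
#' size -- that governs the distribution of its P-value through a
#' noncentral chi-square test statistic. Across signals the noncentralities
#' can be thought of as draws from a distribution. Three models are
#' supported:
#'
#' * `effect_point(lam)`: every true signal has the same noncentrality
#'   (a "typical" effect size, e.g. the mean of an assumed distribution);
#' * `effect_tabulated(lams, weights)`: a discrete set of noncentralities
#'   \eqn{\lambda_j} with relative abundances \eqn{w_j} (bins of an
#'   effect-size distribution, low/medium/high values, etc.);
#' * `effect_gamma(shape, scale)`: \eqn{\lambda \sim}
#'   Gamma(shape, scale). For shape \eqn{\le 1} the density is L-shaped,
#'   matching the biologically common situation of many small effects and
#'   a few large ones.
#'
#' All models carry the degrees of freedom `df` of the underlying
#' chi-square statistic (default 1, the usual association trend test).
#'
#' @param lam Noncentrality \eqn{\lambda \ge 0}.
#' @param lams Numeric vector of distinct noncentralities, each \eqn{\ge 0}.
#' @param weights Relative abundances, same length as `lams`, nonnegative
#'   with a positive sum; normalized to sum to one. Defaults to equal
#'   weights.
#' @param shape,scale Gamma shape \eqn{a > 0} and scale \eqn{b > 0}
#'   (mean \eqn{ab}).
#' @param df Degrees of freedom of the test statistic, integer \eqn{\ge 1}.
#'
#' @return An object of class `effect_model` (subclass `effect_point`,
#'   `effect_tabulated`, or `effect_gamma`).
#'
#' @examples
#' effect_point(7.8)
#' effect_gamma(0.5, 15)          # mean noncentrality 7.5
#' effect_tabulated(c(2, 8), c(0.5, 0.5))
#' @seealso [marginal_cdf()], [study_spec()], [to_tabulated()]
#' @name effect_model
NULL

.check_df <- function(df) {
  if (length(df) != 1L || !is.finite(df) || df < 1 || df != round(df))
    stop("`df` must be a single integer >= 1", call. = FALSE)
  as.integer(df)
}

#' @rdname effect_model
#' @export
effect_point <- function(lam, df = 1L) {
  if (length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("`lam` must be a single finite noncentrality >= 0", call. = FALSE)
  structure(list(kind = "point", lam = as.numeric(lam), df = .check_df(df)),
            class = c("effect_point", "effect_model"))
}

#' @rdname effect_model
#' @export
effect_tabulated <- function(lams, weights = NULL, df = 1L) {
  if (length(lams) < 1L || any(!is.finite(lams)) || any(lams < 0))
    stop("`lams` must be finite noncentralities >= 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(lams))
  if (length(weights) != length(lams) || any(!is.finite(weights)) ||
      any(weights < 0) || sum(weights) <= 0)
    stop("`weights` must be nonnegative with a positive sum, one per lambda",
         call. = FALSE)
  o <- order(lams)
  lams <- as.numeric(lams[o])
  weights <- as.numeric(weights[o])
  if (anyDuplicated(lams))
    stop("`lams` must be distinct", call. = FALSE)
  structure(list(kind = "tabulated", lams = lams,
                 weights = weights / sum(weights), df = .check_df(df)),
            class = c("effect_tabulated", "effect_model"))
}

#' @rdname effect_model
#' @export
effect_gamma <- function(shape, scale, df = 1L) {
  if (length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("Gamma `shape` must be a single value > 0", call. = FALSE)
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("Gamma `scale` must be a single value > 0", call. = FALSE)
  structure(list(kind = "gamma", shape = as.numeric(shape),
                 scale = as.numeric(scale), df = .check_df(df)),
            class = c("effect_gamma", "effect_model"))
}

#' @export
print.effect_model <- function(x, ...) {
  desc <- switch(x$kind,
    point = sprintf("point mass at lambda = %g", x$lam),
    tabulated = sprintf("%d tabulated noncentralities (mean %g)",
                        length(x$lams), effect_mean(x)),
    gamma = sprintf("Gamma(shape = %g, scale = %g), mean %g",
                    x$shape, x$scale, x$shape * x$scale))
  cat(sprintf("<effect_model> %s, df = %d\n", desc, x$df))
  invisible(x)
}

is_effect_model <- function(x) inherits(x, "effect_model")

#' Moments of an effect-size model
#'
#' Mean and variance of the noncentrality distribution of true signals.
#'
#' @param model An [effect_model] object.
#' @return A single numeric value.
#' @examples
#' effect_mean(effect_gamma(1, 5))       # 5
#' effect_variance(effect_point(7.8))    # 0
#' @export
effect_mean <- function(model) {
  stopifnot(is_effect_model(model))
  switch(model$kind,
    point = model$lam,
    tabulated = sum(model$weights * model$lams),
    gamma = model$shape * model$scale)
}

#' @rdname effect_mean
#' @export
effect_variance <- function(model) {
  stopifnot(is_effect_model(model))
  switch(model$kind,
    point = 0,
    tabulated = {
      mu <- sum(model$weights * model$lams)
      sum(model$weights * (model$lams - mu)^2)
    },
    gamma = model$shape * model$scale^2)
}

#' Collapse an effect-size model to its mean
#'
#' Replaces the noncentrality distribution by a point mass at its mean
#' \eqn{\mu = E(\lambda)}. Using the resulting model inside
#' [marginal_cdf()] is the first-order Taylor approximation
#' \eqn{\bar G(p) \approx G(p; \mu)} to the full mixture: computationally
#' trivial, and often adequate when the number of top hits examined is not
#' too small relative to the number of tests.
#'
#' @param model An [effect_model] object.
#' @return A point-mass `effect_model` at the mean noncentrality.
#' @examples
#' to_mean_model(effect_gamma(1, 5))  # point mass at 5
#' @export
to_mean_model <- function(model) {
  stopifnot(is_effect_model(model))
  effect_point(effect_mean(model), df = model$df)
}

#' Discretize an effect-size model into equal-probability bins
#'
#' Reduces a continuous noncentrality distribution to `n_bins`
#' representative values with relative abundances: the support is cut at
#' its `1/n_bins, 2/n_bins, ...` quantiles, each bin is represented by its
#' conditional mean, and each receives weight `1/n_bins`. With three bins
#' (low/medium/high typical effects, equally abundant) this recovers most
#' of the precision of the full distribution at a fraction of the cost --
#' the practical middle ground between the full mixture and the
#' single-mean shortcut of [to_mean_model()].
#'
#' The overall mean is preserved exactly (law of total expectation).
#' Point models are returned as a single bin; tabulated models are
#' returned unchanged.
#'
#' @param model An [effect_model] object.
#' @param n_bins Number of equal-probability bins (default 3).
#' @return A tabulated `effect_model`.
#' @examples
#' to_tabulated(effect_gamma(1, 5), 3)
#' @export
to_tabulated <- function(model, n_bins = 3L) {
  stopifnot(is_effect_model(model))
  if (length(n_bins) != 1L || n_bins < 1 || n_bins != round(n_bins))
    stop("`n_bins` must be a single integer >= 1", call. = FALSE)
  n_bins <- as.integer(n_bins)
  switch(model$kind,
    point = effect_tabulated(model$lam, 1, df = model$df),
    tabulated = model,
    gamma = {
      a <- model$shape; b <- model$scale
      edges <- stats::qgamma(seq(0, n_bins) / n_bins, a, scale = b)
      # conditional mean of Gamma(a, b) on (lo, hi]:
      #   a b [P(hi; a+1) - P(lo; a+1)] / (1/n_bins)
      cm <- a * b * n_bins *
        (stats::pgamma(edges[-1L], a + 1, scale = b) -
         stats::pgamma(edges[-(n_bins + 1L)], a + 1, scale = b))
      effect_tabulated(cm, rep(1 / n_bins, n_bins), df = model$df)
    })
}

# draw n noncentralities from the model (uses the current RNG stream)
draw_noncentralities <- function(model, n) {
  switch(model$kind,
    point = rep.int(model$lam, n),
    tabulated = model$lams[sample.int(length(model$lams), n, replace = TRUE,
                                      prob = model$weights)],
    gamma = stats::rgamma(n, shape = model$shape, scale = model$scale))
}
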