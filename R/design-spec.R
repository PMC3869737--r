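#' Case-control design specification
#'
#' Epidemiological parameters of a 2x2 allele-count association test:
#' group sizes, the control (baseline) allele frequency, and the allelic
#' odds ratio / genotype relative risk. These map to the noncentrality of
#' the one-degree-of-freedom chi-square trend statistic via
#' [noncentrality_from_design()].
#'
#' @param n_case,n_control Numbers of cases and controls (individuals),
#'   positive integers.
#' @param allele_freq Control allele frequency \eqn{p_0 \in (0, 1)}.
#' @param relative_risk Allelic odds ratio / relative risk
#'   \eqn{\psi > 0}.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(3000, 3000, allele_freq = 0.15, relative_risk = 1.15)
#' @export
design_spec <- function(n_case, n_control, allele_freq, relative_risk) {
  if (length(n_case) != 1L || n_case < 1 || n_case != round(n_case))
    stop("`n_case` must be a single positive integer", call. = FALSE)
  if (length(n_control) != 1L || n_control < 1 || n_control != round(n_control))
    stop("`n_control` must be a single positive integer", call. = FALSE)
  if (length(allele_freq) != 1L || !is.finite(allele_freq) ||
      allele_freq <= 0 || allele_freq >= 1)
    stop("`allele_freq` must lie strictly inside (0, 1)", call. = FALSE)
  if (length(relative_risk) != 1L || !is.finite(relative_risk) ||
      relative_risk <= 0)
    stop("`relative_risk` must be > 0", call. = FALSE)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 allele_freq = as.numeric(allele_freq),
                 relative_risk = as.numeric(relative_risk)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %d cases / %d controls, allele freq %g, relative risk %g\n",
    x$n_case, x$n_control, x$allele_freq, x$relative_risk))
  cat(sprintf("  noncentrality (df = 1): %.4g\n",
              noncentrality_from_design(x)))
  invisible(x)
}

# allele-count row totals, their half harmonic mean, and the pooled
# allele frequency implied by the risk model
.design_internals <- function(design) {
  psi <- design$relative_risk
  p0 <- design$allele_freq
  # case allele frequency under the multiplicative risk model:
  # odds are multiplied by psi, so p1 = psi p0 / (1 + (psi - 1) p0)
  p1 <- psi * p0 / (1 + (psi - 1) * p0)
  r_case <- 2 * design$n_case      # allele-count row totals
  r_control <- 2 * design$n_control
  n_tilde <- 1 / (0.5 * (1 / r_case + 1 / r_control)) / 2
  p_bar <- (r_case * p1 + r_control * p0) / (r_case + r_control)
  list(p1 = p1, n_tilde = n_tilde, p_bar = p_bar)
}

#' Noncentrality implied by a case-control design
#'
#' Converts design parameters to the approximate noncentrality of the
#' chi-square statistic for testing a zero log odds ratio:
#' \deqn{\lambda = (\ln \psi)^2 \, \tilde n \, \bar p (1 - \bar p),}
#' where \eqn{\tilde n} is one half of the harmonic mean of the two
#' allele-count row totals (\eqn{2 n_{case}} and \eqn{2 n_{control}}) and
#' \eqn{\bar p} is the allele frequency pooled across the rows. The case
#' allele frequency is derived from \eqn{(p_0, \psi)} under the
#' multiplicative (odds) risk model. \eqn{\lambda = 0} exactly when
#' \eqn{\psi = 1}.
#'
#' Because \eqn{\lambda} is linear in \eqn{\tilde n}, the per-allele
#' effect term `per_allele_effect()` (\eqn{c = \lambda / \tilde n}) is a
#' sample-size-free effect summary: \eqn{\lambda = c \tilde n} for any
#' group sizes, which is what [find_sample_size()] exploits.
#'
#' @param design A [design_spec()] object.
#' @return The noncentrality \eqn{\lambda \ge 0}.
#' @examples
#' d <- design_spec(3000, 3000, allele_freq = 0.15, relative_risk = 1.15)
#' noncentrality_from_design(d)   # about 7.85
#' per_allele_effect(d)           # about 0.0026
#' @export
noncentrality_from_design <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  int <- .design_internals(design)
  if (int$p_bar <= 0 || int$p_bar >= 1)
    stop("degenerate pooled allele frequency", call. = FALSE)
  log(design$relative_risk)^2 * int$n_tilde * int$p_bar * (1 - int$p_bar)
}

#' @rdname noncentrality_from_design
#' @export
per_allele_effect <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  noncentrality_from_design(design) / .design_internals(design)$n_tilde
}
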