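# shared study fixtures (built in code; no data files)

# GWAS motivating scenario: 2e6 trend tests, 75 true signals with the
# "typical" noncentrality 7.8 from 3000/3000 cases/controls, p0 = 0.15,
# relative risk 1.15
gwas_study <- function() study_spec(2e6, 75, effect_point(7.8))

gwas_design <- function() design_spec(3000, 3000, allele_freq = 0.15,
                                      relative_risk = 1.15)

# QQ-plot illustration scenario: 1000 tests, 10 true signals with
# Gamma(1/2, 15) noncentralities
fig1_study <- function() study_spec(1000, 10, effect_gamma(0.5, 15))

# exact ranking probability by integration over the Beta law of the
# (u - t + 1)-th null order statistic: the independent oracle for the
# plug-in approximation
exact_ranking_prob <- function(t, u, study) {
  K <- study$K; M <- study$M
  r <- u - t + 1
  stats::integrate(function(x)
    stats::pbinom(t - 1, M, marginal_cdf(x, study$effect),
                  lower.tail = FALSE) *
      stats::dbeta(x, r, K - M - r + 1),
    0, 1, rel.tol = 1e-9, abs.tol = 1e-12)$value
}
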