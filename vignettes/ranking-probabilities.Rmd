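---
title: "Ranking probabilities, top hits, and the ranking FDR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking probabilities, top hits, and the ranking FDR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankprob)
```

# The model

A study consists of $K$ independent tests, of which $M$ are *true
signals*. Each test yields a chi-square statistic with $df$ degrees of
freedom ($df = 1$ throughout the defaults, the usual association trend
test; the parameter is carried everywhere for generality). A true
signal has noncentrality $\lambda > 0$, a standardized effect size
multiplied by sample size; a null test has $\lambda = 0$ and therefore
a Uniform(0,1) P-value.

The P-value of a test with noncentrality $\lambda$ has CDF

$$G(p;\lambda) = 1 - F_\lambda\{F_0^{-1}(1-p)\},$$

with $F_0, F_\lambda$ the central and noncentral chi-square CDFs
(`pvalue_cdf()`), density $g(p;\lambda) = f_\lambda(x)/f_0(x)$ at
$x = F_0^{-1}(1-p)$ (`pvalue_density()`), and inverse-CDF sampler
$p = 1 - F_0\{F_\lambda^{-1}(1-U)\}$ (`sample_pvalues()`).

Different signals have different effect sizes. The package treats the
noncentralities of true signals as draws from an *effect-size model*
$\gamma(\lambda)$, with three interchangeable representations
(`effect_point()`, `effect_tabulated()`, `effect_gamma()`). The Gamma
family is the continuous workhorse: for shape $\le 1$ it is L-shaped,
encoding many small effects and a few large ones, which is the
biologically typical situation. The marginal P-value CDF of a true
signal is the mixture

$$\bar G(p) = \int G(p;\lambda)\, d\gamma(\lambda),$$

a finite sum for point/tabulated models and an adaptive quadrature for
the Gamma model (`marginal_cdf()`, `marginal_density()`).

Two systematic simplifications of a continuous model are first-class
operations, because specifying a full effect-size distribution is the
hardest input in practice:

* `to_mean_model()` replaces $\gamma$ by a point mass at
  $\mu = E(\lambda)$. This is the first-order Taylor approximation
  $\bar G(p) \approx G(p;\mu)$: easy to elicit ("a typical effect"),
  adequate when the number of top hits examined is not too small, but
  substantially imprecise when $K$ is very large and $u$ is small.
* `to_tabulated(model, 3)` cuts the distribution into
  equal-probability bins represented by their conditional means
  (closed-form for the Gamma: the bin mean over $(l, h]$ is
  $ab\,n\{P(h;a{+}1,b) - P(l;a{+}1,b)\}$). Three bins — low, medium,
  high, equally abundant — recover most of the precision of the full
  integral; the test suite asserts that wherever the mean shortcut is
  badly off, the three-bin model lands closer to the full-integration
  value. The bin boundaries here are the model's own terciles; any
  partition with correct conditional abundances behaves similarly.

Second-order (variance-corrected) expansions are deliberately not
implemented: away from the expansion point they can behave worse than
the first-order form, especially at tiny P-values.

# Ranking probabilities

The ranking probability $P_{t,u}$ is the chance that at least $t$ true
signals rank among the $u$ smallest P-values of the whole experiment.
The event is equivalent to the $t$-th smallest *true* P-value falling
below the $(u-t+1)$-th smallest *null* P-value. With $M$ independent
true signals, the $j$-th ordered true P-value has CDF
$1 - \mathrm{Bin}(j-1; M, \bar G(p))$ (`ordered_true_cdf()`); the null
order statistic is Beta$(u-t+1,\, K-M-u+t)$ distributed. Rather than
integrating over that Beta law, `ranking_prob()` plugs in a single
position

$$q_{t,u} = \frac{u - t + 1/2}{K - M + 1},$$

giving $P_{t,u} \approx 1 - \mathrm{Bin}\{t-1;\, M,\, \bar G(q_{t,u})\}$.

**Why this plug-in.** The mean of the Beta law is $(u-t+1)/(K-M+1)$;
because $\bar G$ is concave, evaluating at the mean overstates
$E[\bar G(B)]$, and the $1/2$ continuity correction pulls the position
down to compensate. This form was chosen because it simultaneously (i)
reproduces the published worked-example values to their printed
precision across every scenario the test suite checks, and (ii) makes
the identity below exact. With `correlated = TRUE` the $1/2$ term is
dropped. Under strong local correlation (e.g. linkage disequilibrium)
the effective number of null tests is smaller than $K - M$, so the null
order statistics sit higher; raising $q$ is the correct direction, and
dropping the continuity term is the smallest modification that achieves
it. This interpretation of the correlation variant is a design choice
of this package; it is monotone (the correlated probability is always
the larger) and reduces to the independence form as the correction
becomes negligible.

**Accuracy.** The plug-in is an approximation with bias of order a few
tenths of a percent at $K$ in the hundreds (a few percent at $K$ near
10, vanishing as $K$ and the rank grow). The test suite quantifies it
against the exact order-statistic integral
$E_B[1 - \mathrm{Bin}(t-1; M, \bar G(B))]$ at $K = 200$: the worst cell
over $t \in \{1,2,3\}$, $u \in \{1,5,10,20\}$ differs by about 0.011.
This bias is inherent to the plug-in form, not to its implementation;
Monte Carlo comparisons at a precision finer than it (e.g. $3$ standard
errors at $10^5$ replicates) will resolve the bias rather than disagree
with the distributional model.

**Identities.** At $t = u = 1$,
$P_{1,1} = 1 - \{1 - \bar G(\tfrac{1/2}{K-M+1})\}^M$, which is exactly
`power_any()` at the level $\frac{1/2}{K-M+1}$ — for $K$ in the
millions, about ten times the Bonferroni-adjusted 0.05 level. The suite
asserts this identity to $10^{-12}$.

# Yield, rFDR, and posterior probabilities

`expected_true_in_top()` computes $E(T) = \sum_{t\ge 1} P_{t,u}$, and
`rfdr_expected()` the ranking FDR $1 - E(T)/u$: the expected proportion
of nulls among the top $u$ hits, with the *rank* fixed rather than a
P-value threshold as in threshold-based FDR control.

`posterior_null()` gives the two-group posterior
$\pi_0/\{\pi_0 + (1-\pi_0) g(p)\}$ with $\pi_0 = (K-M)/K$; it depends
only on the P-value, not its rank, so selecting the smallest P-values
does not invalidate it. `rfdr_study()` averages it over the $u$
smallest observed P-values — the study-specific rFDR for real data read
with `read_pvalues()`. The posterior-averaged and ranking-probability
versions of rFDR agree only approximately: the ranking form fixes $M$,
the posterior form treats each test as true with probability
$1-\pi_0$. The discrepancy is small (the suite bounds it by 0.02 in a
$K = 10^4$, $M = 100$ setting) and grows only where posteriors approach
one.

`prob_true_beats_null_rank()` connects to the expected-P-value view of
test quality: the chance a true signal's P-value beats the $r$-th
smallest of $K - M$ nulls, $\int \{1 - F_{B(r, K-M-r+1)}(p)\} g(p)\,dp$,
reducing to $1 - E(P_{\mathrm{true}})$ for a single null.

# Design questions

`find_top_u()` inverts $u \mapsto P_{t,u}$ (monotone, so integer
bisection; the returned $u^*$ satisfies $P_{t,u^*} \ge$ target and
$P_{t,u^*-1} <$ target). A target is unattainable only when $t > M$;
the function then returns a tagged `design_result` with
`attained = FALSE` instead of raising an error, so exploration
pipelines can branch.

`noncentrality_from_design()` converts a case-control design to
$\lambda = (\ln\psi)^2\, \tilde n\, \bar p(1-\bar p)$, with $\tilde n$
one half of the harmonic mean of the allele-count row totals
($2n_{case}$, $2n_{ctrl}$) and $\bar p$ the pooled allele frequency.
The case allele frequency is derived from the control frequency and
$\psi$ under the multiplicative odds model
$p_1 = \psi p_0 / \{1 + (\psi - 1)p_0\}$ — the source context does not
pin this convention down, and it was adopted because it reproduces the
reference design's printed noncentrality (3000/3000, $p_0 = 0.15$,
$\psi = 1.15 \Rightarrow \lambda = 7.850$, printed as 7.8). The
per-allele term $c = \lambda/\tilde n$ (about 0.0026 for that design)
is sample-size free, so $\lambda = c\,\tilde n$ scales linearly:
`find_sample_size()` searches the smallest per-group size on a grid
(default 500-step; group sizes are integers, so a grid is exact where a
continuous root-finder would not be) whose yield $E(T)$ among the top
$u$ reaches a target. Yields saturate at $M$ as the sample grows.

# The simulator

`simulate_experiment()` mirrors the generative model exactly: draw $M$
noncentralities from the effect model, transform $M$ uniforms through
the inverse P-value CDF, append $K - M$ uniforms, sort with labels.
`empirical_rfdr()` repeats this (default `n_reps = 1000`, matching the
convention of reporting simulation averages over 1000 experiments, with
the standard error always attached) and records the proportion of true
signals among the top $u$; noncentralities are redrawn *every*
replicate, so the simulation variance includes effect-size variability.

For large $K$ with only top-$u$ summaries needed,
`simulate_top_counts(method = "topm")` generates just the $m = \max(u)$
smallest null order statistics by the records construction
($X_{(n)} = U_1^{1/n}$, $X_{(n-j)} = X_{(n-j+1)} U_{j+1}^{1/(n-j)}$,
applied to $1-U$), which is exact, not approximate; "full" and "topm"
are distributionally identical and the suite compares them at
$K = 10^4$.

Numerical and RNG choices:

* **Sampling speed.** For $df = 1$ the noncentral chi-square is a
  squared shifted normal, so the sampler uses the exact closed form
  $p = 2\Phi(-|\Phi^{-1}(U) + \sqrt\lambda|)$ — one uniform per draw,
  vectorized, about two orders of magnitude faster than the noncentral
  quantile function, and distributionally identical to the inverse-CDF
  transform. General $df$ uses the quantile function. Under
  $\lambda = 0$ the samples are exactly the uniform draws.
* **Tiny P-values.** $F_0^{-1}(1-p)$ is always computed via the
  upper-tail quantile, avoiding cancellation for $p < 10^{-12}$;
  density ratios are computed on the log scale.
* **Quadrature.** Gamma mixtures integrate over
  $(0, Q_\Gamma(1 - 10^{-12})]$ with absolute tolerance $10^{-10}$; the
  CDF integrand is bounded by one, so the truncated tail contributes
  below tolerance. The binomial tail uses `pbinom(lower.tail = FALSE)`
  (regularized incomplete beta), stable at large $M$; plug-in positions
  are clipped to $[10^{-300}, 1]$.
* **RNG.** Every stochastic entry point takes a single integer seed and
  saves/restores the caller's RNG state. A single seeded stream (rather
  than per-replicate substreams) is used: there is no parallelism to
  justify substreams, and one stream keeps whole-run reproducibility
  byte-exact. Ties among continuous P-values are probability-zero;
  sorting is stable in generation order (true signals first) for
  reproducibility of labels.

# QQ reference line

For QQ plots of $-\log_b$ P-values, plugging the expectation *inside*
the logarithm ($-\log_b \frac{i}{K+1}$) is biased by Jensen's
inequality and makes the smallest null P-values appear inflated. The
exact line uses the Beta$(i, K-i+1)$ law of the $i$-th null order
statistic:

$$E\{-\log_b p_{(i)}\} = \frac{\psi(K+1) - \psi(i)}{\ln b},$$

with $\psi$ the digamma function (`expected_neglog_null_order()`,
`qq_line()`). The suite verifies the $K = 1$ case ($-E\ln U = 1$),
Monte Carlo agreement, and the strict Jensen direction.

# What the simulations do and do not show

The simulator generates *independent* tests. Real large-scale studies
(GWAS in particular) have local correlation; the closed forms remain
robust under even fairly strong correlation among the (majority) null
tests as $u$ grows, and the `correlated` variant adjusts the plug-in in
the right direction, but the package does not simulate linkage
disequilibrium or genotype-level data, so that robustness is asserted,
not re-verified here. Estimating the effect-size distribution (or $M$,
or $\pi_0$) from data is likewise out of scope: all inputs are assumed
known or elicited. P-values are assumed exactly uniform under the null
and the chi-square model exact — discreteness, inflation, or
misspecified statistics are not modelled.

Problem sizes in the shipped tests were chosen to keep the full suite
under roughly half a minute while leaving Monte Carlo standard errors
well below the effects being checked: $10^5$ replicates for the
brute-force ranking grid at $K = 200$, $10^4$ for the Gamma scenario at
$K = 1000$, 1000 replicates (the reporting convention) for the
$K = 10^4$ simulation rows, and grid-based empirical-CDF checks with
$10^5$ draws in place of full Kolmogorov–Smirnov evaluation against
quadrature-priced marginal CDFs.
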