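test_that("study_spec tracks the null fraction and validates M <= K", {
  s <- study_spec(1000, 10, effect_point(5))
  expect_equal(s$pi0, 0.99)
  expect_error(study_spec(10, 11, effect_point(5)), "exceed")
  expect_error(study_spec(10, 1), "effect")
  s0 <- study_spec(100, 0)
  expect_equal(s0$pi0, 1)
})

test_that("ordered true-signal CDF reduces to the marginal for one signal", {
  s1 <- study_spec(100, 1, effect_point(5))
  p <- c(1e-4, 0.01, 0.3)
  expect_equal(ordered_true_cdf(1, p, s1), marginal_cdf(p, s1$effect))
  expect_equal(ordered_true_cdf(1, 1, s1), 1)
  s10 <- study_spec(1000, 10, effect_point(5))
  expect_error(ordered_true_cdf(11, 0.1, s10), "between 1 and M")
  expect_true(all(diff(ordered_true_cdf(3, seq(0.001, 0.5, len = 20),
                                        s10)) >= 0))
})

test_that("ordered true-signal CDF matches direct simulation", {
  # oracle: frequency that >= 3 of 10 true-signal P-values fall below 0.01
  s <- study_spec(1000, 10, effect_point(5))
  set.seed(4)
  pm <- matrix(sample_pvalues(effect_point(5), 1e5 * 10), ncol = 10)
  hits <- rowSums(pm <= 0.01)
  emp <- mean(hits >= 3)
  se <- sqrt(emp * (1 - emp) / 1e5)
  expect_equal(ordered_true_cdf(3, 0.01, s), emp, tolerance = 3 * se / emp)
})

test_that("ranking probability handles the degenerate ranks", {
  s <- study_spec(1000, 10, effect_point(5))
  expect_equal(ranking_prob(0, 5, s)$prob, 1)
  expect_equal(ranking_prob(6, 5, s)$prob, 0)   # t > u
  expect_equal(ranking_prob(11, 50, s)$prob, 0) # t > M
  expect_error(ranking_prob(1, 1001, s), "exceed")
  r <- ranking_prob(2, 10, s)
  expect_true(r$q > 0 && r$q < 1)
  expect_equal(r$q, (10 - 2 + 0.5) / (1000 - 10 + 1))
})

test_that("ranking probability is monotone in t, u, M and lambda", {
  s <- study_spec(500, 20, effect_point(6))
  pt <- vapply(1:6, function(t) ranking_prob(t, 10, s)$prob, numeric(1))
  expect_true(all(diff(pt) <= 0))
  pu <- vapply(c(1, 2, 5, 10, 50, 200), function(u)
    ranking_prob(2, u, s)$prob, numeric(1))
  expect_true(all(diff(pu) >= 0))
  pM <- vapply(c(5, 10, 20, 40), function(M)
    ranking_prob(2, 10, study_spec(500, M, effect_point(6)))$prob,
    numeric(1))
  expect_true(all(diff(pM) >= 0))
  pl <- vapply(c(1, 3, 6, 12), function(l)
    ranking_prob(2, 10, study_spec(500, 20, effect_point(l)))$prob,
    numeric(1))
  expect_true(all(diff(pl) >= 0))
})

test_that("dropping the continuity term raises the ranking probability", {
  s <- study_spec(500, 20, effect_point(6))
  expect_gt(ranking_prob(2, 10, s, correlated = TRUE)$prob,
            ranking_prob(2, 10, s, correlated = FALSE)$prob)
})

test_that("P(1,1) equals power_any at half the reciprocal null count", {
  for (s in list(gwas_study(), fig1_study(),
                 study_spec(50, 5, effect_point(4)))) {
    alpha <- 0.5 / (s$K - s$M + 1)
    expect_equal(ranking_prob(1, 1, s)$prob, power_any(alpha, s),
                 tolerance = 1e-12)
  }
})

test_that("plug-in ranking probabilities track the exact order-statistic integral", {
  # the approximation's error is small even at a few hundred tests
  # (documented accuracy: a few percent at K as small as 10)
  s <- study_spec(200, 5, effect_point(6))
  for (t in 1:3) for (u in c(1, 5, 10, 20)) {
    if (t > u) next  # degenerate: both exactly zero
    expect_equal(ranking_prob(t, u, s)$prob, exact_ranking_prob(t, u, s),
                 tolerance = 0.03)
  }
})

test_that("expected yield sums the tail probabilities and respects bounds", {
  s <- study_spec(500, 20, effect_point(6))
  et <- expected_true_in_top(10, s)
  expect_equal(et, sum(vapply(1:10, function(t)
    ranking_prob(t, 10, s)$prob, numeric(1))))
  expect_lte(et, 10)
  ets <- vapply(c(1, 5, 10, 50, 200), expected_true_in_top, numeric(1),
                study = s)
  expect_true(all(diff(ets) >= 0))
  expect_equal(expected_true_in_top(10, study_spec(100, 0)), 0)
})

test_that("expected yield agrees with the Monte Carlo mean count", {
  s <- study_spec(2000, 20, effect_point(8))
  cnt <- simulate_top_counts(s, 20, 2000, seed = 8)
  se <- sd(cnt) / sqrt(2000)
  expect_lt(abs(mean(cnt) - expected_true_in_top(20, s)), 3 * se)
})

test_that("rFDR complements the expected true-discovery proportion", {
  s <- study_spec(500, 20, effect_point(6))
  expect_equal(rfdr_expected(10, s) + true_discovery_proportion(10, s), 1)
  expect_equal(rfdr_expected(10, study_spec(500, 0)), 1)
})

test_that("posterior null probability follows the two-group Bayes formula", {
  # an alternative indistinguishable from the null: g = 1, posterior = pi0
  s <- study_spec(1000, 100, effect_point(0))
  expect_equal(posterior_null(c(0.01, 0.5), s), rep(0.9 / (0.9 + 0.1), 2))
  expect_equal(posterior_null(0.3, study_spec(100, 0)), 1)
  s5 <- study_spec(1000, 100, effect_point(5))
  expect_error(posterior_null(0, s5), "\\(0, 1\\)")
  # small P-values carry more evidence against the null
  expect_true(all(diff(posterior_null(c(1e-6, 1e-3, 0.05), s5)) > 0))
})

test_that("study-specific rFDR averages posteriors over the top hits", {
  s <- study_spec(1000, 10, effect_point(8))
  pv <- sort(sample_pvalues(effect_point(0), 1000, seed = 5))
  pv[1] <- 1e-9
  expect_equal(rfdr_study(pv, 1, s), posterior_null(pv[1], s))
  expect_warning(r_unsorted <- rfdr_study(rev(pv), 5, s), "sort")
  expect_equal(r_unsorted, rfdr_study(pv, 5, s))
  expect_true(rfdr_study(pv, 10, s) >= 0 && rfdr_study(pv, 10, s) <= 1)
})

test_that("mean study-specific rFDR converges to the expected rFDR", {
  s <- study_spec(500, 10, effect_point(6))
  set.seed(6)
  vals <- replicate(300, {
    ex <- simulate_experiment(s)
    rfdr_study(ex$pvalues, 10, s)
  })
  se <- sd(vals) / sqrt(300)
  # Eq-16-vs-17-type slack: the analytic form fixes M, the posterior
  # treats signals as exchangeable
  expect_lt(abs(mean(vals) - rfdr_expected(10, s)), 3 * se + 0.02)
})

test_that("power relations reduce to the marginal CDF", {
  expect_equal(power_at_level(0.05, 0), 0.05)
  grid_a <- c(1e-8, 1e-6, 1e-4, 0.01)
  expect_true(all(diff(power_at_level(grid_a, 7.8)) > 0))
  expect_true(all(diff(vapply(c(1, 5, 10, 20),
    function(l) power_at_level(1e-4, l), numeric(1))) > 0))
  s1 <- study_spec(100, 1, effect_point(5))
  expect_equal(power_any(1e-3, s1), marginal_cdf(1e-3, s1$effect))
})

test_that("power to detect at least one of two signals matches simulation", {
  s2 <- study_spec(100, 2, effect_point(5))
  alpha <- 0.01
  set.seed(7)
  pm <- matrix(sample_pvalues(effect_point(5), 2e5), ncol = 2)
  emp <- mean(pm[, 1] <= alpha | pm[, 2] <= alpha)
  se <- sqrt(emp * (1 - emp) / 1e5)
  expect_lt(abs(power_any(alpha, s2) - emp), 3 * se)
})

test_that("a uniform 'true' signal beats a single null with probability 1/2", {
  s <- study_spec(2, 1, effect_point(0))
  expect_equal(prob_true_beats_null_rank(1, s), 0.5, tolerance = 1e-8)
})

test_that("one-vs-one comparison equals one minus the expected true P-value", {
  s <- study_spec(2, 1, effect_point(5))
  p <- sample_pvalues(effect_point(5), 2e5, seed = 8)
  se <- sd(p) / sqrt(2e5)
  expect_lt(abs(prob_true_beats_null_rank(1, s) - (1 - mean(p))), 3 * se)
})

test_that("beating the r-th smallest null matches direct simulation", {
  s <- study_spec(101, 1, effect_point(5))
  set.seed(9)
  reps <- 2e4
  p_true <- sample_pvalues(effect_point(5), reps)
  nulls <- matrix(runif(reps * 100), nrow = reps)
  third <- apply(nulls, 1, function(x) sort(x, partial = 3)[3])
  emp <- mean(p_true < third)
  se <- sqrt(emp * (1 - emp) / reps)
  expect_lt(abs(prob_true_beats_null_rank(3, s) - emp), 3 * se)
  expect_error(prob_true_beats_null_rank(101, s), "K - M")
})
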