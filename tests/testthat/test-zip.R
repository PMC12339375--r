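# Zero-inflated Poisson inference: histogram, lambda, ANI, bootstrap,
# coverage and error-term estimation.

p31 <- sketch_params()

test_that("build_histogram tallies multiplicities and checks params", {
  p <- sketch_params(k = 5, c = 1)
  gh <- c(10, 20, 30, 40, 50)
  # sample multiplicities for the genome k-mers: (0, 1, 1, 2, 0)
  sh <- c(20, 30, 40, 99)
  sc <- c(1, 1, 2, 7)
  g <- make_genome_sketch(gh, p)
  s <- make_sample_sketch(sh, sc, p)
  h <- build_histogram(g, s)
  expect_equal(h$n_sketch_kmers, 5L)
  expect_equal(h$n_contained, 3L)
  expect_equal(as.integer(h$counts), c(2L, 1L))
  expect_equal(names(h$counts), c("1", "2"))
  expect_equal(h$mode_a, 1L)
  expect_equal(h$median_nonzero, 1)

  # full containment at multiplicity 1 / disjoint sketches
  s_full <- make_sample_sketch(gh, rep(1, 5), p)
  h_full <- build_histogram(g, s_full)
  expect_equal(h_full$n_contained, 5L)
  expect_equal(as.integer(h_full$counts), 5L)
  h_dis <- build_histogram(g, make_sample_sketch(c(1, 2), c(1, 1), p))
  expect_equal(h_dis$n_contained, 0L)
  expect_length(h_dis$counts, 0L)

  # parameter mismatch names the offending field
  s_bad <- make_sample_sketch(sh, sc, sketch_params(k = 7, c = 1))
  expect_error(build_histogram(g, s_bad), "mismatch: k")
  s_bad2 <- make_sample_sketch(sh, sc, sketch_params(k = 5, c = 2))
  expect_error(build_histogram(g, s_bad2), "mismatch: c")
})

test_that("naive ANI is the k-th root of containment", {
  expect_equal(naive_ani(make_hist(100, c(`1` = 100)), 31), 1.0)
  expect_equal(naive_ani(make_hist(100, integer(0)), 31), 0)
  # containment 0.96^31 recovers ANI 0.96 (up to integer rounding of counts)
  N <- 1e6
  h <- make_hist(N, c(`1` = round(N * 0.96^31)))
  expect_equal(naive_ani(h, 31), 0.96, tolerance = 1e-6)
  expect_error(naive_ani(make_hist(0, integer(0)), 31), "no k-mers")
})

test_that("ratio-of-multiplicity estimator follows the count filters", {
  expect_equal(estimate_lambda(make_hist(1000, c(`1` = 100, `2` = 50))), 1.0)
  expect_true(is.na(estimate_lambda(make_hist(1000, c(`1` = 100, `2` = 2)))))
  expect_true(is.na(estimate_lambda(make_hist(1000, c(`1` = 2, `2` = 100)))))
  expect_true(is.na(estimate_lambda(make_hist(1000, integer(0)))))
  # mode ties break to the smallest multiplicity
  h_tie <- make_hist(1000, c(`1` = 50, `2` = 50, `3` = 10))
  expect_equal(h_tie$mode_a, 1L)
  expect_equal(estimate_lambda(h_tie), (50 / 50) * 2)
})

test_that("lambda estimator is consistent on i.i.d. ZIP draws", {
  set.seed(101)
  x <- rzip(1e5, 0.9, 1.5)
  h <- sketchani:::new_histogram(length(x), x[x > 0])
  lam <- estimate_lambda(h)
  expect_lt(abs(lam - 1.5) / 1.5, 0.02)
})

test_that("estimator tracks the ML oracle across the parameter grid", {
  # At N = 1e5 the sampling SD of the ratio estimator alone exceeds 2%
  # relative at lambda = 0.2 (N_{a+1} ~ 500), so the lambda agreement bound
  # is 6%; the quantity that matters downstream, the ANI, agrees with the
  # ML fit to well under half a point everywhere on the grid.
  set.seed(202)
  for (lam in c(0.2, 1, 3)) {
    for (tau in c(0.96, 1.0)) {
      x <- rzip(1e5, tau^31, lam)
      h <- sketchani:::new_histogram(length(x), x[x > 0])
      lam_hat <- estimate_lambda(h)
      tau_hat <- adjusted_ani(h, lam_hat, 31)
      ml <- oracle_zip_ml(x)
      expect_lt(abs(lam_hat - ml$lambda) / ml$lambda, 0.06)
      expect_lt(abs(tau_hat - min(1, ml$pi1^(1 / 31))), 0.003)
    }
  }
})

test_that("adjusted ANI applies the coverage correction exactly", {
  # containment 0.5 with lambda = ln 2: correction cancels -> ANI 1
  h <- make_hist(1000, c(`1` = 500))
  expect_equal(adjusted_ani(h, log(2), 31), 1.0)
  # large lambda: adjustment converges to the naive value
  expect_equal(adjusted_ani(h, 50, 31), naive_ani(h, 31), tolerance = 1e-9)
  # containment 0.6 with lambda 0.5 overshoots 1 and clamps
  h6 <- make_hist(1000, c(`1` = 600))
  expect_identical(adjusted_ani(h6, 0.5, 31), 1)
  # independent arithmetic evaluation at containment 0.3, lambda 0.5
  h3 <- make_hist(1000, c(`1` = 300))
  expected <- exp((log(0.3) - log(1 - exp(-0.5))) / 31)
  expect_equal(adjusted_ani(h3, 0.5, 31), expected, tolerance = 1e-12)
  expect_error(adjusted_ani(h6, 0, 31), "positive")
  expect_error(adjusted_ani(h6, -1, 31), "positive")
})

test_that("adjustment invariants hold across random histograms", {
  set.seed(303)
  for (i in 1:25) {
    N <- sample(200:2000, 1)
    lam <- runif(1, 0.1, 2.5)
    x <- rzip(N, runif(1, 0.3, 1), lam)
    h <- sketchani:::new_histogram(N, x[x > 0])
    lam_hat <- estimate_lambda(h)
    if (is.na(lam_hat) || lam_hat <= 0) next
    adj <- adjusted_ani(h, lam_hat, 31)
    expect_gte(adj, naive_ani(h, 31))   # division by (1 - e^-lam) <= 1
    expect_lte(adj, 1)
    # monotone non-increasing in lambda for fixed containment
    expect_lte(adjusted_ani(h, lam_hat * 1.5, 31), adj)
  }
})

test_that("bootstrap CI is deterministic, shrinks with N, can be absent", {
  h_small <- make_hist(500, c(`1` = 100, `2` = 25))
  h_large <- make_hist(10000, c(`1` = 2000, `2` = 500))
  ci1 <- bootstrap_ci(h_small, 31, seed = 7)
  ci2 <- bootstrap_ci(h_small, 31, seed = 7)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(h_small, 31, seed = 8)
  expect_false(identical(ci1, ci3))
  ci_big <- bootstrap_ci(h_large, 31, seed = 7)
  expect_lt(diff(ci_big), diff(ci1))
  expect_lte(ci1[1], ci1[2])
  expect_null(bootstrap_ci(make_hist(100, integer(0)), 31, seed = 1))
})

test_that("effective coverage picks the documented branch", {
  pol <- coverage_policy()
  # deep sample: median branch
  expect_equal(effective_coverage(make_hist(100, c(`20` = 100)), NA, pol), 20)
  # m <= 3 with lambda available
  h2 <- make_hist(1000, c(`1` = 100, `2` = 300, `3` = 100))
  expect_equal(effective_coverage(h2, 1.8, pol), 1.8)
  # m <= 3, lambda absent: falls back to the nonzero median
  expect_equal(effective_coverage(h2, NA, pol), 2)
  expect_error(effective_coverage(make_hist(100, integer(0)), NA, pol),
               "empty")
})

test_that("robust mean excludes outliers above the Poisson tail cutoff", {
  pol <- coverage_policy()
  # independent alpha oracle: direct cumulative summation of the Poisson pmf
  m <- 5
  pmf_sum <- 0; a <- 0
  repeat {
    pmf_sum <- pmf_sum + exp(-m) * m^a / factorial(a)
    if (1 - pmf_sum < pol$tail_prob) break
    a <- a + 1
  }
  alpha_oracle <- a
  expect_equal(sketchani:::poisson_tail_cutoff(5, pol$tail_prob),
               alpha_oracle)
  # histogram with median 5 and a huge outlier at 500 (mobile-element-like)
  h <- make_hist(1300, c(`4` = 300, `5` = 500, `6` = 300, `500` = 10))
  expect_equal(h$median_nonzero, 5)
  eff <- effective_coverage(h, NA, pol)
  expect_equal(eff, (4 * 300 + 5 * 500 + 6 * 300) / 1100)
  expect_lt(eff, 10)  # outlier did not drag the mean
})

test_that("error term: user epsilon, auto formula and fallback", {
  p <- sketch_params(k = 31, c = 1)
  s <- make_sample_sketch(1:10, rep(1, 10), p)
  em0 <- estimate_error_term(s, user_epsilon = 0)
  expect_equal(em0$E, 1)
  em <- estimate_error_term(s, user_epsilon = 0.005)
  expect_equal(em$E, (1 - 0.005)^31)
  # auto: n_1 = 100, n_2 = 450 -> denominator 900 -> E = 1 - 100/900
  s2 <- make_sample_sketch(seq_len(550), c(rep(1, 100), rep(2, 450)), p)
  em2 <- estimate_error_term(s2)
  expect_equal(em2$E, 1 - 100 / 900)
  expect_equal(em2$source, "auto")
  # degenerate: all singletons -> warning and E = 1
  expect_warning(em3 <- estimate_error_term(s), "E = 1|error")
  expect_equal(em3$E, 1)
})

test_that("auto error estimate recovers (1-eps)^k from deep simulated reads", {
  p <- sketch_params(k = 31, c = 20)
  g <- random_genome(2e5, seed = 44)
  rr <- sample_reads(g, 20, L = 150, epsilon = 0.005, seed = 45)
  ss <- sketch_reads(rr$reads1, params = p, dedup = FALSE)
  em <- estimate_error_term(ss)
  target <- (1 - 0.005)^31
  expect_lt(abs(em$E - target) / target, 0.10)
})

test_that("true coverage inverts the effective-coverage relation", {
  expect_equal(true_coverage(8, 150, 31, E = 1), 8 * 150 / 120)
  expect_equal(true_coverage(3, 1e6, 31, E = 1), 3, tolerance = 1e-4)
  expected <- (100 / 70) / (0.99^31)
  expect_equal(true_coverage(1, 100, 31, E = 0.99^31), expected,
               tolerance = 1e-12)
  expect_error(true_coverage(1, 31, 31), "exceed")
  expect_error(true_coverage(1, 20, 31), "exceed")
})

test_that("estimate_ani orchestration: saturation, refusal, adjustment", {
  p <- sketch_params(k = 31, c = 1)
  # saturated coverage: every k-mer at multiplicity 8 -> no adjustment
  gh <- seq_len(200)
  g <- make_genome_sketch(gh, p)
  s <- make_sample_sketch(gh, rep(8, 200), p, total_bases = 1e5)
  est <- estimate_ani(g, s, error_model = estimate_error_term(s, 0))
  expect_equal(est$naive_ani, 1)
  expect_equal(est$adjusted_ani, 1)
  expect_false(est$adjustment_applied)
  expect_equal(est$effective_coverage, 8)
  # too few sketch k-mers: refused
  g40 <- make_genome_sketch(seq_len(40), p)
  expect_message(expect_null(
    estimate_ani(g40, s, error_model = estimate_error_term(s, 0))),
    "skipping")
})

test_that("coverage adjustment debiases a low-coverage 100%-ANI genome", {
  p <- sketch_params()
  g <- random_genome(1e6, seed = 55)
  gs <- sketch_genome(g, p)
  em <- NULL
  adj <- naive <- numeric(20)
  for (r in 1:20) {
    rr <- sample_reads(g, delta_for_lambda(0.2, 150, 31), L = 150,
                       seed = 600 + r)
    ss <- sketch_reads(rr$reads1, params = p, dedup = FALSE)
    if (is.null(em)) em <- estimate_error_term(ss, user_epsilon = 0)
    est <- estimate_ani(gs, ss, error_model = em, seed = r)
    adj[r] <- est$adjusted_ani
    naive[r] <- est$naive_ani
  }
  expect_lt(abs(median(adj) - 1) * 100, 0.5)  # within 0.5 points of 100
  expect_lt(median(naive), 0.995)             # naive clearly biased down
})
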