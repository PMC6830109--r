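test_that("hypergeometric pmf matches hand-enumerated values", {
  # M=10, N=4, n=5, k=3: 60/252 distinguishable placements
  expect_equal(hypergeom_pmf(3, M = 10, n = 5, N = 4), 60 / 252,
               tolerance = 1e-14)
  # certainty when the sample is the universe
  expect_equal(hypergeom_pmf(4, M = 4, n = 4, N = 4), 1)
  # normalisation
  expect_equal(sum(hypergeom_pmf(0:5, M = 12, n = 6, N = 5)), 1,
               tolerance = 1e-12)
  # outside the support
  expect_equal(hypergeom_pmf(7, M = 10, n = 5, N = 4), 0)
})

test_that("over/under tails follow the strictly-greater / from-one sums", {
  r <- over_under_test(k = 3, M = 10, n = 5, N = 4)
  expect_equal(r$p_over, 6 / 252, tolerance = 1e-12)
  expect_equal(r$p_under, 240 / 252, tolerance = 1e-12)
  expect_equal(r$expected, 2)
  # complementarity: p_over + p_under + pmf(0) = 1
  for (k in 0:4) {
    rr <- over_under_test(k, M = 10, n = 5, N = 4)
    expect_equal(rr$p_over + rr$p_under +
                   hypergeom_pmf(0, M = 10, n = 5, N = 4), 1,
                 tolerance = 1e-12)
  }
  expect_output(print(r), "Hypergeometric")
})

test_that("tails equal the exhaustive enumeration oracle for small universes", {
  for (M in c(5L, 8L, 12L)) {
    for (N in 0:M) {
      for (n in c(1L, M %/% 2L, M)) {
        oracle <- enumerate_hypergeom(M, n, N)
        for (k in 0:min(n, N)) {
          r <- over_under_test(k, M = M, n = n, N = N)
          expect_equal(r$p_over, oracle$p_over(k), tolerance = 1e-12,
                       info = sprintf("M=%d N=%d n=%d k=%d", M, N, n, k))
          expect_equal(r$p_under, oracle$p_under(k), tolerance = 1e-12,
                       info = sprintf("M=%d N=%d n=%d k=%d", M, N, n, k))
        }
      }
    }
  }
})

test_that("p_over is non-increasing in k at fixed (M, N, n)", {
  p <- vapply(0:20, function(k) over_under_test(k, 100, 30, 20)$p_over,
              numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("expected counts are proportional", {
  expect_equal(expected_count(M = 100, n = 10, N = 30), 3)
  expect_equal(expected_count(M = 24070, n = 1204, N = 1479), 73.98,
               tolerance = 1e-4)
  expect_equal(expected_count(M = 50, n = 10, N = 0), 0)
})

test_that("term enrichment: contained term, empty term, EASE discount", {
  universe <- sprintf("g%02d", 1:10)
  selected <- universe[1:3]
  terms <- list(hit = universe[1:3],     # fully inside the selection
                none = universe[8:10],   # disjoint
                half = universe[2:5])
  te <- term_enrichment(selected, universe, terms)
  # all three members selected out of C(10,3) samples
  expect_equal(te$p_value[te$term == "hit"], 1 / 120, tolerance = 1e-12)
  expect_equal(te$p_value[te$term == "none"], 1)
  expect_equal(te$k[te$term == "none"], 0L)
  # EASE: evaluated at k - 1, never smaller than standard
  ease <- term_enrichment(selected, universe, terms, variant = "ease")
  expect_true(all(ease$p_value >= te$p_value))
  # EASE with k = 1 gives p = 1
  te1 <- term_enrichment(selected, universe, list(single = universe[3]),
                         variant = "ease")
  expect_equal(te1$p_value, 1)
  expect_error(term_enrichment(c("zz", selected), universe, terms),
               "subset")
  # BH-adjusted column present and >= raw p
  expect_true(all(te$fdr >= te$p_value - 1e-15))
})

test_that("the empirical call rate matches the exact rejection probability", {
  # The strictly-greater overrepresentation tail rejects at the smallest
  # k with P(X > k) < alpha, so its exact size is P(X >= k*) -- always
  # at or slightly above alpha for a discrete statistic.  The Monte-
  # Carlo call rate must match that exact size, and the empirical tails
  # must match the analytic ones.
  M <- 400; N <- 40; n <- 50; reps <- 4000
  k <- simulate_null_universe(M = M, N = N, n = n, reps = reps, seed = 99)
  p_over <- vapply(0:min(n, N),
                   function(kk) over_under_test(kk, M, n, N)$p_over,
                   numeric(1))
  rate <- mean(p_over[k + 1] < 0.05)
  kstar <- min(which(p_over < 0.05)) - 1L
  exact_size <- over_under_test(kstar - 1L, M, n, N)$p_over  # P(X >= k*)
  mc_se <- sqrt(exact_size * (1 - exact_size) / reps)
  expect_lt(abs(rate - exact_size), 3 * mc_se)
})

test_that("mcc covers agreement, disagreement and degenerate margins", {
  expect_equal(mcc(5, 0, 0, 5), 1)
  expect_equal(mcc(0, 5, 5, 0), -1)
  expect_equal(mcc(3, 4, 1, 7), 17 / sqrt(2464), tolerance = 1e-12)
  expect_equal(mcc(0, 0, 3, 7), 0)   # zero marginal -> defined as 0
  # matrix input
  expect_equal(mcc(matrix(c(3, 1, 4, 7), 2)), mcc(3, 4, 1, 7))
})

test_that("classification concordance builds the 2x2 table over shared extremes", {
  l1 <- c(a = "enriched", b = "enriched", c = "deficient",
          d = "deficient", e = "intermediate")
  l2 <- c(a = "enriched", b = "deficient", c = "deficient",
          d = "enriched", e = "enriched")
  out <- classification_concordance(l1, l2)
  expect_equal(unname(out$table), c(1, 1, 1, 1))
  expect_equal(out$mcc, 0)
  expect_equal(out$n_shared, 4)
})
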