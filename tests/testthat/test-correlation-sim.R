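test_that("Weber population constructor validates and prints its model", {
  d <- weber_distribution(0.17, 0.07)
  expect_s3_class(d, "weber_distribution")
  expect_equal(d$floor, 0.01)
  expect_error(weber_distribution(-1, 0.1), class = "anslope_invalid_parameter")
  expect_error(weber_distribution(0.05, 0.001, floor = 0.2),
               class = "anslope_infeasible_truncation")
})

test_that("population intervals and normal coverage are the closed forms", {
  expect_equal(population_interval(typical_weber_population("adult")),
               c(0.03, 0.31))
  expect_equal(population_interval(typical_weber_population("adolescent")),
               c(0.087, 0.471))
  expect_equal(round(normal_coverage(2), 1), 95.4)
})

test_that("sample_weber draws from the truncated normal population", {
  d <- typical_weber_population("adult")
  set.seed(42)
  x <- sample_weber(d, 5000)
  expect_length(x, 5000)
  expect_true(all(x >= d$floor))
  # sample mean within 4 standard errors of the (slightly truncation-shifted) mean
  expect_lt(abs(mean(x) - d$mean), 4 * d$sd / sqrt(5000) + 0.002)

  # vanishing sd: all draws collapse to the mean
  set.seed(1)
  y <- sample_weber(weber_distribution(0.2, 1e-9), 10)
  expect_true(all(abs(y - 0.2) < 1e-6))

  # heavy truncation raises the mean relative to the untruncated draw
  dtr <- weber_distribution(0.05, 0.07, floor = 0.001)
  set.seed(7); m_tr <- mean(sample_weber(dtr, 20000))
  set.seed(7); m_free <- mean(rnorm(20000, 0.05, 0.07))
  expect_gt(m_tr, m_free)
})

test_that("correlation simulation is seed-deterministic and extendable", {
  d <- typical_weber_population("adult")
  p <- ratio_pair(1.25, 2)
  a <- simulate_correlations(d, p, 20, 50, seed = 9)
  b <- simulate_correlations(d, p, 20, 50, seed = 9)
  expect_identical(a$r_values, b$r_values)
  expect_true(all(a$r_values >= -1 & a$r_values <= 1))
  # growing the replication count extends, not reshuffles, the sequence
  c200 <- simulate_correlations(d, p, 20, 200, seed = 9)
  expect_identical(c200$r_values[1:50], a$r_values)
})

test_that("correlation attenuation: adult population beats adolescent for 1.25-2", {
  p <- ratio_pair(1.25, 2)
  ad <- simulate_correlations(typical_weber_population("adult"), p,
                              n_replications = 300, seed = 21)
  ao <- simulate_correlations(typical_weber_population("adolescent"), p,
                              n_replications = 300, seed = 22)
  expect_gt(mean(abs(ad$r_values)), mean(abs(ao$r_values)))
  expect_gt(ad$summary$mean, 0.6)
  expect_lt(abs(ao$summary$mean), 0.2)
})

test_that("a strictly linear effect gives perfect correlation every replication", {
  d <- typical_weber_population("adult")
  cd <- simulate_correlations(d, ratio_pair(1.25, 2), 20, 30, seed = 3,
                              effect_fun = function(w) 2 * w + 0.1)
  expect_equal(cd$r_values, rep(1, 30), tolerance = 1e-12)
  neg <- simulate_correlations(d, ratio_pair(1.25, 2), 20, 10, seed = 3,
                               effect_fun = function(w) -w)
  expect_equal(neg$r_values, rep(-1, 10), tolerance = 1e-12)
})

test_that("zero-variance replications are dropped and counted, not recorded", {
  d <- weber_distribution(0.2, 1e-12)
  cd <- simulate_correlations(d, ratio_pair(1.25, 2), 10, 20, seed = 4)
  expect_equal(cd$n_dropped, 20L)
  expect_length(cd$r_values, 0)
})

test_that("the standard design grid produces all six cells", {
  g <- correlation_grid(n_replications = 20, seed = 2)
  expect_length(g$cells, 6)
  expect_equal(nrow(g$summary), 6L)
  expect_setequal(unique(g$summary$ratio_pair), c("1.125-2", "1.25-2", "2-5"))
  expect_setequal(unique(g$summary$group), c("adult", "adolescent"))
  # 2-5 sits on the rising limb for adults: positive mean r
  expect_gt(g$summary$mean_r[g$summary$group == "adult" &
                             g$summary$ratio_pair == "2-5"], 0)
})
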