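test_that("ratio_effect matches frozen oracle differences and rejects bad pairs", {
  # frozen values from the Riemann-grid oracle
  expect_equal(ratio_effect(ratio_pair(1.25, 5.0), 0.4), 0.6963171, tolerance = 1e-6)
  expect_equal(ratio_effect(ratio_pair(1.25, 5.0), 0.04), 0.00543586, tolerance = 1e-5)
  expect_error(ratio_pair(2, 2), class = "anslope_invalid_pair")
  expect_error(ratio_pair(3, 2), class = "anslope_invalid_pair")
  # continuity: effect vanishes as the two ratios meet
  expect_lt(ratio_effect(ratio_pair(2, 2 + 1e-7), 0.3), 1e-5)
})

test_that("ratio_effect is non-negative and bounded on the lattice", {
  for (w in lattice_webers) {
    eff <- ratio_effect(ratio_pair(1.125, 4), w)
    expect_true(eff >= 0 && eff <= 1)
  }
})

test_that("two-point linear slope obeys the sign/scale identity with ratio_effect", {
  for (w in c(0.04, 0.2, 0.4, 1)) {
    for (p in list(c(1.25, 5), c(1.125, 1.4), c(4, 9))) {
      expect_equal(
        linear_slope(p, w),
        -ratio_effect(ratio_pair(p[1], p[2]), w) / (p[2] - p[1]),
        tolerance = 1e-10,
        label = sprintf("pair %g-%g at w=%g", p[1], p[2], w)
      )
    }
  }
})

test_that("multi-ratio linear slope equals the least-squares fit of overlap on ratio", {
  ratios <- c(1.125, 1.4, 2.0, 4.0)
  for (w in c(0.1, 0.2, 0.5)) {
    o <- overlap(ratios, w)
    expect_equal(linear_slope(ratios, w),
                 unname(coef(lm(o ~ ratios))[2]), tolerance = 1e-10)
  }
  # equal overlaps at both ratios give a zero slope
  expect_equal(linear_slope(c(20, 40), 0.01), 0, tolerance = 1e-12)
  expect_error(linear_slope(c(2, 2), 0.1), class = "anslope_invalid_input")
})

test_that("slope curve evaluates element-wise and validates its grid", {
  g <- seq(0.04, 1, by = 0.01)
  sc <- slope_curve(ratio_pair(1.25, 5), g)
  expect_equal(nrow(sc), length(g))
  expect_equal(sc$ratio_effect, ratio_effect(ratio_pair(1.25, 5), g))
  sc1 <- slope_curve(ratio_pair(1.25, 5), 0.2)
  expect_equal(nrow(sc1), 1L)
  expect_equal(sc1$ratio_effect, ratio_effect(ratio_pair(1.25, 5), 0.2))
  expect_error(slope_curve(ratio_pair(1.25, 5), c(0.3, 0.2)),
               class = "anslope_invalid_parameter")
})

test_that("the 1.25-5 effect curve rises then falls over the scan range", {
  sc <- slope_curve(ratio_pair(1.25, 5), seq(0.04, 1, by = 0.01))
  peak <- which.max(sc$ratio_effect)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(sc))
  expect_gt(sc$ratio_effect[peak], sc$ratio_effect[1])
  expect_gt(sc$ratio_effect[peak], sc$ratio_effect[nrow(sc)])
})

test_that("the 4-9 effect curve is predominantly increasing over the scan range", {
  sc <- slope_curve(ratio_pair(4, 9), seq(0.04, 1, by = 0.01))
  expect_gt(mean(diff(sc$ratio_effect) > 0), 0.9)
})

test_that("expected range over an interval matches the frozen oracle value", {
  sr <- expected_range(ratio_pair(1.25, 5), 0.1, 0.4)
  # frozen from the grid oracle at w step 1e-3: effects span ~[0.264, 0.697]
  expect_equal(sr$min_effect, 0.2641496, tolerance = 1e-5)
  expect_equal(sr$max_effect, 0.6970464, tolerance = 1e-5)
  expect_equal(sr$range, 0.4328968, tolerance = 1e-5)
  expect_equal(sr$range, sr$max_effect - sr$min_effect)
  expect_true(sr$range >= 0 && sr$range <= 1)
  # degenerate interval
  expect_equal(expected_range(ratio_pair(1.25, 5), 0.2, 0.2)$range, 0)
  expect_error(expected_range(ratio_pair(1.25, 5), 0.4, 0.1),
               class = "anslope_invalid_interval")
})

test_that("expected range stays within [0, 1] across pairs and intervals", {
  for (p in reference_ratio_pairs()) {
    for (iv in list(c(0.03, 0.31), c(0.087, 0.471), c(0.04, 1))) {
      sr <- expected_range(p, iv[1], iv[2], grid_step = 5e-3)
      expect_true(sr$range >= 0 && sr$range <= 1)
      expect_true(sr$min_effect >= 0 && sr$max_effect <= 1)
    }
  }
})

test_that("direction classification labels the reference pairs stably", {
  labels <- vapply(reference_ratio_pairs(), function(p) {
    classify_direction(p, 0.04, 1)$label
  }, character(1))
  expect_equal(unname(labels["1.125-1.4"]), "negative")
  expect_equal(unname(labels["4-9"]), "positive")
  expect_equal(unname(labels["1.125-4"]), "mixed")
  # the remaining pairs have a stable documented label under defaults
  expect_equal(unname(labels["1.125-2"]), "negative")
  expect_equal(unname(labels["1.5-5"]), "mixed")
  expect_equal(unname(labels["2-5"]), "mixed")
})

test_that("direction thresholds are honoured and degenerate intervals rejected", {
  d <- classify_direction(ratio_pair(1.125, 4), 0.04, 1)
  expect_true(d$fraction_negative_steps > 0.2 && d$fraction_negative_steps < 0.8)
  # with a permissive negative threshold the same curve classifies negative
  d2 <- classify_direction(ratio_pair(1.125, 4), 0.04, 1, neg_threshold = 0.5)
  expect_equal(d2$label, "negative")
  expect_error(classify_direction(ratio_pair(1.25, 5), 0.2, 0.2),
               class = "anslope_invalid_interval")
})

test_that("slope range table covers every pair-interval combination", {
  tab <- slope_range_table(intervals = list(c(0.1, 0.4), c(0.04, 1)),
                           grid_step = 5e-3)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$range >= 0 & tab$range <= 1))
  row <- tab[tab$ratio_pair == "1.25-5" & tab$w_lo == 0.1, ]
  expect_equal(nrow(row), 0L)  # 1.25-5 is not a reference pair
  expect_setequal(unique(tab$ratio_pair), names(reference_ratio_pairs()))
})
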