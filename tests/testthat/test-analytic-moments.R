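det_half <- partition_law(0.5, 0)
adder <- single_step_params(1, 1, 1)

test_that("adder moments reproduce the deterministic-halving constants", {
  ms <- adder_moments(adder, det_half, max_order = 3)
  expect_equal(ms$cv2, log(4) - 1, tolerance = 1e-12)
  # mean = -mu/(k <log beta>) = 1/log 2; second moment follows the recursion
  expect_equal(ms$mean_size, 1 / log(2), tolerance = 1e-12)
  expect_equal(ms$second_moment, ms$mean_size / (1 - 0.5),
               tolerance = 1e-12)
  expect_true(ms$exact)
  expect_equal(ms$second_moment / ms$mean_size^2 - 1, ms$cv2,
               tolerance = 1e-12)
  expect_error(adder_moments(single_step_params(1, 1, 2), det_half),
               "alpha = 1")
})

test_that("adder noise and skewness are invariant under (mu, k) rescaling", {
  law <- partition_law(0.5, 0.07)
  a <- adder_moments(single_step_params(1, 1, 1), law)
  b <- adder_moments(single_step_params(10, 10, 1), law)
  expect_equal(a$cv2, b$cv2, tolerance = 1e-12)
  expect_equal(a$skewness, b$skewness, tolerance = 1e-12)
  # mean scales as mu/k
  d <- adder_moments(single_step_params(3, 1, 1), law)
  expect_equal(d$mean_size, 3 * a$mean_size, tolerance = 1e-12)
})

test_that("closed product form equals the moment recursion up to order 6", {
  for (law in list(det_half, partition_law(0.5, 0.1),
                   partition_law(0.6, 0.2))) {
    ms <- adder_moments(single_step_params(1.3, 0.7, 1), law, max_order = 6)
    for (p in 1:6)
      expect_equal(
        cellsizer:::.adder_moment_closed(single_step_params(1.3, 0.7, 1),
                                         law, p),
        ms$moments[[p]], tolerance = 1e-10)
  }
})

test_that("small-noise adder noise approximation behaves as documented", {
  expect_equal(adder_cv2_approx(0), log(4) - 1)
  xs <- seq(0, 0.3, by = 0.05)
  expect_true(all(diff(adder_cv2_approx(xs)) > 0))
  # within 0.02 of the exact digamma value in the small-noise regime
  for (x in c(0.02, 0.05, 0.1)) {
    exact <- adder_moments(adder, partition_law(0.5, x))$cv2
    expect_lt(abs(adder_cv2_approx(x) - exact), 0.02)
  }
  expect_error(adder_cv2_approx(1), "cv2_beta >= 1")
  expect_error(adder_cv2_approx(partition_law(0.6, 0.1)), "symmetric")
})

test_that("steady-state skewness is ~1.68 and matches simulation under noise", {
  expect_equal(adder_skewness(det_half), 1.68, tolerance = 0.005)
  # roughly constant over small partitioning noise
  for (x in c(0.02, 0.05))
    expect_equal(adder_skewness(partition_law(0.5, x)), 1.68,
                 tolerance = 0.05)
  # simulator oracle at substantial noise
  sim <- simulate_lineage(sim_config(adder, partition_law(0.5, 0.2),
                                     n_cycles = 4e4, seed = 271828))
  est <- time_average_moments(sim)
  expect_lt(abs(est$skewness - adder_skewness(partition_law(0.5, 0.2))),
            3 * est$se$skewness)
})

test_that("newborn size noise has floor 1/3 and sensitivity 16/9", {
  expect_equal(newborn_cv2(0, 1), 1 / 3)
  for (M in c(2, 5, 10))
    expect_equal(newborn_cv2(0, 1 / M), 1 / (3 * M))
  # Erlang-added-size form at cv2_added = 1 equals the printed special case
  x <- 0.07
  expect_equal(newborn_cv2(x, 1), (1 + 5 * x) / (3 - x))
  # derivative in cv2_beta at 0 by central finite difference
  h <- 1e-6
  slope <- (newborn_cv2(h, 1) - newborn_cv2(-h, 1)) / (2 * h)
  expect_equal(slope, 16 / 9, tolerance = 1e-6)
  expect_error(newborn_cv2(3, 1), "cv2_beta >= 3")
})

test_that("exact noise slope in partitioning noise is 1 at zero", {
  h <- 1e-6
  f <- function(x) adder_moments(adder, partition_law(0.5, x))$cv2
  expect_equal((f(2 * h) - f(0)) / (2 * h), 1, tolerance = 1e-4)
})

test_that("y = s^alpha transform reduces to and extends the adder machinery", {
  expect_equal(powerlaw_y_moments(adder, det_half, 4)$moments,
               adder_moments(adder, det_half, 4)$moments,
               tolerance = 1e-12)
  # mean of y is independent of alpha
  for (a in c(0.5, 2, 3.7))
    expect_equal(
      powerlaw_y_moments(single_step_params(1, 1, a), det_half)$mean_size,
      -1 / log(0.5), tolerance = 1e-12)
  # order-6 moments match the closed product form evaluated independently
  a <- 3; mu <- 1.2; k <- 0.8
  law <- partition_law(0.5, 0.1)
  ym <- powerlaw_y_moments(single_step_params(mu, k, a), law, 6)$moments
  for (p in 1:5) {
    closed <- -(a * mu / k)^(p + 1) * factorial(p) /
      (a * mean_log_beta(law) *
         prod(1 - beta_power_moment(law, a * seq_len(p))))
    expect_equal(ym[[p + 1]], closed, tolerance = 1e-10)
  }
})

test_that("rational exponents alpha = 1/q give exact size moments", {
  expect_equal(powerlaw_exact_rational(adder, det_half)$cv2,
               adder_moments(adder, det_half)$cv2, tolerance = 1e-12)
  p3 <- single_step_params(1, 1, 1 / 3)
  ym <- powerlaw_y_moments(p3, det_half, 6)$moments
  ms <- powerlaw_exact_rational(p3, det_half)
  expect_equal(ms$mean_size, ym[[3]], tolerance = 1e-12)
  expect_equal(ms$second_moment, ym[[6]], tolerance = 1e-12)
  expect_error(powerlaw_exact_rational(single_step_params(1, 1, 0.7),
                                       det_half), "closure")
  # alpha = 1/2 against a lineage simulation
  ph <- single_step_params(1, 1, 0.5)
  sim <- simulate_lineage(sim_config(ph, det_half, n_cycles = 4e4,
                                     seed = 31415))
  est <- time_average_moments(sim, orders = 1:2)
  ex <- powerlaw_exact_rational(ph, det_half)
  expect_lt(abs(est$mean_size - ex$mean_size), 3 * est$se$mean_size)
  expect_lt(abs(est$cv2 - ex$cv2), 3 * est$se$cv2)
})

test_that("derivative-matching closure is exact at alpha 1 and decreasing in alpha", {
  expect_equal(powerlaw_closure(adder, det_half)$cv2,
               adder_moments(adder, det_half)$cv2, tolerance = 1e-12)
  expect_equal(powerlaw_closure(adder, det_half)$mean_size, 1 / log(2),
               tolerance = 1e-12)
  expect_true(powerlaw_closure(adder, det_half)$exact)
  c2 <- powerlaw_closure(single_step_params(1, 1, 2), det_half)
  expect_equal(c2$cv2, sqrt(log(4)) - 1, tolerance = 1e-12)
  expect_false(c2$exact)
  for (law in list(det_half, partition_law(0.5, 0.1))) {
    cv <- vapply(c(1, 2, 4, 8),
                 function(a) powerlaw_closure(single_step_params(1, 1, a),
                                              law)$cv2, numeric(1))
    expect_true(all(diff(cv) < 0))
  }
  expect_error(powerlaw_closure(single_step_params(1, 1, 0.5), det_half),
               "alpha >= 1")
})

test_that("multi-step recursion agrees with its closed forms and limits", {
  law <- partition_law(0.5, 0.02)
  # M = 1 recovers the single-step adder
  m1 <- multistep_moments(multi_step_params(1, 2), law)
  a1 <- adder_moments(single_step_params(1, 2, 1), law)
  expect_equal(m1$mean_size, a1$mean_size, tolerance = 1e-12)
  expect_equal(m1$second_moment, a1$second_moment, tolerance = 1e-12)
  # equal rates: recursion equals the closed form
  for (M in c(2, 5, 10))
    for (lw in list(det_half, law)) {
      r <- multistep_moments(equal_rate_params(1, 1, M), lw)
      cf <- multistep_equal_rates(1, 1, M, lw)
      expect_equal(r$mean_size, cf$mean_size, tolerance = 1e-12)
      expect_equal(r$cv2, cf$cv2, tolerance = 1e-12)
    }
  # all-but-first rates -> infinity reduces to the single-step second moment
  fast <- multistep_moments(multi_step_params(1, c(1, rep(1e6, 4))), law)
  expect_equal(fast$second_moment, a1$second_moment * 4,  # k = 1 vs k = 2
               tolerance = 1e-4)
})

test_that("unordered-pair double-sum cross-check matches the recursion", {
  # independent evaluation of the second moment as an explicit double sum
  eq_sum <- function(mu, ks, law) {
    Lb <- mean_log_beta(law); mb <- law$mean_beta
    mean_s <- -mu / Lb * sum(1 / ks)
    M <- length(ks)
    pair <- 0
    if (M > 1)
      for (i in 1:(M - 1)) for (j in (i + 1):M)
        pair <- pair + 1 / (ks[i] * ks[j])
    mu * mean_s / (1 - mb) * sum(1 / ks) + mu^2 / Lb * pair
  }
  for (ks in list(c(2), c(1, 3), c(0.5, 2, 7), rep(10, 5))) {
    law <- partition_law(0.45, 0.05)
    expect_equal(multistep_moments(multi_step_params(1.7, ks), law)$second_moment,
                 eq_sum(1.7, ks, law), tolerance = 1e-10)
  }
})

test_that("equal-rate noise decreases in M toward the closed-form floor", {
  expect_equal(multistep_equal_rates(1, 1, 1, det_half)$cv2, log(4) - 1,
               tolerance = 1e-12)
  expect_equal(multistep_equal_rates(1, 1, 10, det_half)$cv2,
               -1 + (15.5 / 20) * 2 * log(2), tolerance = 1e-12)
  expect_equal(multistep_cv2_limit(det_half), 1.5 * log(2) - 1,
               tolerance = 1e-12)
  # the finite-M excess is (1-<beta>) R / (2M) ~ 3.5e-7 at M = 1e6
  expect_lt(abs(multistep_equal_rates(1, 1, 1e6, det_half)$cv2 -
                  multistep_cv2_limit(det_half)), 1e-6)
  for (law in list(det_half, partition_law(0.5, 0.05))) {
    cv <- vapply(c(1, 2, 5, 20, 100),
                 function(M) multistep_equal_rates(1, 1, M, law)$cv2,
                 numeric(1))
    expect_true(all(diff(cv) < 0))
    expect_true(all(cv > multistep_cv2_limit(law)))
  }
  # small-noise limit form: 0.04 + 3 cv2_beta / 4
  lim <- multistep_cv2_limit(partition_law(0.5, 0.04))
  expect_lt(abs(lim - (1.5 * log(2) - 1 + 3 * 0.04 / 4)), 5e-3)
})

test_that("noise is positive and increasing in partitioning noise everywhere", {
  for (mb in c(0.4, 0.5, 0.6)) {
    cv <- vapply(c(0, 0.02, 0.05, 0.1), function(x)
      adder_moments(adder, partition_law(mb, x))$cv2, numeric(1))
    expect_true(all(cv > 0))
    expect_true(all(diff(cv) > 0))
  }
  expect_gt(multistep_cv2_limit(partition_law(0.7, 0.1)), 0)
})
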