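# Unequal-variance SDT core: LLR, rating simulation, zROC and type-2 ROC.

test_that("llr matches direct Gaussian log-density differences", {
  p_sym <- uvsdt_params(mu_low = -1, mu_high = 1)
  expect_equal(llr(0, p_sym), 0)

  p_uv <- uvsdt_params(mu_low = 0, sigma_low = 1, mu_high = 1, sigma_high = 2)
  oracle <- dnorm(0, 1, 2, log = TRUE) - dnorm(0, 0, 1, log = TRUE)
  expect_equal(llr(0, p_uv), oracle, tolerance = 1e-12)
  expect_equal(oracle, log(1 / 2) - 1 / 8)  # closed form for these params

  # even function when the class means coincide
  p_even <- uvsdt_params(mu_low = 0, sigma_low = 1, mu_high = 0, sigma_high = 2)
  x <- c(0.3, 1.7, 4.2)
  expect_equal(llr(x, p_even), llr(-x, p_even))

  expect_error(llr(NA_real_, p_sym), "finite")
  expect_error(llr(Inf, p_sym), "finite")
})

test_that("llr is linear in x exactly when the class variances are equal", {
  x <- c(-1, 0.5, 2)
  second_diff <- function(p) {
    v <- llr(sort(x), p)
    (v[3] - v[2]) / (sort(x)[3] - sort(x)[2]) -
      (v[2] - v[1]) / (sort(x)[2] - sort(x)[1])
  }
  expect_equal(second_diff(uvsdt_params(-0.7, 1.3, 0.9, 1.3)), 0,
               tolerance = 1e-12)
  expect_gt(abs(second_diff(uvsdt_params(0, 1, 1, 1.5))), 0.01)
})

test_that("simulate_ratings respects class totals, limits and the seed", {
  p <- uvsdt_params(mu_low = 0, mu_high = 1, sigma_high = 1.4)
  tab <- simulate_ratings(p, 500, seed = 3)
  expect_equal(unname(rowSums(tab)), c(500, 500))
  expect_identical(tab, simulate_ratings(p, 500, seed = 3))

  # 10-sigma separation: implied decisions essentially always correct
  p_far <- uvsdt_params(mu_low = 0, mu_high = 10)
  tf <- simulate_ratings(p_far, 2000, seed = 1)
  acc <- (sum(tf["low", 1:6]) + sum(tf["high", 7:12])) / 4000
  expect_gt(acc, 0.99)

  # identical classes, symmetric criteria: accuracy near chance
  p_null <- uvsdt_params(mu_low = 0, mu_high = 0,
                         criteria = seq(-2.5, 2.5, length.out = 11))
  tn <- simulate_ratings(p_null, 5000, seed = 2)
  acc0 <- (sum(tn["low", 1:6]) + sum(tn["high", 7:12])) / 10000
  expect_equal(acc0, 0.5, tolerance = 0.03)
})

test_that("zroc_slope converges to the sd ratio and inverts under label swap", {
  p <- uvsdt_params(mu_low = 0, sigma_low = 1, mu_high = 1,
                    sigma_high = 1 / 0.55)
  tab <- simulate_ratings(p, 1e5, seed = 7)
  expect_equal(zroc_slope(tab), 0.55, tolerance = 0.02)

  p_eq <- uvsdt_params(mu_low = 0, mu_high = 1)
  expect_equal(zroc_slope(simulate_ratings(p_eq, 1e5, seed = 8)), 1,
               tolerance = 0.02)

  # swapping class labels reverses the rating axis: slope -> 1/slope
  small <- simulate_ratings(p, 400, seed = 9)
  swapped <- small[2:1, 12:1]
  expect_equal(zroc_slope(swapped), 1 / zroc_slope(small), tolerance = 1e-10)

  degenerate <- matrix(0L, 2, 12, dimnames = list(c("low", "high"), NULL))
  degenerate[, 1] <- c(50L, 50L)
  expect_error(zroc_slope(degenerate), "degenerate")
})

test_that("zroc_slope recovers generating sd ratios across seeds", {
  for (ratio in c(0.55, 0.74, 1.0)) {
    p <- uvsdt_params(mu_low = 0, sigma_low = 1, mu_high = 1,
                      sigma_high = 1 / ratio)
    est <- vapply(1:20, function(s)
      zroc_slope(simulate_ratings(p, 1e4, seed = 100 + s)), numeric(1))
    expect_lt(mean(abs(est - ratio)), 0.05)
  }
})

test_that("auroc2 matches the trapezoid oracle and its invariances", {
  # proportional counts: confidence carries no information
  expect_equal(auroc2(c(2, 4, 6), c(1, 2, 3)), 0.5)
  expect_equal(auroc2(c(0, 0, 10), c(10, 0, 0)), 1.0)

  # independent hand-summed trapezoid oracle on 3 levels
  oracle_auc <- function(corr, err) {
    pc <- c(0, cumsum(rev(corr)) / sum(corr))
    pe <- c(0, cumsum(rev(err)) / sum(err))
    a <- 0
    for (i in 1:(length(pc) - 1))
      a <- a + (pe[i + 1] - pe[i]) * (pc[i] + pc[i + 1]) / 2
    a
  }
  expect_equal(auroc2(c(1, 2, 3), c(3, 2, 1)), oracle_auc(c(1, 2, 3), c(3, 2, 1)))

  # invariant to scaling either count vector by a positive constant
  expect_equal(auroc2(7 * c(1, 2, 3), 3 * c(3, 2, 1)),
               auroc2(c(1, 2, 3), c(3, 2, 1)))

  expect_error(auroc2(c(0, 0, 0), c(1, 1, 1)), "positive total")
  expect_error(auroc2(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("predicted_low_response_rate matches Monte Carlo and its limits", {
  expect_equal(predicted_low_response_rate(uvsdt_params(-1, 1, 1, 1)), 0.5)

  p <- uvsdt_params(mu_low = 0, sigma_low = 1, mu_high = 1.8157,
                    sigma_high = 1 / 0.74)
  r <- predicted_low_response_rate(p)
  expect_gt(r, 0.5)

  set.seed(21)
  n <- 1e6
  x <- c(rnorm(n / 2, p$mu_low, p$sigma_low),
         rnorm(n / 2, p$mu_high, p$sigma_high))
  mc <- mean(llr(x, p) <= 0)
  expect_equal(r, mc, tolerance = 3 * sqrt(mc * (1 - mc) / n) + 1e-6)
})

test_that("uvsdt_params validates its invariants", {
  expect_error(uvsdt_params(sigma_low = 0), "positive")
  expect_error(uvsdt_params(prior_high = 1), "prior_high")
  expect_error(uvsdt_params(criteria = rep(0, 11)), "strictly increasing")
  expect_error(uvsdt_params(criteria = 1:5), "length")
})
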