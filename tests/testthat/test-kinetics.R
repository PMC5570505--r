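test_that("fork-rate samples come from green tracks continuing from red", {
  f <- fib("URGU", c(100, 5, 9.1, 100))
  fr <- fork_rates(f)
  expect_equal(fr$rate_kb_per_min, 0.91)
  expect_false(fr$at_fiber_end)

  # a GRG origin yields one sample per sister fork
  f <- fib("UGRGU", c(80, 8, 5, 10, 80))
  fr <- fork_rates(f)
  expect_equal(sort(fr$rate_kb_per_min), c(0.8, 1.0))

  # isolated green has no red continuation; RGR greens are terminations
  expect_equal(nrow(fork_rates(fib("UGU"))), 0)
  expect_equal(nrow(fork_rates(fib("URGRU"))), 0)

  # greens touching the physical fiber end are flagged
  fr <- fork_rates(fib("GRU", c(7, 5, 100)))
  expect_true(fr$at_fiber_end)
  fr <- fork_rates(fib("URG", c(100, 5, 7)))
  expect_true(fr$at_fiber_end)
})

test_that("the Gaussian fit recovers the center of a fork-rate distribution", {
  set.seed(5)
  x <- stats::rnorm(1000, 0.9, 0.15)
  fit <- fit_fork_rate_gaussian(x)
  expect_identical(fit$method, "gaussian_fit")
  expect_lt(abs(fit$mean - 0.9), 0.02)
  expect_lt(abs(fit$sd - 0.15), 0.03)

  # symmetric contamination leaves the fitted mean near the sample mean
  y <- c(stats::rnorm(500, 0.9, 0.1), 0.9 + c(-0.3, 0.3))
  fit <- fit_fork_rate_gaussian(y)
  expect_lt(abs(fit$mean - mean(y)), 0.02)

  # small samples fall back to sample statistics with a warning
  expect_warning(fit <- fit_fork_rate_gaussian(stats::rnorm(10, 0.9, 0.1)),
                 "30")
  expect_identical(fit$method, "sample")
  expect_equal(fit$mean, fit$sample_mean)

  # a degenerate (constant) distribution falls back to the exact value
  suppressWarnings(fit <- fit_fork_rate_gaussian(rep(0.9, 100)))
  expect_equal(fit$mean, 0.9)
})

test_that("origin firing rate normalizes by unreplicated length and pulse time", {
  # 2 GRG + 1 G over 1000 kb unlabeled, 15 min: 0.2 origins/Mb/min
  f <- fib("UGRGUGRGUGU", c(300, 9, 5, 9, 300, 9, 5, 9, 200, 9, 200))
  r <- origin_firing_rate(f, mode = "naive")
  expect_equal(unname(r["origin_rate_total"]), 3 / 1000 / 15)
  expect_equal(unname(r["origin_rate_p1"]), 2 / 1000 / 5)
  expect_equal(unname(r["origin_rate_p2"]), 1 / 1000 / 10)

  # probabilistic mode equals naive mode at s = 0 (no definite stalls)
  expect_equal(origin_firing_rate(f, s = 0, mode = "probabilistic"), r)

  expect_warning(v <- origin_firing_rate(fib("RG"), mode = "naive"),
                 "unlabeled")
  expect_true(all(is.na(v)))
})

test_that("fork density implements the per-pulse counting rules", {
  # {1 GRG, 1 RGR, 2 RG} over 500 kb unlabeled
  f <- fib("UGRGURGRURGURGU",
           c(100, 9, 5, 9, 100, 5, 9, 5, 100, 5, 9, 100, 5, 9, 100))
  d <- fork_density(f, mode = "naive")
  expect_equal(unname(d["fork_density_p1"]), 6 / 500)
  expect_equal(unname(d["fork_density_p2"]), 6 / 500)
  expect_equal(unname(d["fork_density_total"]), 6 / 500)
})

test_that("total fork density bounds the per-pulse densities in naive mode", {
  set.seed(53)
  for (i in 1:40) {
    f <- random_fiber()
    if (unreplicated_kb_test(f) <= 0) next
    d <- fork_density(f, mode = "naive")
    expect_gte(d["fork_density_total"],
               max(d["fork_density_p1"], d["fork_density_p2"]) - 1e-12)
  }
})

test_that("probabilistic fork densities match the enumeration oracle", {
  set.seed(59)
  for (i in 1:40) {
    f <- random_fiber()
    u <- unreplicated_kb_test(f)
    if (u <= 0) next
    o <- oracle_expected_counts(f, 0.25)
    d <- fork_density(f, s = 0.25, mode = "probabilistic")
    expect_equal(unname(d["fork_density_p1"]), unname(o["forks_p1"]) / u,
                 tolerance = 1e-9)
    expect_equal(unname(d["fork_density_p2"]), unname(o["forks_p2"]) / u,
                 tolerance = 1e-9)
  }
})

test_that("sister-fork asymmetry is the longer over the shorter green arm", {
  f <- fib("UGRGU", c(50, 8, 5, 10, 50))
  expect_equal(sister_fork_asymmetry(f), 1.25)
  f <- fib("UGRGU", c(50, 9, 5, 9, 50))
  expect_equal(sister_fork_asymmetry(f), 1)
  expect_length(sister_fork_asymmetry(fib("URGU")), 0)
})

test_that("dataset comparison reproduces the Welch t-test", {
  mock <- function(vals) structure(
    list(fiber_metrics = data.frame(stall_rate = vals),
         fork_rate_samples = data.frame(rate_kb_per_min = vals)),
    class = "replication_kinetics")
  cmp <- compare_datasets(mock(c(1, 2, 3)), mock(c(2, 3, 4)), "stall_rate")
  ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = FALSE)
  expect_equal(cmp$p_value, ref$p.value)
  expect_equal(cmp$ratio, 2 / 3)
  # hand-computed Welch statistic: t = -1 / sqrt(2/3), df = 4
  expect_equal(cmp$p_value, 2 * stats::pt(-1 / sqrt(2 / 3), 4),
               tolerance = 1e-12)

  cmp <- compare_datasets(mock(c(1, 2, 3)), mock(c(1, 2, 3)), "stall_rate")
  expect_equal(cmp$ratio, 1)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_datasets(mock(1:3), mock(1:3), "nope"), "metric")
})
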