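# fixtures: one definite stall (RUG), one (GUR), one GUG, per fiber
fib_rug <- function() fib("GRUG", c(60, 60, 60, 60))   # (R,G) junction
fib_gur <- function() fib("GURG", c(60, 60, 60, 60))   # (G,R) junction
fib_gug <- function() fib("RGUGR", c(50, 50, 50, 50, 50))

test_that("apparent stall rate pools definite stalls over informative junctions", {
  fibers <- c(list(fib_rug(), fib_gur()), replicate(8, fib_gug(), FALSE))
  expect_equal(apparent_stall_rate(fibers), 0.2)

  expect_equal(apparent_stall_rate(replicate(5, fib_gug(), FALSE)), 0)
  expect_equal(apparent_stall_rate(list(fib_rug(), fib_gur())), 1)
  expect_error(apparent_stall_rate(list(fib("URGU"))), "informative")
})

test_that("apparent stall rate is invariant to fiber order and sharding", {
  set.seed(41)
  fibers <- c(replicate(6, fib_gug(), FALSE), list(fib_rug(), fib_gur(),
                                                   fib_rug()))
  s_all <- apparent_stall_rate(fibers)
  expect_equal(apparent_stall_rate(rev(fibers)), s_all)
  expect_equal(apparent_stall_rate(sample(fibers)), s_all)
  # pooling junction counts across shards reproduces the pooled estimate
  n_def <- 3; n_gug <- 6
  expect_equal(s_all, n_def / (n_def + n_gug))
})

test_that("stalls per kb divides expected stalls by unreplicated length", {
  # two definite stalls over 400 kb of unlabeled DNA
  f <- fib("GURUG", c(60, 200, 8, 200, 60))
  expect_equal(stalls_per_kb(f, s = 0), 2 / 400)

  # one RUR group at s = 0.1 contributes 2 x 0.01 expected stalls
  f <- fib("GRURG", c(50, 5, 200, 5, 50))
  expect_equal(stalls_per_kb(f, s = 0.1), 0.02 / 200)

  # no red gap-edges: zero at any s
  f <- fib("GRGUGRG", c(9, 5, 9, 300, 9, 5, 9))
  expect_equal(stalls_per_kb(f, s = 0.8), 0)

  # no unlabeled DNA: undefined with a warning
  expect_warning(v <- stalls_per_kb(fib("RG"), s = 0), "unlabeled")
  expect_true(is.na(v))
})

test_that("an origin with one context-unambiguous stalled fork has 50% stall rate", {
  f <- fib("UGURGU", c(50, 10, 60, 6, 9, 50))
  expect_equal(stall_rate(f, s = 0), 0.5)
})

test_that("stall rate is zero with only no-stall junctions and s = 0", {
  f <- fib("RGUGR", c(5, 9, 60, 9, 5))
  expect_equal(stall_rate(f, s = 0), 0)
  # and undefined without pulse-1 forks
  expect_warning(v <- stall_rate(fib("UGU"), s = 0), "no first-pulse")
  expect_true(is.na(v))
})

test_that("stall rate equals the oracle ratio on random fibers", {
  set.seed(43)
  for (i in 1:60) {
    f <- random_fiber()
    s <- sample(c(0.05, 0.2, 0.5), 1)
    o <- oracle_expected_counts(f, s)
    if (o["forks_p1"] > 0)
      expect_equal(stall_rate(f, s), unname(o["stalls"] / o["forks_p1"]),
                   tolerance = 1e-9)
  }
})

test_that("stall summary of identical fibers has zero SD and the per-fiber value", {
  fibers <- replicate(6, fib("GURUG", c(60, 200, 8, 200, 60)),
                      simplify = FALSE)
  sm <- stall_summary(fibers, s = 0.1)
  expect_equal(sm$stall_rate_sd, 0)
  expect_equal(sm$stall_rate_mean, stall_rate(fibers[[1]], s = 0.1))
  expect_equal(sm$stalls_per_kb_mean, stalls_per_kb(fibers[[1]], s = 0.1))
  expect_equal(sm$stall_rate_pooled, sm$stall_rate_mean)
})

test_that("stall summary estimates s from the data when not supplied", {
  fibers <- c(list(fib_rug(), fib_gur()), replicate(8, fib_gug(), FALSE))
  sm <- stall_summary(fibers)
  expect_equal(sm$s_apparent, 0.2)
  expect_equal(sm$n_definite_stalls, 2)
  expect_equal(sm$n_gug, 8)
})

test_that("simulated datasets recover the true detectable stall fraction", {
  # monotone in the spontaneous stall burden; absolutely accurate in the
  # physiological regime (fractions up to ~0.2). At heavy stall burden
  # (~0.4) the apparent stall rate -- a junction-conditional quantity --
  # overstates the per-fork stall probability and the estimate runs a few
  # points high; only the looser bound holds there.
  ests <- truths <- numeric(0)
  for (q in c(0, 0.01, 0.03, 0.08)) {
    sim <- simulate_fibers(sim_config(genome_mb = 25, seed = 7,
                                      spontaneous_stall_per_kb = q))
    fit <- replication_kinetics(sim$fibers,
                                s = if (q == 0) 0 else NULL)
    ests <- c(ests, unname(fit$summary$stall_rate["mean"]))
    truths <- c(truths, sim$truth$summary$detectable_stall_fraction)
  }
  expect_true(all(diff(ests) > 0))
  low <- truths <= 0.25
  expect_true(all(abs(ests[low] - truths[low]) <= 0.05))
  expect_true(all(abs(ests - truths) <= 0.08))
})
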