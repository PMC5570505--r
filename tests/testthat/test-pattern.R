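test_that("junction classification follows the flanking-color rules", {
  expect_identical(classify_junction("G", "G"), "NO_STALL")
  expect_identical(classify_junction("R", "G"), "DEFINITE_STALL")
  expect_identical(classify_junction("G", "R"), "DEFINITE_STALL")
  expect_identical(classify_junction("R", "R"), "AMBIGUOUS_RR")
  expect_identical(classify_junction("FIBER_END", "R"), "UNINFORMATIVE")
  expect_identical(classify_junction("G", "FIBER_END"), "UNINFORMATIVE")
  expect_error(classify_junction("U", "G"), "flanks")
})

test_that("segmentation yields the expected events and junctions", {
  # unidirectional rightward fork with uninformative ends
  seg <- segment_fiber(fib("URGU"))
  expect_identical(seg$events$code, "RG")
  expect_identical(seg$junctions$klass,
                   c("UNINFORMATIVE", "UNINFORMATIVE"))

  # origin with both forks stalled: two definite junctions in context
  seg <- segment_fiber(fib("GURUG"))
  expect_identical(seg$events$code, c("G", "R", "G"))
  expect_identical(seg$junctions$klass,
                   c("DEFINITE_STALL", "DEFINITE_STALL"))

  # red/red gap links its neighbors into one composite event
  seg <- segment_fiber(fib("GRURG"))
  expect_identical(seg$events$code, "GRURG")
  expect_identical(seg$junctions$klass, "AMBIGUOUS_RR")
  expect_equal(seg$events$span_kb, 50)

  # a fiber with no labeled tracks has no events
  seg <- segment_fiber(fib("U"))
  expect_equal(nrow(seg$events), 0)
})

test_that("red/red gaps resolve jointly: two stalls with weight s^2", {
  f <- fib("UGRURGU", c(60, 10, 8, 30, 8, 10, 60))
  sets <- enumerate_interpretations(f, s = 0.10)
  expect_length(sets, 1)
  ip <- sets[[1]]$interpretations
  expect_equal(sum(ip$weight), 1, tolerance = 1e-9)
  two <- ip[ip$stalls == 2, ]
  expect_equal(nrow(two), 1)
  expect_equal(two$weight, 0.01)
  expect_equal(two$origins_p1, 2)    # two origins, each with a stalled fork
  expect_equal(two$forks_p1, 4)      # 4 expected forks, 2 apparent
  expect_equal(two$forks_p2, 2)
  none <- ip[ip$stalls == 0, ]
  expect_equal(none$weight, 0.99)
  expect_equal(none$forks_p1, 2)     # forks moving away from an origin
})

test_that("s = 0 collapses every ambiguous group to its minimal-stall reading", {
  for (pat in c("UGRURGU", "URU", "URURU", "UGRU")) {
    sets <- enumerate_interpretations(fib(pat), s = 0)
    for (set in sets) {
      ip <- set$interpretations
      expect_equal(ip$weight[ip$k_enumerated == 0], 1)
      expect_true(all(ip$weight[ip$k_enumerated > 0] == 0))
    }
  }
})

test_that("an isolated red event has three interpretations weighted 1-s-s^2, s, s^2", {
  s <- 0.2
  sets <- enumerate_interpretations(fib("URU", c(100, 8, 100)), s = s)
  ip <- sets[[1]]$interpretations
  expect_equal(nrow(ip), 3)
  expect_equal(ip$weight[ip$stalls == 0], 1 - s - s^2)   # termination
  expect_equal(ip$weight[ip$stalls == 1], s)             # stalled fork
  expect_equal(ip$weight[ip$stalls == 2], s^2)           # origin, both stalled
  expect_equal(ip$forks_p1[ip$stalls == 0], 2)
  expect_equal(ip$forks_p1[ip$stalls == 1], 1)
  expect_equal(ip$forks_p1[ip$stalls == 2], 2)
  expect_equal(ip$origins_p1[ip$stalls == 2], 1)
})

test_that("interpretation weights always sum to one", {
  set.seed(11)
  for (i in 1:50) {
    f <- random_fiber()
    for (s in c(0, 0.17, 0.5, 0.93)) {
      for (set in enumerate_interpretations(f, s))
        expect_equal(sum(set$interpretations$weight), 1, tolerance = 1e-9)
    }
  }
})

test_that("expected counts follow the fixed taxonomy for unambiguous fibers", {
  # one GRG origin and one isolated G origin
  f <- fib("UGRGUGU", c(50, 9, 5, 9, 40, 9, 50))
  cnt <- expected_event_counts(f, s = 0)
  expect_equal(unname(cnt["origins_p1"]), 1)
  expect_equal(unname(cnt["origins_p2"]), 1)
  expect_equal(unname(cnt["stalls"]), 0)
  expect_equal(unname(cnt["forks_p1"]), 2)
  expect_equal(unname(cnt["forks_p2"]), 4)

  # origin with both forks stalled, fixed by definite junctions
  cnt <- expected_event_counts(fib("GURUG"), s = 0.1)
  expect_equal(unname(cnt["stalls"]), 2)
  expect_equal(unname(cnt["forks_p1"]), 2)   # both stalled forks count in p1
  expect_equal(unname(cnt["forks_p2"]), 4)   # the two flanking G origins only
  expect_equal(unname(cnt["origins_p1"]), 1)
})

test_that("expected counts equal the brute-force enumeration oracle", {
  set.seed(23)
  for (i in 1:300) {
    f <- random_fiber()
    s <- sample(c(0, 0.1, 0.37, 0.8), 1)
    expect_equal(expected_event_counts(f, s), oracle_expected_counts(f, s),
                 tolerance = 1e-9)
  }
})

test_that("chained red/red gaps match the oracle at every s", {
  f <- fib("URURURU", c(50, 8, 40, 8, 40, 8, 50))
  for (s in c(0, 0.05, 0.2, 0.6))
    expect_equal(expected_event_counts(f, s), oracle_expected_counts(f, s),
                 tolerance = 1e-12)
})

test_that("expected stalls are non-decreasing in the stall probability", {
  set.seed(31)
  grid <- seq(0, 1, by = 0.1)
  for (i in 1:40) {
    f <- random_fiber()
    st <- vapply(grid, function(s)
      unname(expected_event_counts(f, s)["stalls"]), numeric(1))
    expect_true(all(diff(st) >= -1e-12))
  }
})

test_that("green gap-edges are never assigned stalls", {
  # only green edges face gaps: no stall at any s
  for (pat in c("UGUGU", "GRGUGRG", "UGRGU")) {
    cnt <- expected_event_counts(fib(pat), s = 0.95)
    expect_equal(unname(cnt["stalls"]), 0)
  }
})

test_that("naive mode applies the simple taxonomy with no stall accounting", {
  # isolated red counts as a termination even with definite-stall context
  cnt <- expected_event_counts(fib("GURUG"), mode = "naive")
  expect_equal(unname(cnt["stalls"]), 0)
  expect_equal(unname(cnt["terminations_p1"]), 1)
  expect_equal(unname(cnt["forks_p1"]), 2)
})

test_that("excluding fiber-end events drops the first and last group", {
  f <- fib("UGRGUGRGUGRGU")
  cnt <- expected_event_counts(f, s = 0, exclude_ends = TRUE)
  expect_equal(unname(cnt["origins_p1"]), 1)   # only the middle GRG remains
  cnt_all <- expected_event_counts(f, s = 0)
  expect_equal(unname(cnt_all["origins_p1"]), 3)
})
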