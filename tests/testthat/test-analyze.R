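sim_small <- function(seed = 61, ...) {
  simulate_fibers(sim_config(genome_mb = 5, seed = seed, ...))
}

test_that("analysis of the same input is deterministic", {
  sim <- sim_small()
  f1 <- replication_kinetics(sim$fibers)
  f2 <- replication_kinetics(sim$fibers)
  expect_identical(write_kinetics_summary(f1), write_kinetics_summary(f2))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_kinetics_summary(f1, json_path = p1)
  write_kinetics_summary(f2, json_path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("JSON and TSV summaries agree field for field", {
  sim <- sim_small()
  fit <- replication_kinetics(sim$fibers)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  flat <- write_kinetics_summary(fit, json_path = jp, tsv_path = tp)
  js <- jsonlite::read_json(jp, simplifyVector = TRUE)
  tsv <- utils::read.delim(tp, stringsAsFactors = FALSE)
  expect_setequal(names(js), tsv$field)
  for (nm in names(flat)) {
    v <- tsv$value[tsv$field == nm]
    if (is.numeric(flat[[nm]]))
      expect_equal(as.numeric(v), flat[[nm]], tolerance = 1e-12, info = nm)
    else expect_identical(v, as.character(flat[[nm]]))
  }
})

test_that("probabilistic mode equals naive mode on a stall-free dataset at s = 0", {
  sim <- sim_small(spontaneous_stall_per_kb = 0)
  fp <- replication_kinetics(sim$fibers, mode = "probabilistic", s = 0)
  fn <- replication_kinetics(sim$fibers, mode = "naive", s = 0)
  for (m in c("origin_rate_total", "origin_rate_p1", "origin_rate_p2",
              "fork_density_p1", "fork_density_p2", "fork_density_total"))
    expect_equal(fp$fiber_metrics[[m]], fn$fiber_metrics[[m]],
                 tolerance = 1e-12, info = m)
  expect_equal(fp$summary$fork_rate, fn$summary$fork_rate)
})

test_that("comparison of a dataset with itself gives unit ratios", {
  sim <- sim_small()
  fit <- replication_kinetics(sim$fibers)
  cmp <- compare_kinetics(fit, fit)
  expect_true(all(abs(cmp$ratio - 1) < 1e-12))
  expect_true(all(cmp$p_value > 0.999))
})

test_that("comparison refuses fits produced with different options", {
  sim <- sim_small()
  a <- replication_kinetics(sim$fibers, mode = "probabilistic")
  b <- replication_kinetics(sim$fibers, mode = "naive")
  expect_error(compare_kinetics(a, b), "different options")
})

test_that("treated/untreated ratios track the simulated ground truth", {
  untreated <- simulate_fibers(sim_config(genome_mb = 12, seed = 67))
  treated <- simulate_fibers(sim_config(genome_mb = 12, seed = 71,
                                        lesion_density_per_kb = 1,
                                        p_stall_per_lesion = 0.04,
                                        pause_min_per_lesion = 0.3))
  fu <- replication_kinetics(untreated$fibers)
  ft <- replication_kinetics(treated$fibers)
  cmp <- compare_kinetics(ft, fu, metrics = c("fork_rate", "stall_rate"))
  # frequent mild lesions slow forks and multiply stalls
  expect_lt(cmp$ratio[cmp$metric == "fork_rate"], 0.95)
  expect_gt(cmp$ratio[cmp$metric == "stall_rate"], 1.5)
  # and the stall-rate ratio is in line with the generating truth
  truth_ratio <- treated$truth$summary$detectable_stall_fraction /
    untreated$truth$summary$detectable_stall_fraction
  expect_lt(abs(cmp$ratio[cmp$metric == "stall_rate"] - truth_ratio),
            0.5 * truth_ratio)
})

test_that("end-exclusion leaves stall rate and fork rate nearly unchanged", {
  sim <- simulate_fibers(sim_config(genome_mb = 10, seed = 73))
  full <- replication_kinetics(sim$fibers)
  endx <- replication_kinetics(sim$fibers, exclude_ends = TRUE)
  expect_lt(abs(unname(full$summary$stall_rate["mean"] -
                         endx$summary$stall_rate["mean"])), 0.05)
  expect_lt(abs(full$summary$fork_rate - endx$summary$fork_rate) /
              full$summary$fork_rate, 0.05)
})

test_that("the length cutoff is enforced and reported", {
  sim <- sim_small()
  fit <- replication_kinetics(sim$fibers, min_fiber_kb = 120)
  expect_equal(fit$summary$n_fibers + fit$summary$n_excluded,
               length(sim$fibers))
  expect_true(all(fit$fiber_metrics$total_kb >= 120))
  expect_error(replication_kinetics(sim$fibers, min_fiber_kb = 1e6),
               "no fibers")
})

test_that("print and coef expose the headline estimates", {
  sim <- sim_small()
  fit <- replication_kinetics(sim$fibers)
  expect_output(print(fit), "origin firing rate")
  co <- coef(fit)
  expect_true(all(c("origin_rate_total", "fork_rate", "stall_rate",
                    "s_apparent") %in% names(co)))
  expect_equal(unname(co["fork_rate"]), fit$summary$fork_rate)
})
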