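# Dataset-level analysis: the replication_kinetics() fit object and its
# methods, dataset comparison, and summary export.

#' Estimate replication kinetics from a fiber dataset
#'
#' The central estimator. Pools informative junctions to estimate the
#' apparent stall rate, resolves ambiguous patterns probabilistically,
#' and computes per-fiber and dataset-level replication kinetics: origin
#' firing rate, per-pulse fork density, Gaussian-fit fork rate, stalls
#' per kb of unreplicated DNA, and fork stall rate. Dataset means and SDs
#' are unweighted across fibers; the fork-weighted pooled stall rate is
#' reported alongside.
#'
#' @param fibers a [fiber_set()], or a list of [fiber()] objects.
#' @param mode `"probabilistic"` (stall-corrected, the default) or
#'   `"naive"` (simple pattern taxonomy, no stall accounting).
#' @param min_fiber_kb analysis cutoff; fibers shorter than this are
#'   excluded (re-applied here regardless of flags set at read time).
#' @param exclude_ends drop the first and last labeled event of every
#'   fiber, the guard against combing artifacts at fiber ends; also
#'   drops fork-rate samples whose green track touches a fiber end.
#' @param s apparent stall rate; estimated from the pooled junctions when
#'   `NULL`.
#' @param bin_width fork-rate histogram bin width (kb/min) for the
#'   Gaussian fit.
#' @return An object of class `"replication_kinetics"` with components
#'   `fiber_metrics` (per-fiber data.frame), `summary` (named list of
#'   dataset estimates), `fork_rate_fit`, `fork_rate_samples`,
#'   `s_apparent`, `stall` (the [stall_summary()]), `options`, and
#'   `n_excluded`. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' sim <- simulate_fibers(sim_config(genome_mb = 3, seed = 1))
#' fit <- replication_kinetics(sim$fibers)
#' coef(fit)["origin_rate_total"]  # origins/Mb/min
#' @export
replication_kinetics <- function(fibers,
                                 mode = c("probabilistic", "naive"),
                                 min_fiber_kb = 120,
                                 exclude_ends = FALSE,
                                 s = NULL,
                                 bin_width = 0.1) {
  mode <- match.arg(mode)
  if (inherits(fibers, "fiber")) fibers <- list(fibers)
  meta <- fiber_set_meta(fibers)
  keep <- vapply(fibers, function(f) f$total_kb >= min_fiber_kb, logical(1))
  n_excluded <- sum(!keep)
  use <- unclass(fibers)[keep]
  if (length(use) == 0L)
    stop("no fibers remain after the ", min_fiber_kb, " kb length cutoff")
  use <- lapply(use, function(f) { f$excluded <- FALSE; f })

  if (is.null(s)) s <- apparent_stall_rate(use)
  st <- stall_summary(use, s = s, mode = mode, exclude_ends = exclude_ends)

  p1 <- meta$pulse1_min; p2 <- meta$pulse2_min
  per <- do.call(rbind, lapply(use, function(f) {
    orr <- suppressWarnings(
      origin_firing_rate(f, s = s, mode = mode, pulse1_min = p1,
                         pulse2_min = p2, exclude_ends = exclude_ends))
    fd <- suppressWarnings(
      fork_density(f, s = s, mode = mode, exclude_ends = exclude_ends))
    data.frame(fiber_id = f$fiber_id, total_kb = f$total_kb,
               unreplicated_kb = unreplicated_kb(f),
               t(orr), t(fd), stringsAsFactors = FALSE)
  }))
  per$stalls_per_kb <- st$fibers$stalls_per_kb
  per$stall_rate <- st$fibers$stall_rate
  per$expected_stalls <- st$fibers$expected_stalls
  per$forks_p1 <- st$fibers$forks_p1

  fr <- do.call(rbind, lapply(use, fork_rates, pulse2_min = p2))
  if (exclude_ends && nrow(fr) > 0) fr <- fr[!fr$at_fiber_end, , drop = FALSE]
  fit <- suppressWarnings(
    fit_fork_rate_gaussian(fr$rate_kb_per_min, bin_width = bin_width))

  asym <- unlist(lapply(use, sister_fork_asymmetry))

  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE))
  summ <- list(
    n_fibers = length(use),
    n_excluded = n_excluded,
    total_mb = sum(per$total_kb) / 1000,
    s_apparent = s,
    mode = mode,
    origin_rate_total = msd(per$origin_rate_total),
    origin_rate_p1 = msd(per$origin_rate_p1),
    origin_rate_p2 = msd(per$origin_rate_p2),
    fork_density_p1 = msd(per$fork_density_p1),
    fork_density_p2 = msd(per$fork_density_p2),
    fork_density_total = msd(per$fork_density_total),
    stalls_per_kb = msd(per$stalls_per_kb),
    stall_rate = msd(per$stall_rate),
    stall_rate_pooled = st$stall_rate_pooled,
    fork_rate = fit$mean,
    fork_rate_sd = fit$sd,
    fork_rate_sample_mean = fit$sample_mean,
    fork_rate_sample_sd = fit$sample_sd,
    n_fork_rate_samples = fit$n,
    sister_asymmetry = if (length(asym) > 0) msd(asym) else
      c(mean = NA_real_, sd = NA_real_))

  structure(list(fiber_metrics = per, summary = summ,
                 fork_rate_fit = fit, fork_rate_samples = fr,
                 s_apparent = s, stall = st,
                 options = list(mode = mode, min_fiber_kb = min_fiber_kb,
                                exclude_ends = exclude_ends,
                                bin_width = bin_width,
                                pulse1_min = p1, pulse2_min = p2),
                 n_excluded = n_excluded),
            class = "replication_kinetics")
}

#' @export
print.replication_kinetics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<replication_kinetics> %d fibers (%.1f Mb), %d excluded; mode = %s\n",
              s$n_fibers, s$total_mb, s$n_excluded, s$mode))
  cat(sprintf("  origin firing rate: %.2f +/- %.2f origins/Mb/min\n",
              s$origin_rate_total["mean"] * 1000,
              s$origin_rate_total["sd"] * 1000))
  cat(sprintf("  fork rate:          %.2f kb/min (Gaussian fit; sample mean %.2f, n = %d)\n",
              s$fork_rate, s$fork_rate_sample_mean, s$n_fork_rate_samples))
  cat(sprintf("  stall rate:         %.1f%% +/- %.1f%% (s_apparent = %.3f)\n",
              100 * s$stall_rate["mean"], 100 * s$stall_rate["sd"],
              s$s_apparent))
  invisible(x)
}

#' @export
summary.replication_kinetics <- function(object, ...) {
  s <- object$summary
  print(object)
  cat(sprintf("  origin rate p1/p2:  %.2f / %.2f origins/Mb/min\n",
              s$origin_rate_p1["mean"] * 1000, s$origin_rate_p2["mean"] * 1000))
  cat(sprintf("  fork density p1/p2/total: %.1f / %.1f / %.1f forks/Mb unreplicated\n",
              s$fork_density_p1["mean"] * 1000, s$fork_density_p2["mean"] * 1000,
              s$fork_density_total["mean"] * 1000))
  cat(sprintf("  stalls/kb unreplicated: %.5f +/- %.5f\n",
              s$stalls_per_kb["mean"], s$stalls_per_kb["sd"]))
  cat(sprintf("  sister-fork asymmetry:  %.2f +/- %.2f\n",
              s$sister_asymmetry["mean"], s$sister_asymmetry["sd"]))
  invisible(s)
}

#' @export
coef.replication_kinetics <- function(object, ...) {
  s <- object$summary
  c(origin_rate_total = unname(s$origin_rate_total["mean"]) * 1000,
    origin_rate_p1 = unname(s$origin_rate_p1["mean"]) * 1000,
    origin_rate_p2 = unname(s$origin_rate_p2["mean"]) * 1000,
    fork_rate = s$fork_rate,
    fork_density_p1 = unname(s$fork_density_p1["mean"]),
    fork_density_p2 = unname(s$fork_density_p2["mean"]),
    fork_density_total = unname(s$fork_density_total["mean"]),
    stalls_per_kb = unname(s$stalls_per_kb["mean"]),
    stall_rate = unname(s$stall_rate["mean"]),
    s_apparent = s$s_apparent)
}

#' @export
plot.replication_kinetics <- function(x, ...) {
  r <- x$fork_rate_samples$rate_kb_per_min
  if (length(r) == 0L) stop("no fork-rate samples to plot")
  bw <- x$options$bin_width
  h <- graphics::hist(r, breaks = seq(0, max(r) + bw, by = bw),
                      col = "grey85", border = "grey50",
                      xlab = "fork rate (kb/min)",
                      main = "Fork-rate distribution", ...)
  fit <- x$fork_rate_fit
  if (fit$method == "gaussian_fit") {
    xx <- seq(0, max(r) + bw, length.out = 200)
    amp <- max(h$counts) * exp(-(xx - fit$mean)^2 / (2 * fit$sd^2))
    graphics::lines(xx, amp, col = "firebrick", lwd = 2)
    graphics::abline(v = fit$mean, col = "firebrick", lty = 2)
  }
  invisible(x)
}

#' Compare two analyzed datasets metric by metric
#'
#' Ratios of dataset means (treated over untreated) with Welch t-test
#' p-values, mirroring treated-vs-untreated ratio plots. Ratio standard
#' errors are first-order (delta-method) propagated from the two SDs.
#' Errors out when the two fits were produced with different options, to
#' prevent invalid comparisons.
#'
#' @param treated,untreated [replication_kinetics()] fits computed with
#'   identical options.
#' @param metrics character vector of metrics (see [compare_datasets()]).
#' @return data.frame: `metric`, `ratio`, `se_ratio`, `mean_treated`,
#'   `mean_untreated`, `sd_treated`, `sd_untreated`, `n_treated`,
#'   `n_untreated`, `p_value`.
#' @export
compare_kinetics <- function(treated, untreated,
                             metrics = c("origin_rate_total",
                                         "fork_density_p1",
                                         "fork_density_p2", "fork_rate",
                                         "stalls_per_kb", "stall_rate")) {
  if (!identical(treated$options, untreated$options))
    stop("datasets were analyzed with different options; re-analyze ",
         "both with identical settings before comparing")
  rows <- lapply(metrics, function(m) {
    cmp <- compare_datasets(treated, untreated, m)
    se <- with(cmp, abs(ratio) *
                 sqrt((sd_treated / mean_treated)^2 / n_treated +
                        (sd_untreated / mean_untreated)^2 / n_untreated))
    data.frame(metric = m, ratio = cmp$ratio, se_ratio = se,
               mean_treated = cmp$mean_treated,
               mean_untreated = cmp$mean_untreated,
               sd_treated = cmp$sd_treated, sd_untreated = cmp$sd_untreated,
               n_treated = cmp$n_treated, n_untreated = cmp$n_untreated,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a dataset summary to JSON and TSV
#'
#' @param fit a [replication_kinetics()] fit.
#' @param json_path,tsv_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the flattened summary list that was written.
#' @export
write_kinetics_summary <- function(fit, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(fit, "replication_kinetics"))
  s <- fit$summary
  flat <- list(
    n_fibers = s$n_fibers, n_excluded = s$n_excluded,
    total_mb = s$total_mb, mode = s$mode, s_apparent = s$s_apparent,
    origin_rate_total_mean = unname(s$origin_rate_total["mean"]),
    origin_rate_total_sd = unname(s$origin_rate_total["sd"]),
    origin_rate_p1_mean = unname(s$origin_rate_p1["mean"]),
    origin_rate_p2_mean = unname(s$origin_rate_p2["mean"]),
    fork_density_p1_mean = unname(s$fork_density_p1["mean"]),
    fork_density_p1_sd = unname(s$fork_density_p1["sd"]),
    fork_density_p2_mean = unname(s$fork_density_p2["mean"]),
    fork_density_p2_sd = unname(s$fork_density_p2["sd"]),
    fork_density_total_mean = unname(s$fork_density_total["mean"]),
    fork_rate_fit_mean = s$fork_rate, fork_rate_fit_sd = s$fork_rate_sd,
    fork_rate_sample_mean = s$fork_rate_sample_mean,
    n_fork_rate_samples = s$n_fork_rate_samples,
    stalls_per_kb_mean = unname(s$stalls_per_kb["mean"]),
    stalls_per_kb_sd = unname(s$stalls_per_kb["sd"]),
    stall_rate_mean = unname(s$stall_rate["mean"]),
    stall_rate_sd = unname(s$stall_rate["sd"]),
    stall_rate_pooled = s$stall_rate_pooled)
  if (!is.null(json_path))
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    df <- data.frame(field = names(flat),
                     value = vapply(flat, function(v)
                       if (is.numeric(v)) format(v, digits = 15) else
                         as.character(v), character(1)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(flat)
}
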