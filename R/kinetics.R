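# Replication kinetics: fork rates (Gaussian-fit), origin firing rates,
# per-pulse fork densities, sister-fork asymmetry, dataset comparison.

#' Fork-rate samples from a fiber
#'
#' One sample per green track continuing from a red track (the patterns
#' RG, GR and GRG; a GRG origin yields two samples, one per fork). The
#' rate is the green track length divided by the chase (second pulse)
#' duration. Isolated green events have no red continuation and yield no
#' sample. Samples whose green track touches the physical end of the fiber
#' are flagged `at_fiber_end`: broken forks under-estimate the rate.
#'
#' @param f a [fiber()].
#' @param pulse2_min second-pulse duration in minutes.
#' @return data.frame with `rate_kb_per_min`, `green_kb`, `code` (the
#'   event the sample came from) and `at_fiber_end`.
#' @examples
#' f <- fiber(c("U","R","G","U"), c(100, 5, 9.1, 100))
#' fork_rates(f)$rate_kb_per_min  # 0.91
#' @export
fork_rates <- function(f, pulse2_min = 10) {
  stopifnot(inherits(f, "fiber"))
  if (!is.numeric(pulse2_min) || pulse2_min <= 0)
    stop("pulse2_min must be positive")
  parsed <- parse_fiber(f)
  n <- length(f$labels)
  out <- list()
  for (g in parsed$groups) for (si in g$segs) {
    s <- parsed$segments[[si]]
    m <- length(s$labels)
    if (m < 2L) next
    for (pos in c(1L, m)) {
      if (s$labels[pos] != "G") next
      inner <- if (pos == 1L) 2L else m - 1L
      if (s$labels[inner] != "R") next  # defensive; segments alternate
      tr <- if (pos == 1L) s$first else s$last
      out[[length(out) + 1L]] <- data.frame(
        rate_kb_per_min = s$lengths[pos] / pulse2_min,
        green_kb = s$lengths[pos],
        code = paste(s$labels, collapse = ""),
        at_fiber_end = tr == 1L || tr == n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(rate_kb_per_min = numeric(0), green_kb = numeric(0),
                      code = character(0), at_fiber_end = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Gaussian fit to a fork-rate distribution
#'
#' Bins the samples into a histogram and least-squares fits a Gaussian
#' curve to the bin counts; the fitted mean is the fork-rate estimate,
#' robust to the left tail contributed by forks that stalled or terminated
#' during the chase. Falls back to the sample mean and SD, with a warning,
#' when there are fewer than 30 samples or the fit does not converge.
#'
#' @param samples numeric vector of fork rates (kb/min).
#' @param bin_width histogram bin width in kb/min.
#' @return A list: `mean` and `sd` (fitted, or fallback), `sample_mean`,
#'   `sample_sd`, `n`, `method` (`"gaussian_fit"` or `"sample"`), and
#'   `converged`.
#' @export
fit_fork_rate_gaussian <- function(samples, bin_width = 0.1) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  sm <- mean(samples); ss <- stats::sd(samples)
  fallback <- list(mean = sm, sd = ss, sample_mean = sm, sample_sd = ss,
                   n = n, method = "sample", converged = FALSE)
  if (n < 30L) {
    warning("fewer than 30 fork-rate samples; reporting sample mean/SD")
    return(fallback)
  }
  breaks <- seq(0, max(samples) + bin_width, by = bin_width)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = df,
                      start = list(A = max(df$y), mu = sm,
                                   sigma = max(ss, bin_width)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian fit did not converge; reporting sample mean/SD")
    return(fallback)
  }
  cf <- stats::coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       sample_mean = sm, sample_sd = ss, n = n,
       method = "gaussian_fit", converged = TRUE)
}

#' Origin firing rate of a fiber
#'
#' Origin firing events divided by the fiber's unreplicated (unlabeled)
#' length and by the pulse duration. The combined rate uses the total
#' labeling time (first plus second pulse); per-pulse rates use the
#' respective pulse duration. In naive mode origins are the GRG events
#' (first pulse) and isolated green events (second pulse); in
#' probabilistic mode the expected origin counts credit origins disrupted
#' by fork stalling (appearing as GR, RG or isolated red).
#'
#' @param f a [fiber()].
#' @param s apparent stall rate (probabilistic mode).
#' @param mode `"probabilistic"` or `"naive"`.
#' @param pulse1_min,pulse2_min pulse durations, minutes.
#' @param exclude_ends drop the first and last labeled event of the fiber.
#' @return Named vector, origins per kb per minute: `origin_rate_total`,
#'   `origin_rate_p1`, `origin_rate_p2`. `NA` with a warning when the
#'   fiber has no unlabeled DNA.
#' @export
origin_firing_rate <- function(f, s = 0, mode = c("probabilistic", "naive"),
                               pulse1_min = 5, pulse2_min = 10,
                               exclude_ends = FALSE) {
  mode <- match.arg(mode)
  u <- unreplicated_kb(f)
  if (u <= 0) {
    warning("fiber ", f$fiber_id,
            " has no unlabeled DNA; origin rate undefined")
    return(c(origin_rate_total = NA_real_, origin_rate_p1 = NA_real_,
             origin_rate_p2 = NA_real_))
  }
  cnt <- expected_event_counts(f, s, mode = mode, exclude_ends = exclude_ends)
  c(origin_rate_total =
      unname(cnt["origins_p1"] + cnt["origins_p2"]) / u / (pulse1_min + pulse2_min),
    origin_rate_p1 = unname(cnt["origins_p1"]) / u / pulse1_min,
    origin_rate_p2 = unname(cnt["origins_p2"]) / u / pulse2_min)
}

#' Fork density of a fiber
#'
#' Forks per kb of unreplicated DNA, per pulse and total. In naive mode the
#' counting is: first pulse, origins (GRG) and terminations (isolated R and
#' RGR) twice each plus unidirectional forks (GR, RG) once; second pulse,
#' second-pulse origins (isolated G), first-pulse origins (GRG) and
#' second-pulse terminations (RGR) twice each plus unidirectional forks
#' once; total, every origin and termination twice plus unidirectional
#' forks once. Probabilistic mode substitutes the expected fork counts
#' under stall resolution (stalled forks count in the first pulse only).
#'
#' @inheritParams origin_firing_rate
#' @return Named vector, forks per kb: `fork_density_p1`,
#'   `fork_density_p2`, `fork_density_total`.
#' @export
fork_density <- function(f, s = 0, mode = c("probabilistic", "naive"),
                         exclude_ends = FALSE) {
  mode <- match.arg(mode)
  u <- unreplicated_kb(f)
  if (u <= 0) {
    warning("fiber ", f$fiber_id,
            " has no unlabeled DNA; fork density undefined")
    return(c(fork_density_p1 = NA_real_, fork_density_p2 = NA_real_,
             fork_density_total = NA_real_))
  }
  cnt <- expected_event_counts(f, s, mode = mode, exclude_ends = exclude_ends)
  c(fork_density_p1 = unname(cnt["forks_p1"]) / u,
    fork_density_p2 = unname(cnt["forks_p2"]) / u,
    fork_density_total = unname(cnt["forks_total"]) / u)
}

#' Sister-fork asymmetry of first-pulse origins
#'
#' For every simple GRG origin (both sister forks continuing into the
#' chase), the ratio of the longer to the shorter green track. Symmetric
#' sister forks give 1.
#'
#' @param f a [fiber()].
#' @return Numeric vector of ratios (>= 1), one per GRG origin.
#' @export
sister_fork_asymmetry <- function(f) {
  stopifnot(inherits(f, "fiber"))
  parsed <- parse_fiber(f)
  out <- numeric(0)
  for (g in parsed$groups) for (si in g$segs) {
    s <- parsed$segments[[si]]
    if (identical(s$labels, c("G", "R", "G"))) {
      g1 <- s$lengths[1L]; g2 <- s$lengths[3L]
      out <- c(out, max(g1, g2) / min(g1, g2))
    }
  }
  out
}

#' Compare a metric between two analyzed datasets
#'
#' Ratio of dataset means (treated over untreated) with a two-sample Welch
#' t-test. Per-fiber values are compared for fiber-level metrics; fork rate
#' is compared on the per-fork samples.
#'
#' @param treated,untreated [replication_kinetics()] fits.
#' @param metric one of the per-fiber metric columns
#'   (`"origin_rate_total"`, `"origin_rate_p1"`, `"origin_rate_p2"`,
#'   `"fork_density_p1"`, `"fork_density_p2"`, `"fork_density_total"`,
#'   `"stalls_per_kb"`, `"stall_rate"`) or `"fork_rate"`.
#' @return A list: `metric`, `ratio`, `mean_treated`, `mean_untreated`,
#'   `sd_treated`, `sd_untreated`, `n_treated`, `n_untreated`, `p_value`.
#' @export
compare_datasets <- function(treated, untreated, metric) {
  stopifnot(inherits(treated, "replication_kinetics"),
            inherits(untreated, "replication_kinetics"))
  vt <- metric_values(treated, metric)
  vu <- metric_values(untreated, metric)
  mt <- mean(vt, na.rm = TRUE); mu <- mean(vu, na.rm = TRUE)
  tt <- stats::t.test(vt, vu, var.equal = FALSE)
  list(metric = metric, ratio = mt / mu,
       mean_treated = mt, mean_untreated = mu,
       sd_treated = stats::sd(vt, na.rm = TRUE),
       sd_untreated = stats::sd(vu, na.rm = TRUE),
       n_treated = sum(is.finite(vt)), n_untreated = sum(is.finite(vu)),
       p_value = tt$p.value)
}

metric_values <- function(fit, metric) {
  if (metric == "fork_rate")
    return(fit$fork_rate_samples$rate_kb_per_min)
  if (!metric %in% names(fit$fiber_metrics))
    stop("metric '", metric, "' not present in the dataset summary")
  fit$fiber_metrics[[metric]]
}
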