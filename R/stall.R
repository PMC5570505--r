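# Stall estimation: dataset-level apparent stall rate from unambiguous
# junctions, then per-fiber stalls/kb and stall rate via probabilistic
# resolution of ambiguous patterns.

#' Apparent stall rate of a dataset
#'
#' Pools every informative interior junction across the dataset's fibers
#' and returns definite stalls over informative junctions:
#' `(RUG + GUR) / (RUG + GUR + GUG)`. The definite-stall junctions are kept
#' in the denominator because each stall is the loss of one fork. This is
#' the `s` used as the per-fork stall probability when resolving ambiguous
#' patterns.
#'
#' @param fibers a [fiber_set()] or list of fibers. Fibers flagged
#'   `excluded` are skipped.
#' @return The apparent stall rate, a value in `[0, 1]`.
#' @examples
#' # 1 RUG + 1 GUR + 8 GUG junctions pool to s = 0.20
#' @export
apparent_stall_rate <- function(fibers) {
  cnt <- junction_counts(fibers)
  if (cnt["definite"] + cnt["gug"] == 0)
    stop("no informative (RUG/GUR/GUG) junctions in the dataset; ",
         "a larger dataset is needed to estimate the apparent stall rate")
  unname(cnt["definite"] / (cnt["definite"] + cnt["gug"]))
}

junction_counts <- function(fibers) {
  if (inherits(fibers, "fiber")) fibers <- list(fibers)
  def <- 0L; gug <- 0L; amb <- 0L; uninf <- 0L
  for (f in fibers) {
    if (isTRUE(f$excluded)) next
    kl <- parse_fiber(f)$junctions$klass
    def <- def + sum(kl == "DEFINITE_STALL")
    gug <- gug + sum(kl == "NO_STALL")
    amb <- amb + sum(kl == "AMBIGUOUS_RR")
    uninf <- uninf + sum(kl == "UNINFORMATIVE")
  }
  c(definite = def, gug = gug, ambiguous = amb, uninformative = uninf)
}

#' Stalls per kb of unreplicated DNA on a fiber
#'
#' Expected stalls (definite plus the stalled fraction of ambiguous
#' patterns at stall probability `s`) divided by the fiber's unlabeled
#' length.
#'
#' @param f a [fiber()].
#' @param s apparent stall rate, from [apparent_stall_rate()].
#' @inheritParams expected_event_counts
#' @return Stalls per kb, or `NA` with a warning when the fiber has no
#'   unlabeled DNA.
#' @export
stalls_per_kb <- function(f, s, mode = c("probabilistic", "naive"),
                          exclude_ends = FALSE) {
  mode <- match.arg(mode)
  u <- unreplicated_kb(f)
  if (u <= 0) {
    warning("fiber ", f$fiber_id,
            " has no unlabeled DNA; stalls/kb undefined")
    return(NA_real_)
  }
  cnt <- expected_event_counts(f, s, mode = mode, exclude_ends = exclude_ends)
  unname(cnt["stalls"] / u)
}

#' Fork stall rate of a fiber
#'
#' Expected stalls divided by expected ongoing first-pulse forks, both from
#' [expected_event_counts()]. Stalled forks are counted in the denominator:
#' an origin with exactly one stalled fork has a stall rate of 50%, since
#' one fork is stalled but there should be two.
#'
#' @inheritParams stalls_per_kb
#' @return Fraction of first-pulse forks stalled, in `[0, 1]`, or `NA`
#'   with a warning when the fiber carries no first-pulse forks.
#' @export
stall_rate <- function(f, s, mode = c("probabilistic", "naive"),
                       exclude_ends = FALSE) {
  mode <- match.arg(mode)
  cnt <- expected_event_counts(f, s, mode = mode, exclude_ends = exclude_ends)
  if (cnt["forks_p1"] <= 0) {
    warning("fiber ", f$fiber_id,
            " has no first-pulse forks; stall rate undefined")
    return(NA_real_)
  }
  unname(cnt["stalls"] / cnt["forks_p1"])
}

#' Dataset stall summary
#'
#' Per-fiber stall metrics and their dataset mean and SD. The apparent
#' stall rate is estimated once by pooling junctions across the dataset,
#' then used to resolve each fiber's ambiguous patterns. Fibers flagged
#' `excluded`, or with undefined metrics (no unlabeled DNA, no first-pulse
#' forks), are dropped from the respective aggregate.
#'
#' @param fibers a [fiber_set()] or list of fibers.
#' @param s apparent stall rate; estimated from the data when `NULL`.
#' @param mode `"probabilistic"` (full enumeration) or `"naive"`.
#' @param exclude_ends drop the first and last labeled event of each fiber.
#' @return A list of class `"stall_summary"`: `s_apparent`, junction
#'   counts, a per-fiber data.frame (`fiber_id`, `unreplicated_kb`,
#'   `expected_stalls`, `forks_p1`, `stalls_per_kb`, `stall_rate`), the
#'   unweighted dataset means and SDs across fibers, and the fork-weighted
#'   pooled stall rate (`stall_rate_pooled` = total stalls / total p1
#'   forks).
#' @export
stall_summary <- function(fibers, s = NULL,
                          mode = c("probabilistic", "naive"),
                          exclude_ends = FALSE) {
  mode <- match.arg(mode)
  if (inherits(fibers, "fiber")) fibers <- list(fibers)
  use <- Filter(function(f) !isTRUE(f$excluded), fibers)
  if (length(use) == 0L) stop("no analyzable fibers in the dataset")
  cnt <- junction_counts(use)
  if (is.null(s)) s <- apparent_stall_rate(use)
  per <- do.call(rbind, lapply(use, function(f) {
    ec <- expected_event_counts(f, s, mode = mode,
                                exclude_ends = exclude_ends)
    u <- unreplicated_kb(f)
    data.frame(fiber_id = f$fiber_id,
               unreplicated_kb = u,
               expected_stalls = unname(ec["stalls"]),
               forks_p1 = unname(ec["forks_p1"]),
               stalls_per_kb = if (u > 0) unname(ec["stalls"]) / u else NA_real_,
               stall_rate = if (ec["forks_p1"] > 0)
                 unname(ec["stalls"] / ec["forks_p1"]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res <- list(
    s_apparent = s,
    n_definite_stalls = unname(cnt["definite"]),
    n_gug = unname(cnt["gug"]),
    n_ambiguous = unname(cnt["ambiguous"]),
    fibers = per,
    mode = mode,
    exclude_ends = exclude_ends,
    stalls_per_kb_mean = mean(per$stalls_per_kb, na.rm = TRUE),
    stalls_per_kb_sd = stats::sd(per$stalls_per_kb, na.rm = TRUE),
    stall_rate_mean = mean(per$stall_rate, na.rm = TRUE),
    stall_rate_sd = stats::sd(per$stall_rate, na.rm = TRUE),
    stall_rate_pooled = sum(per$expected_stalls) / max(sum(per$forks_p1), 1e-12))
  class(res) <- "stall_summary"
  res
}

#' @export
print.stall_summary <- function(x, ...) {
  cat(sprintf("<stall_summary> %d fibers, mode = %s\n", nrow(x$fibers), x$mode))
  cat(sprintf("  apparent stall rate s: %.3f (%d definite / %d GUG / %d ambiguous junctions)\n",
              x$s_apparent, x$n_definite_stalls, x$n_gug, x$n_ambiguous))
  cat(sprintf("  stall rate:  %.3f +/- %.3f (per-fiber mean +/- SD); pooled %.3f\n",
              x$stall_rate_mean, x$stall_rate_sd, x$stall_rate_pooled))
  cat(sprintf("  stalls/kb:   %.5f +/- %.5f\n",
              x$stalls_per_kb_mean, x$stalls_per_kb_sd))
  invisible(x)
}
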