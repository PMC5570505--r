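# Poisson inference of DNA lesion density from gel-quantified
# intact-molecule fractions, and derived lesion-spacing arithmetic.

#' Lesion density from the intact-fragment fraction
#'
#' Assuming lesions (converted to strand breaks) fall as a Poisson process
#' along the DNA, the fraction of restriction fragments of length `L` with
#' zero breaks is `exp(-lambda * L)`, so the lesion density is
#' `lambda = -log(intact_fraction) / fragment_length_kb`.
#'
#' @param intact_fraction fraction of molecules with no breaks, in
#'   `(0, 1]` (treated band intensity relative to untreated).
#' @param fragment_length_kb restriction-fragment length in kb; 20 kb is
#'   the typical gel exclusion-volume band average.
#' @return Lesions per kb.
#' @examples
#' poisson_lesion_density(exp(-20), 20)  # 1 lesion per kb
#' poisson_lesion_density(0.5, 20)       # log(2)/20
#' @export
poisson_lesion_density <- function(intact_fraction, fragment_length_kb = 20) {
  if (any(!is.finite(intact_fraction)) || any(intact_fraction <= 0))
    stop("intact_fraction must be in (0, 1]")
  if (any(intact_fraction > 1))
    stop("intact_fraction cannot exceed 1")
  if (any(!is.finite(fragment_length_kb)) || any(fragment_length_kb <= 0))
    stop("fragment_length_kb must be positive")
  -log(intact_fraction) / fragment_length_kb
}

#' Nick spacing implied by a double-strand-break spacing
#'
#' Agents that create an `excess_low`- to `excess_high`-fold excess of
#' single-strand nicks over double-strand breaks produce one nick every
#' `dsb_spacing_kb / excess` kb.
#'
#' @param dsb_spacing_kb kb per double-strand break.
#' @param excess_low,excess_high fold excess of nicks over breaks
#'   (`excess_high >= excess_low > 0`).
#' @return Named vector `c(min_kb, max_kb)`: the nick-spacing range.
#' @examples
#' nick_spacing_range(50, 6, 20)  # one nick every 2.5 to 8.3 kb
#' @export
nick_spacing_range <- function(dsb_spacing_kb, excess_low, excess_high) {
  if (!is.finite(dsb_spacing_kb) || dsb_spacing_kb <= 0)
    stop("dsb_spacing_kb must be positive")
  if (!is.finite(excess_low) || !is.finite(excess_high) ||
      excess_low <= 0 || excess_high < excess_low)
    stop("need excess_high >= excess_low > 0")
  c(min_kb = dsb_spacing_kb / excess_high,
    max_kb = dsb_spacing_kb / excess_low)
}

#' Expected lesions encountered by a fork
#'
#' A fork moving at `fork_rate_kb_min` for `duration_min` minutes through
#' DNA carrying `density_per_kb` lesions per kb encounters their product.
#'
#' @param fork_rate_kb_min fork speed, kb per minute.
#' @param duration_min travel time, minutes.
#' @param density_per_kb lesion density, per kb.
#' @return Expected number of lesions encountered.
#' @examples
#' lesions_encountered(0.91, 10, 1)  # ~9 lesions during an MMS chase
#' @export
lesions_encountered <- function(fork_rate_kb_min, duration_min,
                                density_per_kb) {
  v <- c(fork_rate_kb_min, duration_min, density_per_kb)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all inputs must be non-negative")
  fork_rate_kb_min * duration_min * density_per_kb
}
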