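# shared fixtures: quick fiber construction and a random-fiber generator

# fib("URGU") -> fiber with one track per character, default 10 kb each
fib <- function(pattern, lengths = NULL, ...) {
  labs <- strsplit(pattern, "")[[1]]
  if (is.null(lengths)) lengths <- rep(10, length(labs))
  fiber(labs, lengths, min_fiber_kb = 0, ...)
}

# random fiber with up to max_segments labeled segments: alternating
# R/G runs separated by unlabeled gaps, optional unlabeled overhangs
random_fiber <- function(max_segments = 6) {
  ns <- sample.int(max_segments, 1)
  labs <- character(0)
  if (stats::runif(1) < 0.7) labs <- "U"
  for (k in seq_len(ns)) {
    m <- sample.int(4, 1)
    start <- sample(c("R", "G"), 1)
    seg <- rep(c(start, setdiff(c("R", "G"), start)), length.out = m)
    labs <- c(labs, seg)
    if (k < ns) labs <- c(labs, "U")
  }
  if (stats::runif(1) < 0.7) labs <- c(labs, "U")
  fiber(labs, stats::runif(length(labs), 2, 40), min_fiber_kb = 0)
}

# unlabeled length of a fiber (mirrors the package's internal normalizer)
unreplicated_kb_test <- function(f) sum(f$lengths_kb[f$labels == "U"])
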