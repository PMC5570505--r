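# Pattern engine: parse fibers into labeled segments and unlabeled
# junctions, classify junctions for stall evidence, and enumerate
# geometrically consistent interpretations of ambiguous patterns.
#
# The model: every red (first-analog) segment edge that faces unlabeled DNA
# is a potential stalled fork. The state of the unlabeled gap decides it:
# a gap that stayed unreplicated implies the red edge is a fork that stalled
# there; a gap replicated before the pulses implies the edge is the passive
# tail of a moving fork. A green flank on the far side of a gap proves the
# gap unreplicated (an active fork was still moving into it), so a
# red/green gap is a definite stall. A red/red gap is ambiguous: either
# side (pre-pulse replicated, 0 stalls) or (unreplicated, both inbound
# forks stalled, 2 stalls) -- mixed readings are geometrically impossible.
# Red edges with no informative far context (fiber ends) are free
# candidates resolved probabilistically.

#' Classify an unlabeled junction by its flanking label colors
#'
#' An interior unlabeled gap flanked by green on both sides (GUG) is the
#' signature of two unstalled forks; red/green in either order (RUG, GUR)
#' is unambiguous evidence of exactly one stalled fork, on the red-flank
#' side; red/red (RUR) is ambiguous; any fiber-end flank is uninformative.
#'
#' @param left_flank,right_flank `"R"`, `"G"` or `"FIBER_END"`.
#' @return One of `"NO_STALL"`, `"DEFINITE_STALL"`, `"AMBIGUOUS_RR"`,
#'   `"UNINFORMATIVE"`.
#' @examples
#' classify_junction("G", "G")  # NO_STALL
#' classify_junction("R", "G")  # DEFINITE_STALL
#' @export
classify_junction <- function(left_flank, right_flank) {
  ok <- c("R", "G", "FIBER_END")
  if (!left_flank %in% ok || !right_flank %in% ok)
    stop("flanks must be R, G or FIBER_END")
  if (left_flank == "FIBER_END" || right_flank == "FIBER_END")
    return("UNINFORMATIVE")
  if (left_flank == "G" && right_flank == "G") return("NO_STALL")
  if (left_flank == "R" && right_flank == "R") return("AMBIGUOUS_RR")
  "DEFINITE_STALL"
}

# Parse a fiber into segments, junctions, per-edge stall-candidate states
# and ambiguity groups. Internal workhorse shared by all estimators.
#
# Returns a list:
#   segments:  list of (labels, lengths, first, last)
#   junctions: data.frame(gap_kb, left_flank, right_flank, klass,
#                         left_seg, right_seg)
#   edges:     data.frame(seg, side ("L"/"R"), label,
#                         state ("none","fixed_stall","coupled","free"),
#                         junction (id or NA))
#   groups:    list of (segs, amb_junctions, free_edges (edge row ids),
#                       fixed_edges (edge row ids), code)
parse_fiber <- function(f) {
  lab <- f$labels
  n <- length(lab)
  labeled <- lab != "U"
  if (!any(labeled)) {
    return(list(segments = list(),
                junctions = data.frame(gap_kb = numeric(0),
                                       left_flank = character(0),
                                       right_flank = character(0),
                                       klass = character(0),
                                       left_seg = integer(0),
                                       right_seg = integer(0),
                                       stringsAsFactors = FALSE),
                edges = data.frame(), groups = list()))
  }
  # maximal labeled runs
  runs <- rle(labeled)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg_idx <- which(runs$values)
  segments <- lapply(seg_idx, function(i) {
    rng <- starts[i]:ends[i]
    list(labels = lab[rng], lengths = f$lengths_kb[rng],
         first = starts[i], last = ends[i])
  })
  ns <- length(segments)
  # junctions: every U run
  gap_idx <- which(!runs$values)
  jn <- lapply(gap_idx, function(i) {
    left_seg <- if (starts[i] == 1L) NA_integer_ else
      match(TRUE, vapply(segments, function(s) s$last == starts[i] - 1L, logical(1)))
    right_seg <- if (ends[i] == n) NA_integer_ else
      match(TRUE, vapply(segments, function(s) s$first == ends[i] + 1L, logical(1)))
    lf <- if (is.na(left_seg)) "FIBER_END" else {
      s <- segments[[left_seg]]; s$labels[length(s$labels)]
    }
    rf <- if (is.na(right_seg)) "FIBER_END" else segments[[right_seg]]$labels[1L]
    data.frame(gap_kb = sum(f$lengths_kb[starts[i]:ends[i]]),
               left_flank = lf, right_flank = rf,
               klass = classify_junction(lf, rf),
               left_seg = left_seg, right_seg = right_seg,
               stringsAsFactors = FALSE)
  })
  junctions <- if (length(jn) > 0) do.call(rbind, jn) else
    data.frame(gap_kb = numeric(0), left_flank = character(0),
               right_flank = character(0), klass = character(0),
               left_seg = integer(0), right_seg = integer(0),
               stringsAsFactors = FALSE)
  # per-segment edge states
  edge_rows <- vector("list", 2L * ns)
  for (si in seq_len(ns)) {
    s <- segments[[si]]
    for (side in c("L", "R")) {
      elab <- if (side == "L") s$labels[1L] else s$labels[length(s$labels)]
      jid <- NA_integer_
      state <- "none"
      if (elab == "R") {
        if (side == "L") {
          jid0 <- which(!is.na(junctions$right_seg) & junctions$right_seg == si)
        } else {
          jid0 <- which(!is.na(junctions$left_seg) & junctions$left_seg == si)
        }
        if (length(jid0) == 0L) {
          state <- "free"      # red edge at the physical fiber end
        } else {
          jid <- jid0[1L]
          state <- switch(junctions$klass[jid],
                          DEFINITE_STALL = "fixed_stall",
                          AMBIGUOUS_RR = "coupled",
                          UNINFORMATIVE = "free",
                          "none")
        }
      }
      edge_rows[[2L * (si - 1L) + (side == "R") + 1L]] <-
        data.frame(seg = si, side = side, label = elab, state = state,
                   junction = jid, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edge_rows)
  # groups: segments linked through AMBIGUOUS_RR junctions
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  amb <- which(junctions$klass == "AMBIGUOUS_RR")
  for (j in amb) {
    a <- find(junctions$left_seg[j]); b <- find(junctions$right_seg[j])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(ns), find, integer(1))
  groups <- lapply(unique(roots), function(r) {
    segs <- which(roots == r)
    gj <- amb[junctions$left_seg[amb] %in% segs]
    code <- paste(vapply(segs, function(si)
      paste(segments[[si]]$labels, collapse = ""), character(1)),
      collapse = "U")
    fe <- which(edges$seg %in% segs & edges$state == "free")
    fx <- which(edges$seg %in% segs & edges$state == "fixed_stall")
    list(segs = segs, amb_junctions = gj, free_edges = fe,
         fixed_edges = fx, code = code)
  })
  list(segments = segments, junctions = junctions, edges = edges,
       groups = groups)
}

# Event role accounting for one labeled segment given the stall state of
# its two edges. Interior red tracks are origins fired in pulse 1; interior
# green tracks are pulse-2 terminations; edge red tracks are unidirectional
# forks, or origins with one stalled fork when the edge is stalled; an
# isolated red track is a pulse-1 termination, a stalled elongating fork,
# or an origin with both forks stalled; an isolated green track is a
# pulse-2 origin. Stalled forks count toward pulse-1 forks but not pulse-2.
segment_counts <- function(labels, left_stalled, right_stalled) {
  z <- c(origins_p1 = 0, origins_p2 = 0, terminations_p1 = 0,
         terminations_p2 = 0, forks_p1 = 0, forks_p2 = 0,
         forks_total = 0, stalls = 0)
  m <- length(labels)
  if (m == 1L) {
    if (labels == "G") {
      z["origins_p2"] <- 1; z["forks_p2"] <- 2; z["forks_total"] <- 2
    } else {
      k <- left_stalled + right_stalled
      if (k == 0L) {
        z["terminations_p1"] <- 1; z["forks_p1"] <- 2; z["forks_total"] <- 2
      } else if (k == 1L) {
        z["stalls"] <- 1; z["forks_p1"] <- 1; z["forks_total"] <- 1
      } else {
        z["origins_p1"] <- 1; z["stalls"] <- 2; z["forks_p1"] <- 2
        z["forks_total"] <- 2
      }
    }
    return(z)
  }
  for (i in seq_len(m)) {
    interior <- i > 1L && i < m
    if (labels[i] == "R") {
      if (interior) {
        z["origins_p1"] <- z["origins_p1"] + 1
        z["forks_p1"] <- z["forks_p1"] + 2
        z["forks_p2"] <- z["forks_p2"] + 2
        z["forks_total"] <- z["forks_total"] + 2
      } else {
        st <- if (i == 1L) left_stalled else right_stalled
        if (st) {  # origin with one stalled fork
          z["origins_p1"] <- z["origins_p1"] + 1
          z["stalls"] <- z["stalls"] + 1
          z["forks_p1"] <- z["forks_p1"] + 2
          z["forks_p2"] <- z["forks_p2"] + 1
          z["forks_total"] <- z["forks_total"] + 2
        } else {   # unidirectional elongating fork
          z["forks_p1"] <- z["forks_p1"] + 1
          z["forks_p2"] <- z["forks_p2"] + 1
          z["forks_total"] <- z["forks_total"] + 1
        }
      }
    } else if (interior) {  # green flanked by red: pulse-2 termination
      z["terminations_p2"] <- z["terminations_p2"] + 1
    }
  }
  z
}

count_names <- c("origins_p1", "origins_p2", "terminations_p1",
                 "terminations_p2", "forks_p1", "forks_p2",
                 "forks_total", "stalls")

# Enumerate one ambiguity group. Variables: each red/red gap is replicated
# (0 stalls) or unreplicated (2 stalls, coupled); each free red edge is
# independently stalled or not. Definite-stall edges are fixed. Assignments
# with identical count signatures collapse to one interpretation. Weights:
# an interpretation requiring k enumerated stalls gets s^k; the
# minimal-stall interpretation absorbs the remainder so weights sum to 1
# (floored at 0 and renormalized when s is large).
enumerate_group <- function(parsed, g, s) {
  junctions <- parsed$junctions
  edges <- parsed$edges
  segments <- parsed$segments
  nj <- length(g$amb_junctions)
  nf <- length(g$free_edges)
  nv <- nj + nf
  if (nv > 16L)
    stop("ambiguity group too large to enumerate (", nv, " variables)")
  grid <- if (nv == 0L) matrix(0L, nrow = 1L, ncol = 0L) else
    as.matrix(expand.grid(rep(list(0:1), nv), KEEP.OUT.ATTRS = FALSE))
  res <- matrix(0, nrow = nrow(grid), ncol = length(count_names),
                dimnames = list(NULL, count_names))
  kvec <- integer(nrow(grid))
  for (a in seq_len(nrow(grid))) {
    gap_state <- if (nj > 0) grid[a, seq_len(nj)] else integer(0)
    free_state <- if (nf > 0) grid[a, nj + seq_len(nf)] else integer(0)
    kvec[a] <- 2L * sum(gap_state) + sum(free_state)
    tot <- stats::setNames(numeric(length(count_names)), count_names)
    for (si in g$segs) {
      st <- c(L = FALSE, R = FALSE)
      for (side in c("L", "R")) {
        e <- which(edges$seg == si & edges$side == side)
        st[side] <- switch(edges$state[e],
          fixed_stall = TRUE,
          coupled = gap_state[match(edges$junction[e], g$amb_junctions)] == 1L,
          free = free_state[match(e, g$free_edges)] == 1L,
          FALSE)
      }
      tot <- tot + segment_counts(segments[[si]]$labels, st["L"], st["R"])
    }
    res[a, ] <- tot
  }
  key <- apply(res, 1L, paste, collapse = ",")
  keep <- !duplicated(key)
  res <- res[keep, , drop = FALSE]
  kvec <- kvec[keep]
  ord <- order(kvec)
  res <- res[ord, , drop = FALSE]
  kvec <- kvec[ord]
  w <- ifelse(kvec == 0L, 0, s^kvec)
  if (any(kvec == 0L)) {
    w[kvec == 0L] <- max(0, 1 - sum(w))
  }
  if (sum(w) <= 0) w[1L] <- 1  # s = 0 with no zero-stall reading: degenerate
  w <- w / sum(w)
  data.frame(res, k_enumerated = kvec, weight = w)
}

#' Enumerate interpretations of ambiguous label patterns on a fiber
#'
#' Groups labeled segments linked through ambiguous red/red gaps and
#' enumerates every geometrically consistent reading of each group: which
#' red gap-edges are stalled forks, and the event roles (origins,
#' terminations, unidirectional forks) that follow. Interpretations
#' requiring `k` stalls beyond the definite ones are weighted `s^k`, `s`
#' being the dataset's apparent stall rate used as the per-fork stall
#' probability; the minimal-stall interpretation takes the remaining
#' probability. A red/red gap resolves jointly: both inbound forks stalled
#' (weight `s^2`) or neither.
#'
#' @param f a [fiber()].
#' @param s apparent stall rate in `[0, 1]`.
#' @return A list of interpretation sets, one per event group, each a list
#'   with `code` (the composite event pattern, e.g. `"GRURG"`) and
#'   `interpretations`, a data.frame of count signatures
#'   (`origins_p1`, `origins_p2`, `terminations_p1`, `terminations_p2`,
#'   `forks_p1`, `forks_p2`, `forks_total`, `stalls`), the number of
#'   enumerated stalls `k_enumerated` and the probability `weight`
#'   (summing to 1 within each set).
#' @examples
#' f <- fiber(c("U","G","R","U","R","G","U"), c(60, 10, 8, 30, 8, 10, 60))
#' sets <- enumerate_interpretations(f, s = 0.10)
#' sets[[1]]$interpretations  # two-stall reading has weight 0.01
#' @export
enumerate_interpretations <- function(f, s) {
  stopifnot(inherits(f, "fiber"))
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
    stop("s must be a single value in [0, 1]")
  parsed <- parse_fiber(f)
  lapply(parsed$groups, function(g)
    list(code = g$code, interpretations = enumerate_group(parsed, g, s)))
}

#' Segment a fiber into events and junctions
#'
#' Splits a fiber into maximal labeled segments and unlabeled junctions,
#' classifies every junction ([classify_junction()]) and reports composite
#' event codes: segments linked through ambiguous red/red gaps are grouped
#' into a single event (e.g. `"GRURG"`).
#'
#' @param f a [fiber()].
#' @return A list with `events` (data.frame: `code`, `span_kb`,
#'   `n_segments`) and `junctions` (data.frame: `gap_kb`, `left_flank`,
#'   `right_flank`, `klass`). A fiber with no labeled tracks yields zero
#'   events.
#' @export
segment_fiber <- function(f) {
  stopifnot(inherits(f, "fiber"))
  parsed <- parse_fiber(f)
  events <- if (length(parsed$groups) == 0L) {
    data.frame(code = character(0), span_kb = numeric(0),
               n_segments = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(parsed$groups, function(g) {
      span <- sum(vapply(g$segs, function(si)
        sum(parsed$segments[[si]]$lengths), numeric(1))) +
        sum(parsed$junctions$gap_kb[g$amb_junctions])
      data.frame(code = g$code, span_kb = span,
                 n_segments = length(g$segs), stringsAsFactors = FALSE)
    }))
  }
  list(events = events,
       junctions = parsed$junctions[, c("gap_kb", "left_flank",
                                        "right_flank", "klass")])
}

#' Expected event counts for a fiber
#'
#' Weight-averaged counts of origins, terminations, forks and stalls over
#' all interpretations of the fiber's patterns. In `"probabilistic"` mode,
#' definite stalls (red/green junctions) are fixed and ambiguous patterns
#' are resolved with [enumerate_interpretations()] at stall probability
#' `s`; stall-disrupted origins are credited back. In `"naive"` mode the
#' simple pattern taxonomy is applied with no stall accounting: isolated
#' red events are terminations, junction context is ignored.
#'
#' @param f a [fiber()].
#' @param s apparent stall rate in `[0, 1]` (probabilistic mode).
#' @param mode `"probabilistic"` or `"naive"`.
#' @param exclude_ends if `TRUE`, the first and last event group of the
#'   fiber are dropped from the counts, the guard against combing
#'   artifacts at fiber ends.
#' @return Named numeric vector: `origins_p1`, `origins_p2`,
#'   `terminations_p1`, `terminations_p2`, `forks_p1`, `forks_p2`,
#'   `forks_total`, `stalls`.
#' @examples
#' f <- fiber(c("U","G","R","G","U","G","U"), c(50, 9, 5, 9, 40, 9, 50))
#' expected_event_counts(f, s = 0)  # one p1 origin, one p2 origin
#' @export
expected_event_counts <- function(f, s = 0,
                                  mode = c("probabilistic", "naive"),
                                  exclude_ends = FALSE) {
  stopifnot(inherits(f, "fiber"))
  mode <- match.arg(mode)
  parsed <- parse_fiber(f)
  groups <- parsed$groups
  if (length(groups) == 0L)
    return(stats::setNames(numeric(length(count_names)), count_names))
  if (exclude_ends && length(groups) > 0L) {
    firsts <- vapply(groups, function(g)
      min(vapply(g$segs, function(si) parsed$segments[[si]]$first, integer(1))),
      integer(1))
    ord <- order(firsts)
    drop <- c(ord[1L], ord[length(ord)])
    groups <- groups[-unique(drop)]
    if (length(groups) == 0L)
      return(stats::setNames(numeric(length(count_names)), count_names))
  }
  tot <- stats::setNames(numeric(length(count_names)), count_names)
  if (mode == "naive") {
    for (g in groups) for (si in g$segs)
      tot <- tot + segment_counts(parsed$segments[[si]]$labels, FALSE, FALSE)
    return(tot)
  }
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
    stop("s must be a single value in [0, 1]")
  for (g in groups) {
    interp <- enumerate_group(parsed, g, s)
    w <- interp$weight
    tot <- tot + colSums(as.matrix(interp[, count_names]) * w)
  }
  tot
}
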