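# Brute-force oracle for expected event counts: an independent
# implementation that enumerates every stall assignment exhaustively over
# each ambiguity group, computes event roles from closed-form per-segment
# formulas, collapses identical count signatures, and applies the s^k
# weighting with the remainder on the minimal-stall reading.

oracle_segment_counts <- function(p, l, r) {
  m <- length(p)
  if (m == 1L && p == "G")
    return(c(origins_p1 = 0, origins_p2 = 1, terminations_p1 = 0,
             terminations_p2 = 0, forks_p1 = 0, forks_p2 = 2,
             forks_total = 2, stalls = 0))
  if (m == 1L && p == "R") {
    k <- l + r
    v <- if (k == 0) c(0, 0, 1, 0, 2, 0, 2, 0) else
      if (k == 1) c(0, 0, 0, 0, 1, 0, 1, 1) else
        c(1, 0, 0, 0, 2, 0, 2, 2)
    names(v) <- c("origins_p1", "origins_p2", "terminations_p1",
                  "terminations_p2", "forks_p1", "forks_p2",
                  "forks_total", "stalls")
    return(v)
  }
  inner <- if (m > 2L) p[2:(m - 1L)] else character(0)
  iR <- sum(inner == "R"); iG <- sum(inner == "G")
  eL <- p[1L] == "R"; eR <- p[m] == "R"
  c(origins_p1 = iR + (eL && l) + (eR && r),
    origins_p2 = 0,
    terminations_p1 = 0,
    terminations_p2 = iG,
    forks_p1 = 2 * iR + eL * (1 + l) + eR * (1 + r),
    forks_p2 = 2 * iR + eL + eR,
    forks_total = 2 * iR + eL * (1 + l) + eR * (1 + r),
    stalls = (eL && l) + (eR && r))
}

oracle_expected_counts <- function(f, s) {
  labs <- f$labels
  n <- length(labs)
  zero <- c(origins_p1 = 0, origins_p2 = 0, terminations_p1 = 0,
            terminations_p2 = 0, forks_p1 = 0, forks_p2 = 0,
            forks_total = 0, stalls = 0)
  if (all(labs == "U")) return(zero)
  r <- rle(labs != "U")
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  segs <- which(r$values)
  pat <- lapply(segs, function(i) labs[lo[i]:hi[i]])
  nseg <- length(pat)
  # gap between consecutive segments k, k+1: "none" if adjacent runs of U
  # are absent (cannot happen), else classify by flanks
  gap_type <- character(max(nseg - 1L, 0))
  for (k in seq_len(nseg - 1L)) {
    lf <- labs[hi[segs[k]]]; rf <- labs[lo[segs[k + 1L]]]
    gap_type[k] <- if (lf == "R" && rf == "R") "RR" else
      if (lf == "G" && rf == "G") "GG" else "DEF"
  }
  # edge states: TRUE-fixed, variable, or inert
  # left edge of segment k faces gap k-1 (or fiber end), right edge gap k
  edge_state <- function(k, side) {
    p <- pat[[k]]
    lab <- if (side == "L") p[1L] else p[length(p)]
    if (lab != "R") return("inert")
    g <- if (side == "L") k - 1L else k
    if (g < 1L || g > nseg - 1L) return("free")  # fiber end context
    switch(gap_type[g], RR = "coupled", DEF = "fixed", GG = "inert")
  }
  # groups: consecutive segments joined by RR gaps
  grp <- cumsum(c(1L, as.integer(gap_type != "RR")))
  tot <- zero
  for (g in unique(grp)) {
    members <- which(grp == g)
    rr_gaps <- members[-length(members)]   # gap k joins k and k+1
    free <- list()
    for (k in members) for (side in c("L", "R"))
      if (edge_state(k, side) == "free")
        free[[length(free) + 1L]] <- c(k, side)
    nv <- length(rr_gaps) + length(free)
    grid <- if (nv == 0L) matrix(0L, 1L, 0L) else
      as.matrix(do.call(expand.grid, rep(list(0:1), nv)))
    sig <- character(nrow(grid)); cnts <- list(); kk <- integer(nrow(grid))
    for (a in seq_len(nrow(grid))) {
      gs <- if (length(rr_gaps) > 0) grid[a, seq_along(rr_gaps)] else integer(0)
      fs <- if (length(free) > 0)
        grid[a, length(rr_gaps) + seq_along(free)] else integer(0)
      acc <- zero
      for (k in members) {
        st <- c(L = FALSE, R = FALSE)
        for (side in c("L", "R")) {
          es <- edge_state(k, side)
          if (es == "fixed") st[side] <- TRUE
          else if (es == "coupled") {
            gidx <- if (side == "L") k - 1L else k
            st[side] <- gs[match(gidx, rr_gaps)] == 1L
          } else if (es == "free") {
            fidx <- which(vapply(free, function(z)
              identical(z, c(k, side)), logical(1)))
            st[side] <- fs[fidx] == 1L
          }
        }
        acc <- acc + oracle_segment_counts(pat[[k]], st["L"], st["R"])
      }
      sig[a] <- paste(acc, collapse = "|")
      cnts[[a]] <- acc
      kk[a] <- 2L * sum(gs) + sum(fs)
    }
    keep <- !duplicated(sig)
    cnts <- cnts[keep]; kk <- kk[keep]
    w <- ifelse(kk == 0L, 0, s^kk)
    w[kk == 0L] <- max(0, 1 - sum(w))
    if (sum(w) <= 0) w[which.min(kk)] <- 1
    w <- w / sum(w)
    for (a in seq_along(cnts)) tot <- tot + w[a] * cnts[[a]]
  }
  tot
}
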