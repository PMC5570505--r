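# Stochastic simulator of dual-pulse-labeled combing fibers with full
# ground truth. A linear genome replicates in continuous time: unfired
# origins fire as a Poisson process over unreplicated DNA, forks move at
# per-fork speeds, stall spontaneously per kb traversed or at lesions,
# and pause at non-stalling lesions. DNA replicated during the first
# pulse window is labeled red, during the second green. The molecule is
# then fragmented, optical resolution merging and measurement noise are
# applied, and fibers below the minimum length are flagged excluded.

#' Simulation configuration
#'
#' Defaults emulate the mid-S-phase fission-yeast labeling design: a
#' 5-minute red (CldU) pulse chased by a 10-minute green (IdU) pulse,
#' applied 10 minutes into the simulated replication so that pre-pulse
#' replicated (unlabeled) regions exist; ~25 Mb of genome; origin firing
#' at 2.3 origins/Mb/min over unreplicated DNA; fork speed 0.91 kb/min
#' with 10% between-fork CV; fragmentation to ~450 kb pieces with a
#' 120 kb analysis cutoff; 2 kb optical resolution and 2% multiplicative
#' length noise. The default spontaneous stall rate per kb traversed is
#' calibrated so that roughly 14% of first-pulse forks carry a detectable
#' stall, the spontaneous level seen in untreated cells.
#'
#' @param genome_mb simulated genome size, Mb.
#' @param origin_rate_per_mb_min origin firing rate I over unreplicated
#'   DNA, origins/Mb/min.
#' @param fork_speed_kb_min mean fork speed v, kb/min.
#' @param fork_speed_cv coefficient of variation of per-fork speed.
#' @param lesion_density_per_kb Poisson density of lesions, per kb.
#' @param p_stall_per_lesion probability a fork permanently stalls at a
#'   lesion it encounters.
#' @param pause_min_per_lesion pause duration (minutes) at a
#'   non-stalling lesion.
#' @param spontaneous_stall_per_kb rate of spontaneous permanent stalls
#'   per kb traversed.
#' @param sim_start_to_pulse1_min minutes of unlabeled replication before
#'   the first pulse.
#' @param pulse1_min,pulse2_min pulse durations, minutes.
#' @param fragment_mean_kb mean fragment length under Poisson shearing.
#' @param min_fiber_kb analysis length cutoff; shorter fibers are flagged
#'   excluded.
#' @param resolution_kb optical resolution: tracks and gaps shorter than
#'   this are merged into their longer neighbor.
#' @param length_noise_cv multiplicative measurement noise CV per track.
#' @param lesion_linked_breaks if `TRUE`, fragmentation cuts also occur
#'   at lesion sites (heat-labile lesions break during preparation).
#' @param seed integer seed; seeded runs are bit-reproducible.
#' @param dt_min integration time step, minutes; pulse boundaries must be
#'   multiples of it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(genome_mb = 25,
                       origin_rate_per_mb_min = 2.3,
                       fork_speed_kb_min = 0.91,
                       fork_speed_cv = 0.1,
                       lesion_density_per_kb = 0,
                       p_stall_per_lesion = 0,
                       pause_min_per_lesion = 0,
                       spontaneous_stall_per_kb = 0.022,
                       sim_start_to_pulse1_min = 10,
                       pulse1_min = 5,
                       pulse2_min = 10,
                       fragment_mean_kb = 450,
                       min_fiber_kb = 120,
                       resolution_kb = 2,
                       length_noise_cv = 0.02,
                       lesion_linked_breaks = FALSE,
                       seed = NULL,
                       dt_min = 0.05) {
  cfg <- list(genome_mb = genome_mb,
              origin_rate_per_mb_min = origin_rate_per_mb_min,
              fork_speed_kb_min = fork_speed_kb_min,
              fork_speed_cv = fork_speed_cv,
              lesion_density_per_kb = lesion_density_per_kb,
              p_stall_per_lesion = p_stall_per_lesion,
              pause_min_per_lesion = pause_min_per_lesion,
              spontaneous_stall_per_kb = spontaneous_stall_per_kb,
              sim_start_to_pulse1_min = sim_start_to_pulse1_min,
              pulse1_min = pulse1_min, pulse2_min = pulse2_min,
              fragment_mean_kb = fragment_mean_kb,
              min_fiber_kb = min_fiber_kb,
              resolution_kb = resolution_kb,
              length_noise_cv = length_noise_cv,
              lesion_linked_breaks = lesion_linked_breaks,
              seed = seed, dt_min = dt_min)
  pos <- c("genome_mb", "origin_rate_per_mb_min", "fork_speed_kb_min",
           "pulse1_min", "pulse2_min", "fragment_mean_kb", "dt_min")
  for (p in pos) if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
    stop(p, " must be positive")
  nonneg <- c("fork_speed_cv", "lesion_density_per_kb",
              "pause_min_per_lesion", "spontaneous_stall_per_kb",
              "sim_start_to_pulse1_min", "min_fiber_kb", "resolution_kb",
              "length_noise_cv")
  for (p in nonneg) if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
    stop(p, " must be non-negative")
  if (cfg$p_stall_per_lesion < 0 || cfg$p_stall_per_lesion > 1)
    stop("p_stall_per_lesion must be in [0, 1]")
  for (tt in c("sim_start_to_pulse1_min", "pulse1_min", "pulse2_min")) {
    k <- cfg[[tt]] / cfg$dt_min
    if (abs(k - round(k)) > 1e-8)
      stop(tt, " must be a multiple of dt_min")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %.1f Mb, I = %.2f origins/Mb/min, ",
                     "v = %.2f kb/min (cv %.2f)\n"),
              x$genome_mb, x$origin_rate_per_mb_min, x$fork_speed_kb_min,
              x$fork_speed_cv))
  cat(sprintf("  lesions %.3f/kb (p_stall %.3f, pause %.2f min), spontaneous stalls %.4f/kb\n",
              x$lesion_density_per_kb, x$p_stall_per_lesion,
              x$pause_min_per_lesion, x$spontaneous_stall_per_kb))
  invisible(x)
}

#' Damage presets
#'
#' Lesion regimes matching the three damaging agents' densities: MMS, one
#' lesion per kb (frequent, mild: short pauses and rare stalls); 4NQO,
#' one lesion per 25 kb (rare, severe: bulky adducts stall a larger
#' fraction of encountering forks); bleomycin, one break per 50 kb (rare;
#' leading-strand nick encounters collapse the fork). The per-lesion
#' stall probabilities and pause durations are effective values chosen to
#' reproduce the qualitative stall/slowing regimes, not measured
#' constants.
#'
#' @param config a base [sim_config()] to modify.
#' @param ... further `sim_config` fields to override.
#' @return A `"sim_config"`.
#' @name damage_presets
NULL

#' @rdname damage_presets
#' @export
mms_like <- function(config = sim_config(), ...) {
  preset_config(config, list(lesion_density_per_kb = 1.0,
                             p_stall_per_lesion = 0.04,
                             pause_min_per_lesion = 0.30), ...)
}

#' @rdname damage_presets
#' @export
nqo_like <- function(config = sim_config(), ...) {
  preset_config(config, list(lesion_density_per_kb = 0.04,
                             p_stall_per_lesion = 0.05,
                             pause_min_per_lesion = 0), ...)
}

#' @rdname damage_presets
#' @export
bleo_like <- function(config = sim_config(), ...) {
  preset_config(config, list(lesion_density_per_kb = 0.02,
                             p_stall_per_lesion = 0.5,
                             pause_min_per_lesion = 0), ...)
}

preset_config <- function(config, preset, ...) {
  stopifnot(inherits(config, "sim_config"))
  over <- list(...)
  args <- utils::modifyList(unclass(config), preset)
  args <- utils::modifyList(args, over)
  do.call(sim_config, args)
}

#' Simulate a labeled combing dataset
#'
#' Runs the continuous-time replication model of [sim_config()], labels
#' the simulated molecule, fragments it and measures the resulting fibers.
#' Returns both the fibers and the full ground truth (origins, fork
#' trajectories, stalls with detectability flags, lesion positions), so
#' every estimator can be validated against the generating parameters. A
#' stall is detectable only if it begins before the start of the second
#' pulse and persists to the end of labeling; stalled forks never restart
#' within the simulated window.
#'
#' @param config a [sim_config()].
#' @return A list with `fibers` (a [fiber_set()]) and `truth`, a list of
#'   class `"fiber_truth"` holding `origins`, `forks`, `stalls`,
#'   `lesions` data, the `config`, and a `summary` with `n_forks_p1`,
#'   `n_detectable_stalls` and `detectable_stall_fraction`.
#' @export
simulate_fibers <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_mb * 1000
  I_kb <- config$origin_rate_per_mb_min / 1000
  v <- config$fork_speed_kb_min
  cv <- config$fork_speed_cv
  q <- config$spontaneous_stall_per_kb
  dt <- config$dt_min
  t0 <- config$sim_start_to_pulse1_min
  t1e <- t0 + config$pulse1_min
  t2e <- t1e + config$pulse2_min
  nsteps <- round(t2e / dt)
  snap_p1s <- round(t0 / dt); snap_p1e <- round(t1e / dt)
  pause <- config$pause_min_per_lesion
  p_stall <- config$p_stall_per_lesion
  lesion_active <- config$lesion_density_per_kb > 0 &&
    (p_stall > 0 || pause > 0)

  lesions <- sort(stats::runif(stats::rpois(1, config$lesion_density_per_kb * L),
                               0, L))
  nles <- length(lesions)
  lesion_stall <- if (nles > 0) stats::runif(nles) < p_stall else logical(0)

  cap <- 4096L
  f_dir <- integer(cap); f_speed <- numeric(cap); f_pos <- numeric(cap)
  f_state <- integer(cap)  # 0 moving, 1 paused, 2 stalled, 3 dead
  f_pause_until <- numeric(cap); f_spont <- numeric(cap)
  f_birth_t <- numeric(cap); f_birth_pos <- numeric(cap)
  f_stall_t <- rep(NA_real_, cap); f_stall_type <- character(cap)
  f_death_t <- rep(NA_real_, cap)
  f_p1s <- rep(NA_real_, cap); f_p1e <- rep(NA_real_, cap)
  f_masked <- logical(cap); f_lptr <- integer(cap)
  nf <- 0L

  grow <- function() {
    cap2 <- 2L * cap
    f_dir <<- c(f_dir, integer(cap)); f_speed <<- c(f_speed, numeric(cap))
    f_pos <<- c(f_pos, numeric(cap)); f_state <<- c(f_state, integer(cap))
    f_pause_until <<- c(f_pause_until, numeric(cap))
    f_spont <<- c(f_spont, numeric(cap))
    f_birth_t <<- c(f_birth_t, numeric(cap))
    f_birth_pos <<- c(f_birth_pos, numeric(cap))
    f_stall_t <<- c(f_stall_t, rep(NA_real_, cap))
    f_stall_type <<- c(f_stall_type, character(cap))
    f_death_t <<- c(f_death_t, rep(NA_real_, cap))
    f_p1s <<- c(f_p1s, rep(NA_real_, cap))
    f_p1e <<- c(f_p1e, rep(NA_real_, cap))
    f_masked <<- c(f_masked, logical(cap))
    f_lptr <<- c(f_lptr, integer(cap))
    cap <<- cap2
  }

  new_fork <- function(x, dir, t) {
    if (nf + 1L > cap) grow()
    nf <<- nf + 1L
    sp <- stats::rnorm(1, v, cv * v)
    if (sp < 0.01 * v) sp <- 0.01 * v
    f_dir[nf] <<- dir; f_speed[nf] <<- sp; f_pos[nf] <<- x
    f_state[nf] <<- 0L; f_pause_until[nf] <<- 0
    f_spont[nf] <<- if (q > 0) stats::rexp(1, q) else Inf
    f_birth_t[nf] <<- t; f_birth_pos[nf] <<- x
    f_lptr[nf] <<- if (nles == 0L) 0L else
      if (dir > 0L) findInterval(x, lesions) + 1L else findInterval(x, lesions)
    nf
  }

  icap <- 4096L
  i_a <- numeric(icap); i_b <- numeric(icap)
  i_lf <- integer(icap); i_rf <- integer(icap); i_act <- logical(icap)
  ni <- 0L
  new_interval <- function(a, b, lf, rf) {
    if (ni + 1L > icap) {
      i_a <<- c(i_a, numeric(icap)); i_b <<- c(i_b, numeric(icap))
      i_lf <<- c(i_lf, integer(icap)); i_rf <<- c(i_rf, integer(icap))
      i_act <<- c(i_act, logical(icap)); icap <<- 2L * icap
    }
    ni <<- ni + 1L
    i_a[ni] <<- a; i_b[ni] <<- b; i_lf[ni] <<- lf; i_rf[ni] <<- rf
    i_act[ni] <<- TRUE
    ni
  }
  new_interval(0, L, 0L, 0L)

  origins <- list(); stalls <- list(); terminations <- list()

  stall_fork <- function(i, x, tm, type) {
    f_pos[i] <<- x; f_state[i] <<- 2L
    f_stall_t[i] <<- tm; f_stall_type[i] <<- type
    stalls[[length(stalls) + 1L]] <<-
      c(fork = i, pos = x, time = tm, lesion = as.numeric(type == "lesion"))
  }

  for (step in seq_len(nsteps)) {
    t <- (step - 1L) * dt
    # resume paused forks whose pause has elapsed
    paused <- which(f_state[seq_len(nf)] == 1L)
    if (length(paused) > 0) {
      done <- paused[f_pause_until[paused] <= t]
      if (length(done) > 0) f_state[done] <- 0L
    }
    # origin firing over unreplicated DNA
    act <- which(i_act[seq_len(ni)])
    lens <- i_b[act] - i_a[act]
    tot <- sum(lens)
    nfire <- stats::rpois(1, I_kb * tot * dt)
    if (nfire > 0) for (k in seq_len(nfire)) {
      act <- which(i_act[seq_len(ni)])
      lens <- i_b[act] - i_a[act]
      if (sum(lens) <= 0) break
      j <- if (length(act) == 1L) act else
        sample(act, 1L, prob = lens / sum(lens))
      x <- stats::runif(1, i_a[j], i_b[j])
      fl <- new_fork(x, -1L, t)   # leftward fork
      fr <- new_fork(x, +1L, t)   # rightward fork
      origins[[length(origins) + 1L]] <- c(pos = x, time = t, left = fl,
                                           right = fr)
      a <- i_a[j]; b <- i_b[j]; lf <- i_lf[j]; rf <- i_rf[j]
      i_act[j] <- FALSE
      new_interval(a, x, lf, fl)
      new_interval(x, b, fr, rf)
    }
    # advance moving forks
    mv <- which(f_state[seq_len(nf)] == 0L)
    if (length(mv) > 0) {
      stepd <- f_speed[mv] * dt
      dlesion <- rep(Inf, length(mv))
      if (lesion_active) {
        ptr <- f_lptr[mv]
        fw <- f_dir[mv] > 0L
        okf <- fw & ptr >= 1L & ptr <= nles
        dlesion[okf] <- lesions[ptr[okf]] - f_pos[mv[okf]]
        okb <- !fw & ptr >= 1L & ptr <= nles
        dlesion[okb] <- f_pos[mv[okb]] - lesions[ptr[okb]]
      }
      ev <- f_spont[mv] <= stepd | dlesion <= stepd
      plain <- mv[!ev]
      f_pos[plain] <- f_pos[plain] + f_dir[plain] * f_speed[plain] * dt
      f_spont[plain] <- f_spont[plain] - f_speed[plain] * dt
      for (i in mv[ev]) {
        rem <- f_speed[i] * dt
        tcur <- t
        while (rem > 1e-12 && f_state[i] == 0L) {
          dl <- Inf
          if (lesion_active && f_lptr[i] >= 1L && f_lptr[i] <= nles) {
            dl <- if (f_dir[i] > 0L) lesions[f_lptr[i]] - f_pos[i] else
              f_pos[i] - lesions[f_lptr[i]]
          }
          if (f_spont[i] <= min(dl, rem)) {
            x <- f_pos[i] + f_dir[i] * f_spont[i]
            stall_fork(i, x, tcur + f_spont[i] / f_speed[i], "spontaneous")
          } else if (dl <= rem) {
            li <- f_lptr[i]
            f_pos[i] <- lesions[li]
            tcur <- tcur + dl / f_speed[i]
            rem <- rem - dl
            f_spont[i] <- f_spont[i] - dl
            f_lptr[i] <- f_lptr[i] + f_dir[i]
            if (lesion_stall[li]) {
              stall_fork(i, lesions[li], tcur, "lesion")
            } else if (pause > 0) {
              f_state[i] <- 1L
              f_pause_until[i] <- tcur + pause
            }
          } else {
            f_pos[i] <- f_pos[i] + f_dir[i] * rem
            f_spont[i] <- f_spont[i] - rem
            rem <- 0
          }
        }
      }
    }
    # interval bookkeeping and collisions
    act <- which(i_act[seq_len(ni)])
    if (length(act) > 0) {
      prev_a <- i_a[act]; prev_b <- i_b[act]
      new_a <- prev_a; new_b <- prev_b
      hasl <- i_lf[act] > 0L; hasr <- i_rf[act] > 0L
      new_a[hasl] <- f_pos[i_lf[act][hasl]]
      new_b[hasr] <- f_pos[i_rf[act][hasr]]
      i_a[act] <- new_a; i_b[act] <- new_b
      closed <- which(new_a >= new_b - 1e-12)
      for (jj in closed) {
        j <- act[jj]
        dA <- new_a[jj] - prev_a[jj]; dB <- prev_b[jj] - new_b[jj]
        m <- if (dA + dB > 0)
          prev_a[jj] + (prev_b[jj] - prev_a[jj]) * dA / (dA + dB)
        else (prev_a[jj] + prev_b[jj]) / 2
        lf <- i_lf[j]; rf <- i_rf[j]
        died <- integer(0)
        for (fk in c(lf, rf)) {
          if (fk > 0L && f_state[fk] %in% c(0L, 1L)) {
            f_state[fk] <- 3L; f_pos[fk] <- m; f_death_t[fk] <- t + dt
            died <- c(died, fk)
          } else if (fk > 0L && f_state[fk] == 2L) {
            f_masked[fk] <- TRUE   # gap consumed by the converging fork
          }
        }
        if (length(died) > 0)
          terminations[[length(terminations) + 1L]] <-
            c(pos = m, time = t + dt, nforks = length(died))
        i_act[j] <- FALSE
      }
    }
    if (step == snap_p1s) f_p1s[seq_len(nf)] <- f_pos[seq_len(nf)]
    if (step == snap_p1e) f_p1e[seq_len(nf)] <- f_pos[seq_len(nf)]
  }

  idx <- seq_len(nf)
  p1s <- ifelse(is.na(f_p1s[idx]), f_birth_pos[idx], f_p1s[idx])
  p1e <- ifelse(is.na(f_p1e[idx]), f_birth_pos[idx], f_p1e[idx])
  p2e <- f_pos[idx]
  red <- cbind(pmin(p1s, p1e), pmax(p1s, p1e))
  green <- cbind(pmin(p1e, p2e), pmax(p1e, p2e))
  red_w <- red[, 2] - red[, 1]
  green_w <- green[, 2] - green[, 1]

  forks <- data.frame(
    fork = idx, dir = f_dir[idx], speed = f_speed[idx],
    birth_time = f_birth_t[idx], birth_pos = f_birth_pos[idx],
    final_pos = f_pos[idx],
    state = c("moving", "paused", "stalled", "terminated")[f_state[idx] + 1L],
    stall_time = f_stall_t[idx],
    stall_masked = f_masked[idx],
    death_time = f_death_t[idx],
    red_kb = red_w, green_kb = green_w)
  forks$p1_active <- red_w > 1e-9 |
    (forks$state == "stalled" & !is.na(forks$stall_time) &
       forks$stall_time < t1e)

  stalls_df <- if (length(stalls) > 0) {
    s <- as.data.frame(do.call(rbind, stalls))
    s$type <- ifelse(s$lesion > 0, "lesion", "spontaneous")
    s$lesion <- NULL
    s$detectable <- s$time < t1e   # begins before the second pulse starts
    s$masked <- f_masked[s$fork]
    s
  } else {
    data.frame(fork = integer(0), pos = numeric(0), time = numeric(0),
               type = character(0), detectable = logical(0),
               masked = logical(0))
  }
  origins_df <- if (length(origins) > 0)
    as.data.frame(do.call(rbind, origins)) else
    data.frame(pos = numeric(0), time = numeric(0), left = integer(0),
               right = integer(0))

  # label intervals along the genome
  red_iv <- merge_intervals(red[red_w > 1e-9, , drop = FALSE])
  green_iv <- merge_intervals(green[green_w > 1e-9, , drop = FALSE])

  # fragmentation
  ncut <- stats::rpois(1, L / config$fragment_mean_kb)
  cuts <- sort(stats::runif(ncut, 0, L))
  if (config$lesion_linked_breaks && nles > 0)
    cuts <- sort(c(cuts, lesions[stats::runif(nles) < 0.1]))
  bounds <- unique(c(0, cuts, L))
  nfib <- length(bounds) - 1L

  fibers <- vector("list", nfib)
  for (k in seq_len(nfib)) {
    tr <- build_tracks(bounds[k], bounds[k + 1L], red_iv, green_iv)
    tr <- merge_short_tracks(tr$labels, tr$lengths, config$resolution_kb)
    lens <- tr$lengths
    if (config$length_noise_cv > 0) {
      noise <- stats::rnorm(length(lens), 1, config$length_noise_cv)
      lens <- lens * pmax(noise, 0.01)
    }
    fibers[[k]] <- fiber(tr$labels, lens,
                         fiber_id = sprintf("sim_%04d", k),
                         dataset_id = "simulated",
                         min_fiber_kb = config$min_fiber_kb)
  }
  meta <- dataset_meta(pulse1_min = config$pulse1_min,
                       pulse2_min = config$pulse2_min,
                       treatment = "simulated", genotype = "simulated")
  fs <- fiber_set(fibers, meta)

  if (nrow(stalls_df) > 0)
    stalls_df$fiber <- findInterval(stalls_df$pos, bounds,
                                    rightmost.closed = TRUE)
  if (nrow(origins_df) > 0)
    origins_df$fiber <- findInterval(origins_df$pos, bounds,
                                     rightmost.closed = TRUE)

  n_p1 <- sum(forks$p1_active)
  n_det <- sum(stalls_df$detectable)
  truth <- structure(list(
    origins = origins_df, forks = forks, stalls = stalls_df,
    lesions = data.frame(pos = lesions, stall = lesion_stall),
    fragment_bounds = bounds,
    config = config,
    summary = list(
      n_origins = nrow(origins_df),
      n_forks = nf,
      n_forks_p1 = n_p1,
      n_detectable_stalls = n_det,
      detectable_stall_fraction = if (n_p1 > 0) n_det / n_p1 else NA_real_,
      replicated_fraction = 1 - (sum(i_b[which(i_act[seq_len(ni)])] -
                                       i_a[which(i_act[seq_len(ni)])]) / L))),
    class = "fiber_truth")
  list(fibers = fs, truth = truth)
}

#' @export
print.fiber_truth <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<fiber_truth> %d origins, %d forks (%d in pulse 1), ",
                     "%d detectable stalls\n  detectable stall fraction %.3f, ",
                     "replicated fraction %.3f\n"),
              s$n_origins, s$n_forks, s$n_forks_p1, s$n_detectable_stalls,
              s$detectable_stall_fraction, s$replicated_fraction))
  invisible(x)
}

# merge sorted/overlapping intervals (matrix of lo, hi)
merge_intervals <- function(m, tol = 1e-6) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  lo <- m[, 1]; hi <- m[, 2]
  out_lo <- lo[1]; out_hi <- hi[1]
  res <- list()
  for (i in seq_len(nrow(m))[-1]) {
    if (lo[i] <= out_hi + tol) {
      out_hi <- max(out_hi, hi[i])
    } else {
      res[[length(res) + 1L]] <- c(out_lo, out_hi)
      out_lo <- lo[i]; out_hi <- hi[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_lo, out_hi)
  do.call(rbind, res)
}

# overlay red/green intervals on a fragment, return alternating tracks
build_tracks <- function(a, b, red_iv, green_iv, tol = 1e-9) {
  clip <- function(m) {
    if (nrow(m) == 0L) return(m)
    lo <- pmax(m[, 1], a); hi <- pmin(m[, 2], b)
    keep <- hi - lo > tol
    cbind(lo[keep], hi[keep])
  }
  r <- clip(red_iv); g <- clip(green_iv)
  iv <- rbind(if (nrow(r) > 0) cbind(r, 1) else NULL,
              if (nrow(g) > 0) cbind(g, 2) else NULL)
  if (is.null(iv) || nrow(iv) == 0L)
    return(list(labels = "U", lengths = b - a))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  labels <- character(0); lengths <- numeric(0)
  cur <- a
  for (i in seq_len(nrow(iv))) {
    lo <- iv[i, 1]; hi <- iv[i, 2]
    if (lo - cur > tol) {
      labels <- c(labels, "U"); lengths <- c(lengths, lo - cur)
    }
    labels <- c(labels, c("R", "G")[iv[i, 3]])
    lengths <- c(lengths, hi - max(lo, cur))
    cur <- max(cur, hi)
  }
  if (b - cur > tol) {
    labels <- c(labels, "U"); lengths <- c(lengths, b - cur)
  }
  list(labels = labels, lengths = lengths)
}

# Optical resolution model. Resolution limits the separation of nearby
# objects, not the detection of a bright punctum on a dark background:
# sub-resolution unlabeled gaps are invisible (interior gaps are absorbed
# into a flanking track, fiber-end slivers are trimmed) and a
# sub-resolution labeled track adjacent to another labeled track cannot
# be resolved from it (absorbed into the longer labeled neighbor), but an
# isolated labeled punctum flanked by unlabeled DNA stays visible.
merge_short_tracks <- function(labels, lengths, resolution_kb) {
  if (resolution_kb <= 0) return(list(labels = labels, lengths = lengths))
  repeat {
    n <- length(labels)
    if (n <= 1L) break
    is_short <- lengths < resolution_kb
    labeled_nb <- (c(FALSE, labels[-n] != "U") |
                     c(labels[-1L] != "U", FALSE))
    cand <- which(is_short & (labels == "U" | labeled_nb))
    if (length(cand) == 0L) break
    i <- cand[which.min(lengths[cand])]
    if (labels[i] == "U" && (i == 1L || i == n)) {
      labels <- labels[-i]; lengths <- lengths[-i]
    } else {
      if (labels[i] == "U") {
        nb <- if (i == 1L) 2L else if (i == n) n - 1L else
          if (lengths[i - 1L] >= lengths[i + 1L]) i - 1L else i + 1L
      } else {
        opts <- c(if (i > 1L && labels[i - 1L] != "U") i - 1L,
                  if (i < n && labels[i + 1L] != "U") i + 1L)
        nb <- opts[which.max(lengths[opts])]
      }
      lengths[nb] <- lengths[nb] + lengths[i]
      labels <- labels[-i]; lengths <- lengths[-i]
    }
    # re-merge equal-label neighbors
    grp <- cumsum(c(TRUE, labels[-1L] != labels[-length(labels)]))
    lengths <- as.numeric(tapply(lengths, grp, sum))
    labels <- labels[!duplicated(grp)]
  }
  list(labels = labels, lengths = lengths)
}
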