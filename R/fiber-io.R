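#' Construct a single combed fiber
#'
#' A fiber is an ordered sequence of labeled tracks measured along a combed
#' DNA molecule, read left to right. Each track carries a label --
#' `"R"` (red, CldU, first analog pulse), `"G"` (green, IdU, second analog
#' pulse) or `"U"` (unlabeled) -- and a length in kb. Consecutive tracks
#' with the same label are merged on construction, so a valid fiber always
#' alternates labels.
#'
#' @param labels character vector of track labels, each one of `"R"`, `"G"`,
#'   `"U"`.
#' @param lengths_kb numeric vector of track lengths in kb; all must be
#'   strictly positive.
#' @param fiber_id identifier for this fiber.
#' @param dataset_id identifier for the dataset the fiber belongs to.
#' @param min_fiber_kb minimum analyzable fiber length in kb. Shorter fibers
#'   are retained but flagged `excluded`, so excluded counts remain
#'   reportable; downstream estimators skip them.
#' @return An object of class `"fiber"`: a list with elements `fiber_id`,
#'   `dataset_id`, `labels`, `lengths_kb`, `total_kb` and `excluded`.
#' @examples
#' f <- fiber(c("U", "R", "G"), c(50, 4, 9))
#' f$total_kb    # 63
#' f$excluded    # TRUE: below the 120 kb cutoff
#' @export
fiber <- function(labels, lengths_kb, fiber_id = "fiber1",
                  dataset_id = "dataset1", min_fiber_kb = 120) {
  labels <- as.character(labels)
  lengths_kb <- as.numeric(lengths_kb)
  if (length(labels) != length(lengths_kb))
    stop("labels and lengths_kb must have the same length")
  if (length(labels) == 0L)
    stop("a fiber must contain at least one track")
  bad <- !labels %in% c("R", "G", "U")
  if (any(bad))
    stop("unknown label code(s): ", paste(unique(labels[bad]), collapse = ", "),
         " (expected R, G or U)")
  if (any(!is.finite(lengths_kb)) || any(lengths_kb <= 0))
    stop("all track lengths must be finite and > 0 kb")
  # merge equal-label neighbors: lengths are additive
  grp <- cumsum(c(TRUE, labels[-1L] != labels[-length(labels)]))
  lengths_kb <- as.numeric(tapply(lengths_kb, grp, sum))
  labels <- labels[!duplicated(grp)]
  total <- sum(lengths_kb)
  structure(
    list(fiber_id = as.character(fiber_id),
         dataset_id = as.character(dataset_id),
         labels = labels,
         lengths_kb = lengths_kb,
         total_kb = total,
         excluded = total < min_fiber_kb),
    class = "fiber")
}

#' @export
print.fiber <- function(x, ...) {
  cat(sprintf("<fiber %s> %s, %.1f kb%s\n  %s\n",
              x$fiber_id, x$dataset_id, x$total_kb,
              if (x$excluded) " [excluded]" else "",
              paste(x$labels, collapse = "")))
  invisible(x)
}

#' Dataset metadata for a combing experiment
#'
#' Pulse durations and sample annotation for a fiber dataset. The defaults
#' match the canonical labeling design: a 5-minute CldU (red) pulse chased
#' with a 10-minute IdU (green) pulse in mid-S-phase fission yeast cells.
#'
#' @param pulse1_min duration of the first (red) analog pulse, minutes.
#' @param pulse2_min duration of the second (green) analog pulse, minutes.
#' @param treatment free-text treatment annotation.
#' @param genotype free-text genotype annotation.
#' @param stretch_kb_per_pixel optional kb-per-pixel conversion factor used
#'   when the fiber table carries pixel lengths.
#' @return An object of class `"dataset_meta"`.
#' @export
dataset_meta <- function(pulse1_min = 5, pulse2_min = 10,
                         treatment = "untreated", genotype = "wild-type",
                         stretch_kb_per_pixel = NULL) {
  if (!is.numeric(pulse1_min) || pulse1_min <= 0 ||
      !is.numeric(pulse2_min) || pulse2_min <= 0)
    stop("pulse durations must be positive")
  structure(list(pulse1_min = pulse1_min, pulse2_min = pulse2_min,
                 treatment = treatment, genotype = genotype,
                 stretch_kb_per_pixel = stretch_kb_per_pixel),
            class = "dataset_meta")
}

#' Read dataset metadata from a YAML file
#'
#' @param path path to a YAML file with any of the fields of
#'   [dataset_meta()].
#' @return A `"dataset_meta"` object.
#' @export
read_dataset_meta <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(dataset_meta))
  do.call(dataset_meta, y[intersect(names(y), known)])
}

#' Bundle fibers into a fiber set
#'
#' @param fibers a list of [fiber()] objects.
#' @param meta a [dataset_meta()] object attached to the set.
#' @return An object of class `"fiber_set"`: a list of fibers with a
#'   `meta` attribute.
#' @export
fiber_set <- function(fibers, meta = dataset_meta()) {
  if (inherits(fibers, "fiber")) fibers <- list(fibers)
  ok <- vapply(fibers, inherits, logical(1), what = "fiber")
  if (!all(ok)) stop("all elements must be fiber objects")
  structure(fibers, class = "fiber_set", meta = meta)
}

#' @export
print.fiber_set <- function(x, ...) {
  excl <- vapply(x, `[[`, logical(1), "excluded")
  tot <- sum(vapply(x, `[[`, numeric(1), "total_kb"))
  cat(sprintf("<fiber_set> %d fibers (%d excluded < min length), %.2f Mb total\n",
              length(x), sum(excl), tot / 1000))
  invisible(x)
}

#' @export
`[.fiber_set` <- function(x, i) {
  structure(unclass(x)[i], class = "fiber_set", meta = attr(x, "meta"))
}

fiber_set_meta <- function(fibers) {
  m <- attr(fibers, "meta")
  if (is.null(m)) m <- dataset_meta()
  m
}

#' Read a fiber track table
#'
#' Reads the tab-separated fiber dialect: one row per track with columns
#' `dataset_id`, `fiber_id`, `track_index`, `label` and `length_kb`
#' (header required). `label` must be `R`, `G` or `U`; `track_index` is
#' 1-based and strictly increasing within a fiber. An optional `length_px`
#' column is converted to kb with `meta$stretch_kb_per_pixel` when
#' `length_kb` is absent. Tracks sharing a label with their neighbor are
#' merged; fibers shorter than `min_fiber_kb` are flagged `excluded`, not
#' dropped. File order of fibers and tracks is preserved.
#'
#' @param path path to the TSV file.
#' @param meta a [dataset_meta()] object.
#' @param min_fiber_kb minimum analyzable fiber length (kb).
#' @return A [fiber_set()].
#' @export
read_fibers <- function(path, meta = dataset_meta(), min_fiber_kb = 120) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("dataset_id", "fiber_id", "track_index", "label")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("fiber table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"length_kb" %in% names(d)) {
    if (!"length_px" %in% names(d))
      stop("fiber table must carry a length_kb or length_px column")
    if (is.null(meta$stretch_kb_per_pixel))
      stop("length_px column present but meta$stretch_kb_per_pixel is not set")
    d$length_kb <- as.numeric(d$length_px) * meta$stretch_kb_per_pixel
  }
  n <- nrow(d)
  if (n == 0L) stop("fiber table contains no rows")
  line_no <- seq_len(n) + 1L  # header is line 1
  len <- suppressWarnings(as.numeric(d$length_kb))
  idx <- suppressWarnings(as.integer(d$track_index))
  bad <- which(is.na(len) | is.na(idx) | d$fiber_id == "" | d$dataset_id == "")
  if (length(bad) > 0)
    stop("malformed fiber table row at line ", line_no[bad[1L]])
  bad <- which(!d$label %in% c("R", "G", "U"))
  if (length(bad) > 0)
    stop("unknown label code '", d$label[bad[1L]], "' at line ", line_no[bad[1L]])
  bad <- which(len <= 0)
  if (length(bad) > 0)
    stop("non-positive track length at line ", line_no[bad[1L]])
  key <- paste(d$dataset_id, d$fiber_id, sep = "\r")
  fibers <- vector("list", length(unique(key)))
  names(fibers) <- unique(key)
  for (k in unique(key)) {
    rows <- which(key == k)
    ord <- idx[rows]
    if (any(diff(ord) <= 0))
      stop("track_index not strictly increasing for fiber '",
           d$fiber_id[rows[1L]], "' (line ", line_no[rows[which(diff(ord) <= 0)[1L] + 1L]], ")")
    fibers[[k]] <- fiber(d$label[rows], len[rows],
                         fiber_id = d$fiber_id[rows[1L]],
                         dataset_id = d$dataset_id[rows[1L]],
                         min_fiber_kb = min_fiber_kb)
  }
  names(fibers) <- NULL
  fiber_set(fibers, meta)
}

#' Write a fiber set to the TSV track dialect
#'
#' Lengths are written in kb at 3-decimal precision, the stored precision of
#' combing measurements.
#'
#' @param fibers a [fiber_set()] or list of fibers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fibers <- function(fibers, path) {
  rows <- lapply(fibers, function(f) {
    data.frame(dataset_id = f$dataset_id, fiber_id = f$fiber_id,
               track_index = seq_along(f$labels), label = f$labels,
               length_kb = sprintf("%.3f", f$lengths_kb),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert pixel measurements to kb using a lambda DNA standard
#'
#' Combed fibers are measured in pixels and calibrated against co-combed
#' lambda phage DNA of known length (48.502 kb).
#'
#' @param length_px measured length in pixels (vectorized).
#' @param lambda_px measured pixel length of the lambda DNA standard.
#' @param lambda_kb physical length of the standard; the lambda genome,
#'   48.502 kb.
#' @return Length(s) in kb: `length_px * lambda_kb / lambda_px`.
#' @examples
#' pixels_to_kb(100, 100)  # 48.502
#' @export
pixels_to_kb <- function(length_px, lambda_px, lambda_kb = 48.502) {
  if (any(!is.finite(length_px)) || any(length_px <= 0))
    stop("length_px must be positive")
  if (any(!is.finite(lambda_px)) || any(lambda_px <= 0))
    stop("lambda_px must be positive")
  if (!is.finite(lambda_kb) || lambda_kb <= 0)
    stop("lambda_kb must be positive")
  length_px * lambda_kb / lambda_px
}

# Sum of unlabeled track lengths: the normalizer for origin firing rate,
# fork density and stalls/kb. Conflates pre-pulse-replicated DNA with
# truly unreplicated DNA, as the assay cannot distinguish them.
unreplicated_kb <- function(f) sum(f$lengths_kb[f$labels == "U"])
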