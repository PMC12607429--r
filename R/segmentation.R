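# Sliding-window segmentation, majority labelling, and curation of
# behaviourally pure events for leakage-safe splitting.

#' Windowing parameters
#'
#' Defaults follow the motivating protocol: a 2.6 s window (130 samples at
#' 50 Hz) aligned with the mean spin-event duration, a 1.3 s stride (50%
#' overlap), and an inclusive 50% majority labelling rule.
#'
#' @param window_size window length, seconds.
#' @param stride hop between consecutive window starts, seconds.
#' @param label_fraction a window is labelled spinning iff at least this
#'   fraction of its samples lie inside an annotated spin interval
#'   (inclusive).
#' @return an object of class `windowing_params`.
#' @export
windowing_params <- function(window_size = 2.6, stride = 1.3,
                             label_fraction = 0.5) {
  if (!(stride > 0 && stride <= window_size)) {
    stop("stride must satisfy 0 < stride <= window_size", call. = FALSE)
  }
  if (!(label_fraction > 0 && label_fraction <= 1)) {
    stop("label_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(window_size = window_size, stride = stride,
                 label_fraction = label_fraction),
            class = "windowing_params")
}

#' Window length in samples
#' @param params a [windowing_params()].
#' @param sampling_rate Hz.
#' @export
window_samples <- function(params, sampling_rate) {
  as.integer(round(params$window_size * sampling_rate))
}

#' Stride in samples
#' @param params a [windowing_params()].
#' @param sampling_rate Hz.
#' @export
stride_samples <- function(params, sampling_rate) {
  max(1L, as.integer(round(params$stride * sampling_rate)))
}

new_segment_set <- function(data, info, sampling_rate, params) {
  structure(list(data = data, info = info, sampling_rate = sampling_rate,
                 params = params),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segment(s) of %d samples x 6 channels (%d spinning)\n",
              n_segments(x), dim(x$data)[2],
              sum(x$info$label == LABEL_SPIN)))
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs a `segment_set`.
#' @export
n_segments <- function(segs) dim(segs$data)[1]

#' Labels of a segment set
#' @param segs a `segment_set`.
#' @return character vector, `"spinning"` / `"non_spinning"`.
#' @export
segment_labels <- function(segs) segs$info$label

#' Segment a recording with a sliding window
#'
#' Windows start at the first sample and advance by the stride while fully
#' inside the stream; the trailing partial window is dropped. Each window is
#' labelled spinning iff the fraction of ground-truth-positive samples in it
#' is at least `label_fraction` (a window with exactly half its samples
#' inside a spin is spinning).
#'
#' @param rec an [imu_recording()].
#' @param mask logical per-sample ground-truth mask (see
#'   [annotations_to_mask()]); `NULL` for unlabelled data (all windows
#'   labelled non-spinning).
#' @param params a [windowing_params()].
#' @param event_id optional provenance identifier stamped on every segment.
#' @param start_offset sample offset (0-based, added to `start_sample`
#'   provenance) when `rec` is a slice of a longer stream.
#' @return a `segment_set`: a `[n_segments, window_samples, 6]` data array
#'   plus an `info` data.frame (subject_id, start_sample, label, event_id,
#'   positive_fraction).
#' @export
segment_stream <- function(rec, mask = NULL, params = windowing_params(),
                           event_id = NA_character_, start_offset = 0L) {
  fs <- rec$sampling_rate
  w <- window_samples(params, fs)
  s <- stride_samples(params, fs)
  n <- n_samples(rec)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length must equal trace length", call. = FALSE)
  if (n < w) {
    warning("stream shorter than one window; returning empty segment set")
    data <- array(numeric(0), dim = c(0, w, 6),
                  dimnames = list(NULL, NULL, imu_channels()))
    info <- data.frame(subject_id = character(0), start_sample = integer(0),
                       label = character(0), event_id = character(0),
                       positive_fraction = numeric(0))
    return(new_segment_set(data, info, fs, params))
  }
  starts <- seq.int(1L, n - w + 1L, by = s)  # 1-based first sample
  k <- length(starts)
  data <- array(NA_real_, dim = c(k, w, 6),
                dimnames = list(NULL, NULL, imu_channels()))
  frac <- numeric(k)
  for (i in seq_len(k)) {
    idx <- starts[i]:(starts[i] + w - 1L)
    data[i, , ] <- rec$data[idx, ]
    frac[i] <- sum(mask[idx]) / w
  }
  info <- data.frame(
    subject_id = rep(rec$subject_id, k),
    start_sample = as.integer(starts - 1L + start_offset),
    label = ifelse(frac >= params$label_fraction, LABEL_SPIN, LABEL_NONSPIN),
    event_id = rep(as.character(event_id), k),
    positive_fraction = frac,
    stringsAsFactors = FALSE)
  new_segment_set(data, info, fs, params)
}

# Concatenate segment sets (same window geometry).
bind_segment_sets <- function(sets) {
  sets <- Filter(function(s) n_segments(s) > 0, sets)
  if (length(sets) == 0L) stop("no segments to bind", call. = FALSE)
  w <- dim(sets[[1]]$data)[2]
  data <- do.call(abind3, sets)
  info <- do.call(rbind, lapply(sets, `[[`, "info"))
  rownames(info) <- NULL
  new_segment_set(data, info, sets[[1]]$sampling_rate, sets[[1]]$params)
}

abind3 <- function(...) {
  sets <- list(...)
  mats <- lapply(sets, `[[`, "data")
  ns <- vapply(mats, function(m) dim(m)[1], integer(1))
  out <- array(NA_real_, dim = c(sum(ns), dim(mats[[1]])[2], 6),
               dimnames = list(NULL, NULL, imu_channels()))
  at <- 0L
  for (m in mats) {
    if (dim(m)[1] > 0) out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

# Subset a segment set by row index.
subset_segments <- function(segs, idx) {
  new_segment_set(segs$data[idx, , , drop = FALSE],
                  segs$info[idx, , drop = FALSE],
                  segs$sampling_rate, segs$params)
}

#' Curate behaviourally pure events
#'
#' Partitions a recording into non-overlapping fixed-length events, each
#' behaviourally pure: a `spin` event contains one or more complete annotated
#' spin intervals and no partial spin at its boundaries; a `non_spin` event
#' overlaps no spin interval at all. Spin events are centred on their
#' annotated interval when possible, otherwise shifted to restore purity, and
#' dropped when no pure placement exists. Spin intervals longer than
#' `event_length` are excluded with a warning. Non-spin events are tiled over
#' the spin-free stretches with a seeded random offset per stretch.
#'
#' @param rec an [imu_recording()].
#' @param ann an [annotation_track()].
#' @param event_length event duration, seconds (default 7.8 s = 3 windows).
#' @param seed seed for the non-spin tiling offsets.
#' @return data.frame of class `curated_events` with columns `subject_id`,
#'   `event_id`, `start_s`, `end_s`, `class`.
#' @export
curate_events <- function(rec, ann, event_length = 7.8, seed = 1) {
  dur <- recording_duration(rec)
  if (event_length <= 0 || event_length > dur) {
    stop("event_length must be positive and fit in the recording", call. = FALSE)
  }
  fs <- rec$sampling_rate
  # event spans are snapped to the sample grid so every event slices to the
  # same whole number of samples (and hence the same window count)
  L_samp <- round(event_length * fs)
  event_length <- L_samp / fs
  max_start <- (n_samples(rec) - L_samp) / fs
  iv <- ann$intervals
  spans <- data.frame(start_s = numeric(0), end_s = numeric(0))

  is_pure_spin_span <- function(a, b, focal) {
    if (a < 0 || b > dur) return(FALSE)
    if (!(iv$start_s[focal] >= a && iv$end_s[focal] <= b)) return(FALSE)
    for (k in seq_len(nrow(iv))) {
      inside <- iv$start_s[k] >= a && iv$end_s[k] <= b
      outside <- iv$end_s[k] <= a || iv$start_s[k] >= b
      if (!inside && !outside) return(FALSE)
    }
    if (nrow(spans) > 0 && any(a < spans$end_s & b > spans$start_s)) return(FALSE)
    TRUE
  }

  dropped <- 0L
  for (k in seq_len(nrow(iv))) {
    len_k <- iv$end_s[k] - iv$start_s[k]
    if (len_k > event_length) {
      warning(sprintf("spin interval %d (%.2f s) exceeds event_length; excluded",
                      k, len_k))
      next
    }
    mid <- (iv$start_s[k] + iv$end_s[k]) / 2
    candidates <- c(mid - event_length / 2,            # centred
                    iv$start_s[k] - 0.1,               # anchored at onset
                    iv$end_s[k] + 0.1 - event_length)  # anchored at offset
    placed <- FALSE
    for (a in candidates) {
      a <- round(min(max(a, 0), max_start) * fs) / fs
      if (is_pure_spin_span(a, a + event_length, k)) {
        spans <- rbind(spans, data.frame(start_s = a, end_s = a + event_length))
        placed <- TRUE
        break
      }
    }
    if (!placed) dropped <- dropped + 1L
  }
  if (dropped > 0L) {
    message(sprintf("curate_events: %d spin interval(s) had no pure placement and were dropped",
                    dropped))
  }
  spin_spans <- spans

  # spin-free stretches: complement of (annotated intervals union spin spans)
  occ <- rbind(iv[, c("start_s", "end_s")], spin_spans)
  occ <- occ[order(occ$start_s), , drop = FALSE]
  free <- data.frame(start_s = numeric(0), end_s = numeric(0))
  pos <- 0
  for (k in seq_len(nrow(occ))) {
    if (occ$start_s[k] > pos) {
      free <- rbind(free, data.frame(start_s = pos, end_s = occ$start_s[k]))
    }
    pos <- max(pos, occ$end_s[k])
  }
  if (pos < dur) free <- rbind(free, data.frame(start_s = pos, end_s = dur))

  non_spans <- with_seed(seed, {
    out <- data.frame(start_s = numeric(0), end_s = numeric(0))
    for (k in seq_len(nrow(free))) {
      len <- free$end_s[k] - free$start_s[k]
      m <- floor(len / event_length)
      if (m < 1) next
      offset <- stats::runif(1, 0, len - m * event_length)
      base <- ceiling((free$start_s[k] + offset) * fs) / fs  # grid-aligned
      m <- floor((free$end_s[k] - base + 1e-9) / event_length)
      if (m < 1) next
      a <- base + (seq_len(m) - 1) * event_length
      out <- rbind(out, data.frame(start_s = a, end_s = a + event_length))
    }
    out
  })

  mk <- function(spans, cls) {
    if (nrow(spans) == 0L) {
      return(data.frame(subject_id = character(0), event_id = character(0),
                        start_s = numeric(0), end_s = numeric(0),
                        class = character(0)))
    }
    data.frame(subject_id = rec$subject_id,
               event_id = sprintf("%s_%s_%03d", rec$subject_id, cls,
                                  seq_len(nrow(spans))),
               start_s = spans$start_s, end_s = spans$end_s,
               class = cls, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(spin_spans, EVENT_SPIN), mk(non_spans, EVENT_NONSPIN))
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("curated_events", "data.frame")
  out
}

#' Stratified event-level train/test split
#'
#' Splits curated events into event-disjoint train and test partitions.
#' Under stratification the class proportions are preserved to within one
#' event per class. Deterministic per seed.
#'
#' @param events a `curated_events` data.frame (possibly pooled over
#'   subjects).
#' @param ratio training fraction (default 0.8).
#' @param stratify preserve class proportions (default `TRUE`).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_events <- function(events, ratio = 0.8, stratify = TRUE, seed = 1) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)", call. = FALSE)
  if (stratify) {
    counts <- table(events$class)
    if (length(counts) < 2L) {
      stop("stratified split needs at least one event of each class",
           call. = FALSE)
    }
    if (any(counts < 2L)) {
      stop("a class has fewer than 2 events; use stratify = FALSE",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    pick_train <- logical(nrow(events))
    groups <- if (stratify) split(seq_len(nrow(events)), events$class) else
      list(all = seq_len(nrow(events)))
    for (g in groups) {
      n_tr <- round(ratio * length(g))
      n_tr <- min(max(n_tr, 1L), length(g) - 1L)
      pick_train[sample(g, n_tr)] <- TRUE
    }
    list(train = events[pick_train, , drop = FALSE],
         test = events[!pick_train, , drop = FALSE])
  })
}

#' Extract labelled segments from curated events
#'
#' Slices each event span out of its subject's recording, segments it with
#' the sliding window, labels windows against the subject's annotations, and
#' stamps each segment with the event's identifier (the provenance used by
#' the leakage audits).
#'
#' @param study an `imu_study` (or named list of `list(recording,
#'   annotations)`).
#' @param events a `curated_events` data.frame.
#' @param params a [windowing_params()].
#' @return a pooled `segment_set`.
#' @export
segments_from_events <- function(study, events, params = windowing_params()) {
  sets <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    sub <- events$subject_id[i]
    pair <- study[[sub]]
    if (is.null(pair)) stop("unknown subject in events: ", sub, call. = FALSE)
    rec <- pair$recording
    fs <- rec$sampling_rate
    a <- round(events$start_s[i] * fs)   # 0-based
    # slice length from the event duration so equal-length events always
    # yield the same window count regardless of grid alignment
    b <- min(a + round((events$end_s[i] - events$start_s[i]) * fs),
             n_samples(rec))
    slice <- imu_recording(rec$data[(a + 1):b, , drop = FALSE], fs,
                           rec$subject_id, units = rec$units)
    mask <- annotations_to_mask(rec, pair$annotations)[(a + 1):b]
    sets[[i]] <- segment_stream(slice, mask, params,
                                event_id = events$event_id[i],
                                start_offset = a)
  }
  bind_segment_sets(sets)
}
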