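# Shared fixtures and independent oracles, built in code at test time.

# A small, fast study configuration.
small_config <- function(seed = 7, ...) {
  simulation_config(n_subjects = 2, events_per_subject = c(5, 3),
                    background_minutes = 2, seed = seed, ...)
}

# Noise-free configuration: the separability regime where the gyro-magnitude
# heuristic has a perfect threshold.
noiseless_config <- function(seed = 11) {
  simulation_config(n_subjects = 3, events_per_subject = c(6, 5, 4),
                    background_minutes = 3,
                    noise_sd_accel = 0, noise_sd_gyro = 0,
                    duration_min = 1.8, duration_max = 3.4,
                    duration_mean = 2.58, seed = seed)
}

# Brute-force O(n^2) DFT periodogram, independent of stats::fft.
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  kmax <- floor(n / 2)
  power <- vapply(seq_len(kmax), function(k) {
    w <- 2 * pi * k * (0:(n - 1)) / n
    Mod(sum(x * complex(real = cos(w), imaginary = -sin(w))))^2
  }, numeric(1))
  data.frame(freq = seq_len(kmax) * fs / n, power = power)
}

# Brute-force sliding-window enumerator: start indices (1-based) of all
# full windows.
oracle_window_starts <- function(n, w, s) {
  starts <- integer(0)
  a <- 1L
  while (a + w - 1L <= n) {
    starts <- c(starts, a)
    a <- a + s
  }
  starts
}

# Exhaustive heuristic-threshold scan: maximum attainable spin-class F1 over
# all real thresholds (F1 changes only at observed values).
oracle_best_f1 <- function(values, labels) {
  pos <- labels == "spinning"
  cand <- sort(unique(c(values - 1e-9, values, values + 1e-9, -Inf, Inf)))
  max(vapply(cand, function(th) {
    pred <- values > th
    tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1)))
}

# Purity audit: TRUE iff every emitted event is behaviourally pure w.r.t.
# the annotated intervals.
oracle_events_pure <- function(events, intervals) {
  for (i in seq_len(nrow(events))) {
    a <- events$start_s[i]; b <- events$end_s[i]
    complete <- 0L
    for (k in seq_len(nrow(intervals))) {
      inside <- intervals$start_s[k] >= a && intervals$end_s[k] <= b
      outside <- intervals$end_s[k] <= a || intervals$start_s[k] >= b
      if (!inside && !outside) return(FALSE)        # partial spin at boundary
      if (inside) complete <- complete + 1L
    }
    if (events$class[i] == "spin" && complete < 1L) return(FALSE)
    if (events$class[i] == "non_spin" && complete > 0L) return(FALSE)
  }
  TRUE
}
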