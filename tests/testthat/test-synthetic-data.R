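# Simulator: duration sampling, spin kinematics, study assembly.

test_that("event durations follow the truncated-normal specification", {
  cfg <- simulation_config()

  # degenerate truncation window returns the constant
  cfg_const <- simulation_config(duration_mean = 2.58, duration_min = 2.58,
                                 duration_max = 2.58)
  expect_equal(sample_event_duration(cfg_const, 5), rep(2.58, 5))

  draws <- spindetect:::with_seed(123, sample_event_duration(cfg, 10000))
  expect_true(all(draws >= cfg$duration_min & draws <= cfg$duration_max))
  expect_lt(abs(mean(draws) - 2.58), 0.05)

  # truncation bounds hold for arbitrary seeds (property)
  for (s in c(2, 17, 991)) {
    d <- spindetect:::with_seed(s, sample_event_duration(cfg, 500))
    expect_true(all(d >= 1.02 & d <= 5.42))
  }

  expect_error(simulation_config(duration_min = 3, duration_max = 2),
               "min <= mean <= max")
  expect_error(simulation_config(duration_min = 0), "positive")
})

test_that("spin kinematics integrate to two full rotations with consistent sign", {
  cfg <- simulation_config()
  kin <- spindetect:::with_seed(1, synthesize_spin(2.0, cfg))

  expect_equal(mean(abs(kin$yaw_rate)), 360, tolerance = 0.05)
  # numerically integrated yaw = rotations * 360 deg within 1%
  integral <- sum(kin$yaw_rate) / cfg$sampling_rate
  expect_equal(abs(integral), 720, tolerance = 0.01)
  # clockwise convention: yaw rate sign consistent over the whole event
  expect_true(all(kin$yaw_rate <= 0))

  ccw <- simulation_config(direction = "counterclockwise")
  kin2 <- spindetect:::with_seed(1, synthesize_spin(2.0, ccw))
  expect_true(all(kin2$yaw_rate >= 0))

  # integral conservation across random durations and seeds (property)
  for (s in 1:5) {
    d <- spindetect:::with_seed(s, sample_event_duration(cfg, 1))
    k <- spindetect:::with_seed(s + 100, synthesize_spin(d, cfg))
    expect_equal(abs(sum(k$yaw_rate) / cfg$sampling_rate), 720,
                 tolerance = 0.01)
  }

  expect_error(synthesize_spin(-1, cfg), "positive")
  expect_identical(spindetect:::with_seed(4, synthesize_spin(2.58, cfg)),
                   spindetect:::with_seed(4, synthesize_spin(2.58, cfg)))
})

test_that("spin acceleration carries the rotation-frequency component", {
  cfg <- simulation_config()
  kin <- spindetect:::with_seed(2, synthesize_spin(2.58, cfg))
  # two rotations in 2.58 s -> ~0.775 Hz; compare against a brute-force DFT
  pg <- oracle_periodogram(kin$accel[, 1] - mean(kin$accel[, 1]),
                           cfg$sampling_rate)
  f_dom <- pg$freq[which.max(pg$power)]
  f_rot <- 2 / kin$duration
  expect_lt(abs(f_dom - f_rot), cfg$sampling_rate / length(kin$yaw_rate) + 1e-9)
  expect_lt(abs(f_rot - 0.78), 0.01)
})

test_that("simulated subjects carry exactly the configured events, annotated in place", {
  cfg <- small_config()
  pair <- simulate_subject(cfg, 1)
  expect_equal(nrow(pair$annotations$intervals), 5)
  expect_equal(n_samples(pair$recording), 2 * 60 * 50)

  # annotations align exactly with injected kinematics: the integrated
  # angular velocity over every annotated interval has magnitude 720 degrees
  # (the per-subject frame rotation preserves it)
  pair0 <- simulate_subject(small_config(noise_sd_accel = 0,
                                         noise_sd_gyro = 0), 1)
  iv0 <- pair0$annotations$intervals
  for (k in seq_len(nrow(iv0))) {
    idx <- (round(iv0$start_s[k] * 50) + 1):round(iv0$end_s[k] * 50)
    rot <- pair0$recording$data[idx, c("Gyro_X", "Gyro_Y", "Gyro_Z")]
    expect_equal(sqrt(sum(colSums(rot / 50)^2)), 720, tolerance = 0.015)
  }

  none <- simulation_config(n_subjects = 1, events_per_subject = 0,
                            background_minutes = 1, seed = 3)
  pair_none <- simulate_subject(none, 1)
  expect_equal(nrow(pair_none$annotations$intervals), 0)
  expect_gt(n_samples(pair_none$recording), 0)

  crowded <- simulation_config(n_subjects = 1, events_per_subject = 100,
                               background_minutes = 1, seed = 3)
  expect_error(simulate_subject(crowded, 1), "cannot fit")
})

test_that("a full study reproduces the cohort structure deterministically", {
  cfg <- simulation_config(seed = 5)
  study <- simulate_study(cfg)
  counts <- vapply(study, function(p) nrow(p$annotations$intervals), integer(1))
  expect_equal(unname(counts), c(74, 23, 16, 10, 9, 3))
  expect_equal(sum(counts), 135)
  expect_equal(names(study),
               c("Stuart", "Rosie", "Teddy", "Ranger", "Tori", "Nadia"))

  spin_s <- sum(vapply(study, function(p)
    sum(p$annotations$intervals$end_s - p$annotations$intervals$start_s),
    numeric(1)))
  expect_lt(abs(spin_s - 135 * 2.58) / (135 * 2.58), 0.10)

  expect_identical(study, simulate_study(simulation_config(seed = 5)))
  study2 <- simulate_study(simulation_config(seed = 6))
  expect_false(identical(study[[1]]$recording$data, study2[[1]]$recording$data))
})

test_that("noise-free spins dominate every background window in gyro magnitude", {
  study <- simulate_study(noiseless_config())
  for (pair in study) {
    mask <- annotations_to_mask(pair$recording, pair$annotations)
    segs <- segment_stream(pair$recording, mask)
    g <- segment_gyro_magnitude(segs)
    background <- segs$info$positive_fraction == 0
    # mean gyro magnitude inside every annotated interval beats every
    # spin-free window: the heuristic has a perfect threshold here
    gmag <- sqrt(rowSums(pair$recording$data[, c("Gyro_X", "Gyro_Y",
                                                 "Gyro_Z")]^2))
    iv <- pair$annotations$intervals
    inside_means <- vapply(seq_len(nrow(iv)), function(k) {
      mean(gmag[(round(iv$start_s[k] * 50) + 1):round(iv$end_s[k] * 50)])
    }, numeric(1))
    expect_gt(min(inside_means), max(g[background]))
  }
})

test_that("study CSV export is byte-reproducible per seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(small_config(seed = 9)), d1)
  write_study(simulate_study(small_config(seed = 9)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
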