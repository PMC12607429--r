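# Metrics, protocols, OR-aggregation and leakage audits.

test_that("metrics recompute exactly from confusion counts", {
  # the event-level confusion of the motivating LODO analysis:
  # 19 hits, 4 misses, 3 false alarms, 102 correct rejections
  truth <- c(rep("spin", 23), rep("non_spin", 105))
  pred <- c(rep("spin", 19), rep("non_spin", 4),
            rep("spin", 3), rep("non_spin", 102))
  m <- compute_metrics(truth, pred, positive = "spin")
  expect_equal(m$confusion, c(TP = 19, FP = 3, FN = 4, TN = 102))
  expect_equal(m$sensitivity, 19 / 23)
  expect_equal(m$accuracy, 121 / 128)
  expect_equal(m$specificity, 102 / 105)
  expect_equal(m$f1, 2 * 19 / (2 * 19 + 3 + 4))
  expect_equal(sum(m$confusion), length(truth))
  # F1 and accuracy recomputable from the stored counts
  cc <- m$confusion
  expect_equal(m$accuracy, unname((cc["TP"] + cc["TN"]) / sum(cc)))
  expect_equal(m$f1, unname(2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"])))
})

test_that("rank-statistic ROC-AUC matches pROC and handles edge cases", {
  skip_if_not_installed("pROC")
  dat <- spindetect:::with_seed(17, {
    truth <- sample(c("spinning", "non_spinning"), 200, replace = TRUE)
    scores <- rnorm(200) + (truth == "spinning") * 0.8
    list(truth = truth, scores = scores)
  })
  m <- compute_metrics(dat$truth,
                       ifelse(dat$scores > 0.4, "spinning", "non_spinning"),
                       dat$scores)
  ref <- pROC::auc(pROC::roc(dat$truth, dat$scores, levels =
                               c("non_spinning", "spinning"),
                             direction = "<", quiet = TRUE))
  expect_equal(m$roc_auc, as.numeric(ref), tolerance = 1e-12)

  # perfect separation -> 1; random scores on balanced labels -> ~0.5
  perf <- compute_metrics(c("spinning", "non_spinning"),
                          c("spinning", "non_spinning"), scores = c(2, 1))
  expect_equal(perf$roc_auc, 1)
  big <- spindetect:::with_seed(18, compute_metrics(
    rep(c("spinning", "non_spinning"), 2000),
    rep("non_spinning", 4000),
    scores = rnorm(4000)))
  expect_lt(abs(big$roc_auc - 0.5), 0.05)

  # single-class truth: ROC-AUC absent, not NaN
  one <- compute_metrics(rep("spinning", 4), rep("spinning", 4),
                         scores = 1:4)
  expect_null(one$roc_auc)
})

test_that("event OR-aggregation follows the at-least-one-window rule", {
  # decision rule in isolation: (0,0,1,0,0) -> spin; all zero -> non_spin
  study <- simulate_study(small_config(seed = 31))
  pair <- study[[1]]
  ev <- curate_events(pair$recording, pair$annotations, seed = 1)
  # use the heuristic with extreme thresholds to force window patterns
  always_no <- structure(list(threshold = Inf), class = "heuristic_model")
  res_no <- evaluate_events(always_no, study, ev)
  expect_true(all(res_no$per_event$pred == "non_spin"))

  always_yes <- structure(list(threshold = -Inf), class = "heuristic_model")
  res_yes <- evaluate_events(always_yes, study, ev)
  expect_true(all(res_yes$per_event$pred == "spin"))
  expect_true(all(res_yes$per_event$n_windows == 5))

  # a real model: event = spin iff any of its windows was predicted spin
  segs <- spindetect:::study_segments(study, names(study), windowing_params())
  m <- fit_heuristic(segs)
  res <- evaluate_events(m, study, ev)
  segs_ev <- segments_from_events(study, ev, windowing_params())
  win_pred <- predict(m, segs_ev)
  for (i in seq_len(nrow(res$per_event))) {
    idx <- segs_ev$info$event_id == res$per_event$event_id[i]
    expect_identical(res$per_event$pred[i],
                     if (any(win_pred[idx] == "spinning")) "spin" else "non_spin")
  }
})

test_that("LODO protocols hold out whole subjects and pass the leakage audit", {
  study <- simulate_study(simulation_config(
    n_subjects = 3, events_per_subject = c(6, 5, 4),
    background_minutes = 3, seed = 19))
  rep <- run_protocol(study, split_protocol("lodo_full_cv"),
                      classifier_spec("logistic"))
  ok <- Filter(function(f) !isTRUE(f$skipped), rep$folds)
  expect_length(ok, 3)
  for (f in ok) {
    expect_length(f$test_subjects, 1)
    expect_false(f$test_subjects %in% f$train_subjects)
  }
  audit <- leakage_audit(rep)
  expect_true(all(vapply(audit, function(a)
    length(a$event_overlap) + length(a$subject_overlap) == 0, logical(1))))

  rep1 <- run_protocol(study,
                       split_protocol("lodo_single_holdout",
                                      holdout_subject = "subject_2"),
                       "heuristic")
  expect_length(Filter(function(f) !isTRUE(f$skipped), rep1$folds), 1)
  expect_error(run_protocol(study,
                            split_protocol("lodo_single_holdout",
                                           holdout_subject = "Rex"),
                            "heuristic"),
               "unknown holdout")

  # event-based split: audit event disjointness
  rep2 <- run_protocol(study, split_protocol("event_stratified_8020"),
                       classifier_spec("naive_bayes"))
  audit2 <- leakage_audit(rep2)
  expect_true(all(vapply(audit2, function(a)
    length(a$event_overlap) == 0, logical(1))))

  # reproducibility: identical inputs give identical reports
  rep3 <- run_protocol(study, split_protocol("lodo_full_cv"),
                       classifier_spec("logistic"))
  expect_identical(rep$segment_confusion, rep3$segment_confusion)
})

test_that("event-level sensitivity dominates segment-level sensitivity", {
  # under the event-based split the test segments are exactly the event
  # windows, so the comparison is on the same data
  study <- simulate_study(simulation_config(
    n_subjects = 3, events_per_subject = c(8, 6, 5),
    background_minutes = 3, seed = 23))
  ev_all <- do.call(rbind, lapply(names(study), function(s)
    curate_events(study[[s]]$recording, study[[s]]$annotations, seed = 1)))
  sp <- split_events(ev_all, ratio = 0.8, stratify = TRUE, seed = 1)
  segs_test <- segments_from_events(study, sp$test, windowing_params())
  pos_windows <- tapply(segs_test$info$label == "spinning",
                        segs_test$info$event_id, sum)
  for (model in list("heuristic", classifier_spec("logistic"))) {
    rep <- run_protocol(study, split_protocol("event_stratified_8020",
                                              seed = 1), model)
    pe <- rep$folds[["split"]]$event_result$per_event
    # spin events visible at window level are detected at least as often as
    # individual spinning windows are hit
    visible <- pe$class == "spin" & pos_windows[pe$event_id] > 0
    expect_gte(mean(pe$pred[visible] == "spin"),
               rep$segment_metrics$confusion[["TP"]] /
                 (rep$segment_metrics$confusion[["TP"]] +
                    rep$segment_metrics$confusion[["FN"]]))
    # constructional identity: event false negatives are exactly the spin
    # events whose every window was predicted negative
    expect_equal(rep$event_confusion[["FN"]],
                 sum(pe$class == "spin" & pe$pred == "non_spin"))
  }
})

test_that("within-subject evaluation on a separable fixture is perfect", {
  # hand-crafted fixture with spins aligned to the window grid, so every
  # window is either fully spin or fully background and a magnitude
  # threshold separates the classes exactly
  n <- 390 * 8
  data <- matrix(0, n, 6, dimnames = list(NULL, imu_channels()))
  data[, "Accel_LN_Z"] <- 9.81
  spin_starts <- c(390, 1430, 2600)  # 0-based, multiples of the 65 stride
  for (s0 in spin_starts) data[(s0 + 1):(s0 + 260), "Gyro_Z"] <- -360
  rec <- imu_recording(data, 50, "crafted")
  ann <- annotation_track("crafted",
                          data.frame(start_s = spin_starts / 50,
                                     end_s = (spin_starts + 260) / 50,
                                     label = "spin"))
  study <- structure(list(crafted = list(recording = rec, annotations = ann)),
                     class = "imu_study")
  rep <- run_protocol(study, split_protocol("within_subject_random"),
                      "heuristic")
  expect_equal(rep$segment_metrics$accuracy, 1)
  expect_null(rep$event_metrics)  # random-window split has no event corpus
})

test_that("a fold with single-class training data is skipped and recorded", {
  # only one subject spins: holding it out leaves single-class training data
  study <- simulate_study(simulation_config(
    n_subjects = 3, events_per_subject = c(4, 0, 0),
    background_minutes = 2, seed = 37))
  expect_warning(
    rep <- run_protocol(study, split_protocol("lodo_full_cv"), "heuristic"),
    "skipped")
  expect_true(isTRUE(rep$folds[["subject_1"]]$skipped))
  expect_length(Filter(function(f) !isTRUE(f$skipped), rep$folds), 2)
  expect_error(suppressWarnings(
    run_protocol(study,
                 split_protocol("lodo_single_holdout",
                                holdout_subject = "subject_1"),
                 "heuristic")),
    "every fold was skipped")
})
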