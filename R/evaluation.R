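# Evaluation protocols (within-subject and Leave-One-Dog-Out), segment-level
# metrics, and the event-level OR-aggregation with confusion matrices.

#' Split protocol specification
#'
#' @param kind one of `"within_subject_random"` (pooled windows, stratified
#'   random split — permits subject/event overlap between partitions by
#'   design), `"event_stratified_8020"` (event-disjoint stratified split of
#'   curated events), `"lodo_single_holdout"` (all data of one named subject
#'   held out) or `"lodo_full_cv"` (every subject held out in turn).
#' @param holdout_subject subject id for `lodo_single_holdout`.
#' @param ratio training fraction for the random/event splits.
#' @param seed RNG seed for any randomised split.
#' @return an object of class `split_protocol`.
#' @export
split_protocol <- function(kind = c("lodo_full_cv", "lodo_single_holdout",
                                    "event_stratified_8020",
                                    "within_subject_random"),
                           holdout_subject = NULL, ratio = 0.8, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "lodo_single_holdout" && is.null(holdout_subject)) {
    stop("lodo_single_holdout requires holdout_subject", call. = FALSE)
  }
  structure(list(kind = kind, holdout_subject = holdout_subject,
                 ratio = ratio, seed = seed),
            class = "split_protocol")
}

#' Confusion counts
#'
#' @param truth,pred label vectors.
#' @param positive the positive-class label.
#' @return named numeric vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  c(TP = sum(pred == positive & truth == positive),
    FP = sum(pred == positive & truth != positive),
    FN = sum(pred != positive & truth == positive),
    TN = sum(pred != positive & truth != positive))
}

# Rank-statistic ROC-AUC (equivalent to trapezoidal integration of the ROC
# curve); tied scores handled by mid-ranks. NULL when truth is single-class.
roc_auc_rank <- function(scores, truth, positive) {
  pos <- truth == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0 || is.null(scores)) return(NULL)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics from predictions
#'
#' Accuracy, positive-class F1, sensitivity, specificity and (when
#' continuous scores are supplied and both classes occur in the truth)
#' ROC-AUC by the mid-rank statistic. All ratio metrics are recomputable
#' from the returned confusion counts.
#'
#' @param truth,pred label vectors.
#' @param scores optional continuous scores (larger = more positive).
#' @param positive positive-class label (default segment-level
#'   `"spinning"`).
#' @return list with `confusion` and the metric values; `roc_auc` is absent
#'   (`NULL`) when undefined.
#' @export
compute_metrics <- function(truth, pred, scores = NULL,
                            positive = LABEL_SPIN) {
  if (length(truth) == 0L) stop("no predictions to score", call. = FALSE)
  cc <- confusion_counts(truth, pred, positive)
  tp <- cc["TP"]; fp <- cc["FP"]; fn <- cc["FN"]; tn <- cc["TN"]
  list(confusion = cc,
       accuracy = unname((tp + tn) / sum(cc)),
       f1 = unname(f1_score(tp, fp, fn)),
       sensitivity = unname(if (tp + fn == 0) NA_real_ else tp / (tp + fn)),
       specificity = unname(if (tn + fp == 0) NA_real_ else tn / (tn + fp)),
       roc_auc = roc_auc_rank(scores, truth, positive))
}

# --- fold machinery -------------------------------------------------------

fit_fold <- function(train_segs, model, sel_par) {
  labels <- segment_labels(train_segs)
  if (length(unique(labels)) < 2L) {
    stop("single-class training fold", call. = FALSE)
  }
  if (identical(model, "heuristic")) {
    return(list(kind = "heuristic", model = fit_heuristic(train_segs),
                selection = NULL))
  }
  feats <- extract_features(train_segs)
  sel <- fit_selection(feats, labels,
                       var_thresh = sel_par$var_thresh,
                       corr_thresh = sel_par$corr_thresh, k = sel_par$k)
  clf <- fit_classifier(model, apply_selection(sel, feats), labels)
  list(kind = "classifier", model = clf, selection = sel)
}

predict_fold <- function(fitobj, segs) {
  if (fitobj$kind == "heuristic") {
    g <- segment_gyro_magnitude(segs)
    list(labels = predict(fitobj$model, g),
         scores = predict(fitobj$model, g, type = "score"))
  } else {
    x <- apply_selection(fitobj$selection, extract_features(segs))
    list(labels = predict(fitobj$model, x),
         scores = predict(fitobj$model, x, type = "score"))
  }
}

study_segments <- function(study, subjects, params) {
  sets <- lapply(subjects, function(s) {
    pair <- study[[s]]
    segment_stream(pair$recording,
                   annotations_to_mask(pair$recording, pair$annotations),
                   params)
  })
  bind_segment_sets(sets)
}

#' Event-level evaluation by OR-aggregation
#'
#' Each curated event is segmented with the sliding window (a 7.8 s event
#' yields five 2.6 s windows at the default 1.3 s stride), the model
#' predicts every window, and the event is called spin iff at least one
#' window prediction is positive. The event score is the maximum window
#' score.
#'
#' @param fitobj a fitted fold object, a `heuristic_model` or a
#'   `spin_classifier` (classifiers need `selection`).
#' @param study the `imu_study` holding the recordings.
#' @param events a `curated_events` data.frame.
#' @param params a [windowing_params()].
#' @param selection a `selection_report` (required for a bare
#'   `spin_classifier`).
#' @return list with `confusion`, `metrics` and a `per_event` data.frame.
#' @export
evaluate_events <- function(fitobj, study, events,
                            params = windowing_params(), selection = NULL) {
  if (inherits(fitobj, "heuristic_model")) {
    fitobj <- list(kind = "heuristic", model = fitobj, selection = NULL)
  } else if (inherits(fitobj, "spin_classifier")) {
    if (is.null(selection)) {
      stop("a spin_classifier needs its selection_report", call. = FALSE)
    }
    fitobj <- list(kind = "classifier", model = fitobj, selection = selection)
  }
  if (nrow(events) == 0L) stop("no events to evaluate", call. = FALSE)
  segs <- segments_from_events(study, events, params)
  pr <- predict_fold(fitobj, segs)
  by_ev <- split(seq_len(n_segments(segs)), segs$info$event_id)
  per_event <- data.frame(
    event_id = events$event_id,
    class = events$class,
    n_windows = NA_integer_, pred = NA_character_, score = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per_event))) {
    idx <- by_ev[[per_event$event_id[i]]]
    per_event$n_windows[i] <- length(idx)
    per_event$pred[i] <- if (any(pr$labels[idx] == LABEL_SPIN))
      EVENT_SPIN else EVENT_NONSPIN
    per_event$score[i] <- max(pr$scores[idx])
  }
  metrics <- compute_metrics(per_event$class, per_event$pred,
                             per_event$score, positive = EVENT_SPIN)
  list(confusion = metrics$confusion, metrics = metrics, per_event = per_event)
}

#' Run a full evaluation protocol
#'
#' Executes the requested split protocol over a labelled study: per fold,
#' the selection pipeline and model are fitted on training rows only, the
#' held-out rows are predicted, and confusion counts accumulate. Segment-
#' and event-level results are reported; across LODO folds the pooled
#' (micro) confusion is the headline aggregate, with per-fold results
#' retained. Folds whose training data contain a single class are skipped
#' with a warning and recorded.
#'
#' @param study an `imu_study`.
#' @param protocol a [split_protocol()].
#' @param model `"heuristic"` or a [classifier_spec()].
#' @param params a [windowing_params()].
#' @param selection_params list with `var_thresh`, `corr_thresh`, `k`.
#' @param event_length curated event length, seconds.
#' @return an object of class `evaluation_report`.
#' @export
run_protocol <- function(study, protocol, model = classifier_spec(),
                         params = windowing_params(),
                         selection_params = list(var_thresh = 0.1,
                                                 corr_thresh = 0.95, k = 20),
                         event_length = 7.8) {
  subjects <- names(study)
  folds <- list()

  add_fold <- function(name, train_segs, test_segs, test_events,
                       train_subjects, test_subjects, train_event_ids) {
    fitobj <- tryCatch(fit_fold(train_segs, model, selection_params),
                       error = function(e) e)
    if (inherits(fitobj, "error")) {
      warning(sprintf("fold '%s' skipped: %s", name, conditionMessage(fitobj)))
      return(list(fold = name, skipped = TRUE,
                  reason = conditionMessage(fitobj)))
    }
    pr <- predict_fold(fitobj, test_segs)
    seg_metrics <- compute_metrics(segment_labels(test_segs), pr$labels,
                                   pr$scores)
    ev <- if (!is.null(test_events) && nrow(test_events) > 0) {
      evaluate_events(fitobj, study, test_events, params)
    } else NULL
    list(fold = name, skipped = FALSE,
         train_subjects = train_subjects, test_subjects = test_subjects,
         train_event_ids = train_event_ids,
         test_event_ids = if (is.null(test_events)) character(0) else
           test_events$event_id,
         segment_truth = segment_labels(test_segs),
         segment_pred = pr$labels, segment_scores = pr$scores,
         segment_metrics = seg_metrics,
         selection = fitobj$selection,
         event_result = ev)
  }

  if (protocol$kind %in% c("lodo_full_cv", "lodo_single_holdout")) {
    if (length(subjects) < 2L) stop("LODO requires >= 2 subjects", call. = FALSE)
    holdouts <- if (protocol$kind == "lodo_full_cv") subjects else {
      if (!protocol$holdout_subject %in% subjects) {
        stop("unknown holdout subject: ", protocol$holdout_subject,
             call. = FALSE)
      }
      protocol$holdout_subject
    }
    for (s in holdouts) {
      train_sub <- setdiff(subjects, s)
      train_segs <- study_segments(study, train_sub, params)
      test_segs <- study_segments(study, s, params)
      test_events <- curate_events(study[[s]]$recording,
                                   study[[s]]$annotations,
                                   event_length = event_length,
                                   seed = protocol$seed)
      folds[[s]] <- add_fold(s, train_segs, test_segs, test_events,
                             train_sub, s, character(0))
    }
  } else if (protocol$kind == "event_stratified_8020") {
    events <- do.call(rbind, lapply(subjects, function(s) {
      curate_events(study[[s]]$recording, study[[s]]$annotations,
                    event_length = event_length, seed = protocol$seed)
    }))
    sp <- split_events(events, ratio = protocol$ratio, stratify = TRUE,
                       seed = protocol$seed)
    train_segs <- segments_from_events(study, sp$train, params)
    test_segs <- segments_from_events(study, sp$test, params)
    folds[["split"]] <- add_fold("split", train_segs, test_segs, sp$test,
                                 subjects, subjects, sp$train$event_id)
  } else {  # within_subject_random
    segs <- study_segments(study, subjects, params)
    lab <- segment_labels(segs)
    idx_train <- with_seed(protocol$seed, {
      pick <- logical(n_segments(segs))
      for (g in split(seq_along(lab), lab)) {
        n_tr <- min(max(round(protocol$ratio * length(g)), 1L), length(g) - 1L)
        pick[sample(g, n_tr)] <- TRUE
      }
      pick
    })
    folds[["split"]] <- add_fold("split",
                                 subset_segments(segs, idx_train),
                                 subset_segments(segs, !idx_train),
                                 NULL, subjects, subjects, character(0))
  }

  ok <- Filter(function(f) !isTRUE(f$skipped), folds)
  if (length(ok) == 0L) stop("every fold was skipped", call. = FALSE)

  truth <- unlist(lapply(ok, `[[`, "segment_truth"))
  pred <- unlist(lapply(ok, `[[`, "segment_pred"))
  scores <- unlist(lapply(ok, `[[`, "segment_scores"))
  seg_metrics <- compute_metrics(truth, pred, scores)

  ev_folds <- Filter(Negate(is.null), lapply(ok, `[[`, "event_result"))
  event_metrics <- NULL
  if (length(ev_folds) > 0) {
    ev_truth <- unlist(lapply(ev_folds, function(e) e$per_event$class))
    ev_pred <- unlist(lapply(ev_folds, function(e) e$per_event$pred))
    ev_scores <- unlist(lapply(ev_folds, function(e) e$per_event$score))
    event_metrics <- compute_metrics(ev_truth, ev_pred, ev_scores,
                                     positive = EVENT_SPIN)
  }

  structure(
    list(protocol = protocol,
         model = if (identical(model, "heuristic")) "heuristic" else model$family,
         segment_confusion = seg_metrics$confusion,
         segment_metrics = seg_metrics,
         event_confusion = event_metrics$confusion,
         event_metrics = event_metrics,
         folds = folds),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / model '%s'\n", x$protocol$kind, x$model))
  cc <- x$segment_confusion
  cat(sprintf("  segments: TP %d FP %d FN %d TN %d | acc %.3f F1 %.3f%s\n",
              cc["TP"], cc["FP"], cc["FN"], cc["TN"],
              x$segment_metrics$accuracy, x$segment_metrics$f1,
              if (!is.null(x$segment_metrics$roc_auc))
                sprintf(" AUC %.3f", x$segment_metrics$roc_auc) else ""))
  if (!is.null(x$event_metrics)) {
    ec <- x$event_confusion
    cat(sprintf("  events:   TP %d FP %d FN %d TN %d | acc %.3f F1 %.3f sens %.3f spec %.3f\n",
                ec["TP"], ec["FP"], ec["FN"], ec["TN"],
                x$event_metrics$accuracy, x$event_metrics$f1,
                x$event_metrics$sensitivity, x$event_metrics$specificity))
  }
  invisible(x)
}

#' Leakage audit of an evaluation report
#'
#' Returns the overlap between train- and test-side provenance for every
#' fold; every entry is empty for a leakage-free run.
#'
#' @param report an `evaluation_report`.
#' @return list per fold with `event_overlap` and, for LODO folds,
#'   `subject_overlap`.
#' @export
leakage_audit <- function(report) {
  lapply(Filter(function(f) !isTRUE(f$skipped), report$folds), function(f) {
    list(event_overlap = intersect(f$train_event_ids, f$test_event_ids),
         subject_overlap = if (report$protocol$kind %in%
                               c("lodo_full_cv", "lodo_single_holdout"))
           intersect(f$train_subjects, f$test_subjects) else character(0))
  })
}
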