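# The tuned gyro-magnitude heuristic baseline and the four supervised
# classifier families behind a uniform fit/predict contract. Engines are the
# standard R implementations (randomForest, e1071, glmnet); this module adds
# train-only standardisation, seeding, score orientation and the tuning
# logic around them.

f1_score <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' Fit the heuristic baseline
#'
#' Classifies a segment as spinning iff its mean gyroscope magnitude
#' strictly exceeds a threshold. The threshold is tuned on the training data
#' only: the candidate grid consists of the midpoints between consecutive
#' sorted distinct training values plus -Inf/+Inf sentinels; the candidate
#' maximising the tuning metric (spin-class F1) is returned, ties broken
#' toward the larger threshold (fewer false alarms).
#'
#' @param gyro_means numeric vector of per-segment mean gyro magnitudes
#'   (deg/s), or a `segment_set`.
#' @param labels segment labels (`"spinning"` / `"non_spinning"`).
#' @return an object of class `heuristic_model`.
#' @export
fit_heuristic <- function(gyro_means, labels) {
  if (inherits(gyro_means, "segment_set")) {
    labels <- segment_labels(gyro_means)
    gyro_means <- segment_gyro_magnitude(gyro_means)
  }
  pos <- labels == LABEL_SPIN
  if (all(pos) || !any(pos)) {
    stop("heuristic tuning requires both classes in the training data",
         call. = FALSE)
  }
  v <- sort(unique(gyro_means))
  if (length(v) == 1L) {
    warning("all training gyro magnitudes identical; classes are inseparable")
    grid <- c(-Inf, Inf)
  } else {
    grid <- c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
  }
  scores <- vapply(grid, function(th) {
    pred <- gyro_means > th
    f1_score(sum(pred & pos), sum(pred & !pos), sum(!pred & pos))
  }, numeric(1))
  best <- max(scores)
  threshold <- max(grid[scores == best])  # tie -> larger threshold
  structure(list(threshold = threshold, tuning_metric = "f1",
                 tuning_grid = grid, train_metric = best),
            class = "heuristic_model")
}

#' @export
print.heuristic_model <- function(x, ...) {
  cat(sprintf("<heuristic_model> threshold %.2f deg/s (train %s = %.3f)\n",
              x$threshold, x$tuning_metric, x$train_metric))
  invisible(x)
}

#' Predict with the heuristic baseline
#'
#' @param object a `heuristic_model`.
#' @param newdata numeric vector of mean gyro magnitudes or a `segment_set`.
#' @param type `"class"` for labels, `"score"` for the raw magnitudes (the
#'   ranking score used for ROC analysis).
#' @param ... unused.
#' @export
predict.heuristic_model <- function(object, newdata,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "segment_set")) {
    newdata <- segment_gyro_magnitude(newdata)
  }
  if (type == "score") return(newdata)
  ifelse(newdata > object$threshold, LABEL_SPIN, LABEL_NONSPIN)
}

#' Classifier specification
#'
#' @param family one of `"random_forest"` (randomised tree ensemble),
#'   `"svm"` (RBF-kernel max-margin machine), `"naive_bayes"` (Gaussian
#'   conditional-independence model) or `"logistic"` (L2-regularised linear
#'   log-odds model).
#' @param hyper named list of engine hyperparameters overriding the
#'   defaults (`ntree = 100`; `cost = 1`, `gamma` engine default;
#'   `var_smoothing = 1e-9`; ridge `lambda = 1/n`).
#' @param standardize z-score features using train-fitted statistics;
#'   defaults to `TRUE` for every family except the tree ensemble (which is
#'   invariant to monotone rescaling). For the Gaussian model
#'   standardisation matters because its variance-smoothing floor is shared
#'   across features: on raw scales the floor is dominated by the largest
#'   feature variance (spectral energy), leaving small-scale features
#'   unsmoothed.
#' @param seed seed fixing all stochastic fitting.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "svm", "naive_bayes",
                                       "logistic"),
                            hyper = list(), standardize = NULL, seed = 1) {
  family <- match.arg(family)
  if (is.null(standardize)) {
    standardize <- family %in% c("svm", "logistic", "naive_bayes")
  }
  structure(list(family = family, hyper = hyper, standardize = standardize,
                 seed = seed),
            class = "classifier_spec")
}

#' Fit a supervised spin classifier
#'
#' Fits the family requested by the spec on the (selected) training feature
#' matrix. Standardisation statistics, like every other fitted quantity,
#' derive from the training rows only. The fitted object predicts labels
#' and a continuous spin score (probability or margin) usable for ROC
#' analysis, deterministically per seed.
#'
#' @param spec a [classifier_spec()].
#' @param x training feature matrix.
#' @param labels training labels (`"spinning"` / `"non_spinning"`).
#' @return an object of class `spin_classifier`.
#' @export
fit_classifier <- function(spec, x, labels) {
  x <- as.matrix(x)
  y <- factor(labels, levels = c(LABEL_NONSPIN, LABEL_SPIN))
  if (any(is.na(y))) stop("unknown label values", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  center <- scale_ <- NULL
  if (spec$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  h <- spec$hyper
  fit <- switch(
    spec$family,
    random_forest = with_seed(spec$seed, {
      randomForest::randomForest(x = x, y = y, ntree = h$ntree %||% 100)
    }),
    svm = with_seed(spec$seed, {
      e1071::svm(x = x, y = y, kernel = "radial", cost = h$cost %||% 1,
                 gamma = h$gamma %||% (1 / ncol(x)), scale = FALSE)
    }),
    naive_bayes = {
      m <- e1071::naiveBayes(as.data.frame(x), y)
      # variance floor (sklearn-style smoothing): e1071 yields NaN densities
      # for zero within-class variance, common on low-noise data
      smooth <- h$var_smoothing %||% 1e-9
      max_var <- max(apply(x, 2, stats::var), 1e-12)
      floor_sd <- sqrt(smooth * max_var)
      m$tables <- lapply(m$tables, function(tab) {
        tab[, 2] <- pmax(tab[, 2], floor_sd)
        tab
      })
      m
    },
    logistic = {
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = h$lambda %||% (1 / nrow(x)),
                     standardize = FALSE,
                     maxit = h$maxit %||% 1000)
    })
  structure(list(spec = spec, fit = fit, center = center, scale = scale_,
                 features = colnames(x)),
            class = "spin_classifier")
}

#' @export
print.spin_classifier <- function(x, ...) {
  cat(sprintf("<spin_classifier> family '%s' on %d feature(s)\n",
              x$spec$family, length(x$features)))
  invisible(x)
}

#' Predict labels or spin scores
#'
#' @param object a fitted `spin_classifier`.
#' @param newdata feature matrix with the training columns.
#' @param type `"class"` for labels or `"score"` for a continuous score
#'   oriented so larger means more spin-like (class probability for the tree
#'   ensemble, Gaussian and linear models; signed margin for the kernel
#'   machine).
#' @param ... unused.
#' @export
predict.spin_classifier <- function(object, newdata,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (!is.null(object$center)) {
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  }
  fam <- object$spec$family
  if (fam == "random_forest") {
    if (type == "class") {
      return(as.character(predict(object$fit, x)))
    }
    return(predict(object$fit, x, type = "prob")[, LABEL_SPIN])
  }
  if (fam == "svm") {
    pred <- predict(object$fit, x, decision.values = TRUE)
    if (type == "class") return(as.character(pred))
    dv <- drop(attr(pred, "decision.values"))
    # orient the margin toward the spin class
    orient <- if (grepl(paste0("^", LABEL_SPIN, "/"),
                        colnames(attr(pred, "decision.values"))[1])) 1 else -1
    return(orient * dv)
  }
  if (fam == "naive_bayes") {
    # floor vanishing densities so far-from-training windows compare by
    # their informative features instead of tying at log(0)
    if (type == "class") {
      return(as.character(predict(object$fit, as.data.frame(x),
                                  eps = 1e-300, threshold = 1e-300)))
    }
    return(predict(object$fit, as.data.frame(x), type = "raw",
                   eps = 1e-300, threshold = 1e-300)[, LABEL_SPIN])
  }
  # logistic
  p <- drop(predict(object$fit, x, type = "response"))
  if (type == "score") return(p)
  ifelse(p >= 0.5, LABEL_SPIN, LABEL_NONSPIN)
}
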