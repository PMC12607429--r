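# Per-segment temporal and spectral feature engineering and the three-stage
# selection pipeline (variance filter -> collinearity filter -> ANOVA
# F-test), fitted on training rows only.

FEATURE_STATS <- c("mean", "sd", "range", "dom_freq", "spec_energy", "spec_entropy")

#' Feature schema
#'
#' Stable, ordered names of the 48 engineered features: for each of the six
#' raw channels plus the two derived magnitude traces (per-sample Euclidean
#' norm of the accelerometer and gyroscope axes), six descriptors — mean,
#' population standard deviation, range, dominant frequency (Hz), spectral
#' energy and spectral entropy (bits).
#'
#' @return character vector of length 48.
#' @export
feature_schema <- function() {
  traces <- c(imu_channels(), "Accel_Mag", "Gyro_Mag")
  as.vector(vapply(traces, function(tr) paste(tr, FEATURE_STATS, sep = "_"),
                   character(length(FEATURE_STATS))))
}

# Six descriptors of one trace. Spectral descriptors come from a single
# untapered periodogram of the window, DC bin excluded (the mean already
# carries it). A flat (zero-power) spectrum degenerates to dom_freq = 0,
# energy = 0, entropy = 0 rather than NaN.
trace_features <- function(x, fs) {
  m <- mean(x)
  sdev <- sqrt(mean((x - m)^2))
  rng <- max(x) - min(x)
  n <- length(x)
  X <- stats::fft(x)
  kmax <- floor(n / 2)
  p <- Mod(X[2:(kmax + 1)])^2
  tot <- sum(p)
  if (sdev == 0 || tot <= 0) {
    dom <- 0; energy <- 0; ent <- 0
  } else {
    dom <- which.max(p) * fs / n
    energy <- tot
    q <- p / tot
    q <- q[q > 0]
    ent <- -sum(q * log2(q))
  }
  c(m, sdev, rng, dom, energy, ent)
}

#' Extract the engineered feature matrix
#'
#' Computes the 48 named features of [feature_schema()] for every segment.
#'
#' @param segs a `segment_set` (or a single `[n, 6]` window matrix).
#' @param sampling_rate Hz; taken from `segs` when it is a segment set.
#' @return numeric matrix, one row per segment, columns ordered per schema.
#' @export
extract_features <- function(segs, sampling_rate = NULL) {
  if (is.matrix(segs)) {
    data <- array(segs, dim = c(1, nrow(segs), ncol(segs)))
    dimnames(data)[[3]] <- colnames(segs)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare matrix", call. = FALSE)
  } else {
    data <- segs$data
    fs <- sampling_rate %||% segs$sampling_rate
  }
  k <- dim(data)[1]
  out <- matrix(NA_real_, k, 48, dimnames = list(NULL, feature_schema()))
  acc_idx <- match(accel_channels(), dimnames(data)[[3]])
  gyr_idx <- match(gyro_channels(), dimnames(data)[[3]])
  for (i in seq_len(k)) {
    win <- data[i, , ]
    amag <- sqrt(rowSums(win[, acc_idx, drop = FALSE]^2))
    gmag <- sqrt(rowSums(win[, gyr_idx, drop = FALSE]^2))
    traces <- cbind(win[, imu_channels(), drop = FALSE], amag, gmag)
    out[i, ] <- as.vector(apply(traces, 2, trace_features, fs = fs))
  }
  if (anyNA(out)) stop("feature extraction produced missing values", call. = FALSE)
  out
}

#' Mean gyroscope magnitude per segment
#'
#' The statistic driving the heuristic baseline: the window mean of the
#' per-sample Euclidean norm of the three angular-velocity axes.
#'
#' @param segs a `segment_set`.
#' @return numeric vector, one value per segment.
#' @export
segment_gyro_magnitude <- function(segs) {
  gyr_idx <- match(gyro_channels(), dimnames(segs$data)[[3]])
  vapply(seq_len(n_segments(segs)), function(i) {
    mean(sqrt(rowSums(segs$data[i, , gyr_idx, drop = TRUE]^2)))
  }, numeric(1))
}

# Two-group one-way ANOVA F statistic for every column of x.
# Zero within-group variance with nonzero between-group spread gives Inf;
# fully constant columns give 0.
anova_f <- function(x, y) {
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((x[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!g1, , drop = FALSE] - rep(m2, each = n2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  f
}

#' Fit the three-stage feature selection pipeline
#'
#' Applied in fixed order on training rows only: (1) drop features with
#' population variance below `var_thresh`; (2) among survivors, scanning
#' pairs in schema order, drop the later feature of any pair with absolute
#' Pearson correlation above `corr_thresh`; (3) rank survivors by the
#' two-group ANOVA F statistic against the binary label and keep the top
#' `k`. The returned report is a stateless transform: applying it to new
#' data never refits.
#'
#' @param x training feature matrix (columns named per [feature_schema()] or
#'   any stable schema).
#' @param labels binary segment labels aligned with rows of `x`.
#' @param var_thresh variance threshold (default 0.1, on raw feature values).
#' @param corr_thresh absolute Pearson correlation threshold (default 0.95).
#' @param k number of features to keep (default 20).
#' @return an object of class `selection_report`.
#' @export
fit_selection <- function(x, labels, var_thresh = 0.1, corr_thresh = 0.95,
                          k = 20) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have column names", call. = FALSE)
  y <- as.factor(labels)
  if (nlevels(y) != 2L || any(table(y) < 2L)) {
    stop("selection requires >= 2 training segments in each of two classes",
         call. = FALSE)
  }

  # stage 1: low-variance filter (population variance, raw scale)
  v <- colMeans(x^2) - colMeans(x)^2
  v <- pmax(v, 0)
  keep1 <- colnames(x)[v >= var_thresh]
  dropped_var <- setdiff(colnames(x), keep1)

  if (length(keep1) == 0L) {
    stop(sprintf("all %d features dropped by the variance filter", ncol(x)),
         call. = FALSE)
  }

  # stage 2: collinearity filter; keep the earlier feature in schema order
  xs <- x[, keep1, drop = FALSE]
  dropped_cor <- data.frame(dropped = character(0), kept_partner = character(0))
  if (length(keep1) > 1L) {
    r <- suppressWarnings(stats::cor(xs))
    r[is.na(r)] <- 0
    kept <- character(0)
    for (j in keep1) {
      partner <- kept[which(abs(r[kept, j]) > corr_thresh)[1]]
      if (length(kept) > 0 && !is.na(partner)) {
        dropped_cor <- rbind(dropped_cor,
                             data.frame(dropped = j, kept_partner = partner))
      } else {
        kept <- c(kept, j)
      }
    }
  } else {
    kept <- keep1
  }
  if (length(kept) == 0L) {
    stop(sprintf(
      "no features survive selection (stage 1 dropped %d, stage 2 dropped %d)",
      length(dropped_var), nrow(dropped_cor)), call. = FALSE)
  }

  # stage 3: top-k by univariate ANOVA F
  f <- anova_f(x[, kept, drop = FALSE], y)
  ord <- order(-f, match(kept, colnames(x)))  # ties broken by schema order
  top <- kept[ord[seq_len(min(k, length(kept)))]]
  selected <- kept[kept %in% top]             # stable schema order

  structure(
    list(variance_threshold = var_thresh,
         dropped_low_variance = dropped_var,
         correlation_threshold = corr_thresh,
         dropped_collinear = dropped_cor,
         k = k,
         selected = selected,
         f_statistic = stats::setNames(f, kept),
         schema = colnames(x)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d -> %d (variance) -> %d (collinearity) -> %d selected\n",
    length(x$schema),
    length(x$schema) - length(x$dropped_low_variance),
    length(x$f_statistic),
    length(x$selected)))
  invisible(x)
}

#' Apply a fitted selection report
#'
#' Restricts and orders columns per `report$selected`; never refits.
#'
#' @param report a `selection_report`.
#' @param x feature matrix (or a single named feature vector).
#' @return matrix with `length(report$selected)` columns (or a named vector).
#' @export
apply_selection <- function(report, x) {
  if (is.null(dim(x))) {
    missing <- setdiff(report$selected, names(x))
    if (length(missing) > 0) {
      stop("feature(s) missing from input: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(x[report$selected])
  }
  missing <- setdiff(report$selected, colnames(x))
  if (length(missing) > 0) {
    stop("feature(s) missing from input: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[, report$selected, drop = FALSE]
}

#' Serialise a selection report to JSON
#' @param report a `selection_report`.
#' @param path output file.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a selection report from JSON
#' @param path file written by [write_selection_report()].
#' @return a `selection_report`.
#' @export
read_selection_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$dropped_low_variance <- as.character(obj$dropped_low_variance %||% character(0))
  obj$selected <- as.character(obj$selected)
  obj$schema <- as.character(obj$schema)
  fs <- unlist(obj$f_statistic)
  obj$f_statistic <- stats::setNames(as.numeric(fs), names(fs))
  structure(obj, class = "selection_report")
}
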