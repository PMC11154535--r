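#' Run the full feature-extraction pipeline over a frame sequence
#'
#' Streams frames one at a time: crops the analysis region (when the
#' profile has one), segments each frame, accumulates the green-channel
#' trace over region C, then computes behavioral features and the cardiac
#' trace. Frames are never held in memory together, so long recordings
#' process in constant memory.
#'
#' @param frames A frame source (see [as_frame_source()]): scene, frame
#'   directory, or list of arrays.
#' @param profile A [calibration_profile()].
#' @param backend Segmentation backend name.
#' @param gamma_px Side of cardiac region C in pixels; default
#'   `min(ax, ay) / 2`, keeping region C inside the body for typical
#'   postures.
#' @param fl,fh,t_h Cardiac band (Hz) and rate scaling constant (s).
#' @param min_eigen_ratio,strict_eye_angle,centroid_from Passed to the
#'   behavior/segmentation stages.
#' @param zero_phase Zero-phase filtering (default) or causal.
#' @param fps Frame rate override; defaults to the source's, then the
#'   profile's.
#' @return A `feature_extraction`: list with `features` (per-frame
#'   `data.frame`), `trace` (a `cardiac_trace`), `counts` (frames,
#'   complete, incomplete, no_detection), and `params`.
#' @export
extract_features <- function(frames, profile, backend = "color_threshold",
                             gamma_px = NULL, fl = 4.76, fh = 7.14,
                             t_h = 0.7, min_eigen_ratio = 1.2,
                             strict_eye_angle = FALSE,
                             centroid_from = "contour",
                             zero_phase = TRUE, fps = NULL) {
  src <- as_frame_source(frames, fps = fps)
  fs <- fps %||% (if (!is.na(src$fps)) src$fps) %||% profile$fps
  gamma_px <- gamma_px %||% (min(profile$ax, profile$ay) / 2)
  n <- src$n
  segs <- vector("list", n)
  H_raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    frame <- src$get(i)
    if (!is.null(profile$crop)) frame <- crop_region_a(frame, profile$crop)
    seg <- segment_frame(frame, profile, backend = backend,
                         centroid_from = centroid_from, frame_index = i - 1L)
    if (seg$valid_mask && seg$area >= profile$alpha_th)
      H_raw[i] <- green_mean_region_c(frame, seg$centroid, gamma_px)
    seg$mask <- NULL                      # keep memory flat over long runs
    segs[[i]] <- seg
  }
  beh <- behavior_features(segs, min_eigen_ratio = min_eigen_ratio,
                           strict_eye_angle = strict_eye_angle)
  trace <- cardiac_trace(H_raw, fs = fs, fl = fl, fh = fh, t_h = t_h,
                         zero_phase = zero_phase)
  features <- beh
  features$H_raw <- trace$raw
  features$H_filtered <- trace$filtered
  features$h <- trace$rate
  complete <- sum(stats::complete.cases(
    features[, c("m", "r", "r_prime", "theta_prime", "h")]))
  no_detection <- sum(!features$valid_mask)
  counts <- list(frames = n, complete = complete,
                 incomplete = n - complete - no_detection,
                 no_detection = no_detection)
  structure(list(features = features, trace = trace, counts = counts,
                 params = list(backend = backend, gamma_px = gamma_px,
                               fl = fl, fh = fh, t_h = t_h, fps = fs)),
            class = "feature_extraction")
}

#' @export
print.feature_extraction <- function(x, ...) {
  cat(sprintf(
    "<feature_extraction: %d frames = %d complete + %d incomplete + %d no-detection>\n",
    x$counts$frames, x$counts$complete, x$counts$incomplete,
    x$counts$no_detection))
  invisible(x)
}

#' Train a one-class model from extracted features
#'
#' @param features A `feature_extraction` or its `features` data frame.
#' @param nu,kernel_gamma One-class SVM parameters.
#' @return A `one_class_model`.
#' @export
train_model <- function(features, nu = 1e-4, kernel_gamma = 0.25) {
  if (inherits(features, "feature_extraction")) features <- features$features
  fit_one_class(assemble_samples(features), nu, kernel_gamma)
}

#' Score features with a trained model
#'
#' @param model A `one_class_model`.
#' @param features A `feature_extraction` or features data frame.
#' @return A `state_series` data frame (`frame`, `f`).
#' @export
score_features <- function(model, features) {
  if (inherits(features, "feature_extraction")) features <- features$features
  predict(model, assemble_samples(features, stats = model))
}

#' Persist / restore a trained model
#'
#' The model file carries the serialized decision parameters, the training
#' standardization statistics, a format version, and a config hash so a
#' monitor run can detect schema drift.
#'
#' @param model A `one_class_model`.
#' @param path Output path (RDS).
#' @export
save_model <- function(model, path) {
  payload <- list(format = "cagemon-model", version = 1L,
                  created = format(Sys.time(), tz = "UTC"),
                  config_hash = model_config_hash(model), model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `one_class_model`.
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "cagemon-model"))
    stop("not a cagemon model file: ", path)
  if (!identical(model_config_hash(payload$model), payload$config_hash))
    stop("model file corrupt: config hash mismatch")
  payload$model
}

model_config_hash <- function(model) {
  key <- paste(model$nu, model$kernel_gamma,
               paste(model$train_stats$features, collapse = ","),
               paste(signif(model$train_stats$center, 12), collapse = ","),
               paste(signif(model$train_stats$scale, 12), collapse = ","),
               sep = "|")
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 2147483647
}

#' Debounced anomaly alerts
#'
#' An alert is issued only after `debounce` consecutive anomalous samples,
#' suppressing single-sample flickers; the raw decision series is always
#' kept. Each alert records the onset (first frame of the anomalous run)
#' and the frame at which the debounce count was reached.
#'
#' @param decisions A `state_series` (`frame`, `f`).
#' @param debounce Consecutive-anomaly count required (default 3).
#' @param fps Frame rate for timestamps in seconds.
#' @return `data.frame` with columns `onset_frame`, `detect_frame`,
#'   `onset_time_s`, `detect_time_s` (zero rows when no alert).
#' @export
detect_alerts <- function(decisions, debounce = 3L, fps = 60) {
  f <- decisions$f
  frames <- decisions$frame
  alerts <- data.frame(onset_frame = integer(0), detect_frame = integer(0))
  run <- 0L
  onset <- NA_integer_
  fired <- FALSE
  for (i in seq_along(f)) {
    if (f[i] == 1L) {
      run <- run + 1L
      if (run == 1L) { onset <- frames[i]; fired <- FALSE }
      if (run >= debounce && !fired) {
        alerts <- rbind(alerts, data.frame(onset_frame = onset,
                                           detect_frame = frames[i]))
        fired <- TRUE
      }
    } else run <- 0L
  }
  alerts$onset_time_s <- alerts$onset_frame / fps
  alerts$detect_time_s <- alerts$detect_frame / fps
  alerts
}

#' Monitor a recording with a trained model
#'
#' End-to-end scoring run: extract features, classify each complete sample,
#' debounce alerts, and write the artifacts — `features.csv`,
#' `decisions.csv`, `alerts.csv`, and `summary.json` (frames read, samples
#' formed, anomaly fraction, alerts).
#'
#' @param frames Frame source (path to a frame directory or an object).
#' @param profile Calibration profile (path to YAML or object).
#' @param model Trained model (path to RDS or object).
#' @param out_dir Output directory, created if needed.
#' @param backend Segmentation backend.
#' @param debounce Alert debounce count.
#' @param fps Frame rate override.
#' @param ... Passed to [extract_features()].
#' @return The summary list, invisibly.
#' @export
run_monitor <- function(frames, profile, model, out_dir,
                        backend = "color_threshold", debounce = 3L,
                        fps = NULL, ...) {
  if (is.character(profile)) profile <- read_profile(profile)
  if (is.character(model)) model <- load_model(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- extract_features(frames, profile, backend = backend, fps = fps, ...)
  decisions <- score_features(model, fx)
  alerts <- detect_alerts(decisions, debounce = debounce,
                          fps = fx$params$fps)
  utils::write.csv(fx$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(decisions, file.path(out_dir, "decisions.csv"),
                   row.names = FALSE)
  utils::write.csv(alerts, file.path(out_dir, "alerts.csv"),
                   row.names = FALSE)
  summary <- list(frames = fx$counts$frames,
                  samples = fx$counts$complete,
                  incomplete = fx$counts$incomplete,
                  no_detection = fx$counts$no_detection,
                  anomaly_fraction = mean(decisions$f == 1L),
                  n_alerts = nrow(alerts),
                  debounce = debounce, fps = fx$params$fps)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Summarize a run into report files
#'
#' Writes per-state feature statistics (mean and sd of each feature for
#' routine vs anomalous samples), a confusion matrix when ground-truth
#' labels are supplied, and a feature time-series plot with the anomalous
#' decisions shaded.
#'
#' @param features Features data frame (or `feature_extraction`, or a path
#'   to `features.csv`).
#' @param decisions `state_series` data frame (or path to `decisions.csv`).
#' @param ground_truth Optional data frame with `t` and `anomaly` columns
#'   (or path to `ground_truth.csv`).
#' @param out_dir Output directory.
#' @return List with `state_stats` (and `confusion` when labels are
#'   given), invisibly.
#' @export
run_report <- function(features, decisions, ground_truth = NULL, out_dir) {
  if (is.character(features)) features <- utils::read.csv(features)
  if (inherits(features, "feature_extraction")) features <- features$features
  if (is.character(decisions)) decisions <- utils::read.csv(decisions)
  if (is.character(ground_truth)) ground_truth <- utils::read.csv(ground_truth)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("m", "r", "r_prime", "theta_prime", "h")
  merged <- merge(features, decisions, by.x = "t", by.y = "frame")
  state_stats <- do.call(rbind, lapply(split(merged, merged$f), function(d) {
    data.frame(f = d$f[1],
               feature = cols,
               mean = vapply(cols, function(cc) mean(d[[cc]]), numeric(1)),
               sd = vapply(cols, function(cc) stats::sd(d[[cc]]), numeric(1)),
               n = nrow(d), row.names = NULL)
  }))
  utils::write.csv(state_stats, file.path(out_dir, "state_stats.csv"),
                   row.names = FALSE)
  out <- list(state_stats = state_stats)
  if (!is.null(ground_truth)) {
    if (!all(decisions$frame %in% ground_truth$t))
      stop("decisions and ground truth are misaligned")
    truth <- ground_truth$anomaly[match(decisions$frame, ground_truth$t)]
    conf <- matrix(0L, 2, 2, dimnames = list(c("Normal", "Not normal"),
                                             c("f(t) = 0", "f(t) = 1")))
    for (i in seq_along(truth))
      conf[truth[i] + 1L, decisions$f[i] + 1L] <-
        conf[truth[i] + 1L, decisions$f[i] + 1L] + 1L
    utils::write.csv(as.data.frame(conf),
                     file.path(out_dir, "confusion.csv"))
    out$confusion <- conf
  }
  plot_path <- file.path(out_dir, "features_plot.png")
  grDevices::png(plot_path, width = 900, height = 900, res = 96)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(length(cols), 1), mar = c(2, 4, 1, 1))
  anom_frames <- decisions$frame[decisions$f == 1L]
  for (cc in cols) {
    graphics::plot(features$t, features[[cc]], type = "l", xlab = "",
                   ylab = cc, col = "grey30")
    if (length(anom_frames) > 0L)
      graphics::abline(v = anom_frames, col = grDevices::adjustcolor("red", 0.15))
  }
  invisible(out)
}
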