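#' Anomaly detection on assembled feature vectors
#'
#' Frames where all five features — movement m, body extent r, extent
#' change r', direction change theta', and heart-rate proxy h — are present
#' become samples Z = (m, r, r', theta', h). A one-class SVM with Gaussian
#' kernel, trained on routine-day samples only, separates the bulk of the
#' training distribution from the origin in feature space; new samples
#' falling outside are flagged anomalous (f = 1). The outlier fraction is
#' controlled by nu and the kernel width by `kernel_gamma`.
#'
#' @name anomaly-model
NULL

#' Assemble complete feature vectors into a standardized sample matrix
#'
#' Keeps only frames with all five features present, records the kept-frame
#' mapping, and standardizes columns. Training calls fit the per-feature
#' mean/sd; evaluation matrices must reuse the training statistics (pass
#' `stats = model_or_samples`). Constant features (zero sd) are dropped with
#' a warning when fitting.
#'
#' @param features `data.frame` with columns `t`, `m`, `r`, `r_prime`,
#'   `theta_prime`, `h` (extra columns ignored).
#' @param stats `NULL` to fit standardization statistics, or a
#'   `sample_matrix` / `one_class_model` whose statistics are reused.
#' @return A `sample_matrix`: list with `X` (standardized matrix), `frame_index`,
#'   `center`, `scale`, `features` (kept column names).
#' @export
assemble_samples <- function(features, stats = NULL) {
  cols <- c("m", "r", "r_prime", "theta_prime", "h")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0L)
    stop("features lacks columns: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(features[, cols])
  if (!any(keep))
    stop("no complete samples: every frame is missing at least one feature")
  X <- as.matrix(features[keep, cols])
  frame_index <- if ("t" %in% names(features)) features$t[keep] else which(keep) - 1L
  if (is.null(stats)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    drop <- !is.finite(scale) | scale == 0
    if (any(drop)) {
      warning("dropping constant feature(s): ",
              paste(cols[drop], collapse = ", "))
      X <- X[, !drop, drop = FALSE]
      center <- center[!drop]; scale <- scale[!drop]
    }
  } else {
    if (inherits(stats, "one_class_model")) stats <- stats$train_stats
    center <- stats$center; scale <- stats$scale
    X <- X[, stats$features, drop = FALSE]
  }
  X <- sweep(sweep(X, 2, center), 2, scale, `/`)
  structure(list(X = X, frame_index = frame_index, center = center,
                 scale = scale, features = colnames(X)),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix: %d samples x %d features (%s)>\n",
              nrow(x$X), ncol(x$X), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Fit a one-class SVM on routine samples
#'
#' Solves the nu-parameterized one-class SVM with Gaussian kernel
#' `exp(-kernel_gamma * ||z - z'||^2)`; nu upper-bounds the fraction of
#' training samples treated as outliers (asymptotically). Input must be a
#' standardized [assemble_samples()] matrix; the training statistics are
#' stored in the model so evaluation data can be put on the same scale.
#'
#' @param train A `sample_matrix` with at least 2 rows.
#' @param nu Outlier-fraction bound, in (0, 1).
#' @param kernel_gamma Gaussian kernel width parameter, positive.
#' @return A `one_class_model`.
#' @export
fit_one_class <- function(train, nu, kernel_gamma) {
  stopifnot(inherits(train, "sample_matrix"),
            is_scalar_num(nu), nu > 0, nu < 1,
            is_scalar_num(kernel_gamma), kernel_gamma > 0)
  if (nrow(train$X) < 2L) stop("need at least 2 training samples")
  fit <- e1071::svm(train$X, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = kernel_gamma,
                    scale = FALSE, tolerance = 1e-7)
  structure(list(svm = fit, nu = nu, kernel_gamma = kernel_gamma,
                 train_stats = list(center = train$center,
                                    scale = train$scale,
                                    features = train$features)),
            class = "one_class_model")
}

#' @export
print.one_class_model <- function(x, ...) {
  cat(sprintf("<one_class_model: nu=%g, gamma=%g, %d support vectors>\n",
              x$nu, x$kernel_gamma, x$svm$tot.nSV))
  invisible(x)
}

#' Classify samples as routine (0) or anomalous (1)
#'
#' A sample is anomalous when its decision value falls below zero by more
#' than a small slack proportional to the model's offset: boundary support
#' vectors sit at a decision value of numerical zero, and the soft-margin
#' formulation counts only samples strictly outside the learned region as
#' outliers. Without the slack, at very small nu a sizable share of the
#' training set is flagged purely by the sign of rounding noise.
#'
#' @param object A `one_class_model`.
#' @param samples A `sample_matrix` standardized with the model's training
#'   statistics (see [assemble_samples()]).
#' @param ... Unused.
#' @return `data.frame` with columns `frame` and `f` (0 normal, 1 anomaly);
#'   a `state_series`.
#' @export
predict.one_class_model <- function(object, samples, ...) {
  stopifnot(inherits(samples, "sample_matrix"))
  if (!identical(colnames(samples$X), object$train_stats$features))
    stop("sample columns do not match the model's training features")
  if (nrow(samples$X) == 0L)
    return(data.frame(frame = integer(0), f = integer(0)))
  p <- predict(object$svm, samples$X, decision.values = TRUE)
  dv <- as.numeric(attr(p, "decision.values"))
  slack <- 1e-3 * max(abs(object$svm$rho), 1e-9)
  structure(data.frame(frame = samples$frame_index,
                       f = as.integer(dv < -slack)),
            class = c("state_series", "data.frame"))
}

#' Select (nu, kernel_gamma) by k-fold cross-validation
#'
#' The training data are routine-day samples only, so the objective is the
#' mean held-out routine-classification rate (fraction of held-out samples
#' classified normal) across folds; the maximizer is returned, ties broken
#' toward smaller nu, then smaller gamma (rejecting as little of the
#' routine data as possible).
#'
#' @param train A `sample_matrix`.
#' @param nu_grid Candidate nu values (default logarithmic 1e-4, 1e-3, 1e-2).
#' @param gamma_grid Candidate kernel widths (default 0.01 to 1 by 0.01).
#' @param k_folds Number of folds (default 5, >= 2).
#' @param seed Seed for the fold shuffle.
#' @return List with `nu`, `kernel_gamma`, and `report` (a `data.frame`
#'   with one row per grid point: `nu`, `kernel_gamma`, `mean_normal_rate`).
#' @export
select_params <- function(train, nu_grid = c(1e-4, 1e-3, 1e-2),
                          gamma_grid = seq(0.01, 1, by = 0.01),
                          k_folds = 5L, seed = 1L) {
  stopifnot(inherits(train, "sample_matrix"), k_folds >= 2L,
            length(nu_grid) > 0L, length(gamma_grid) > 0L)
  n <- nrow(train$X)
  if (n < k_folds) stop("fewer samples than folds")
  fold <- with_local_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  grid <- expand.grid(kernel_gamma = sort(gamma_grid), nu = sort(nu_grid))
  grid <- grid[order(grid$nu, grid$kernel_gamma), c("nu", "kernel_gamma")]
  rate <- numeric(nrow(grid))
  sub <- function(i) structure(
    list(X = train$X[i, , drop = FALSE], frame_index = train$frame_index[i],
         center = train$center, scale = train$scale,
         features = train$features), class = "sample_matrix")
  for (g in seq_len(nrow(grid))) {
    fold_rates <- vapply(seq_len(k_folds), function(k) {
      m <- fit_one_class(sub(fold != k), grid$nu[g], grid$kernel_gamma[g])
      mean(predict(m, sub(fold == k))$f == 0L)
    }, numeric(1))
    rate[g] <- mean(fold_rates)
  }
  best <- which.max(rate)    # grid sorted => ties resolve to smaller nu, gamma
  list(nu = grid$nu[best], kernel_gamma = grid$kernel_gamma[best],
       report = data.frame(nu = grid$nu, kernel_gamma = grid$kernel_gamma,
                           mean_normal_rate = rate))
}

#' Compare the one-class model with supervised two-class baselines
#'
#' Fits a two-class SVM (Gaussian kernel), linear discriminant analysis,
#' and a multilayer perceptron (two hidden layers of 20 units) on labeled
#' training data, plus a one-class SVM trained on the routine (label 0)
#' training rows only, and evaluates all four on the evaluation set.
#'
#' @param train A `sample_matrix` of training rows.
#' @param train_labels Integer labels (0 routine, 1 anomalous), both
#'   classes present.
#' @param eval A `sample_matrix` standardized with the same statistics.
#' @param eval_labels Labels for the evaluation rows.
#' @param nu,kernel_gamma Parameters for the one-class model.
#' @param seed Seed for the MLP initialization.
#' @param mlp_hidden Hidden layer sizes (default `c(20, 20)`).
#' @param mlp_epochs Training epochs for the MLP (default 300).
#' @return A `baseline_comparison`: named list (`ocsvm`, `svm`, `lda`,
#'   `mlp`) of 2x2 confusion matrices (rows: true normal / not normal,
#'   columns: predicted f = 0 / f = 1), with per-method accuracy as an
#'   attribute.
#' @export
baseline_compare <- function(train, train_labels, eval, eval_labels,
                             nu = 1e-4, kernel_gamma = 0.25, seed = 1L,
                             mlp_hidden = c(20L, 20L), mlp_epochs = 300L) {
  stopifnot(inherits(train, "sample_matrix"), inherits(eval, "sample_matrix"),
            length(train_labels) == nrow(train$X),
            length(eval_labels) == nrow(eval$X))
  if (length(unique(train_labels)) < 2L)
    stop("both classes must be present in the training labels")
  Xtr <- train$X; Xev <- eval$X
  ytr <- as.integer(train_labels); yev <- as.integer(eval_labels)

  normal_rows <- ytr == 0L
  oc_train <- structure(list(X = Xtr[normal_rows, , drop = FALSE],
                             frame_index = train$frame_index[normal_rows],
                             center = train$center, scale = train$scale,
                             features = train$features),
                        class = "sample_matrix")
  oc <- fit_one_class(oc_train, nu, kernel_gamma)
  pred_oc <- predict(oc, eval)$f

  sv <- e1071::svm(Xtr, factor(ytr), kernel = "radial", scale = FALSE)
  pred_sv <- as.integer(as.character(predict(sv, Xev)))

  ld <- MASS::lda(Xtr, grouping = factor(ytr))
  pred_ld <- as.integer(as.character(predict(ld, Xev)$class))

  ml <- mlp_fit(Xtr, ytr, hidden = mlp_hidden, epochs = mlp_epochs,
                seed = seed)
  pred_ml <- mlp_predict(ml, Xev)

  conf <- function(pred) {
    m <- matrix(0L, 2, 2,
                dimnames = list(c("Normal", "Not normal"),
                                c("f(t) = 0", "f(t) = 1")))
    for (i in seq_along(yev))
      m[yev[i] + 1L, pred[i] + 1L] <- m[yev[i] + 1L, pred[i] + 1L] + 1L
    m
  }
  out <- list(ocsvm = conf(pred_oc), svm = conf(pred_sv),
              lda = conf(pred_ld), mlp = conf(pred_ml))
  attr(out, "accuracy") <- vapply(list(pred_oc, pred_sv, pred_ld, pred_ml),
                                  function(p) mean(p == yev), numeric(1))
  names(attr(out, "accuracy")) <- names(out)
  class(out) <- "baseline_comparison"
  out
}

#' @export
print.baseline_comparison <- function(x, ...) {
  acc <- attr(x, "accuracy")
  for (nm in names(x)) {
    cat(sprintf("== %s (accuracy %.3f) ==\n", toupper(nm), acc[[nm]]))
    print(x[[nm]])
  }
  invisible(x)
}

#' Format a baseline comparison as a state-estimation table
#'
#' @param x A `baseline_comparison`.
#' @param format `"data.frame"` or `"markdown"`.
#' @return A `data.frame` or a character vector of markdown lines.
#' @export
format_comparison <- function(x, format = c("data.frame", "markdown")) {
  format <- match.arg(format)
  df <- do.call(rbind, lapply(names(x), function(nm) {
    m <- x[[nm]]
    data.frame(method = toupper(nm), truth = rownames(m),
               `f0` = m[, 1], `f1` = m[, 2], row.names = NULL,
               check.names = FALSE)
  }))
  names(df)[3:4] <- c("f(t) = 0", "f(t) = 1")
  if (format == "data.frame") return(df)
  c(sprintf("| %s |", paste(names(df), collapse = " | ")),
    sprintf("|%s|", paste(rep("---", ncol(df)), collapse = "|")),
    apply(df, 1, function(r) sprintf("| %s |", paste(r, collapse = " | "))))
}
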