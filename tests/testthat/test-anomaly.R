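# Gaussian feature tables for model tests (5 named feature columns)
gauss_features <- function(n, mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * 5, mean, sd), n))
  names(df) <- c("m", "r", "r_prime", "theta_prime", "h")
  df$t <- seq_len(n) - 1L
  df
}

test_that("assemble_samples keeps exactly the complete frames", {
  df <- gauss_features(10)
  df$r[c(2, 5, 7, 9)] <- NA          # e.g. missed eye detections
  sm <- assemble_samples(df)
  expect_equal(nrow(sm$X), 6)
  expect_equal(sm$frame_index, df$t[!is.na(df$r)])
  # standardized columns
  expect_equal(unname(colMeans(sm$X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(sm$X, 2, sd)), rep(1, 5), tolerance = 1e-12)

  # oracle recount on a messier table
  set.seed(8)
  df2 <- gauss_features(200, seed = 8)
  for (cc in c("m", "r", "r_prime", "theta_prime", "h"))
    df2[[cc]][sample(200, 30)] <- NA
  expected_rows <- sum(!is.na(df2$m) & !is.na(df2$r) & !is.na(df2$r_prime) &
                         !is.na(df2$theta_prime) & !is.na(df2$h))
  expect_equal(nrow(assemble_samples(df2)$X), expected_rows)

  # degenerate cases
  df3 <- gauss_features(20)
  df3$h <- 1
  expect_warning(sm3 <- assemble_samples(df3), "constant")
  expect_equal(ncol(sm3$X), 4)
  df4 <- gauss_features(5); df4$m <- NA
  expect_error(assemble_samples(df4), "no complete samples")
})

test_that("evaluation matrices reuse the training standardization", {
  train <- gauss_features(100, mean = 5, sd = 2)
  sm <- assemble_samples(train)
  ev <- assemble_samples(gauss_features(50, mean = 5, sd = 2, seed = 2),
                         stats = sm)
  expect_equal(ev$center, sm$center)
  expect_equal(ev$scale, sm$scale)
  # reusing via the fitted model gives the same matrix
  model <- fit_one_class(sm, nu = 0.1, kernel_gamma = 0.3)
  ev2 <- assemble_samples(gauss_features(50, mean = 5, sd = 2, seed = 2),
                          stats = model)
  expect_equal(ev$X, ev2$X)
})

test_that("the one-class SVM obeys the nu-property and flags far outliers", {
  for (seed in 1:5) {
    df <- gauss_features(400, seed = seed)
    sm <- assemble_samples(df)
    model <- fit_one_class(sm, nu = 0.05, kernel_gamma = 0.2)
    flagged <- mean(predict(model, sm)$f == 1L)
    expect_lte(flagged, 0.05 + 2 / sqrt(400))
  }
  df <- gauss_features(300)
  sm <- assemble_samples(df)
  model <- fit_one_class(sm, nu = 0.05, kernel_gamma = 0.2)
  # a point 10 sds away is anomalous; the medoid is normal
  far <- df[1, ]; far[, 1:5] <- sm$center + 10 * sm$scale
  far_sm <- assemble_samples(far, stats = sm)
  expect_equal(predict(model, far_sm)$f, 1L)
  med <- df[1, ]; med[, 1:5] <- sm$center
  expect_equal(predict(model, assemble_samples(med, stats = sm))$f, 0L)
})

test_that("predictions are deterministic and scale-covariant", {
  df <- gauss_features(150, seed = 3)
  sm <- assemble_samples(df)
  m1 <- fit_one_class(sm, nu = 0.02, kernel_gamma = 0.5)
  p1 <- predict(m1, sm)
  expect_identical(p1, predict(m1, sm))
  # multiplying a raw feature column by 10 changes no label
  df10 <- df; df10$m <- df10$m * 10
  sm10 <- assemble_samples(df10)
  m10 <- fit_one_class(sm10, nu = 0.02, kernel_gamma = 0.5)
  expect_equal(predict(m10, sm10)$f, p1$f)
  # duplicated rows get identical labels
  dup <- rbind(df[7, ], df[7, ])
  pd <- predict(m1, assemble_samples(dup, stats = sm))
  expect_equal(pd$f[1], pd$f[2])
  # column mismatch is an error
  dfc <- df; dfc$h <- 1
  smc <- suppressWarnings(assemble_samples(dfc))
  expect_error(predict(m1, smc), "do not match")
})

test_that("select_params maximizes held-out normal rate with the tie rule", {
  df <- gauss_features(120, seed = 6)
  sm <- assemble_samples(df)
  sel <- select_params(sm, nu_grid = c(0.01, 0.2), gamma_grid = c(0.1, 0.5),
                       k_folds = 3, seed = 42)
  rep <- sel$report
  expect_equal(nrow(rep), 4)
  best_rate <- max(rep$mean_normal_rate)
  chosen <- rep[rep$nu == sel$nu & rep$kernel_gamma == sel$kernel_gamma, ]
  expect_equal(chosen$mean_normal_rate, best_rate)
  # ties broken toward smaller nu then smaller gamma
  cands <- rep[rep$mean_normal_rate == best_rate, ]
  expect_equal(sel$nu, min(cands$nu))
  expect_equal(sel$kernel_gamma,
               min(cands$kernel_gamma[cands$nu == sel$nu]))
  # determinism under a fixed seed
  sel2 <- select_params(sm, nu_grid = c(0.01, 0.2), gamma_grid = c(0.1, 0.5),
                        k_folds = 3, seed = 42)
  expect_identical(sel$report, sel2$report)
})

test_that("baseline_compare separates well-separated classes and accounts", {
  set.seed(10)
  n0 <- 120; n1 <- 60
  df <- gauss_features(n0 + n1, seed = 10)
  df[(n0 + 1):(n0 + n1), 1:5] <- df[(n0 + 1):(n0 + n1), 1:5] + 8
  labels <- c(rep(0L, n0), rep(1L, n1))
  sm <- assemble_samples(df)
  cmp <- baseline_compare(sm, labels, sm, labels, nu = 0.01,
                          kernel_gamma = 0.3, seed = 1, mlp_epochs = 200)
  acc <- attr(cmp, "accuracy")
  expect_true(all(acc[c("svm", "lda", "mlp")] > 0.95))
  expect_gt(acc["ocsvm"], 0.9)
  # confusion rows sum to the class counts, for every method
  for (m in cmp) expect_equal(unname(rowSums(m)), c(n0, n1))
  # formatting
  tb <- format_comparison(cmp)
  expect_equal(nrow(tb), 8)
  expect_true(any(grepl("OCSVM", tb$method)))
  # single-class training labels are rejected
  expect_error(baseline_compare(sm, rep(0L, n0 + n1), sm, labels),
               "both classes")
})

test_that("shuffled labels drop the baselines to chance level", {
  set.seed(11)
  df <- gauss_features(150, seed = 11)
  df[101:150, 1:5] <- df[101:150, 1:5] + 8
  labels <- c(rep(0L, 100), rep(1L, 50))
  shuffled <- sample(labels)
  sm <- assemble_samples(df)
  cmp <- baseline_compare(sm, shuffled, sm, shuffled, seed = 1,
                          mlp_epochs = 100)
  majority <- 2 / 3
  expect_lt(attr(cmp, "accuracy")["lda"], majority + 0.15)
})
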