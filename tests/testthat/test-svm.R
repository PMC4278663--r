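test_that("feature extraction matches closed forms on degenerate windows", {
  cfg <- window_config(sensors = "wrist_right")
  m <- matrix(0.5, nrow = 10, ncol = 6,
              dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
  fv <- extract_features(m, cfg)
  expect_equal(unname(fv["wrist_right.ax.mean"]), 0.5)
  expect_equal(unname(fv["wrist_right.ax.sd"]), 0)
  expect_equal(unname(fv["wrist_right.ax.max"]), 0.5)
  expect_equal(unname(fv["wrist_right.ax.min"]), 0.5)
  expect_equal(unname(fv["wrist_right.ax.ptp"]), 0)
  expect_equal(unname(fv["wrist_right.ax.rms"]), 0.5)
  expect_equal(unname(fv["wrist_right.cor_ax_ay"]), 0)

  m2 <- m[1:3, ]
  m2[, "az"] <- c(1, 2, 3)
  fv2 <- extract_features(m2, cfg)
  expect_equal(unname(fv2["wrist_right.az.mean"]), 2)
  expect_equal(unname(fv2["wrist_right.az.sd"]), sqrt(2 / 3))
  expect_equal(unname(fv2["wrist_right.az.max"]), 3)
  expect_equal(unname(fv2["wrist_right.az.min"]), 1)
  expect_equal(unname(fv2["wrist_right.az.ptp"]), 2)
  expect_equal(unname(fv2["wrist_right.az.rms"]), sqrt(14 / 3))

  expect_error(extract_features(m[1, , drop = FALSE], cfg), "2 samples")
})

test_that("feature extraction agrees with direct recomputation", {
  cfg <- window_config(sensors = "wrist_right")
  chans <- c("ax", "ay", "az", "gx", "gy", "gz")
  set.seed(11)
  for (k in 1:50) {
    m <- matrix(stats::rnorm(20 * 6), nrow = 20,
                dimnames = list(NULL, chans))
    fv <- extract_features(m, cfg)
    for (cn in chans) {
      x <- m[, cn]
      key <- function(s) paste("wrist_right", cn, s, sep = ".")
      expect_equal(unname(fv[key("mean")]), sum(x) / 20, tolerance = 1e-12)
      expect_equal(unname(fv[key("sd")]),
                   sqrt(sum((x - mean(x))^2) / 20), tolerance = 1e-12)
      expect_equal(unname(fv[key("ptp")]), max(x) - min(x),
                   tolerance = 1e-12)
      expect_equal(unname(fv[key("rms")]), sqrt(sum(x^2) / 20),
                   tolerance = 1e-12)
    }
    expect_equal(unname(fv["wrist_right.cor_gx_gz"]),
                 stats::cor(m[, "gx"], m[, "gz"]), tolerance = 1e-12)
  }
})

test_that("training-set labelling and subsampling behave as specified", {
  sim <- clean_sim(1)
  cfg <- window_config()

  full <- make_training_set(sim$session, sim$truth, cfg, fraction = 1,
                            seed = 3)
  n_windows <- length(seq(0, sim$session$duration_s - cfg$w_s,
                          by = cfg$stride_s))
  expect_equal(nrow(full$features), n_windows)
  expect_setequal(levels(full$label), c("smoking", "not_smoking"))

  # no smoking annotations -> one-class error
  rest <- session_recording(list(toy_stream(n = 3000)), duration_s = 60)
  no_smoke <- annotations("cigarette", 0, 1)
  expect_error(make_training_set(rest, no_smoke, cfg), "empty")

  # fixed seed reproduces the subsample; seeds differ in general
  a <- make_training_set(sim$session, sim$truth, cfg, 0.3, seed = 5)
  b <- make_training_set(sim$session, sim$truth, cfg, 0.3, seed = 5)
  expect_identical(a$start_s, b$start_s)
  others <- vapply(6:15, function(s) {
    identical(make_training_set(sim$session, sim$truth, cfg, 0.3,
                                seed = s)$start_s, a$start_s)
  }, logical(1))
  expect_true(sum(others) < length(others))
})

test_that("training reaches zero error on separable data and chance on noise", {
  set.seed(21)
  # two well-separated clusters
  X <- rbind(matrix(stats::rnorm(60, 0, 0.3), ncol = 3),
             matrix(stats::rnorm(60, 5, 0.3), ncol = 3))
  colnames(X) <- c("f1", "f2", "f3")
  y <- factor(rep(c("smoking", "not_smoking"), each = 20),
              levels = c("smoking", "not_smoking"))
  fit <- train_svm(list(features = X, label = y), seed = 1)
  expect_equal(fit$train_error, 0)

  # one point per class with distinct values
  X1 <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2")))
  y1 <- factor(c("smoking", "not_smoking"),
               levels = c("smoking", "not_smoking"))
  expect_equal(train_svm(list(features = X1, label = y1),
                         seed = 1)$train_error, 0)

  # shuffled labels: the cross-validated misclassification index sits at
  # the class-balance baseline (training error itself can memorize)
  errs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    ys <- sample(y)
    train_svm(list(features = X, label = ys), seed = s)$cv_error
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.10)

  # identical features with conflicting labels are degenerate
  Xd <- matrix(c(1, 2, 1, 2), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2")))
  expect_error(train_svm(list(features = Xd, label = y1)), "degenerate")
})

test_that("decision function matches libsvm and survives JSON round trip", {
  set.seed(31)
  X <- rbind(matrix(stats::rnorm(80, 0, 1), ncol = 4),
             matrix(stats::rnorm(80, 3, 1), ncol = 4))
  colnames(X) <- paste0("f", 1:4)
  y <- factor(rep(c("smoking", "not_smoking"), each = 20),
              levels = c("smoking", "not_smoking"))
  fit <- train_svm(list(features = X, label = y), seed = 2)

  # cross-check against an independently fitted e1071 predictor
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  ref <- e1071::svm(Xs, y, kernel = "radial", gamma = fit$gamma,
                    cost = fit$cost, scale = FALSE,
                    class.weights = c(smoking = 1, not_smoking = 1))
  ref_dec <- attr(stats::predict(ref, Xs, decision.values = TRUE),
                  "decision.values")
  own <- svm_decision(fit, X)
  expect_equal(ifelse(own > 0, "smoking", "not_smoking"),
               as.character(stats::predict(ref, Xs)))

  path <- withr::local_tempfile(fileext = ".json")
  write_svm_model(fit, path)
  back <- read_svm_model(path)
  expect_equal(svm_decision(back, X), own, tolerance = 1e-10)
})

test_that("all classifier-emitted events last exactly one window", {
  sim <- simulate_session(sim_config(seed = 1))
  cfg <- window_config()
  tr <- make_training_set(sim$session, sim$truth, cfg, 0.3, seed = 1)
  model <- train_svm(tr, seed = 1)
  ev <- classify_session(sim$session, model, cfg)
  expect_gt(nrow(ev), 0)
  expect_equal(ev$end_s - ev$start_s, rep(cfg$w_s, nrow(ev)))
  expect_true(all(ev$confidence > 0))
  # output is non-overlapping, so it can feed aggregation directly
  if (nrow(ev) > 1) {
    expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
  }
})

test_that("rest-only sessions yield no classified events", {
  sim <- clean_sim(1)
  cfg <- window_config()
  tr <- make_training_set(sim$session, sim$truth, cfg, 0.3, seed = 1)
  model <- train_svm(tr, seed = 1)
  rest <- session_recording(list(toy_stream(n = 3000)), duration_s = 60)
  expect_equal(nrow(classify_session(rest, model, cfg)), 0L)
  short <- session_recording(list(toy_stream(n = 100)), duration_s = 2)
  expect_warning(out <- classify_session(short, model, cfg), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("both-positive sub-windows produce one event at the best offset", {
  sim <- clean_sim(3)
  cfg <- window_config()
  tr <- make_training_set(sim$session, sim$truth, cfg, 0.3, seed = 3)
  model <- train_svm(tr, seed = 3)
  ev <- classify_session(sim$session, model, cfg)
  # hand-simulate the rule: per main window, compute both sub-window
  # decisions and keep the better positive; then resolve overlaps
  w <- cfg$w_s
  expected <- list()
  for (m in seq(0, sim$session$duration_s - w, by = w)) {
    sub <- m + c(0, w / 2)
    sub <- sub[sub + w <= sim$session$duration_s + 1e-9]
    X <- t(vapply(sub, function(s0) {
      extract_features(smokesense:::session_window(sim$session, s0, cfg),
                       cfg)
    }, numeric(length(feature_layout(cfg)))))
    dec <- svm_decision(model, X)
    pos <- which(dec > 0)
    if (length(pos) == 0) next
    b <- pos[which.max(dec[pos])]
    prev <- if (length(expected) > 0) expected[[length(expected)]] else NULL
    if (!is.null(prev) && sub[b] < prev$end) {
      if (dec[b] > prev$conf) {
        expected[[length(expected)]] <-
          list(start = sub[b], end = sub[b] + w, conf = dec[b])
      }
    } else {
      expected[[length(expected) + 1L]] <-
        list(start = sub[b], end = sub[b] + w, conf = dec[b])
    }
  }
  expect_equal(ev$start_s, vapply(expected, `[[`, numeric(1), "start"))
  expect_equal(ev$confidence, vapply(expected, `[[`, numeric(1), "conf"),
               tolerance = 1e-12)
})
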