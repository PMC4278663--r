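# Sliding-window SVM puff-movement classifier.
#
# Each analysis window of w seconds is summarized by a p-dimensional
# vector of statistical features and classified smoking / not smoking by
# an RBF-kernel support vector machine trained on a seeded random subset
# of labelled windows. Detection walks a main window over the session in
# steps of w; inside each main window a small window of the same size is
# evaluated at offsets 0 and w/2 and the best-confidence smoking
# sub-window becomes the detected event, so event duration is always
# exactly w (the method's granularity limit).

FEATURE_FAMILIES <- c("mean", "sd", "max", "min", "ptp", "rms", "corr")

#' Sliding-window configuration
#'
#' @param w_s window size in seconds; 5, 10, 15 and 20 s are the
#'   candidate sizes swept in configuration selection, with 10 s the
#'   default operating point.
#' @param feature_set subset of the seven statistic families
#'   `mean, sd, max, min, ptp, rms, corr` (axis correlations).
#' @param sensors sensors whose channels contribute features.
#' @return an object of class `window_config`. The sub-window stride is
#'   fixed at `w_s / 2`.
#' @export
window_config <- function(w_s = 10, feature_set = FEATURE_FAMILIES,
                          sensors = "wrist_right") {
  stopifnot(w_s > 0, length(feature_set) >= 1,
            all(feature_set %in% FEATURE_FAMILIES), length(sensors) >= 1)
  structure(list(w_s = w_s, stride_s = w_s / 2,
                 feature_set = feature_set[order(match(feature_set,
                                                       FEATURE_FAMILIES))],
                 sensors = sensors),
            class = "window_config")
}

#' Names of the features a configuration produces
#' @param config a [window_config()].
#' @return character vector giving the fixed feature layout: per sensor,
#'   per channel, the scalar statistics in canonical order, then the
#'   accelerometer-axis and gyroscope-axis correlations.
#' @export
feature_layout <- function(config) {
  scalar <- setdiff(config$feature_set, "corr")
  out <- character(0)
  for (sn in config$sensors) {
    for (cn in CHANNEL_COLS) {
      out <- c(out, paste(sn, cn, scalar, sep = "."))
    }
    if ("corr" %in% config$feature_set) {
      out <- c(out,
               paste(sn, c("cor_ax_ay", "cor_ax_az", "cor_ay_az",
                           "cor_gx_gy", "cor_gx_gz", "cor_gy_gz"),
                     sep = "."))
    }
  }
  out
}

#' Extract the feature vector of one analysis window
#'
#' Per channel: mean, standard deviation (population), maximum, minimum,
#' peak-to-peak and root mean square; per sensor, Pearson correlations
#' between the accelerometer axes and between the gyroscope axes. A
#' zero-variance pair has correlation defined as 0.
#'
#' @param window named list (one element per sensor) of numeric matrices
#'   with columns `ax, ay, az, gx, gy, gz`, or a single such matrix for a
#'   one-sensor configuration.
#' @param config a [window_config()]; sensors must match the list names.
#' @return named numeric feature vector in the [feature_layout()] order.
#' @export
extract_features <- function(window, config = window_config()) {
  if (is.matrix(window)) {
    window <- stats::setNames(list(window), config$sensors[1])
  }
  stopifnot(all(config$sensors %in% names(window)))
  scalar <- setdiff(config$feature_set, "corr")
  vals <- numeric(0)
  for (sn in config$sensors) {
    m <- window[[sn]]
    if (!is.matrix(m) || nrow(m) < 2L) {
      stop("extract_features: window needs >= 2 samples per channel")
    }
    for (cn in CHANNEL_COLS) {
      x <- m[, cn]
      stats_all <- c(
        mean = mean(x),
        sd = sqrt(mean((x - mean(x))^2)),
        max = max(x),
        min = min(x),
        ptp = max(x) - min(x),
        rms = sqrt(mean(x^2)))
      vals <- c(vals, stats_all[scalar])
    }
    if ("corr" %in% config$feature_set) {
      vals <- c(vals,
                safe_cor(m[, "ax"], m[, "ay"]), safe_cor(m[, "ax"], m[, "az"]),
                safe_cor(m[, "ay"], m[, "az"]),
                safe_cor(m[, "gx"], m[, "gy"]), safe_cor(m[, "gx"], m[, "gz"]),
                safe_cor(m[, "gy"], m[, "gz"]))
    }
  }
  stats::setNames(vals, feature_layout(config))
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Slice the configured sensors of a session into the window block
# [start_s, start_s + w_s).
session_window <- function(session, start_s, config) {
  out <- lapply(config$sensors, function(sn) {
    s <- get_stream(session, sn)$samples
    keep <- s$t_s >= start_s & s$t_s < start_s + config$w_s
    as.matrix(s[keep, CHANNEL_COLS])
  })
  stats::setNames(out, config$sensors)
}

# Start times of windows tiling [0, duration - w] at the given stride.
tile_starts <- function(duration_s, w_s, stride_s) {
  if (duration_s < w_s) return(numeric(0))
  seq(0, duration_s - w_s, by = stride_s)
}

# Feature matrix for a set of window start times (rows = windows).
window_feature_matrix <- function(session, starts, config) {
  p <- length(feature_layout(config))
  X <- matrix(NA_real_, nrow = length(starts), ncol = p,
              dimnames = list(NULL, feature_layout(config)))
  for (i in seq_along(starts)) {
    X[i, ] <- extract_features(session_window(session, starts[i], config),
                               config)
  }
  X
}

#' Build a labelled training set of windows
#'
#' Windows tile the session at stride `w/2`; a window is labelled
#' `smoking` when its midpoint falls inside a ground-truth SPM interval.
#' A seeded uniform subsample of size `fraction` times the class count is
#' drawn from each class, mirroring training labels being randomly chosen
#' over the smoking and non-smoking annotations.
#'
#' @param session a [session_recording()].
#' @param truth an [annotations()] table containing `spm` rows.
#' @param config a [window_config()].
#' @param fraction fraction of each class to keep, in (0, 1].
#' @param seed integer seed making the subsample reproducible.
#' @return list with `features` (matrix), `label` (factor
#'   smoking/not_smoking) and `start_s` (window starts).
#' @export
make_training_set <- function(session, truth, config = window_config(),
                              fraction = 0.3, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  starts <- tile_starts(session$duration_s, config$w_s, config$stride_s)
  if (length(starts) == 0L) stop("make_training_set: session shorter than w")
  mids <- starts + config$w_s / 2
  spm <- truth[truth$kind == "spm", , drop = FALSE]
  smoking <- vapply(mids, function(m) {
    any(m >= spm$start_s & m < spm$end_s)
  }, logical(1))
  keep <- local({
    rng <- rng_state()
    on.exit(rng_restore(rng))
    set.seed(seed)
    idx <- logical(length(starts))
    for (cls in c(TRUE, FALSE)) {
      pool <- which(smoking == cls)
      n_take <- max(if (length(pool) > 0L) 1L else 0L,
                    round(fraction * length(pool)))
      if (n_take == 0L) {
        stop("make_training_set: class '",
             if (cls) "smoking" else "not_smoking",
             "' is empty; use a larger fraction or a session containing ",
             "both classes")
      }
      idx[sample(pool, n_take)] <- TRUE
    }
    idx
  })
  X <- window_feature_matrix(session, starts[keep], config)
  list(features = X,
       label = factor(ifelse(smoking[keep], "smoking", "not_smoking"),
                      levels = c("smoking", "not_smoking")),
       start_s = starts[keep])
}

# Save/restore the global RNG so seeded helpers do not disturb callers.
rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

rng_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Train the RBF-kernel window classifier
#'
#' Fits a maximum-margin classifier with a radial basis function kernel.
#' Hyperparameters (cost, kernel width) are selected by a small grid
#' search minimizing the cumulative misclassification ratio --
#' misclassified windows over total windows -- under seeded 3-fold
#' splitting of the training windows; the model is then refit on all
#' windows. Features are standardized with training-set center and scale,
#' stored with the model so it is portable.
#'
#' @param training list from [make_training_set()] (or any list with a
#'   `features` matrix and two-level `label` factor).
#' @param cost_grid,gamma_grid candidate hyperparameters; `gamma_grid`
#'   defaults to `c(0.25, 0.5, 1, 2) / p`.
#' @param folds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @param balanced weight the two classes inversely to their training
#'   frequency. Smoking windows are rare (a few percent of a session), so
#'   without this an error-minimizing fit can ignore them wholesale.
#' @return an object of class `svm_model` with the scaled support
#'   vectors, kernel coefficients, offset, feature layout and the
#'   training-set cumulative misclassification ratio
#'   (`$train_error`).
#' @export
train_svm <- function(training, cost_grid = c(1, 10, 100),
                      gamma_grid = NULL, folds = 3, seed = 1,
                      balanced = TRUE) {
  X <- training$features
  y <- training$label
  stopifnot(is.matrix(X), nlevels(factor(y)) == 2L, nrow(X) == length(y))
  y <- factor(y, levels = c("smoking", "not_smoking"))
  if (any(is.na(y))) stop("train_svm: labels must be smoking/not_smoking")
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (any(dup)) {
    for (i in which(dup)) {
      same <- which(colSums(abs(t(X) - X[i, ])) == 0)
      if (length(unique(y[same])) > 1L) {
        stop("train_svm: identical feature vectors carry both labels; ",
             "the classes are degenerate")
      }
    }
  }
  p <- ncol(X)
  if (is.null(gamma_grid)) gamma_grid <- c(0.25, 0.5, 1, 2) / p
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  cls_w <- if (balanced) {
    tab <- table(y)
    stats::setNames(as.numeric(length(y) / (2 * tab)), names(tab))
  } else {
    c(smoking = 1, not_smoking = 1)
  }
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_err <- rep(NA_real_, nrow(grid))
  fold_id <- local({
    rng <- rng_state()
    on.exit(rng_restore(rng))
    set.seed(seed)
    sample(rep_len(seq_len(folds), nrow(Xs)))
  })
  # folds stratified enough in practice; guard against one-class folds
  for (g in seq_len(nrow(grid))) {
    errs <- 0
    n_eval <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (!any(!tr) || nlevels(droplevels(y[tr])) < 2L) next
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        class.weights = cls_w, scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
      # weighted misclassification so the rare class counts
      wt <- cls_w[as.character(y[!tr])]
      errs <- errs + sum(wt * (pred != y[!tr]))
      n_eval <- n_eval + sum(wt)
    }
    cv_err[g] <- if (n_eval > 0) errs / n_eval else Inf
  }
  best <- which.min(cv_err)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], class.weights = cls_w,
                    scale = FALSE)
  model <- structure(list(
    layout = colnames(X),
    center = ctr, scale = scl,
    gamma = grid$gamma[best], cost = grid$cost[best],
    sv = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    sign_flip = 1,
    train_error = NA_real_,
    cv_error = cv_err[best]), class = "svm_model")
  # orient the decision function so positive values mean "smoking"
  raw <- svm_decision(model, X)
  ref <- stats::predict(fit, Xs)
  i <- which.max(abs(raw))
  if ((raw[i] > 0) != (ref[i] == "smoking")) model$sign_flip <- -1
  pred <- ifelse(svm_decision(model, X) > 0, "smoking", "not_smoking")
  model$train_error <- mean(pred != as.character(y))
  model
}

#' Evaluate the decision function of a trained model
#'
#' Positive values classify a window as smoking; the magnitude (distance
#' to the separating hyperplane in feature space) is used as the
#' detector's confidence.
#'
#' @param model an `svm_model`.
#' @param X feature matrix (rows = windows) in the model layout.
#' @return numeric vector of signed decision values.
#' @export
svm_decision <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == length(model$center))
  Xs <- scale(X, center = model$center, scale = model$scale)
  sq <- outer(rowSums(model$sv^2), rowSums(Xs^2), `+`) -
        2 * model$sv %*% t(Xs)
  K <- exp(-model$gamma * sq)
  model$sign_flip * (drop(crossprod(model$coefs, K)) - model$rho)
}

#' @export
print.svm_model <- function(x, ...) {
  cat("<svm_model> RBF kernel, gamma=", signif(x$gamma, 3),
      ", cost=", x$cost, ", ", nrow(x$sv), " support vectors, ",
      "training misclassification ratio ", signif(x$train_error, 3),
      "\n", sep = "")
  invisible(x)
}

#' Detect SPMs in a session with the sliding-window classifier
#'
#' Main windows tile the session at stride `w`; within each, the small
#' window is evaluated at offsets 0 and `w/2`. If either sub-window is
#' classified smoking, one event spanning the best-confidence sub-window
#' is emitted. All emitted events have duration exactly `w_s`. Because
#' the offset sub-window reaches `w/2` into the next main window,
#' consecutive emissions can overlap; overlaps are resolved by keeping
#' the higher-confidence event so the output is non-overlapping.
#'
#' @param session a [session_recording()].
#' @param model an `svm_model` trained on the same [window_config()]
#'   layout.
#' @param config a [window_config()] matching the model layout.
#' @return an [spm_events()] table with `source = "svm"` and the decision
#'   margin as `confidence`.
#' @export
classify_session <- function(session, model, config = window_config()) {
  stopifnot(identical(model$layout, feature_layout(config)))
  w <- config$w_s
  if (session$duration_s < w) {
    warning("classify_session: session shorter than one window")
    return(spm_events())
  }
  main_starts <- seq(0, session$duration_s - w, by = w)
  starts <- numeric(0)
  ends <- numeric(0)
  confs <- numeric(0)
  for (m in main_starts) {
    offs <- c(0, w / 2)
    sub <- m + offs
    sub <- sub[sub + w <= session$duration_s + 1e-9]
    if (length(sub) == 0L) next
    X <- window_feature_matrix(session, sub, config)
    dec <- svm_decision(model, X)
    pos <- which(dec > 0)
    if (length(pos) == 0L) next
    best <- pos[which.max(dec[pos])]
    k <- length(starts)
    if (k > 0L && sub[best] < ends[k]) {
      # overlap with the previous emission: keep the better one
      if (dec[best] > confs[k]) {
        starts[k] <- sub[best]
        ends[k] <- sub[best] + w
        confs[k] <- dec[best]
      }
    } else {
      starts <- c(starts, sub[best])
      ends <- c(ends, sub[best] + w)
      confs <- c(confs, dec[best])
    }
  }
  spm_events(starts, ends, source = "svm", confidence = confs)
}

#' Serialize a trained model to JSON
#' @param model an `svm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  obj <- unclass(model)
  obj$sv <- as.data.frame(obj$sv)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_svm_model()]
#' @param path JSON file path.
#' @return an `svm_model`.
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sv <- as.matrix(obj$sv)
  dimnames(obj$sv) <- NULL
  obj$center <- stats::setNames(as.numeric(obj$center), obj$layout)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$layout)
  structure(obj, class = "svm_model")
}
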