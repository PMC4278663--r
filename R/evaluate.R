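# Scoring detected events against ground truth, ROC configuration
# sweeps, operating-point selection, and smoking-topography summaries.

#' Match detected events to ground-truth intervals
#'
#' Greedy one-to-one matching in time order: each detected event (by
#' ascending start) is matched to the earliest unmatched truth interval
#' that overlaps it, or whose midpoint lies within `tolerance_s` of the
#' detected midpoint. Unmatched detected events are false positives;
#' unmatched truth events are false negatives.
#'
#' @param detected time-sorted events (`start_s`, `end_s`).
#' @param truth time-sorted truth intervals (`start_s`, `end_s`).
#' @param tolerance_s non-negative midpoint tolerance in seconds; 0 means
#'   pure interval overlap.
#' @return list with counts `tp`, `fp`, `fn` and a `pairs` data frame
#'   (`detected_idx`, `truth_idx`).
#' @export
match_events <- function(detected, truth, tolerance_s = 0) {
  if (tolerance_s < 0) stop("match_events: tolerance_s must be >= 0")
  nd <- nrow(detected)
  nt <- nrow(truth)
  used <- logical(nt)
  di <- integer(0)
  ti <- integer(0)
  for (i in seq_len(nd)) {
    ds <- detected$start_s[i]
    de <- detected$end_s[i]
    dm <- (ds + de) / 2
    for (j in seq_len(nt)) {
      if (used[j]) next
      overlap <- ds < truth$end_s[j] && truth$start_s[j] < de
      near <- tolerance_s > 0 &&
        abs(dm - (truth$start_s[j] + truth$end_s[j]) / 2) <= tolerance_s
      if (overlap || near) {
        used[j] <- TRUE
        di <- c(di, i)
        ti <- c(ti, j)
        break
      }
    }
  }
  list(tp = length(di), fp = nd - length(di), fn = nt - length(di),
       pairs = data.frame(detected_idx = di, truth_idx = ti))
}

# Count of tiled negative (non-smoking) windows of the given size: the
# operational denominator for FPR over interval events.
count_negative_windows <- function(duration_s, truth, window_s) {
  starts <- tile_starts(duration_s, window_s, window_s)
  if (length(starts) == 0L) return(0L)
  spm <- truth[truth$kind == "spm", , drop = FALSE]
  mids <- starts + window_s / 2
  sum(!vapply(mids, function(m) any(m >= spm$start_s & m < spm$end_s),
              logical(1)))
}

#' Sweep detector configurations and score each against ground truth
#'
#' For every configuration the detector is run on the session and its
#' events are matched to the truth SPM intervals; the result is one ROC
#' point per configuration. TPR is matched truth events over all truth
#' events; FPR is unmatched detections over the number of tiled
#' non-smoking windows (window size `w_s` for the SVM method, `max_spm_s`
#' for the edge method), clamped to `[0, 1]`.
#'
#' @param session a [session_recording()].
#' @param truth an [annotations()] table with `spm` rows.
#' @param configs list of [edge_config()]s (edge method) or of
#'   [window_config()]s (SVM method).
#' @param method `"edge"` or `"svm"`.
#' @param spec [filter_spec()] used by the edge method.
#' @param train_fraction,seed training-subsample settings for the SVM
#'   method.
#' @param tolerance_s matching tolerance passed to [match_events()].
#' @return data frame of class `roc_points`: `config_id, tpr, fpr, param,
#'   params_json`, where `param` is the swept scalar (`th` or `w_s`).
#' @export
roc_sweep <- function(session, truth, configs, method = c("edge", "svm"),
                      spec = filter_spec(), train_fraction = 0.3,
                      seed = 1, tolerance_s = 0) {
  method <- match.arg(method)
  stopifnot(length(configs) >= 1L)
  truth_spm <- truth[truth$kind == "spm", , drop = FALSE]
  rows <- lapply(seq_along(configs), function(k) {
    cfg <- configs[[k]]
    if (method == "edge") {
      det <- detect_spms_edge(session, spec, cfg)
      neg_w <- cfg$max_spm_s
      param <- cfg$th
    } else {
      training <- make_training_set(session, truth, cfg,
                                    fraction = train_fraction, seed = seed)
      model <- train_svm(training, seed = seed)
      det <- classify_session(session, model, cfg)
      neg_w <- cfg$w_s
      param <- cfg$w_s
    }
    m <- match_events(det, truth_spm, tolerance_s)
    n_neg <- count_negative_windows(session$duration_s, truth, neg_w)
    data.frame(
      config_id = k,
      tpr = if (nrow(truth_spm) > 0) m$tp / nrow(truth_spm) else 0,
      fpr = if (n_neg > 0) min(1, m$fp / n_neg) else 0,
      param = param,
      params_json = as.character(
        jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Select the best operating point of a ROC sweep
#'
#' Maximizes Youden's index `tpr - fpr`; ties are broken by lower `fpr`,
#' then by smaller swept parameter (lower threshold / smaller window),
#' then by grid order.
#'
#' @param points a `roc_points` data frame from [roc_sweep()] (columns
#'   `tpr`, `fpr` and optionally `param`, `config_id`).
#' @return the selected row.
#' @export
select_best <- function(points) {
  if (nrow(points) == 0L) stop("select_best: no ROC points supplied")
  param <- if (is.null(points$param)) rep(0, nrow(points)) else points$param
  cid <- if (is.null(points$config_id)) seq_len(nrow(points))
         else points$config_id
  ord <- order(-(points$tpr - points$fpr), points$fpr, param, cid)
  points[ord[1L], , drop = FALSE]
}

#' Summarize smoking topography from ground-truth annotations
#'
#' Per participant: mean puffs per cigarette, mean inter-puff interval
#' (end-to-start gaps between consecutive puffs within one cigarette) and
#' mean total cigarette time, followed by the cross-participant average
#' row. Values are rounded to one decimal, half up.
#'
#' @param truth_by_participant named list of [annotations()] tables, one
#'   per participant, each containing `puff` and `cigarette` rows.
#' @return data frame with columns `participant`, `puffs`,
#'   `interpuff_s`, `cigarette_time_s`; the last row is `"Average"`.
#' @export
summarize_topography <- function(truth_by_participant) {
  stopifnot(length(truth_by_participant) >= 1L)
  per <- lapply(names(truth_by_participant), function(pid) {
    ann <- truth_by_participant[[pid]]
    cig <- ann[ann$kind == "cigarette", , drop = FALSE]
    puff <- ann[ann$kind == "puff", , drop = FALSE]
    if (nrow(cig) == 0L) {
      stop("summarize_topography: participant ", pid, " has no cigarettes")
    }
    counts <- numeric(nrow(cig))
    gaps <- numeric(0)
    for (ci in seq_len(nrow(cig))) {
      idx <- if (all(is.na(puff$cigarette_index))) {
        which(puff$start_s >= cig$start_s[ci] & puff$end_s <= cig$end_s[ci])
      } else {
        which(puff$cigarette_index == ci)
      }
      counts[ci] <- length(idx)
      if (length(idx) > 1L) {
        pp <- puff[idx, , drop = FALSE]
        pp <- pp[order(pp$start_s), , drop = FALSE]
        gaps <- c(gaps, pp$start_s[-1L] - pp$end_s[-nrow(pp)])
      }
    }
    data.frame(participant = pid,
               puffs = mean(counts),
               interpuff_s = if (length(gaps) > 0) mean(gaps) else NA_real_,
               cigarette_time_s = mean(cig$end_s - cig$start_s))
  })
  per <- do.call(rbind, per)
  num <- c("puffs", "interpuff_s", "cigarette_time_s")
  for (cn in num) per[[cn]] <- round_half_up(per[[cn]], 1)
  rbind(per, topography_average(per))
}

#' Cross-participant average row of a topography table
#'
#' @param per_participant data frame with columns `puffs`,
#'   `interpuff_s`, `cigarette_time_s` (one row per participant).
#' @return one-row data frame labelled `"Average"`, means rounded to one
#'   decimal (half up).
#' @export
topography_average <- function(per_participant) {
  data.frame(
    participant = "Average",
    puffs = round_half_up(mean(per_participant$puffs), 1),
    interpuff_s = round_half_up(mean(per_participant$interpuff_s), 1),
    cigarette_time_s = round_half_up(mean(per_participant$cigarette_time_s),
                                     1))
}

#' Inter-observer percentage agreement
#'
#' For each paired count the agreement is the smaller number divided by
#' the larger number times 100; the result is the mean over pairs.
#'
#' @param counts_a,counts_b equal-length vectors of positive counts from
#'   two independent observers.
#' @return mean percentage agreement.
#' @export
interobserver_agreement <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) > 0)
  if (any(counts_a <= 0) || any(counts_b <= 0)) {
    stop("interobserver_agreement: counts must be positive")
  }
  mean(100 * pmin(counts_a, counts_b) / pmax(counts_a, counts_b))
}

#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up, matching how the
#' reported tables are rounded (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
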