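random_intervals <- function(n, max_gap = 30) {
  durs <- stats::runif(n, 1, 8)
  gaps <- stats::runif(n, 0.5, max_gap)
  starts <- cumsum(gaps) + c(0, cumsum(durs))[seq_len(n)]
  data.frame(start_s = starts, end_s = starts + durs)
}

test_that("event matching handles identity and empty inputs", {
  truth <- random_intervals(8)
  m <- match_events(truth, truth)
  expect_equal(m$tp, 8)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  m0 <- match_events(truth[0, ], truth)
  expect_equal(m0$tp, 0)
  expect_equal(m0$fn, 8)
  expect_error(match_events(truth, truth, tolerance_s = -1), ">= 0")
})

test_that("greedy matching is near-optimal against a bipartite oracle", {
  skip_if_not_installed("igraph")
  optimal_tp <- function(det, tru) {
    nd <- nrow(det)
    nt <- nrow(tru)
    if (nd == 0 || nt == 0) return(0L)
    edges <- integer(0)
    for (i in seq_len(nd)) {
      for (j in seq_len(nt)) {
        if (det$start_s[i] < tru$end_s[j] &&
            tru$start_s[j] < det$end_s[i]) {
          edges <- c(edges, i, nd + j)
        }
      }
    }
    if (length(edges) == 0) return(0L)
    g <- igraph::make_bipartite_graph(
      c(rep(FALSE, nd), rep(TRUE, nt)), edges)
    igraph::max_bipartite_match(g)$matching_size
  }
  set.seed(606)
  n_equal <- 0
  for (k in 1:1000) {
    det <- random_intervals(sample(0:10, 1))
    tru <- random_intervals(sample(1:10, 1))
    m <- match_events(det, tru)
    opt <- optimal_tp(det, tru)
    expect_gte(m$tp, opt - 1)
    expect_lte(m$tp, opt)
    # both lists are internally non-overlapping here, so greedy = optimal
    if (m$tp == opt) n_equal <- n_equal + 1
    expect_equal(m$tp + m$fn, nrow(tru))
  }
  expect_equal(n_equal, 1000)
})

test_that("edge ROC sweep has the threshold-endpoint behaviour", {
  sim <- clean_sim(1)
  truth <- sim$truth
  ths <- c(0.002, 0.005, 0.01, 0.03, 0.08, 0.5, 5)
  configs <- lapply(ths, function(th) edge_config(th = th))
  pts <- roc_sweep(sim$session, truth, configs, method = "edge")
  expect_equal(nrow(pts), length(ths))
  expect_true(all(pts$tpr >= 0 & pts$tpr <= 1))
  expect_true(all(pts$fpr >= 0 & pts$fpr <= 1))
  # permissive end detects everything; a threshold above every movement
  # difference detects nothing
  expect_equal(pts$tpr[1], 1)
  expect_equal(pts$tpr[nrow(pts)], 0)
  expect_equal(pts$fpr[nrow(pts)], 0)
  # monotone in th on a clean session
  expect_true(all(diff(pts$tpr) <= 1e-12))
  expect_true(all(diff(pts$fpr) <= 1e-12))
})

test_that("operating-point selection maximizes tpr - fpr with tie-breaks", {
  single <- data.frame(config_id = 1, tpr = 0.5, fpr = 0.1, param = 1)
  expect_equal(select_best(single)$config_id, 1)

  two <- data.frame(config_id = 1:2, tpr = c(0.95, 0.7),
                    fpr = c(0.05, 0.2), param = 1:2)
  expect_equal(select_best(two)$config_id, 1)
  expect_error(select_best(two[0, ]), "no ROC points")

  oracle_best <- function(pts) {
    best <- 1
    for (i in seq_len(nrow(pts))[-1]) {
      yi <- pts$tpr[i] - pts$fpr[i]
      yb <- pts$tpr[best] - pts$fpr[best]
      better <- yi > yb ||
        (yi == yb && (pts$fpr[i] < pts$fpr[best] ||
          (pts$fpr[i] == pts$fpr[best] && pts$param[i] < pts$param[best])))
      if (better) best <- i
    }
    pts[best, ]
  }
  set.seed(707)
  for (k in 1:1000) {
    n <- sample(1:15, 1)
    # quantized so ties actually occur
    pts <- data.frame(config_id = seq_len(n),
                      tpr = sample(seq(0, 1, 0.25), n, TRUE),
                      fpr = sample(seq(0, 1, 0.25), n, TRUE),
                      param = sample(seq_len(5), n, TRUE))
    expect_equal(select_best(pts)$config_id, oracle_best(pts)$config_id)
  }
})

test_that("selected point lies on the upper-left frontier", {
  set.seed(808)
  pts <- data.frame(config_id = 1:50, tpr = stats::runif(50),
                    fpr = stats::runif(50), param = 1:50)
  best <- select_best(pts)
  dominated <- any(pts$tpr > best$tpr & pts$fpr < best$fpr)
  expect_false(dominated)
})

test_that("topography summaries reproduce the reference averages", {
  per <- smoking_topography()
  avg <- topography_average(per)
  expect_equal(avg$puffs, 9.2)
  expect_equal(avg$interpuff_s, 42.7)
  expect_equal(avg$cigarette_time_s, 367.2)

  # single-cigarette session: one inter-puff gap of 8 s
  ann <- annotations(c("cigarette", "puff", "puff"),
                     c(0, 0, 10), c(12, 2, 12),
                     cigarette_index = c(NA, 1, 1))
  tab <- summarize_topography(list(p1 = ann))
  expect_equal(tab$interpuff_s[1], 8)
  expect_equal(tab$puffs[1], 2)
  expect_equal(tab$cigarette_time_s[1], 12)

  empty <- annotations("puff", 0, 1, cigarette_index = 1)
  expect_error(summarize_topography(list(p1 = empty)), "no cigarettes")
})

test_that("inter-observer agreement is min/max times 100, averaged", {
  expect_equal(interobserver_agreement(c(5, 7), c(5, 7)), 100)
  expect_equal(interobserver_agreement(8, 10), 80)
  set.seed(909)
  for (k in 1:1000) {
    n <- sample(1:10, 1)
    a <- stats::runif(n, 0.5, 50)
    b <- stats::runif(n, 0.5, 50)
    direct <- sum(vapply(seq_len(n), function(i) {
      100 * min(a[i], b[i]) / max(a[i], b[i])
    }, numeric(1))) / n
    expect_equal(interobserver_agreement(a, b), direct, tolerance = 1e-12)
  }
  expect_error(interobserver_agreement(c(1, 0), c(1, 2)), "positive")
})

test_that("reported one-decimal values round half away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.24, 1), 0.2)
  expect_equal(round_half_up(367.15, 1), 367.2)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})
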