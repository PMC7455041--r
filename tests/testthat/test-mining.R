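test_that("models rank by metric with deterministic tie-breaking", {
  recs <- list(make_record(1, 0.9, "a"), make_record(2, 0.5, "b"),
               make_record(3, 0.7, "c"))
  expect_equal(rank_models(recs, "accuracy", 2), c(1L, 3L))
  expect_equal(rank_models(recs, "accuracy", 3), c(1L, 3L, 2L))
  # equal accuracies fall back to mse, then to subsample id
  ties <- list(make_record(3, 0.8, "a", mse = 0.2),
               make_record(1, 0.8, "b", mse = 0.2),
               make_record(2, 0.8, "c", mse = 0.1))
  expect_equal(rank_models(ties, "accuracy", 3), c(2L, 1L, 3L))
  expect_equal(rank_models(ties, "mse", 3), c(2L, 1L, 3L))
  expect_error(rank_models(list(), "accuracy", 1), "no records")
  expect_error(rank_models(recs, "accuracy", 4), "between")
})

test_that("feature frequencies count appearances and conserve mass", {
  feats <- paste0("f", 1:6)
  recs <- list(make_record(1, 0.9, c("f2", "f3", "f4")),
               make_record(2, 0.8, c("f3", "f5", "f6")))
  tab <- feature_frequencies(recs, feats, m_total = 10)
  expect_equal(unname(tab$counts), c(0, 1, 2, 1, 1, 1))
  expect_equal(sum(tab$counts), 2 * 3)  # m_star records x 3 features each
  expect_equal(tab$m_star, 2)
  expect_equal(tab$m_total, 10L)
  single <- feature_frequencies(recs[1], feats)
  expect_equal(unname(single$counts), c(0, 1, 1, 1, 0, 0))
  expect_error(feature_frequencies(recs, paste0("f", 1:3)), "absent")
})

test_that("frequency counts grow elementwise with m_star", {
  set.seed(8)
  recs <- lapply(1:40, function(i)
    make_record(i, runif(1), sample(paste0("f", 1:20), 5)))
  feats <- paste0("f", 1:20)
  prev <- rep(0L, 20)
  for (m in c(5, 10, 20, 40)) {
    tab <- feature_frequencies(top_records(recs, "accuracy", m),
                               feats, m_total = 40)
    expect_true(all(tab$counts >= prev))
    prev <- tab$counts
  }
})

test_that("the false-discovery cutoff uses the one-sided normal quantile", {
  tab <- feature_frequencies(list(make_record(1, 1, c("f1", "f2"))),
                             paste0("f", 1:50))
  s6 <- fdr_cutoff(tab, 1e-6)
  expect_equal(round(s6$z, 2), 4.75)
  expect_equal(s6$cutoff, s6$mu + s6$z * s6$sigma)
  expect_equal(fdr_cutoff(tab, 0.5)$z, 0)
  expect_equal(fdr_cutoff(tab, 0.5)$cutoff, fdr_cutoff(tab, 0.5)$mu)
  expect_equal(round(fdr_cutoff(tab, 1e-2)$z, 3), 2.326)
  expect_error(fdr_cutoff(tab, 0), "alpha")
  # monotone: smaller alpha, larger cutoff
  alphas <- c(0.5, 0.1, 1e-3, 1e-6, 1e-12)
  cuts <- vapply(alphas, function(a) fdr_cutoff(tab, a)$cutoff, numeric(1))
  expect_true(all(diff(cuts) > 0))
})

test_that("a degenerate frequency distribution warns and returns mu", {
  recs <- list(make_record(1, 1, c("f1", "f2")),
               make_record(2, 1, c("f1", "f2")))
  tab <- feature_frequencies(recs, c("f1", "f2"))
  expect_warning(s <- fdr_cutoff(tab, 1e-3), "degenerate")
  expect_equal(s$cutoff, 2)
})

test_that("confusion counts at a cutoff match the worked example", {
  tab <- structure(list(counts = c(f1 = 10, f2 = 10, f3 = 2, f4 = 2),
                        m_star = 12, m_total = 12L, p = 4L),
                   class = "frequency_table")
  conf <- confusion_at_cutoff(tab, list(cutoff = 5), truth = "f1")
  expect_equal(c(conf$tp, conf$fp, conf$tn, conf$fn), c(1, 1, 2, 0))
  expect_equal(conf$fdr, 0.5)
  # cutoff above the max count: nothing positive, fdr 0 by convention
  none <- confusion_at_cutoff(tab, list(cutoff = 99), truth = "f1")
  expect_equal(c(none$tp, none$fp, none$fdr), c(0, 0, 0))
  # cutoff below the min count: everything positive
  all_pos <- confusion_at_cutoff(tab, list(cutoff = -1), truth = "f1")
  expect_equal(all_pos$tp + all_pos$fp, 4)
  # boundary equality is negative (strict inequality)
  edge <- confusion_at_cutoff(tab, list(cutoff = 10), truth = "f1")
  expect_equal(edge$tp + edge$fp, 0)
})

test_that("confusion counts agree with exhaustive per-feature comparison", {
  set.seed(21)
  for (i in 1:25) {
    p <- sample(3:12, 1)
    counts <- sample(0:20, p, replace = TRUE)
    names(counts) <- paste0("f", seq_len(p))
    tab <- structure(list(counts = counts, m_star = 20, m_total = 20L,
                          p = p), class = "frequency_table")
    cutoff <- runif(1, -1, 21)
    truth <- names(counts)[sample(p, sample(0:p, 1))]
    conf <- confusion_at_cutoff(tab, list(cutoff = cutoff), truth)
    brute <- table(factor(paste0(
      ifelse(counts > cutoff, "P", "N"),
      ifelse(names(counts) %in% truth, "T", "F")),
      levels = c("PT", "PF", "NF", "NT")))
    expect_equal(c(conf$tp, conf$fp, conf$tn, conf$fn),
                 unname(c(brute["PT"], brute["PF"], brute["NF"],
                          brute["NT"])))
    expect_equal(conf$tp + conf$fp + conf$tn + conf$fn, p)
  }
})

test_that("precision and recall use the standard definitions", {
  expect_equal(precision_recall(list(tp = 8, fp = 2, fn = 2)),
               c(precision = 0.8, recall = 0.8))
  expect_equal(precision_recall(list(tp = 5, fp = 0, fn = 0)),
               c(precision = 1, recall = 1))
  # empty denominators default to 1: no such mistake was possible
  expect_equal(precision_recall(list(tp = 0, fp = 0, fn = 3)),
               c(precision = 1, recall = 0))
  expect_equal(precision_recall(list(tp = 0, fp = 0, fn = 0)),
               c(precision = 1, recall = 1))
})

test_that("PR AUC integrates by trapezoid with a recall-zero anchor", {
  expect_equal(pr_auc(data.frame(recall = c(0, 1), precision = c(1, 1))), 1)
  expect_equal(pr_auc(data.frame(recall = c(0, 1), precision = c(1, 0))), 0.5)
  # anchored flat from recall 0 at the lowest-recall precision
  expect_equal(pr_auc(data.frame(recall = 0.5, precision = 0.8)), 0.4)
  expect_equal(pr_auc(data.frame(recall = c(0.2, 0.6),
                                 precision = c(1, 0.5))),
               0.2 * 1 + 0.4 * 0.75)
  # a perfect confusion sequence gives AUC one
  pts <- do.call(rbind, lapply(1:5, function(i)
    precision_recall(list(tp = i, fp = 0, fn = 0))))
  expect_equal(pr_auc(as.data.frame(pts)), 1)
})

test_that("the slicer scans the grids and picks the argmax M*", {
  # 6 informative records always carry f1,f2; 14 noise records do not
  set.seed(4)
  feats <- paste0("f", 1:30)
  recs <- c(
    lapply(1:6, function(i)
      make_record(i, 0.9 - i * 0.001, c("f1", "f2",
                                        sample(feats[3:30], 3)))),
    lapply(7:20, function(i)
      make_record(i, 0.5, sample(feats[3:30], 5))))
  sl <- run_slicer(recs, feats, truth = c("f1", "f2"),
                   m_star_grid = c(6, 20), alpha_grid = c(0.9, 1e-2, 1e-6))
  expect_s3_class(sl, "slicer_result")
  expect_true(all(sl$auc_per_m_star >= 0 & sl$auc_per_m_star <= 1))
  expect_equal(sl$optimal_m_star, 6)  # pure top slice beats diluted full set
  expect_true(all(dim(do.call(rbind, lapply(sl$frequency_tables, `[[`,
                                            "counts"))) == c(2, 30)))
  # truth-free mode reports positive sets instead of AUC
  proxy <- run_slicer(recs, feats, m_star_grid = c(6, 20),
                      alpha_grid = c(0.9, 1e-6))
  expect_equal(proxy$mode, "fdr_proxy")
  expect_true(all(is.na(proxy$auc_per_m_star)))
  expect_type(proxy$cells[["6"]][["0.9"]]$positives, "character")
  expect_error(run_slicer(recs, feats, m_star_grid = c(5, 99)), "M")
})

test_that("single-point M* grid with strong signal is its own optimum", {
  recs <- lapply(1:10, function(i) make_record(i, 0.9, c("f1", "f2")))
  sl <- run_slicer(recs, paste0("f", 1:10), truth = c("f1", "f2"),
                   m_star_grid = 10, alpha_grid = c(0.9, 1e-2))
  expect_equal(sl$optimal_m_star, 10)
})

test_that("ranked features order by frequency at the chosen M*", {
  recs <- c(lapply(1:4, function(i) make_record(i, 0.9, c("f3", "f1"))),
            lapply(5:6, function(i) make_record(i, 0.7, "f2")))
  sl <- run_slicer(recs, paste0("f", 1:4), truth = "f3",
                   m_star_grid = c(4, 6), alpha_grid = 0.5)
  rk <- ranked_features(sl, m_star = 6)
  expect_equal(rk$feature[1:3], c("f1", "f3", "f2"))
  expect_equal(rk$count, c(4L, 4L, 2L, 0L))
})
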