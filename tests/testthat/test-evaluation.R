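test_that("degenerate ROC inputs behave as specified", {
  expect_equal(compute_roc(c(3, 2, 1), c(TRUE, TRUE, FALSE))$auc, 1)
  expect_equal(compute_roc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(compute_roc(1:4, rep(TRUE, 4)), class = "bovw_roc_error")
})

test_that("AUC equals the Mann-Whitney pair-counting statistic", {
  withr::with_seed(20, {
    for (i in 1:30) {
      n <- sample(5:200, 1)
      scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
      labels <- runif(n) < runif(1, 0.2, 0.8)
      if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
      expect_equal(compute_roc(scores, labels)$auc,
                   mann_whitney_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    for (i in 1:5) {
      scores <- rnorm(80)
      labels <- runif(80) < 0.4
      if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(compute_roc(scores, labels)$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("ROC curves are monotone with fixed endpoints", {
  withr::with_seed(22, {
    for (i in 1:20) {
      n <- sample(4:100, 1)
      scores <- round(rnorm(n), 1)
      labels <- runif(n) < 0.5
      if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
      roc <- compute_roc(scores, labels)
      pts <- roc$points
      expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
      expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
      expect_true(all(diff(pts$fpr) >= 0))
      expect_true(all(diff(pts$tpr) >= 0))
      expect_true(all(diff(pts$threshold) <= 0))
    }
  })
})

test_that("operating point maximizes sensitivity under the specificity floor", {
  # endpoints guarantee feasibility
  sep <- compute_roc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(operating_point(sep, 0)$sensitivity, 1)
  expect_equal(operating_point(sep, 1)$sensitivity, 1)
  withr::with_seed(23, {
    scores <- round(rnorm(30), 1)
    labels <- runif(30) < 0.45
    labels[1:2] <- c(TRUE, FALSE)
    roc <- compute_roc(scores, labels)
    got <- operating_point(roc, 0.9)
    # exhaustive search over every curve threshold
    best <- c(-1, -1)
    for (i in seq_len(nrow(roc$points))) {
      sens <- roc$points$tpr[i]; spec <- 1 - roc$points$fpr[i]
      if (spec >= 0.9 && (sens > best[1] || (sens == best[1] && spec > best[2]))) {
        best <- c(sens, spec)
      }
    }
    expect_equal(c(got$sensitivity, got$specificity), best)
  })
})

test_that("confusion metrics match direct counting and handle edge cases", {
  labels <- rep(c(FALSE, TRUE), c(18, 12))
  flags <- labels
  expect_equal(confusion_metrics(flags, labels)$accuracy, 1)
  all_wrong <- confusion_metrics(!labels, labels)
  expect_equal(all_wrong$sensitivity, 0)
  expect_equal(all_wrong$specificity, 0)
  # undefined rather than zero on empty denominators
  und <- confusion_metrics(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(und$sensitivity))
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)),
               class = "bovw_invalid_input")
})

test_that("cross-dataset protocol rejects overlapping cohorts or ids", {
  sp <- small_pair()
  a <- sp$A$manifest
  b <- sp$B$manifest
  expect_error(run_cross_dataset(a, a), class = "bovw_protocol_error")
  b_bad <- b; b_bad$id[1] <- a$id[1]
  expect_error(run_cross_dataset(a, b_bad), class = "bovw_protocol_error")
})

test_that("the full protocol isolates test images and reports every curve", {
  sp <- small_pair()
  cfg <- run_config(codebook_k = 24L, quota_per_class = 1200L, max_pois = 100L,
                    n_codebooks = 2L, seed = 3)
  ev <- run_cross_dataset(sp$A$manifest, sp$B$manifest, cfg,
                          train_images = sp$A$images, test_images = sp$B$images)
  expect_s3_class(ev, "screening_eval")
  expect_setequal(ev$meta$train_ids, sp$A$manifest$id)
  expect_length(intersect(ev$meta$train_ids, ev$meta$test_ids), 0)
  expect_named(ev$rocs, c("bright", "red", "multi_test1", "multi_test2"))
  expect_false(is.null(ev$rocs$multi_test2))
  # dual-lesion subset: 6 normals + 2 both-lesion images
  expect_equal(ev$rocs$multi_test2$n_pos, 2)
  expect_equal(ev$rocs$multi_test2$n_neg, 6)
  expect_identical(ev$screening$referable,
                   ev$screening$flag_bright | ev$screening$flag_red)
  td <- tidy(ev)
  expect_true(all(c("curve", "metric", "value") %in% names(td)))
  g <- glance(ev)
  expect_true(all(g >= 0 & g <= 1, na.rm = TRUE))
})

test_that("within-cohort mode splits one manifest into disjoint halves", {
  sp <- small_pair()
  cfg <- run_config(codebook_k = 16L, quota_per_class = 800L, max_pois = 80L,
                    seed = 4)
  ev <- run_within_cohort(sp$A$manifest, cfg, images = sp$A$images,
                          split_seed = 9)
  expect_length(intersect(ev$meta$train_ids, ev$meta$test_ids), 0)
  expect_equal(sort(c(ev$meta$train_ids, ev$meta$test_ids)),
               sort(sp$A$manifest$id))
})

test_that("evaluation reports export to JSON and CSV", {
  sp <- small_pair()
  cfg <- run_config(codebook_k = 16L, quota_per_class = 800L, max_pois = 80L,
                    seed = 5)
  ev <- run_cross_dataset(sp$A$manifest, sp$B$manifest, cfg,
                          train_images = sp$A$images, test_images = sp$B$images)
  dir <- withr::local_tempdir()
  export_report(ev, dir)
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$n_test, nrow(sp$B$manifest))
  expect_true(file.exists(file.path(dir, "roc_bright.csv")))
  pts <- readr::read_csv(file.path(dir, "roc_red.csv"),
                         show_col_types = FALSE)
  expect_true(all(c("fpr", "tpr", "threshold") %in% names(pts)))
})
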