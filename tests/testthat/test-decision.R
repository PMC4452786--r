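test_that("a separable toy problem is fit perfectly and deterministically", {
  toy <- toy_histograms(12, 12, seed = 2)
  m1 <- train_detector(toy$hists, toy$labels, "bright")
  expect_true(all((score_detector(m1, toy$hists) > 0) == toy$labels))
  m2 <- train_detector(toy$hists, toy$labels, "bright")
  probe <- toy_histograms(5, 5, seed = 99)$hists
  expect_identical(score_detector(m1, probe), score_detector(m2, probe))
})

test_that("single-class training sets are refused", {
  toy <- toy_histograms(6, 6, seed = 1)
  expect_error(train_detector(toy$hists, rep(TRUE, 12), "red"),
               class = "bovw_data_error")
  expect_error(train_detector(toy$hists[1:3, ], c(TRUE, FALSE, FALSE), "red"),
               class = "bovw_data_error")
})

test_that("flipping all labels inverts the score ranking (AUC -> 1 - AUC)", {
  toy <- toy_histograms(20, 20, k = 8, shift = 3, seed = 7)
  m <- train_detector(toy$hists, toy$labels, "bright")
  m_flip <- train_detector(toy$hists, !toy$labels, "bright")
  s <- score_detector(m, toy$hists)
  s_flip <- score_detector(m_flip, toy$hists)
  auc <- compute_roc(s, toy$labels)$auc
  auc_flip <- compute_roc(s_flip, toy$labels)$auc
  expect_equal(auc_flip, 1 - auc, tolerance = 1e-9)
})

test_that("zero histograms score as the bias term and dimensions are checked", {
  toy <- toy_histograms(8, 8, seed = 3)
  m <- train_detector(toy$hists, toy$labels, "red")
  expect_equal(score_detector(m, rep(0, 6)), m$b)
  expect_error(score_detector(m, rep(0, 7)), class = "bovw_invalid_input")
})

test_that("linear scores are monotone along an interpolation path", {
  toy <- toy_histograms(10, 10, seed = 5)
  m <- train_detector(toy$hists, toy$labels, "bright")
  s <- score_detector(m, toy$hists)
  lo <- toy$hists[which.min(s), ]; hi <- toy$hists[which.max(s), ]
  path <- t(vapply(seq(0, 1, length.out = 11),
                   function(a) (1 - a) * lo + a * hi, numeric(6)))
  expect_true(all(diff(score_detector(m, path)) >= -1e-12))
})

test_that("fusion implements the OR truth table exactly", {
  expect_false(fuse(FALSE, FALSE))
  expect_true(fuse(TRUE, FALSE))
  expect_true(fuse(FALSE, TRUE))
  expect_true(fuse(TRUE, TRUE))
})

test_that("fused score is the max and thresholds like the OR of flags", {
  expect_equal(fuse_score(-1, -2), -1)
  withr::with_seed(11, {
    sb <- rnorm(500); sr <- rnorm(500); t <- rnorm(500)
    expect_identical(fuse_score(sb, sr) > t, fuse(sb > t, sr > t))
  })
})

test_that("detectors round-trip bit-exactly through their file format", {
  toy <- toy_histograms(8, 8, seed = 6)
  m <- train_detector(toy$hists, toy$labels, "red", cost = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  save_detector(m, path)
  m2 <- load_detector(path)
  expect_identical(m2$w, m$w)
  expect_identical(m2$b, m$b)
  expect_identical(m2$normal_median, m$normal_median)
  expect_identical(m2$lesion, m$lesion)
  writeLines("garbage", path)
  expect_error(load_detector(path), class = "bovw_format_error")
})

test_that("screening joins two detectors and refuses mismatched codebooks", {
  sp <- small_pair()
  cfg <- run_config(seed = 2)
  ids <- sp$A$manifest$id[1:6]
  pois <- detect_manifest(sp$A$manifest[1:6, ], cfg, images = sp$A$images)
  cb_b <- learn_codebook_kmeans(pois, 6, 1)
  cb_r <- learn_codebook_kmeans(pois, 6, 2)
  hb <- encode_cohort(pois, cb_b, "l2", ids = ids)
  hr <- encode_cohort(pois, cb_r, "l2", ids = ids)
  mkmodel <- function(h, lesion) {
    labs <- rep(c(TRUE, FALSE), length.out = nrow(h))
    m <- train_detector(h$histogram, labs, lesion)
    m$codebook_ref <- attr(h, "codebook_ref")
    m
  }
  mb <- mkmodel(hb, "bright")
  mr <- mkmodel(hr, "red")
  out <- screen_images(hb, hr, mb, mr)
  expect_identical(out$referable, out$flag_bright | out$flag_red)
  expect_error(screen_images(hb, hr, mr, mb), class = "bovw_consistency_error")
})
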