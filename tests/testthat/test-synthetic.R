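test_that("background generation is deterministic and seed-sensitive", {
  a <- generate_background(c(96, 96), 5)
  b <- generate_background(c(96, 96), 5)
  expect_identical(a$image, b$image)
  d <- generate_background(c(96, 96), 6)
  expect_gt(sum(a$image != d$image), 0)
  expect_false(a$label_bright)
  expect_false(a$label_red)
})

test_that("background values are in range and the surround is dark", {
  img <- generate_background(c(120, 150), 3)$image
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)
  H <- dim(img)[1]; W <- dim(img)[2]
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  outside <- sqrt((yy - (H + 1) / 2)^2 + (xx - (W + 1) / 2)^2) > 0.46 * min(H, W) + 2
  expect_lt(mean(img[outside]), 0.1)
})

test_that("undersized backgrounds are rejected", {
  expect_error(generate_background(c(32, 128), 1), class = "bovw_config_error")
})

test_that("lesion spec validation catches empty or out-of-range intervals", {
  expect_error(lesion_spec("bright", count_range = c(3, 1)),
               class = "bovw_config_error")
  expect_error(lesion_spec("red", contrast_range = c(0.2, 1.5)),
               class = "bovw_config_error")
  expect_error(lesion_spec("red", radius_range = c(0, 4)),
               class = "bovw_config_error")
})

test_that("zero-count lesion spec leaves the image untouched", {
  bg <- generate_background(c(96, 96), 2)
  out <- add_lesions(bg, lesion_spec("bright", count_range = c(0, 0)), 9)
  expect_identical(out$image, bg$image)
  expect_false(out$label_bright)
  expect_length(out$roi_masks, 0)
})

test_that("lesion bookkeeping: counts, labels and mask geometry", {
  bg <- generate_background(c(128, 128), 4)
  out <- add_lesions(bg, lesion_spec("bright", count_range = c(3, 3)), 10)
  expect_length(out$roi_masks, 3)
  expect_true(out$label_bright)
  expect_false(out$label_red)
  expect_true(all(vapply(out$roi_masks, function(m) identical(dim(m), c(128L, 128L)),
                         logical(1))))
  both <- add_lesions(out, lesion_spec("red", count_range = c(2, 2)), 11)
  expect_true(both$label_bright && both$label_red)
  expect_identical(both$roi_kinds, c("bright", "bright", "bright", "red", "red"))
})

test_that("bright lesions raise and red lesions lower local intensity", {
  bg <- generate_background(c(160, 160), 8)
  contrast_sign <- function(kind) {
    out <- add_lesions(bg, lesion_spec(kind, count_range = c(3, 3)), 21)
    lum <- 0.299 * out$image[, , 1] + 0.587 * out$image[, , 2] +
      0.114 * out$image[, , 3]
    vapply(out$roi_masks, function(m) {
      ring <- (EBImage::dilate(m, EBImage::makeBrush(9, "disc")) - m) > 0
      mean(lum[m > 0]) - mean(lum[ring])
    }, numeric(1))
  }
  expect_true(all(contrast_sign("bright") > 0))
  expect_true(all(contrast_sign("red") < 0))
})

test_that("cohort generation respects configured class counts and labels", {
  cc <- cohort_config("t", n_normal = 6, n_bright_only = 0, n_red_only = 3,
                      n_both = 2, image_size = c(96, 96), jpeg_quality = NULL,
                      seed = 13)
  out <- generate_cohort(cc)
  m <- out$manifest
  expect_equal(nrow(m), 11)
  expect_equal(sum(!m$label_bright & !m$label_red), 6)
  expect_equal(sum(m$label_bright & m$label_red), 2)
  expect_equal(sum(m$label_red & !m$label_bright), 3)
  expect_equal(sum(m$label_bright & !m$label_red), 0)
  # label soundness against the actual ROI masks
  for (i in seq_len(nrow(m))) {
    im <- out$images[[i]]
    expect_identical(im$label_bright, "bright" %in% im$roi_kinds)
    expect_identical(im$label_red, "red" %in% im$roi_kinds)
  }
})

test_that("cohorts are bit-reproducible and differ across image sizes", {
  cc <- cohort_config("t", n_normal = 2, n_red_only = 1, image_size = c(96, 96),
                      jpeg_quality = 85, seed = 3)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$images[[3]]$image, b$images[[3]]$image)
  expect_identical(a$manifest, b$manifest)
  cc2 <- cc; cc2$image_size <- c(128L, 128L)
  c2 <- generate_cohort(cc2)
  expect_identical(c2$manifest[c("id", "label_bright", "label_red")],
                   a$manifest[c("id", "label_bright", "label_red")])
  expect_false(identical(dim(c2$images[[1]]$image), dim(a$images[[1]]$image)))
})

test_that("written cohorts produce a loadable manifest and mask files", {
  dir <- withr::local_tempdir()
  cc <- cohort_config("disk", n_normal = 2, n_bright_only = 1,
                      image_size = c(96, 96), jpeg_quality = 90, seed = 5)
  out <- generate_cohort(cc, out_dir = dir)
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(manifest_paths(man))))
  masks <- roi_mask_paths(man$id[man$label_bright], dir, "bright")
  expect_gte(length(masks), 1)
  m <- png::readPNG(masks[1])
  expect_identical(dim(m)[1:2], c(96L, 96L))
})
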