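# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small two-cohort in-memory pair with a handful of images per class.
small_pair <- function() {
  cached("small_pair", {
    cc <- study_cohort_configs(42)
    cc$train$n_normal <- 8L; cc$train$n_bright_only <- 3L
    cc$train$n_red_only <- 2L; cc$train$n_both <- 2L
    cc$train$image_size <- c(192L, 256L)
    cc$test$n_normal <- 6L; cc$test$n_red_only <- 3L; cc$test$n_both <- 2L
    cc$test$image_size <- c(240L, 320L)
    A <- generate_cohort(cc$train)
    B <- generate_cohort(cc$test)
    names(A$images) <- A$manifest$id
    names(B$images) <- B$manifest$id
    list(A = A, B = B, configs = cc)
  })
}

# One small lesioned image plus its detected PoIs.
small_lesioned <- function() {
  cached("small_lesioned", {
    img <- generate_background(c(160, 160), 7)
    img <- add_lesions(img, lesion_spec("bright", count_range = c(3, 3)), 11)
    img <- add_lesions(img, lesion_spec("red", count_range = c(4, 4)), 12)
    pois <- detect_pois(img$image, detector_config(), image_id = "fix01")
    list(image = img, pois = pois)
  })
}

# Flat synthetic image with a single Gaussian blob (for localization checks).
blob_image <- function(center_yx = c(65, 65), sigma = 6, amp = 0.4,
                       size = c(128, 128), base = 0.3) {
  yy <- matrix(seq_len(size[1]), size[1], size[2])
  xx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  g <- amp * exp(-((yy - center_yx[1])^2 + (xx - center_yx[2])^2) / (2 * sigma^2))
  img <- array(base, dim = c(size, 3))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + g
  pmin(img, 1)
}

# Brute-force Mann-Whitney pair-counting statistic (ties count 1/2).
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Random synthetic histogram set: positives load word 1, negatives word 2,
# with Poisson noise on the remaining words.
toy_histograms <- function(n_pos, n_neg, k = 6, shift = 8, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    m <- matrix(rpois(n * k, 2), n, k)
    m[seq_len(n_pos), 1] <- m[seq_len(n_pos), 1] + shift
    m[n_pos + seq_len(n_neg), 2] <- m[n_pos + seq_len(n_neg), 2] + shift
    m <- m / pmax(sqrt(rowSums(m^2)), 1e-12)
    list(hists = m, labels = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
  })
}
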