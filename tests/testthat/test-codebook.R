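two_clouds <- function(n_per = 60, d = 5, sep = 10, spread = 0.5, seed = 3) {
  withr::with_seed(seed, {
    mu1 <- rep(0, d); mu2 <- c(sep, rep(0, d - 1))
    x <- rbind(matrix(rnorm(n_per * d, sd = spread), n_per, d),
               matrix(rnorm(n_per * d, sd = spread), n_per, d) +
                 matrix(mu2, n_per, d, byrow = TRUE))
    list(x = x, means = rbind(colMeans(x[1:n_per, ]),
                              colMeans(x[n_per + 1:n_per, ])),
         assignment = rep(1:2, each = n_per))
  })
}

test_that("per-class descriptor sampling is deterministic and quota-bounded", {
  p <- small_lesioned()$pois
  cls <- rep(c("a", "b"), length.out = nrow(p))
  s1 <- sample_descriptors(p, cls, 10, 5)
  s2 <- sample_descriptors(p, cls, 10, 5)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$class)), array(c(10L, 10L)))
  all_of_them <- sample_descriptors(p, cls, 10000, 5)
  expect_equal(nrow(all_of_them), nrow(p))
})

test_that("k = 1 recovers the componentwise mean", {
  x <- matrix(rnorm(200), 50, 4)
  cb <- learn_codebook_kmeans(x, 1, 7)
  expect_equal(as.numeric(cb$words), colMeans(x), tolerance = 1e-8)
})

test_that("k-means recovers two well-separated cloud means", {
  tc <- two_clouds()
  cb <- learn_codebook_kmeans(tc$x, 2, 11)
  sep_norm <- sqrt(sum((tc$means[1, ] - tc$means[2, ])^2))
  # match centroids to generating means up to ordering
  d <- outer(1:2, 1:2, Vectorize(function(i, j)
    sqrt(sum((cb$words[i, ] - tc$means[j, ])^2))))
  best <- min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1])
  expect_lt(best, 2 * 0.05 * sep_norm)
})

test_that("a pool of k distinct points is a zero-inertia fixed point", {
  x <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  cb <- learn_codebook_kmeans(x, 3, 1)
  expect_equal(cb$words[order(cb$words[, 1], cb$words[, 2]), ],
               x[order(x[, 1], x[, 2]), ], ignore_attr = TRUE)
  tr <- attr(cb, "inertia_trace")
  expect_equal(tr[length(tr)], 0)
})

test_that("within-cluster inertia is non-increasing across Lloyd iterations", {
  withr::with_seed(2, {
    for (i in 1:4) {
      x <- matrix(rnorm(80 * 6), 80, 6)
      cb <- learn_codebook_kmeans(x, 4, i, max_iter = 30)
      expect_true(all(diff(attr(cb, "inertia_trace")) <= 1e-9))
    }
  })
})

test_that("final inertia is competitive with a multi-restart Lloyd oracle", {
  withr::with_seed(8, {
    for (i in 1:3) {
      x <- matrix(rnorm(150 * 4), 150, 4) +
        matrix(sample(0:2, 150, replace = TRUE) * 4, 150, 4)
      k <- sample(2:4, 1)
      cb <- learn_codebook_kmeans(x, k, i)
      mine <- min(attr(cb, "inertia_trace"))
      oracle <- stats::kmeans(x, k, nstart = 50, iter.max = 100,
                              algorithm = "Lloyd")$tot.withinss
      expect_lte(mine, oracle * 1.05)
    }
  })
})

test_that("insufficient pools are refused", {
  x <- matrix(rnorm(12), 3, 4)
  expect_error(learn_codebook_kmeans(x, 5, 1), class = "bovw_data_error")
  expect_error(learn_codebook_random(x, 5, 1), class = "bovw_data_error")
})

test_that("random codebooks draw words from the pool deterministically", {
  x <- matrix(rnorm(40), 10, 4)
  cb1 <- learn_codebook_random(x, 4, 9)
  cb2 <- learn_codebook_random(x, 4, 9)
  expect_identical(cb1$words, cb2$words)
  in_pool <- apply(cb1$words, 1, function(w)
    any(apply(x, 1, function(r) all(r == w))))
  expect_true(all(in_pool))
  full <- learn_codebook_random(x, 10, 2)
  expect_equal(full$words[order(full$words[, 1]), ], x[order(x[, 1]), ],
               ignore_attr = TRUE)
})

test_that("codebooks round-trip bit-exactly and preserve word order", {
  cb <- learn_codebook_kmeans(matrix(rnorm(400), 100, 4), 8, 3)
  path <- withr::local_tempfile(fileext = ".txt")
  save_codebook(cb, path)
  cb2 <- load_codebook(path)
  expect_identical(cb2$words, unname(cb$words))
  expect_identical(cb2$k, cb$k)
  expect_identical(cb2$provenance, cb$provenance)
  expect_identical(cb2$seed, cb$seed)
})

test_that("truncated codebook files raise a format error", {
  cb <- learn_codebook_kmeans(matrix(rnorm(400), 100, 4), 8, 3)
  path <- withr::local_tempfile(fileext = ".txt")
  save_codebook(cb, path)
  writeLines(utils::head(readLines(path), 6), path)
  expect_error(load_codebook(path), class = "bovw_format_error")
  writeLines("not a codebook", path)
  expect_error(load_codebook(path), class = "bovw_format_error")
})
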