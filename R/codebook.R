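descriptor_matrix <- function(x) {
  if (is.matrix(x)) x
  else if (is.data.frame(x) && "descriptor" %in% names(x)) x$descriptor
  else stop_invalid("expected a descriptor matrix or a PoI tibble")
}

# squared Euclidean cross-distances between rows of a (n x D) and b (k x D)
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Sample descriptors per class for codebook learning
#'
#' Uniform sampling without replacement, at most `quota` descriptors per
#' class, deterministic given `seed`. Classes are sampled in sorted name
#' order so the pool does not depend on input row order across classes.
#'
#' @param pois PoI tibble (rows are descriptors).
#' @param class Character vector, one class label per row of `pois` (e.g.
#'   `"lesion"` / `"normal"`).
#' @param quota Maximum descriptors kept per class.
#' @param seed Integer seed.
#' @return The sampled PoI tibble with a `class` column; per class,
#'   `min(quota, available)` rows.
#' @export
sample_descriptors <- function(pois, class, quota, seed) {
  if (length(class) != nrow(pois)) {
    stop_invalid("`class` must have one label per PoI row")
  }
  pois$class <- class
  with_seed_(seed, {
    picked <- lapply(sort(unique(class)), function(cl) {
      rows <- which(class == cl)
      if (length(rows) > quota) rows <- sort(sample(rows, quota))
      pois[rows, ]
    })
    dplyr::bind_rows(picked)
  })
}

new_codebook <- function(words, provenance, seed, training_meta = "") {
  structure(list(words = words, k = nrow(words), provenance = provenance,
                 seed = as.integer(seed), training_meta = training_meta),
            class = "bovw_codebook")
}

#' @export
print.bovw_codebook <- function(x, ...) {
  cat(sprintf("<bovw_codebook> k=%d D=%d provenance=%s seed=%d\n",
              x$k, ncol(x$words), x$provenance, x$seed))
  invisible(x)
}

#' Identifier of a codebook (content hash)
#' @param codebook A `bovw_codebook`.
#' @return A short character hash of the words.
#' @export
codebook_id <- function(codebook) {
  substr(rlang::hash(round(codebook$words, 12)), 1, 12)
}

#' Learn a visual codebook by k-means
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ seeding, run
#' `restarts` times from derived seeds with the lowest-inertia solution
#' kept. Each run stops when total centroid movement falls below `tol` or
#' after `max_iter` iterations; a cluster that empties is re-seeded with the
#' point farthest from its assigned centroid. The per-iteration total
#' within-cluster inertia of the winning run is recorded in the
#' `inertia_trace` attribute (non-increasing by construction of Lloyd's
#' updates).
#'
#' @param pool Descriptor matrix (n x D) or PoI tibble; `n >= k`.
#' @param k Number of visual words.
#' @param seed Integer seed (drives k-means++ seeding).
#' @param max_iter,tol Stopping rule.
#' @param restarts Independent seeded runs; the best is returned.
#' @return A `bovw_codebook` with `provenance = "kmeans"`.
#' @export
learn_codebook_kmeans <- function(pool, k, seed, max_iter = 50L, tol = 1e-6,
                                  restarts = 5L) {
  X <- descriptor_matrix(pool)
  n <- nrow(X)
  if (n < k) {
    stop_invalid(sprintf("pool has %d descriptors but k = %d", n, k),
                 "bovw_data_error")
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    cand <- lloyd_once(X, k, derive_seed(seed, 7000 + r), max_iter, tol)
    if (is.null(best) || cand$inertia < best$inertia) best <- cand
  }
  cb <- new_codebook(best$centers, "kmeans", seed,
                     sprintf("n=%d iters=%d restarts=%d",
                             n, length(best$trace), restarts))
  attr(cb, "inertia_trace") <- best$trace
  cb
}

lloyd_once <- function(X, k, seed, max_iter, tol) {
  n <- nrow(X)
  with_seed_(seed, {
    # k-means++ seeding
    centers <- matrix(0, k, ncol(X))
    centers[1, ] <- X[sample.int(n, 1), ]
    if (k > 1) {
      d2 <- cross_dist2(X, centers[1, , drop = FALSE])[, 1]
      for (j in 2:k) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- X[sample.int(n, 1, prob = p), ]
        d2 <- pmin(d2, cross_dist2(X, centers[j, , drop = FALSE])[, 1])
      }
    }
    inertia_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- cross_dist2(X, centers)
      assign <- max.col(-d2, ties.method = "first")
      inertia_trace <- c(inertia_trace, sum(d2[cbind(seq_len(n), assign)]))
      newc <- centers
      for (j in seq_len(k)) {
        rows <- which(assign == j)
        if (length(rows)) {
          newc[j, ] <- colMeans(X[rows, , drop = FALSE])
        } else {
          far <- which.max(d2[cbind(seq_len(n), assign)])
          newc[j, ] <- X[far, ]
          assign[far] <- j
        }
      }
      movement <- sum(sqrt(rowSums((newc - centers)^2)))
      centers <- newc
      if (movement < tol) break
    }
    list(centers = centers, trace = inertia_trace,
         inertia = inertia_trace[length(inertia_trace)])
  })
}

#' Learn a codebook by random word selection
#'
#' `k` descriptors drawn uniformly without replacement become the words.
#'
#' @inheritParams learn_codebook_kmeans
#' @return A `bovw_codebook` with `provenance = "random"`.
#' @export
learn_codebook_random <- function(pool, k, seed) {
  X <- descriptor_matrix(pool)
  if (nrow(X) < k) {
    stop_invalid(sprintf("pool has %d descriptors but k = %d", nrow(X), k),
                 "bovw_data_error")
  }
  with_seed_(seed, {
    new_codebook(X[sort(sample.int(nrow(X), k)), , drop = FALSE], "random", seed)
  })
}

#' Save / load a codebook
#'
#' Plain-text columnar format: a header line
#' `bovw_codebook <k> <D> <provenance> <seed>`, a `meta` line, then `k`
#' tab-separated rows of `D` values printed with `%.17g` so the round trip
#' is bit-exact and word order is preserved.
#'
#' @param codebook A `bovw_codebook`.
#' @param path File path.
#' @return `path` (save) or the reloaded `bovw_codebook` (load).
#' @export
save_codebook <- function(codebook, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("bovw_codebook\t%d\t%d\t%s\t%d",
                     codebook$k, ncol(codebook$words),
                     codebook$provenance, codebook$seed), con)
  writeLines(paste0("meta\t", codebook$training_meta), con)
  writeLines(apply(codebook$words, 1,
                   function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname save_codebook
#' @export
load_codebook <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "bovw_codebook")) {
    stop_invalid(sprintf("'%s' is not a codebook file (bad header)", path),
                 "bovw_format_error")
  }
  hdr <- strsplit(lines[1], "\t")[[1]]
  if (length(hdr) != 5) stop_invalid("malformed codebook header", "bovw_format_error")
  k <- as.integer(hdr[2]); D <- as.integer(hdr[3])
  meta <- sub("^meta\t?", "", lines[2])
  body <- lines[-(1:2)]
  if (length(body) != k) {
    stop_invalid(sprintf("codebook file truncated: expected %d words, found %d",
                         k, length(body)), "bovw_format_error")
  }
  words <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(l, "\t")[[1]])))
  if (ncol(words) != D || anyNA(words)) {
    stop_invalid("codebook file has malformed word rows", "bovw_format_error")
  }
  new_codebook(words, hdr[4], as.integer(hdr[5]), meta)
}
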