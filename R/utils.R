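#' @useDynLib bovwscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort .data
#' @import tibble
#' @importFrom dplyr filter arrange mutate bind_rows group_by summarise ungroup
#'   left_join select desc n
#' @importFrom stats median runif rnorm dnorm
NULL

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a child seed from a parent seed
#'
#' Hierarchical seeding: stream `i` under parent `seed` gets its own
#' reproducible seed, so e.g. image i of a cohort is unchanged when more
#' images are appended. Kept within the 32-bit signed integer range.
#'
#' @param seed Integer parent seed.
#' @param i Integer stream index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

stop_invalid <- function(msg, class = "bovw_invalid_input") {
  abort(msg, class = c(class, "bovw_error"))
}

is_raster3 <- function(img) {
  is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3 && is.numeric(img)
}

check_raster <- function(img, arg = "image") {
  if (!is_raster3(img)) {
    stop_invalid(sprintf("`%s` must be an H x W x 3 numeric array", arg))
  }
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop_invalid(sprintf("`%s` must have values in [0, 1]", arg))
  }
  invisible(img)
}

# Luminance (Rec. 601) projection of an H x W x 3 raster.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear interpolation of matrix `m` at continuous 1-based (row, col)
# positions; coordinates are clamped to the image domain.
bilinear <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H)
  c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  m00 <- m[i00];     m10 <- m[i00 + 1]
  m01 <- m[i00 + H]; m11 <- m[i00 + H + 1]
  (1 - fr) * (1 - fc) * m00 + fr * (1 - fc) * m10 +
    (1 - fr) * fc * m01 + fr * fc * m11
}

`%||%` <- function(a, b) if (is.null(a)) b else a
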