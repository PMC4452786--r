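#' Point-of-interest detector configuration
#'
#' Multi-scale determinant-of-Hessian blob detection on the luminance
#' channel, with a SURF-like 64-dimensional gradient-orientation patch
#' descriptor (4x4 cells of `(sum dx, sum dy, sum |dx|, sum |dy|)`,
#' L2-normalised) and, optionally, the mean R/G/B of the patch appended so
#' colour changes are described as well as boundaries.
#'
#' @param n_scales Number of scale-space levels.
#' @param base_sigma Finest scale (pixels).
#' @param scale_step Geometric step between scales.
#' @param response_threshold Minimum scale-normalised determinant-of-Hessian
#'   response for a local extremum to become a PoI.
#' @param max_pois Keep at most this many PoIs per image, by response rank.
#' @param color_means Append the patch's mean R/G/B to the descriptor
#'   (descriptor length becomes 67).
#' @param patch_scale Descriptor patch half-width in units of the PoI scale.
#' @return A `detector_config` list; its descriptor length is available via
#'   [descriptor_dim()].
#' @export
detector_config <- function(n_scales = 4L, base_sigma = 2.0, scale_step = 1.6,
                            response_threshold = 5e-5, max_pois = 500L,
                            color_means = TRUE, patch_scale = 3.0) {
  if (n_scales < 1 || base_sigma <= 0 || scale_step <= 1 ||
      response_threshold < 0 || max_pois < 1 || patch_scale <= 0) {
    stop_invalid("invalid detector configuration", "bovw_config_error")
  }
  structure(list(n_scales = as.integer(n_scales), base_sigma = base_sigma,
                 scale_step = scale_step,
                 response_threshold = response_threshold,
                 max_pois = as.integer(max_pois),
                 color_means = isTRUE(color_means),
                 patch_scale = patch_scale),
            class = "detector_config")
}

#' Descriptor length implied by a detector configuration
#' @param config A [detector_config()].
#' @return Integer descriptor length (64, or 67 with colour means).
#' @export
descriptor_dim <- function(config) 64L + if (config$color_means) 3L else 0L

empty_pois <- function(config) {
  tibble::tibble(image_id = character(0), x = numeric(0), y = numeric(0),
                 scale = numeric(0), response = numeric(0),
                 descriptor = matrix(numeric(0), 0, descriptor_dim(config)))
}

# central-difference derivative helpers with replicate padding
d_dx <- function(m) (m[, c(2:ncol(m), ncol(m))] - m[, c(1, 1:(ncol(m) - 1))]) / 2
d_dy <- function(m) (m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]) / 2

#' Detect and describe points of interest
#'
#' Finds local maxima of the scale-normalised determinant of Hessian of the
#' luminance image over a 3x3x3 scale-space neighbourhood (blobs of either
#' polarity: exudate-like bright spots and haemorrhage-like dark spots both
#' yield positive responses, while elongated vessels are suppressed).
#' Surviving extrema above the response threshold are ranked by response,
#' capped at `max_pois`, and described by an upright gradient-orientation
#' patch descriptor computed at the PoI's scale.
#'
#' Coordinates are 0-based with `x` the column and `y` the row.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param config A [detector_config()].
#' @param image_id Id recorded in the output (one id per call).
#' @return A tibble with columns `image_id`, `x`, `y`, `scale`, `response`
#'   and a matrix column `descriptor`, ordered by response descending (ties
#'   by `y` then `x` ascending).
#' @export
detect_pois <- function(image, config = detector_config(), image_id = NA_character_) {
  check_raster(image)
  L <- luminance(image)
  H <- nrow(L); W <- ncol(L)
  sigmas <- config$base_sigma * config$scale_step^(0:(config$n_scales - 1))

  smoothed <- lapply(sigmas, function(s) gauss_blur_cpp(L, s))
  resp <- lapply(seq_along(sigmas), function(si) {
    G <- smoothed[[si]]
    Lxx <- G[, c(2:W, W)] - 2 * G + G[, c(1, 1:(W - 1))]
    Lyy <- G[c(2:H, H), ] - 2 * G + G[c(1, 1:(H - 1)), ]
    Lxy <- (G[c(2:H, H), c(2:W, W)] + G[c(1, 1:(H - 1)), c(1, 1:(W - 1))] -
              G[c(2:H, H), c(1, 1:(W - 1))] - G[c(1, 1:(H - 1)), c(2:W, W)]) / 4
    sigmas[si]^4 * (Lxx * Lyy - Lxy^2)
  })

  cand <- scale_space_maxima_cpp(resp, config$response_threshold)
  if (!nrow(cand)) return(empty_pois(config))
  pts <- tibble::tibble(x = cand$col - 1, y = cand$row - 1,
                        scale = sigmas[cand$level], response = cand$response,
                        si = cand$level)
  pts <- dplyr::arrange(pts, dplyr::desc(.data$response), .data$y, .data$x)
  if (nrow(pts) > config$max_pois) pts <- pts[seq_len(config$max_pois), ]

  # descriptor sampling geometry: 16x16 grid over a (2 * patch_scale * sigma)
  # wide window, grouped into 4x4 cells
  gs <- 16L
  base_off <- (seq_len(gs) - (gs + 1) / 2) / gs * 2  # in units of half-width
  cell_of <- rep(rep(1:4, each = gs / 4), times = gs) +
    4 * (rep(rep(1:4, each = gs / 4), each = gs) - 1)  # column-major cell index
  off_x <- rep(base_off, times = gs)                    # column offsets
  off_y <- rep(base_off, each = gs)                     # row offsets
  wgt <- exp(-(off_x^2 + off_y^2) / (2 * 0.6^2))
  cell_ind <- matrix(0, gs * gs, 16L)
  cell_ind[cbind(seq_len(gs * gs), cell_of)] <- 1

  D <- descriptor_dim(config)
  desc <- matrix(0, nrow(pts), D)
  for (si in unique(pts$si)) {
    rows <- which(pts$si == si)
    G <- smoothed[[si]]
    gx <- d_dx(G); gy <- d_dy(G)
    half <- config$patch_scale * sigmas[si]
    R <- outer(pts$y[rows] + 1, rep(1, gs * gs)) +
      outer(rep(1, length(rows)), off_y * half)
    C <- outer(pts$x[rows] + 1, rep(1, gs * gs)) +
      outer(rep(1, length(rows)), off_x * half)
    dx <- matrix(bilinear(gx, R, C), length(rows), gs * gs)
    dy <- matrix(bilinear(gy, R, C), length(rows), gs * gs)
    dx <- sweep(dx, 2, wgt, `*`); dy <- sweep(dy, 2, wgt, `*`)
    feat <- matrix(0, length(rows), 64)
    feat[, seq(1, 64, by = 4)] <- dx %*% cell_ind
    feat[, seq(2, 64, by = 4)] <- dy %*% cell_ind
    feat[, seq(3, 64, by = 4)] <- abs(dx) %*% cell_ind
    feat[, seq(4, 64, by = 4)] <- abs(dy) %*% cell_ind
    nrm <- sqrt(rowSums(feat^2))
    feat <- feat / pmax(nrm, 1e-12)
    desc[rows, 1:64] <- feat
    if (config$color_means) {
      for (ch in 1:3) {
        v <- matrix(bilinear(image[, , ch], R, C), length(rows), gs * gs)
        desc[rows, 64 + ch] <- rowMeans(v)
      }
    }
  }
  out <- tibble::tibble(image_id = rep(image_id, nrow(pts)),
                        x = pts$x, y = pts$y, scale = pts$scale,
                        response = pts$response, descriptor = desc)
  out
}

#' Restrict a descriptor set to regions of interest
#'
#' Keeps the PoIs whose rounded position falls inside (or outside) the union
#' of the given binary masks. Used to harvest lesion-positive descriptors
#' from specialist-marked (here: generated) regions on training images;
#' control images are passed through whole, without masking.
#'
#' @param pois A PoI tibble from [detect_pois()].
#' @param roi_masks A binary matrix or list of binary matrices, all the same
#'   size as the source image.
#' @param mode `"inside"` or `"outside"`.
#' @param image_dim Optional `c(H, W)` to validate mask dimensions against.
#' @return The filtered PoI tibble (original ordering preserved).
#' @export
restrict_to_rois <- function(pois, roi_masks, mode = c("inside", "outside"),
                             image_dim = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(roi_masks)) roi_masks <- list(roi_masks)
  if (!length(roi_masks)) {
    return(if (mode == "inside") pois[0, ] else pois)
  }
  dims <- unique(lapply(roi_masks, dim))
  if (length(dims) != 1) stop_invalid("ROI masks have inconsistent dimensions")
  if (!is.null(image_dim) && !identical(as.integer(dims[[1]]), as.integer(image_dim[1:2]))) {
    stop_invalid("ROI mask dimensions do not match the image")
  }
  un <- Reduce(`+`, roi_masks)
  H <- nrow(un); W <- ncol(un)
  r <- pmin(pmax(floor(pois$y + 0.5) + 1, 1), H)   # round half-up, 1-based
  c <- pmin(pmax(floor(pois$x + 0.5) + 1, 1), W)
  inside <- un[cbind(r, c)] > 0
  if (mode == "inside") pois[inside, ] else pois[!inside, ]
}

#' Persist / load descriptor sets as CSV
#'
#' One row per PoI: `image_id, x, y, scale, response, d1..dD`.
#'
#' @param pois PoI tibble with a `descriptor` matrix column.
#' @param path CSV path.
#' @return `path` (write) or the PoI tibble (read).
#' @export
write_pois <- function(pois, path) {
  dm <- pois$descriptor
  colnames(dm) <- sprintf("d%03d", seq_len(ncol(dm)))
  flat <- dplyr::bind_cols(pois[c("image_id", "x", "y", "scale", "response")],
                           tibble::as_tibble(dm))
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pois
#' @export
read_pois <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  dcols <- grep("^d\\d+$", names(flat), value = TRUE)
  out <- flat[c("image_id", "x", "y", "scale", "response")]
  m <- as.matrix(flat[dcols])
  dimnames(m) <- NULL
  out$descriptor <- m
  out
}
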