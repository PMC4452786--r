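#' Lesion appearance specification
#'
#' Describes one lesion family for the synthetic fundus generator. Lesions
#' are rendered as smooth elliptical Gaussian-profile blobs: bright lesions
#' (hard-exudate-like) add a yellowish intensity offset (red + green
#' channels), red lesions (microaneurysm/haemorrhage-like) subtract a
#' dark-red offset (mostly green + blue). `radius` is the Gaussian sigma of
#' the blob in pixels; the ground-truth ROI mask is its 2-sigma ellipse.
#'
#' The defaults encode the screening reality the generator emulates: hard
#' exudates are conspicuous (large, high-contrast), microaneurysms and small
#' haemorrhages are subtle (small, low-contrast, easily confused with
#' vessels). Radii are interpreted at a 480-pixel reference field height;
#' [generate_cohort()] scales them with the cohort's resolution.
#'
#' @param kind `"bright"` or `"red"`.
#' @param count_range Integer interval `c(lo, hi)`, `lo >= 0`: lesions per image.
#' @param radius_range Pixel interval `c(lo, hi)`, `lo > 0`.
#' @param contrast_range Interval in `(0, 1]`: peak intensity offset relative
#'   to the local background (applied positively for bright, negatively for red).
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(kind = c("bright", "red"),
                        count_range = NULL,
                        radius_range = NULL,
                        contrast_range = NULL) {
  kind <- match.arg(kind)
  defaults <- list(
    bright = list(count = c(3L, 10L), radius = c(4, 12), contrast = c(0.30, 0.60)),
    red    = list(count = c(2L, 6L), radius = c(2, 5), contrast = c(0.10, 0.24))
  )[[kind]]
  count_range <- count_range %||% defaults$count
  radius_range <- radius_range %||% defaults$radius
  contrast_range <- contrast_range %||% defaults$contrast
  bad_interval <- function(x) length(x) != 2 || any(is.na(x)) || x[1] > x[2]
  if (bad_interval(count_range) || count_range[1] < 0) {
    stop_invalid("`count_range` must be a non-empty interval with lower bound >= 0",
                 "bovw_config_error")
  }
  if (bad_interval(radius_range) || radius_range[1] <= 0) {
    stop_invalid("`radius_range` must be a non-empty interval of positive pixels",
                 "bovw_config_error")
  }
  if (bad_interval(contrast_range) || contrast_range[1] <= 0 || contrast_range[2] > 1) {
    stop_invalid("`contrast_range` must lie within (0, 1]", "bovw_config_error")
  }
  structure(list(kind = kind,
                 count_range = as.integer(round(count_range)),
                 radius_range = as.numeric(radius_range),
                 contrast_range = as.numeric(contrast_range)),
            class = "lesion_spec")
}

new_labeled_image <- function(image, field, cohort = NA_character_, id = NA_character_) {
  structure(list(image = image,
                 label_bright = FALSE, label_red = FALSE,
                 roi_masks = list(), roi_kinds = character(),
                 cohort = cohort, id = id, field = field),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_image> %s %dx%d bright=%s red=%s rois=%d\n",
              x$id %||% "?", d[1], d[2], x$label_bright, x$label_red,
              length(x$roi_masks)))
  invisible(x)
}

#' Generate a lesion-free synthetic fundus background
#'
#' Renders a circular retina-like field on a dark surround: a reddish-orange
#' base with smooth low-frequency texture and vignetting, darker curvilinear
#' vessel strokes radiating from a brighter optic-disc disk, plus mild sensor
#' noise. Deterministic given `seed`.
#'
#' @param size `c(height, width)` in pixels, each >= 64.
#' @param seed Integer seed.
#' @return A `labeled_image` with both labels `FALSE` and no ROI masks.
#' @export
generate_background <- function(size, seed) {
  if (length(size) != 2 || any(size < 64)) {
    stop_invalid("`size` must be c(height, width) with both >= 64", "bovw_config_error")
  }
  H <- as.integer(size[1]); W <- as.integer(size[2])
  with_seed_(seed, {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    R0 <- 0.46 * min(H, W)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    fm <- clamp01((R0 - d) / 2)                     # soft field edge (~2 px)
    vig <- pmax(1 - 0.30 * (d / R0)^2, 0)

    lf <- function() {
      n <- gauss_blur_cpp(matrix(rnorm(H * W), H, W), min(H, W) / 24)
      n / max(stats::sd(n), 1e-12)
    }
    R <- (0.72 + 0.05 * lf()) * vig
    G <- (0.36 + 0.04 * lf()) * vig
    B <- (0.13 + 0.03 * lf()) * vig

    # optic disc, offset to one side of the field centre
    side <- sample(c(-1, 1), 1)
    disc_c <- c(cy + runif(1, -0.15, 0.15) * R0, cx + side * 0.55 * R0)
    disc_r <- 0.16 * R0
    dd <- sqrt((yy - disc_c[1])^2 + (xx - disc_c[2])^2)
    gd <- clamp01((disc_r - dd) / (0.35 * disc_r))
    R <- R + gd * (0.97 - R); G <- G + gd * (0.86 - G); B <- B + gd * (0.55 - B)

    # vessels: random walks out of the disc, width tapering with arc length
    V <- matrix(0, H, W)
    n_vessels <- 8L
    for (v in seq_len(n_vessels)) {
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 0.8, 1.4) * R0
      w0 <- runif(1, 1.5, 3.0)
      pos <- disc_c
      steps <- max(10L, as.integer(len / 2))
      for (s in seq_len(steps)) {
        ang <- ang + rnorm(1, 0, 0.12)
        pos <- pos + 2 * c(sin(ang), cos(ang))
        w <- w0 * (1 - 0.6 * s / steps)
        r0 <- max(1L, floor(pos[1] - w)); r1 <- min(H, ceiling(pos[1] + w))
        c0 <- max(1L, floor(pos[2] - w)); c1 <- min(W, ceiling(pos[2] + w))
        if (r0 > r1 || c0 > c1) break
        sub_y <- r0:r1; sub_x <- c0:c1
        dv <- outer((sub_y - pos[1])^2, (sub_x - pos[2])^2, "+")
        V[sub_y, sub_x] <- pmax(V[sub_y, sub_x], clamp01(1.2 - sqrt(dv) / w))
      }
    }
    V <- gauss_blur_cpp(V, 0.8)
    R <- R * (1 - 0.45 * V); G <- G * (1 - 0.60 * V); B <- B * (1 - 0.55 * V)

    img <- array(0, dim = c(H, W, 3))
    img[, , 1] <- (R + rnorm(H * W, 0, 0.008)) * fm
    img[, , 2] <- (G + rnorm(H * W, 0, 0.008)) * fm
    img[, , 3] <- (B + rnorm(H * W, 0, 0.008)) * fm
    new_labeled_image(clamp01(img),
                      field = list(center = c(cy, cx), radius = R0,
                                   disc_center = disc_c, disc_radius = disc_r))
  })
}

#' Add synthetic lesions to a labelled image
#'
#' Draws `n` elliptical Gaussian-profile blobs (`n` uniform in
#' `spec$count_range`) at random positions inside the retinal field, away
#' from the optic disc. Each lesion appends one binary ROI mask (its 2-sigma
#' ellipse) and the corresponding image label is set.
#'
#' @param img A `labeled_image`.
#' @param spec A [lesion_spec()].
#' @param seed Integer seed.
#' @return The modified `labeled_image`.
#' @export
add_lesions <- function(img, spec, seed) {
  if (!inherits(img, "labeled_image")) stop_invalid("`img` must be a labeled_image")
  if (!inherits(spec, "lesion_spec")) {
    stop_invalid("`spec` must be a lesion_spec", "bovw_config_error")
  }
  H <- dim(img$image)[1]; W <- dim(img$image)[2]
  fld <- img$field %||% list(center = c((H + 1) / 2, (W + 1) / 2),
                             radius = 0.46 * min(H, W),
                             disc_center = c(-1e6, -1e6), disc_radius = 0)
  with_seed_(seed, {
    n <- if (spec$count_range[1] == spec$count_range[2]) spec$count_range[1] else
      sample(spec$count_range[1]:spec$count_range[2], 1)
    if (n == 0) return(img)
    for (j in seq_len(n)) {
      a <- runif(1, spec$radius_range[1], spec$radius_range[2])
      b <- a * runif(1, 0.65, 1)
      theta <- runif(1, 0, pi)
      ctr <- runif(1, spec$contrast_range[1], spec$contrast_range[2])
      # rejection-sample a centre inside 85% of the field, off the disc
      for (try in 1:50) {
        rad <- sqrt(runif(1)) * 0.85 * fld$radius
        ang <- runif(1, 0, 2 * pi)
        pos <- fld$center + rad * c(sin(ang), cos(ang))
        if (sqrt(sum((pos - fld$disc_center)^2)) > fld$disc_radius + 2 * a + 2) break
      }
      ext <- ceiling(3 * a)
      r0 <- max(1L, floor(pos[1] - ext)); r1 <- min(H, ceiling(pos[1] + ext))
      c0 <- max(1L, floor(pos[2] - ext)); c1 <- min(W, ceiling(pos[2] + ext))
      sub_y <- r0:r1; sub_x <- c0:c1
      yr <- matrix(sub_y - pos[1], length(sub_y), length(sub_x))
      xr <- matrix(sub_x - pos[2], length(sub_y), length(sub_x), byrow = TRUE)
      u <- cos(theta) * xr + sin(theta) * yr
      v <- -sin(theta) * xr + cos(theta) * yr
      q <- (u / a)^2 + (v / b)^2
      g <- exp(-0.5 * q)
      off <- if (spec$kind == "bright") c(0.90, 0.70, 0.10) else -c(0.50, 0.85, 0.65)
      for (ch in 1:3) {
        img$image[sub_y, sub_x, ch] <- clamp01(img$image[sub_y, sub_x, ch] +
                                                 off[ch] * ctr * g)
      }
      mask <- matrix(0L, H, W)
      mask[sub_y, sub_x] <- as.integer(q <= 4)    # 2-sigma ellipse
      img$roi_masks <- c(img$roi_masks, list(mask))
      img$roi_kinds <- c(img$roi_kinds, spec$kind)
    }
    if (spec$kind == "bright") img$label_bright <- TRUE else img$label_red <- TRUE
    img
  })
}

#' Cohort configuration for the synthetic generator
#'
#' A cohort is a set of images sharing acquisition characteristics:
#' resolution, per-channel colour gain and JPEG quality. Two cohorts with
#' different settings emulate the domain shift between fundus cameras that a
#' cross-dataset protocol must survive.
#'
#' @param name Cohort name (used in ids and the manifest).
#' @param n_normal,n_bright_only,n_red_only,n_both Class counts (>= 0).
#' @param image_size `c(height, width)`, each >= 64.
#' @param jpeg_quality Integer 1-100 for JPEG re-encoding, or `NULL` for
#'   lossless PNG.
#' @param color_shift Per-channel multiplicative gains `c(r, g, b)`, all > 0.
#' @param seed Integer seed; image `i` of the cohort uses `derive_seed(seed, i)`.
#' @param bright_spec,red_spec [lesion_spec()]s for the two lesion families.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(name, n_normal, n_bright_only = 0, n_red_only = 0,
                          n_both = 0, image_size = c(480, 640),
                          jpeg_quality = 95, color_shift = c(1, 1, 1),
                          seed = 1L,
                          bright_spec = lesion_spec("bright"),
                          red_spec = lesion_spec("red")) {
  counts <- c(n_normal, n_bright_only, n_red_only, n_both)
  if (any(counts < 0)) stop_invalid("class counts must be >= 0", "bovw_config_error")
  if (length(image_size) != 2 || any(image_size < 64)) {
    stop_invalid("`image_size` must be c(height, width) with both >= 64",
                 "bovw_config_error")
  }
  if (length(color_shift) != 3 || any(color_shift <= 0)) {
    stop_invalid("`color_shift` must be 3 positive per-channel gains",
                 "bovw_config_error")
  }
  if (!is.null(jpeg_quality) &&
      (jpeg_quality < 1 || jpeg_quality > 100)) {
    stop_invalid("`jpeg_quality` must be in 1..100 or NULL", "bovw_config_error")
  }
  structure(list(name = as.character(name),
                 n_normal = as.integer(n_normal),
                 n_bright_only = as.integer(n_bright_only),
                 n_red_only = as.integer(n_red_only),
                 n_both = as.integer(n_both),
                 image_size = as.integer(image_size),
                 jpeg_quality = if (is.null(jpeg_quality)) NULL else as.integer(jpeg_quality),
                 color_shift = as.numeric(color_shift),
                 seed = as.integer(seed),
                 bright_spec = bright_spec, red_spec = red_spec),
            class = "cohort_config")
}

jpeg_roundtrip <- function(img, quality) {
  tf <- tempfile(fileext = ".jpg")
  on.exit(unlink(tf))
  write_image(img, tf, quality = quality)
  read_image(tf)
}

#' Generate a labelled synthetic cohort
#'
#' Produces the configured number of normal, bright-only, red-only and
#' dual-lesion images (in that order), applies the cohort's colour gains and
#' JPEG re-encoding, and builds the manifest. With `out_dir` set, images are
#' written as JPEG (or PNG when `jpeg_quality` is `NULL`), every ROI mask as
#' `<id>_roi_<kind>_<j>.png`, and the manifest as `manifest.csv`; images are
#' then not kept in memory. With `out_dir = NULL` everything stays in memory
#' (JPEG compression is still applied, via a temporary file).
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory, or `NULL` for in-memory use.
#' @return A list with `manifest` (tibble) and `images` (list of
#'   `labeled_image`, `NULL` when written to disk).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  if (!inherits(config, "cohort_config")) {
    stop_invalid("`config` must be a cohort_config", "bovw_config_error")
  }
  classes <- rep(c("normal", "bright", "red", "both"),
                 c(config$n_normal, config$n_bright_only,
                   config$n_red_only, config$n_both))
  keep <- is.null(out_dir)
  if (!keep) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (is.null(config$jpeg_quality)) "png" else "jpg"
  # lesion radii are declared at a 480-px reference field: a camera with more
  # pixels over the same retina images the same lesion larger
  res_factor <- min(config$image_size) / 480
  bright_spec <- lesion_spec("bright", config$bright_spec$count_range,
                             config$bright_spec$radius_range * res_factor,
                             config$bright_spec$contrast_range)
  red_spec <- lesion_spec("red", config$red_spec$count_range,
                          config$red_spec$radius_range * res_factor,
                          config$red_spec$contrast_range)
  images <- if (keep) vector("list", length(classes)) else NULL
  rows <- vector("list", length(classes))

  for (i in seq_along(classes)) {
    s <- derive_seed(config$seed, i)
    img <- generate_background(config$image_size, s)
    cls <- classes[i]
    if (cls %in% c("bright", "both")) {
      img <- add_lesions(img, bright_spec, derive_seed(s, 1))
    }
    if (cls %in% c("red", "both")) {
      img <- add_lesions(img, red_spec, derive_seed(s, 2))
    }
    for (ch in 1:3) {
      img$image[, , ch] <- clamp01(img$image[, , ch] * config$color_shift[ch])
    }
    img$id <- sprintf("%s_%03d", config$name, i)
    img$cohort <- config$name
    fname <- paste0(img$id, ".", ext)
    if (!keep) {
      write_image(img$image, file.path(out_dir, fname),
                  quality = config$jpeg_quality %||% 95)
      for (j in seq_along(img$roi_masks)) {
        png::writePNG(img$roi_masks[[j]] + 0,
                      file.path(out_dir, sprintf("%s_roi_%s_%02d.png",
                                                 img$id, img$roi_kinds[j], j)))
      }
    } else if (!is.null(config$jpeg_quality)) {
      img$image <- jpeg_roundtrip(img$image, config$jpeg_quality)
    }
    rows[[i]] <- tibble::tibble(id = img$id, cohort = img$cohort, path = fname,
                                label_bright = img$label_bright,
                                label_red = img$label_red)
    if (keep) images[[i]] <- img
  }
  manifest <- dplyr::bind_rows(rows)
  if (!keep) {
    save_manifest(manifest, file.path(out_dir, "manifest.csv"))
    attr(manifest, "base_dir") <- normalizePath(out_dir)
  }
  list(manifest = manifest, images = images)
}

#' Locate the ROI mask files of a manifest image
#'
#' Masks follow the `<id>_roi_<kind>_<j>.png` naming convention used by
#' [generate_cohort()].
#'
#' @param id Image id.
#' @param dir Directory holding the cohort files.
#' @param kind `"bright"`, `"red"` or `"any"`.
#' @return Character vector of mask paths (possibly empty).
#' @export
roi_mask_paths <- function(id, dir, kind = c("any", "bright", "red")) {
  kind <- match.arg(kind)
  pat <- if (kind == "any") "(bright|red)" else kind
  list.files(dir, pattern = sprintf("^%s_roi_%s_\\d+\\.png$", id, pat),
             full.names = TRUE)
}

read_roi_masks <- function(paths) {
  lapply(paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    (m > 0.5) * 1L
  })
}

#' Two-cohort benchmark configuration
#'
#' The packaged study conditions: a training cohort shaped like a referral
#' archive (60 images at 640x480, class mix proportional to a
#' 687/136/82/109 normal/bright-only/red-only/both archive) and a shifted
#' clinic test cohort (30 images at 800x600 with colour gain and stronger
#' JPEG: 18 normal, 7 red-only, 5 with both lesions). Lesion appearance uses
#' the [lesion_spec()] defaults.
#'
#' @param seed Integer seed driving both cohorts.
#' @return List with `train` and `test` [cohort_config()]s.
#' @export
study_cohort_configs <- function(seed = 1L) {
  list(
    train = cohort_config("archive", n_normal = 41, n_bright_only = 8,
                          n_red_only = 5, n_both = 6,
                          image_size = c(480, 640), jpeg_quality = 95,
                          color_shift = c(1, 1, 1),
                          seed = derive_seed(seed, 101)),
    test = cohort_config("clinic", n_normal = 18, n_bright_only = 0,
                         n_red_only = 7, n_both = 5,
                         image_size = c(600, 800), jpeg_quality = 90,
                         color_shift = c(1.06, 0.97, 0.92),
                         seed = derive_seed(seed, 202))
  )
}
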