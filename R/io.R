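#' Read a colour fundus image
#'
#' Loads a PNG, JPEG or TIFF image as an `H x W x 3` array of values in
#' `[0, 1]` (8-bit values map to `value / 255`). Single-channel images are
#' rejected: the pipeline requires colour. An alpha channel, if present, is
#' dropped.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return A numeric `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("image file not found: '%s'", path), "bovw_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else {
    x <- suppressWarnings(EBImage::readImage(path))
    a <- EBImage::imageData(x)
    if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else a
  }
  if (length(dim(img)) == 2) {
    stop_invalid(sprintf("'%s' is single-channel; a colour image is required", path),
                 "bovw_format_error")
  }
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3) {
    stop_invalid(sprintf("'%s' has %d channels; 3 required", path, dim(img)[3]),
                 "bovw_format_error")
  }
  clamp01(unclass(img))
}

#' Write an image to PNG or JPEG
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.png`, `.jpg`/`.jpeg`).
#' @param quality JPEG quality 1-100 (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 95) {
  check_raster(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                        path, quality = quality)
  } else {
    stop_invalid(sprintf("unsupported image extension '%s'", ext), "bovw_format_error")
  }
  invisible(path)
}

parse_bool <- function(x, col) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true")] <- TRUE
  out[v %in% c("0", "false")] <- FALSE
  if (anyNA(out)) {
    bad <- unique(v[is.na(out)])
    stop_invalid(sprintf("column '%s' has non-boolean values: %s",
                         col, paste(bad, collapse = ", ")),
                 "bovw_format_error")
  }
  out
}

manifest_columns <- c("id", "cohort", "path", "label_bright", "label_red")

#' Load a cohort manifest
#'
#' A manifest is a CSV with header `id,cohort,path,label_bright,label_red`.
#' Labels accept `0/1/true/false` case-insensitively. Ids must be unique and,
#' unless `check_paths = FALSE`, every image path (resolved relative to the
#' manifest's directory) must exist.
#'
#' @param path Path to a manifest CSV.
#' @param check_paths Verify that each referenced image file exists.
#' @return A tibble with the five manifest columns; the manifest's directory
#'   is attached as attribute `"base_dir"` for path resolution.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("manifest not found: '%s'", path), "bovw_format_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) {
    stop_invalid(sprintf("manifest missing column(s): %s", paste(missing, collapse = ", ")),
                 "bovw_format_error")
  }
  df <- tibble::as_tibble(df[manifest_columns])
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop_invalid(sprintf("duplicate manifest id(s): %s", paste(dup, collapse = ", ")),
                 "bovw_format_error")
  }
  df$label_bright <- parse_bool(df$label_bright, "label_bright")
  df$label_red <- parse_bool(df$label_red, "label_red")
  base <- dirname(normalizePath(path, mustWork = TRUE))
  if (check_paths) {
    full <- manifest_paths(df, base)
    bad <- df$path[!file.exists(full)]
    if (length(bad)) {
      stop_invalid(sprintf("manifest image path(s) missing: %s",
                           paste(utils::head(bad, 5), collapse = ", ")),
                   "bovw_format_error")
    }
  }
  attr(df, "base_dir") <- base
  df
}

#' Resolve manifest image paths
#'
#' @param manifest A manifest tibble (see [load_manifest()]).
#' @param base_dir Directory relative paths resolve against; defaults to the
#'   manifest's `"base_dir"` attribute (or the working directory).
#' @return Character vector of absolute-ish paths.
#' @export
manifest_paths <- function(manifest, base_dir = NULL) {
  base <- base_dir %||% attr(manifest, "base_dir") %||% "."
  ifelse(grepl("^(/|[A-Za-z]:)", manifest$path),
         manifest$path,
         file.path(base, manifest$path))
}

#' Save a cohort manifest
#'
#' Writes the five manifest columns (labels as `true`/`false`) preserving row
#' order, so a save/load round trip is exact.
#'
#' @param manifest Manifest tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  df <- manifest[manifest_columns]
  df$label_bright <- ifelse(df$label_bright, "true", "false")
  df$label_red <- ifelse(df$label_red, "true", "false")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
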