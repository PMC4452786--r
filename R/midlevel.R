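#' Hard-assign descriptors to their nearest visual word
#'
#' Each descriptor is associated fully and only with its closest codebook
#' word under Euclidean distance; ties break to the lowest word index.
#'
#' @param descriptor A length-D vector or an n x D matrix (or PoI tibble).
#' @param codebook A `bovw_codebook` with matching D.
#' @return Integer word indices (1-based), one per descriptor.
#' @export
hard_assign <- function(descriptor, codebook) {
  X <- if (is.numeric(descriptor) && is.null(dim(descriptor))) {
    matrix(descriptor, 1)
  } else descriptor_matrix(descriptor)
  if (ncol(X) != ncol(codebook$words)) {
    stop_invalid(sprintf("descriptor length %d does not match codebook D = %d",
                         ncol(X), ncol(codebook$words)))
  }
  if (!nrow(X)) return(integer(0))
  max.col(-cross_dist2(X, codebook$words), ties.method = "first")
}

#' Encode a descriptor set as a BoVW histogram
#'
#' Classical hard-assignment coding with sum pooling: `counts[w]` is the
#' number of PoIs whose nearest word is `w`, followed by the selected
#' normalization. An empty descriptor set encodes as the all-zero vector and
#' is flagged `empty` (downstream scoring then reduces to the detector's
#' bias term).
#'
#' @param pois PoI tibble for one image (may be empty).
#' @param codebook A `bovw_codebook`.
#' @param normalization `"l2"` (default), `"l1"` or `"none"`.
#' @param image_id Id recorded on the histogram; defaults to the PoIs' id.
#' @return A `bovw_histogram`: list with `image_id`, `counts` (length k),
#'   `normalized`, `codebook_ref`, `n_pois` and `empty`.
#' @export
encode_bovw <- function(pois, codebook, normalization = c("l2", "l1", "none"),
                        image_id = NULL) {
  normalization <- match.arg(normalization)
  idx <- hard_assign(pois, codebook)
  counts <- tabulate(idx, nbins = codebook$k)
  n_pois <- length(idx)
  counts <- switch(normalization,
    none = as.numeric(counts),
    l1 = if (n_pois > 0) counts / sum(counts) else as.numeric(counts),
    l2 = if (n_pois > 0) counts / sqrt(sum(counts^2)) else as.numeric(counts)
  )
  id <- image_id %||% (if (nrow(pois)) pois$image_id[1] else NA_character_)
  structure(list(image_id = id, counts = counts, normalized = normalization,
                 codebook_ref = codebook_id(codebook),
                 n_pois = n_pois, empty = n_pois == 0),
            class = "bovw_histogram")
}

#' Encode every image of a descriptor table
#'
#' Groups a PoI tibble by `image_id` and encodes each group with
#' [encode_bovw()]. Images listed in `ids` but absent from `pois` (no PoIs
#' detected) get zero histograms.
#'
#' @param pois PoI tibble for one or more images.
#' @param codebook A `bovw_codebook`.
#' @param normalization Passed to [encode_bovw()].
#' @param ids Optional full id vector controlling output rows and order.
#' @return A tibble with `image_id`, `n_pois`, `empty` and a matrix column
#'   `histogram` (n x k); the codebook id and normalization are attached as
#'   attributes `codebook_ref` / `normalized`.
#' @export
encode_cohort <- function(pois, codebook, normalization = c("l2", "l1", "none"),
                          ids = NULL) {
  normalization <- match.arg(normalization)
  ids <- ids %||% unique(pois$image_id)
  hists <- matrix(0, length(ids), codebook$k)
  n_pois <- integer(length(ids))
  for (i in seq_along(ids)) {
    h <- encode_bovw(pois[pois$image_id == ids[i], ], codebook, normalization,
                     image_id = ids[i])
    hists[i, ] <- h$counts
    n_pois[i] <- h$n_pois
  }
  out <- tibble::tibble(image_id = ids, n_pois = n_pois, empty = n_pois == 0,
                        histogram = hists)
  attr(out, "codebook_ref") <- codebook_id(codebook)
  attr(out, "normalized") <- normalization
  out
}

#' Persist / load encoded histograms as CSV
#'
#' One row per image: `image_id, n_pois, w1..wk`; the codebook identifier
#' and normalization are stored in a sidecar YAML (`<path>.meta.yml`).
#'
#' @param hists Histogram tibble from [encode_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the histogram tibble (read).
#' @export
write_histograms <- function(hists, path) {
  hm <- hists$histogram
  colnames(hm) <- sprintf("w%04d", seq_len(ncol(hm)))
  flat <- dplyr::bind_cols(hists[c("image_id", "n_pois")], tibble::as_tibble(hm))
  readr::write_csv(flat, path, progress = FALSE)
  yaml::write_yaml(list(codebook_ref = attr(hists, "codebook_ref"),
                        normalized = attr(hists, "normalized")),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_histograms
#' @export
read_histograms <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  wcols <- grep("^w\\d+$", names(flat), value = TRUE)
  out <- tibble::tibble(image_id = flat$image_id,
                        n_pois = as.integer(flat$n_pois),
                        empty = flat$n_pois == 0,
                        histogram = {
                          m <- as.matrix(flat[wcols]); dimnames(m) <- NULL; m
                        })
  meta_path <- paste0(path, ".meta.yml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(out, "codebook_ref") <- meta$codebook_ref
    attr(out, "normalized") <- meta$normalized
  }
  out
}
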