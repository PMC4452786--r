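run_config_defaults <- list(
  n_scales = 4L, base_sigma = 2.0, scale_step = 1.6,
  response_threshold = 5e-5, max_pois = 500L, color_means = TRUE,
  patch_scale = 3.0,
  codebook_k = 500L, codebook_provenance = "kmeans",
  quota_per_class = 10000L, kmeans_max_iter = 50L, kmeans_tol = 1e-6,
  kmeans_restarts = 5L, n_codebooks = 1L,
  normalization = "l2",
  svm_cost = 1, decision_threshold = 0,
  target_specificity = 0.9,
  seed = 1L
)

#' Pipeline run configuration
#'
#' Flat configuration covering every tunable stage of the pipeline:
#' detector (`n_scales`, `base_sigma`, `scale_step`, `response_threshold`,
#' `max_pois`, `color_means`, `patch_scale`), codebook (`codebook_k`,
#' `codebook_provenance` = `"kmeans"` or `"random"`, `quota_per_class`,
#' `kmeans_max_iter`, `kmeans_tol`, `kmeans_restarts`, `n_codebooks`
#' ensemble members),
#' encoding (`normalization` in `none`/`l1`/`l2`), decision (`svm_cost`,
#' `decision_threshold`), evaluation (`target_specificity`) and the global
#' `seed`. Unknown keys are rejected.
#'
#' @seealso [study_run_config()] for the packaged benchmark configuration.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(run_config_defaults))
  if (length(unknown)) {
    stop_invalid(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                 "bovw_config_error")
  }
  cfg <- utils::modifyList(run_config_defaults, over)
  if (!cfg$codebook_provenance %in% c("kmeans", "random")) {
    stop_invalid("codebook_provenance must be 'kmeans' or 'random'", "bovw_config_error")
  }
  if (!cfg$normalization %in% c("none", "l1", "l2")) {
    stop_invalid("normalization must be one of none/l1/l2", "bovw_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Benchmark run configuration
#'
#' The configuration used for the packaged two-cohort benchmark (see
#' [study_cohort_configs()]): a tight salience cap of 100 PoIs per image
#' (lesion PoIs rank high by detector response, so the cap concentrates the
#' histograms on salient structure), a 128-word codebook per detector, a
#' 4000-descriptor per-class sampling quota, and an ensemble of 3 codebooks
#' whose standardized scores are averaged to damp word-quantization
#' variance at small training-set sizes.
#'
#' @param seed Integer seed.
#' @param ... Further [run_config()] overrides.
#' @return A `run_config`.
#' @export
study_run_config <- function(seed = 1L, ...) {
  run_config(max_pois = 100L, codebook_k = 128L, quota_per_class = 4000L,
             n_codebooks = 3L, kmeans_restarts = 2L,
             seed = as.integer(seed), ...)
}

detector_config_from <- function(cfg) {
  detector_config(n_scales = cfg$n_scales, base_sigma = cfg$base_sigma,
                  scale_step = cfg$scale_step,
                  response_threshold = cfg$response_threshold,
                  max_pois = cfg$max_pois, color_means = cfg$color_means,
                  patch_scale = cfg$patch_scale)
}

#' Hash of a configuration
#'
#' Recorded in stage artifacts so mismatched artifacts can be refused.
#'
#' @param config A `run_config`.
#' @return 12-character hash string.
#' @export
config_hash <- function(config) {
  substr(rlang::hash(unclass(config)[order(names(unclass(config)))]), 1, 12)
}

#' Read / write a run configuration file
#'
#' Flat `key: value` YAML with one documented key per [run_config()] field;
#' unknown keys are rejected.
#'
#' @param path File path.
#' @param config A `run_config` (write).
#' @return A `run_config` (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("config file not found: '%s'", path), "bovw_format_error")
  }
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals %||% list())
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read / write a cohort configuration file
#'
#' Flat `key: value` YAML describing one synthetic cohort: `name`, the four
#' class counts, `height`/`width`, optional `jpeg_quality`, the three
#' channel gains `gain_r`/`gain_g`/`gain_b`, `seed`, and the six
#' `<kind>_{count,radius,contrast}_{min,max}` lesion keys.
#'
#' @param path File path.
#' @param config A [cohort_config()] (write).
#' @return A `cohort_config` (read) or `path` invisibly (write).
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("config file not found: '%s'", path), "bovw_format_error")
  }
  v <- yaml::read_yaml(path)
  known <- c("name", "n_normal", "n_bright_only", "n_red_only", "n_both",
             "height", "width", "jpeg_quality", "gain_r", "gain_g", "gain_b",
             "seed",
             as.vector(outer(c("bright", "red"),
                             as.vector(outer(c("count", "radius", "contrast"),
                                             c("min", "max"), paste, sep = "_")),
                             paste, sep = "_")))
  unknown <- setdiff(names(v), known)
  if (length(unknown)) {
    stop_invalid(sprintf("unknown cohort config key(s): %s",
                         paste(unknown, collapse = ", ")), "bovw_config_error")
  }
  spec_from <- function(kind) {
    g <- function(key, default) {
      lo <- v[[paste(kind, key, "min", sep = "_")]]
      hi <- v[[paste(kind, key, "max", sep = "_")]]
      if (is.null(lo) && is.null(hi)) return(NULL)
      c(lo %||% hi, hi %||% lo)
    }
    lesion_spec(kind, count_range = g("count"), radius_range = g("radius"),
                contrast_range = g("contrast"))
  }
  cohort_config(name = v$name %||% "cohort",
                n_normal = v$n_normal %||% 0,
                n_bright_only = v$n_bright_only %||% 0,
                n_red_only = v$n_red_only %||% 0,
                n_both = v$n_both %||% 0,
                image_size = c(v$height %||% 480, v$width %||% 640),
                jpeg_quality = v$jpeg_quality,
                color_shift = c(v$gain_r %||% 1, v$gain_g %||% 1, v$gain_b %||% 1),
                seed = v$seed %||% 1L,
                bright_spec = spec_from("bright"),
                red_spec = spec_from("red"))
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  v <- list(name = config$name, n_normal = config$n_normal,
            n_bright_only = config$n_bright_only,
            n_red_only = config$n_red_only, n_both = config$n_both,
            height = config$image_size[1], width = config$image_size[2],
            gain_r = config$color_shift[1], gain_g = config$color_shift[2],
            gain_b = config$color_shift[3], seed = config$seed)
  if (!is.null(config$jpeg_quality)) v$jpeg_quality <- config$jpeg_quality
  for (kind in c("bright", "red")) {
    sp <- config[[paste0(kind, "_spec")]]
    v[[paste0(kind, "_count_min")]] <- sp$count_range[1]
    v[[paste0(kind, "_count_max")]] <- sp$count_range[2]
    v[[paste0(kind, "_radius_min")]] <- sp$radius_range[1]
    v[[paste0(kind, "_radius_max")]] <- sp$radius_range[2]
    v[[paste0(kind, "_contrast_min")]] <- sp$contrast_range[1]
    v[[paste0(kind, "_contrast_max")]] <- sp$contrast_range[2]
  }
  yaml::write_yaml(v, path)
  invisible(path)
}
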