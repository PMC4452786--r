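#' Detect PoIs for every image of a manifest
#'
#' @param manifest Manifest tibble (see [load_manifest()]).
#' @param config A `run_config`.
#' @param base_dir Directory image paths resolve against (defaults to the
#'   manifest's `base_dir` attribute).
#' @param images Optional named list of in-memory `labeled_image`s keyed by
#'   id (used instead of reading files).
#' @return A PoI tibble covering all images (ids with no PoIs contribute no
#'   rows).
#' @export
detect_manifest <- function(manifest, config = run_config(), base_dir = NULL,
                            images = NULL) {
  dcfg <- detector_config_from(config)
  paths <- if (is.null(images)) manifest_paths(manifest, base_dir) else NULL
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- if (!is.null(images)) images[[manifest$id[i]]]$image else read_image(paths[i])
    out[[i]] <- detect_pois(img, dcfg, image_id = manifest$id[i])
  }
  dplyr::bind_rows(out)
}

# Harvest the codebook training pool for one lesion family: ROI-restricted
# PoIs of lesion-positive images plus whole-image PoIs of normals.
codebook_pool <- function(pois, manifest, lesion, base_dir, images = NULL) {
  label <- manifest[[paste0("label_", lesion)]]
  pos_ids <- manifest$id[label]
  neg_ids <- manifest$id[!manifest$label_bright & !manifest$label_red]
  pos <- vector("list", length(pos_ids))
  for (i in seq_along(pos_ids)) {
    id <- pos_ids[i]
    p <- pois[pois$image_id == id, ]
    masks <- if (!is.null(images)) {
      im <- images[[id]]
      im$roi_masks[im$roi_kinds == lesion]
    } else {
      read_roi_masks(roi_mask_paths(id, base_dir, lesion))
    }
    pos[[i]] <- if (length(masks)) restrict_to_rois(p, masks, "inside") else p
  }
  pos <- dplyr::bind_rows(pos)
  neg <- pois[pois$image_id %in% neg_ids, ]
  list(pos = pos, neg = neg)
}

#' Train codebooks and detectors on a training manifest
#'
#' For each lesion family, builds the descriptor pool (lesion-positive PoIs
#' restricted to their ROI masks, plus PoIs of control images taken whole),
#' samples it per class, learns that family's codebook, encodes the
#' relevant training images in full, and fits the maximum-margin detector
#' (positives = images carrying the lesion, negatives = normal images).
#'
#' With `n_codebooks > 1`, each ensemble member re-samples the descriptor
#' pool and re-learns codebook + detector under a derived seed; member
#' scores are standardized on training statistics (median of training
#' normals, spread of all training scores) and averaged, which damps
#' codebook-quantization variance when few training images are available.
#' The per-lesion flag threshold is calibrated on the training scores as
#' the midpoint between the normal median (0 after standardization) and
#' the median lesion-positive score.
#'
#' @param manifest Training manifest.
#' @param pois PoIs of the training images (from [detect_manifest()]).
#' @param config A `run_config`.
#' @param base_dir Directory holding images/ROI masks.
#' @param images Optional in-memory images (as in [detect_manifest()]).
#' @return A `bovw_pipeline_fit`: list with `members` (per lesion, a list of
#'   `(codebook, model, center, scale)`), `thresholds`, `codebooks`/`models`
#'   (first member, for single-codebook workflows), `config`, `train_ids`.
#' @export
train_pipeline <- function(manifest, pois, config = run_config(),
                           base_dir = NULL, images = NULL) {
  base_dir <- base_dir %||% attr(manifest, "base_dir")
  members <- list(); thresholds <- list()
  for (lesion in c("bright", "red")) {
    pool <- codebook_pool(pois, manifest, lesion, base_dir, images)
    if (!nrow(pool$pos) || !nrow(pool$neg)) {
      stop_invalid(sprintf("no descriptors available for the %s codebook", lesion),
                   "bovw_data_error")
    }
    both <- dplyr::bind_rows(pool$pos, pool$neg)
    cls <- rep(c("lesion", "normal"), c(nrow(pool$pos), nrow(pool$neg)))
    label <- manifest[[paste0("label_", lesion)]]
    normal <- !manifest$label_bright & !manifest$label_red
    use <- label | normal
    use_pois <- pois[pois$image_id %in% manifest$id[use], ]
    base_off <- if (lesion == "bright") 10 else 20
    mem <- vector("list", config$n_codebooks)
    train_scores <- matrix(0, sum(use), config$n_codebooks)
    for (j in seq_len(config$n_codebooks)) {
      sampled <- sample_descriptors(both, cls, config$quota_per_class,
                                    derive_seed(config$seed, base_off + 100 * j + 1))
      cb_seed <- derive_seed(config$seed, base_off + 100 * j + 2)
      cb <- if (config$codebook_provenance == "kmeans") {
        learn_codebook_kmeans(sampled, config$codebook_k, cb_seed,
                              config$kmeans_max_iter, config$kmeans_tol,
                              restarts = config$kmeans_restarts)
      } else {
        learn_codebook_random(sampled, config$codebook_k, cb_seed)
      }
      hists <- encode_cohort(use_pois, cb, config$normalization,
                             ids = manifest$id[use])
      model <- train_detector(hists, label[use], lesion,
                              cost = config$svm_cost,
                              threshold = config$decision_threshold)
      s <- score_detector(model, hists)
      center <- stats::median(s[!label[use]])
      scale <- max(stats::sd(s), 1e-9)
      train_scores[, j] <- (s - center) / scale
      mem[[j]] <- list(codebook = cb, model = model,
                       center = center, scale = scale)
    }
    ens <- rowMeans(train_scores)
    members[[lesion]] <- mem
    thresholds[[lesion]] <- max(stats::median(ens[label[use]]) / 2, 0)
  }
  structure(list(members = members, thresholds = thresholds,
                 codebooks = list(bright = members$bright[[1]]$codebook,
                                  red = members$red[[1]]$codebook),
                 models = list(bright = members$bright[[1]]$model,
                               red = members$red[[1]]$model),
                 config = config, train_ids = manifest$id),
            class = "bovw_pipeline_fit")
}

#' @export
print.bovw_pipeline_fit <- function(x, ...) {
  cat(sprintf("<bovw_pipeline_fit> %d train images, k=%d, %d codebook(s) per lesion\n",
              length(x$train_ids), x$config$codebook_k, x$config$n_codebooks))
  invisible(x)
}

ensemble_scores <- function(fit, lesion, pois, ids) {
  s <- vapply(fit$members[[lesion]], function(m) {
    h <- encode_cohort(pois, m$codebook, fit$config$normalization, ids = ids)
    (score_detector(m$model, h) - m$center) / m$scale
  }, numeric(length(ids)))
  rowMeans(matrix(s, nrow = length(ids)))
}

#' Screen images with a fitted pipeline
#'
#' Scores every image with both per-lesion detector ensembles, applies the
#' calibrated flag thresholds, and fuses the flags with the OR rule (an
#' image is normal only if both detectors agree it is normal). Scores are
#' standardized (training normals at median 0), so `fused_score` is their
#' maximum.
#'
#' @param object A `bovw_pipeline_fit` from [train_pipeline()].
#' @param pois PoI tibble of the images to screen.
#' @param ids Image ids to report (defaults to ids present in `pois`).
#' @param ... Unused.
#' @return A screening tibble: `id, score_bright, score_red, flag_bright,
#'   flag_red, referable, fused_score`.
#' @export
predict.bovw_pipeline_fit <- function(object, pois, ids = NULL, ...) {
  ids <- ids %||% unique(pois$image_id)
  sb <- ensemble_scores(object, "bright", pois, ids)
  sr <- ensemble_scores(object, "red", pois, ids)
  fb <- sb > object$thresholds$bright
  fr <- sr > object$thresholds$red
  tibble::tibble(id = ids, score_bright = sb, score_red = sr,
                 flag_bright = fb, flag_red = fr,
                 referable = fuse(fb, fr),
                 fused_score = fuse_score(sb, sr))
}

#' Cross-dataset screening experiment
#'
#' The full protocol: PoIs and codebooks from the training cohort only,
#' detectors trained on the training cohort only, then scoring, flags and
#' ROC evaluation on the unseen test cohort. Train and test manifests must
#' have disjoint cohort names and image ids; the ids actually used for
#' training are logged in the report so test isolation is auditable.
#'
#' Reported curves: per-lesion ROCs (lesion-positive vs normal images), the
#' fused multi-lesion ROC over the full test set ("test 1" shape: normals
#' vs any-lesion), and, when the test cohort contains dual-lesion images,
#' the normals-vs-dual-lesion ROC ("test 2" shape).
#'
#' @param train_manifest,test_manifest Manifest tibbles.
#' @param config A `run_config`.
#' @param train_dir,test_dir Directories holding each cohort's files
#'   (default: the manifests' `base_dir` attributes).
#' @param train_images,test_images Optional in-memory image lists.
#' @return A `screening_eval` object; see [tidy.screening_eval()],
#'   [glance.screening_eval()] and `autoplot()`.
#' @export
run_cross_dataset <- function(train_manifest, test_manifest,
                              config = run_config(),
                              train_dir = NULL, test_dir = NULL,
                              train_images = NULL, test_images = NULL) {
  if (length(intersect(unique(train_manifest$cohort),
                       unique(test_manifest$cohort)))) {
    stop_invalid("train and test cohorts must be disjoint",
                 "bovw_protocol_error")
  }
  overlap <- intersect(train_manifest$id, test_manifest$id)
  if (length(overlap)) {
    stop_invalid(sprintf("image id(s) appear in both cohorts: %s",
                         paste(utils::head(overlap, 5), collapse = ", ")),
                 "bovw_protocol_error")
  }
  train_dir <- train_dir %||% attr(train_manifest, "base_dir")
  test_dir <- test_dir %||% attr(test_manifest, "base_dir")

  train_pois <- detect_manifest(train_manifest, config, train_dir, train_images)
  fit <- train_pipeline(train_manifest, train_pois, config, train_dir, train_images)

  test_pois <- detect_manifest(test_manifest, config, test_dir, test_images)
  screening <- predict(fit, test_pois, ids = test_manifest$id)
  screening <- dplyr::left_join(
    screening,
    test_manifest[c("id", "label_bright", "label_red")], by = "id")

  normal <- !screening$label_bright & !screening$label_red
  roc_or_null <- function(scores, labels) {
    if (length(unique(labels)) < 2) return(NULL)
    compute_roc(scores, labels)
  }
  sub_b <- normal | screening$label_bright
  sub_r <- normal | screening$label_red
  sub_2 <- normal | (screening$label_bright & screening$label_red)
  rocs <- list(
    bright = roc_or_null(screening$score_bright[sub_b], screening$label_bright[sub_b]),
    red = roc_or_null(screening$score_red[sub_r], screening$label_red[sub_r]),
    multi_test1 = roc_or_null(screening$fused_score, !normal),
    multi_test2 = if (any(screening$label_bright & screening$label_red)) {
      roc_or_null(screening$fused_score[sub_2], !normal[sub_2])
    } else NULL
  )
  ops <- dplyr::bind_rows(lapply(names(rocs), function(nm) {
    if (is.null(rocs[[nm]])) return(NULL)
    dplyr::mutate(operating_point(rocs[[nm]], config$target_specificity),
                  curve = nm, .before = 1)
  }))
  conf <- dplyr::bind_rows(
    dplyr::mutate(confusion_metrics(screening$flag_bright[sub_b],
                                    screening$label_bright[sub_b]),
                  curve = "bright", .before = 1),
    dplyr::mutate(confusion_metrics(screening$flag_red[sub_r],
                                    screening$label_red[sub_r]),
                  curve = "red", .before = 1),
    dplyr::mutate(confusion_metrics(screening$referable, !normal),
                  curve = "multi_test1", .before = 1),
    if (any(screening$label_bright & screening$label_red)) {
      dplyr::mutate(confusion_metrics(screening$referable[sub_2], !normal[sub_2]),
                    curve = "multi_test2", .before = 1)
    }
  )
  structure(list(screening = screening, rocs = rocs,
                 operating_points = ops, confusion = conf,
                 meta = list(train_cohort = unique(train_manifest$cohort),
                             test_cohort = unique(test_manifest$cohort),
                             train_ids = fit$train_ids,
                             test_ids = test_manifest$id,
                             seed = config$seed,
                             config_hash = config_hash(config),
                             target_specificity = config$target_specificity),
                 fit = fit),
            class = "screening_eval")
}

#' Within-cohort evaluation via a stratified held-out split
#'
#' Splits one manifest 50/50 within each (bright, red) label stratum using
#' `split_seed`, then runs the standard protocol on the two halves.
#'
#' @param manifest A single-cohort manifest.
#' @param config A `run_config`.
#' @param base_dir Directory holding the cohort files.
#' @param images Optional in-memory images.
#' @param split_seed Seed for the stratified split.
#' @return A `screening_eval`.
#' @export
run_within_cohort <- function(manifest, config = run_config(), base_dir = NULL,
                              images = NULL, split_seed = config$seed) {
  base_dir <- base_dir %||% attr(manifest, "base_dir")
  strata <- paste(manifest$label_bright, manifest$label_red)
  take <- with_seed_(split_seed, {
    sel <- logical(nrow(manifest))
    for (s in unique(strata)) {
      rows <- which(strata == s)
      sel[sample(rows, ceiling(length(rows) / 2))] <- TRUE
    }
    sel
  })
  tr <- manifest[take, ]; te <- manifest[!take, ]
  tr$cohort <- paste0(tr$cohort, "_train")
  te$cohort <- paste0(te$cohort, "_test")
  attr(tr, "base_dir") <- base_dir; attr(te, "base_dir") <- base_dir
  run_cross_dataset(tr, te, config, base_dir, base_dir,
                    train_images = images, test_images = images)
}

#' @export
print.screening_eval <- function(x, ...) {
  cat(sprintf("<screening_eval> train=%s test=%s (%d test images)\n",
              paste(x$meta$train_cohort, collapse = "+"),
              paste(x$meta$test_cohort, collapse = "+"),
              length(x$meta$test_ids)))
  for (nm in names(x$rocs)) {
    if (!is.null(x$rocs[[nm]])) {
      cat(sprintf("  %-12s AUC = %.3f\n", nm, x$rocs[[nm]]$auc))
    }
  }
  invisible(x)
}

#' Tidy a screening evaluation
#'
#' @param x A `screening_eval`.
#' @param ... Unused.
#' @return Long tibble of per-curve metrics: AUC, the operating point at the
#'   configured specificity floor, and the confusion-matrix rates at the
#'   default decision threshold.
#' @export
tidy.screening_eval <- function(x, ...) {
  aucs <- dplyr::bind_rows(lapply(names(x$rocs), function(nm) {
    if (is.null(x$rocs[[nm]])) return(NULL)
    tibble::tibble(curve = nm, metric = "auc", value = x$rocs[[nm]]$auc)
  }))
  ops <- tidyr::pivot_longer(x$operating_points[c("curve", "sensitivity", "specificity")],
                             -"curve", names_to = "metric", values_to = "value")
  ops$metric <- paste0(ops$metric, "_at_target")
  conf <- tidyr::pivot_longer(
    x$confusion[c("curve", "sensitivity", "specificity", "accuracy")],
    -"curve", names_to = "metric", values_to = "value")
  dplyr::bind_rows(aucs, ops, conf)
}

#' Glance at a screening evaluation
#'
#' @param x A `screening_eval`.
#' @param ... Unused.
#' @return One-row tibble with the AUC of each reported curve.
#' @export
glance.screening_eval <- function(x, ...) {
  vals <- lapply(x$rocs, function(r) if (is.null(r)) NA_real_ else r$auc)
  names(vals) <- paste0("auc_", names(vals))
  tibble::as_tibble(vals)
}

#' @export
autoplot.screening_eval <- function(object, ...) {
  pts <- dplyr::bind_rows(lapply(names(object$rocs), function(nm) {
    if (is.null(object$rocs[[nm]])) return(NULL)
    dplyr::mutate(tidy(object$rocs[[nm]]),
                  curve = sprintf("%s (AUC %.3f)", nm, object$rocs[[nm]]$auc))
  }))
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr, colour = .data$curve)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_path() +
    coord_equal() +
    labs(x = "False-positive rate", y = "True-positive rate", colour = NULL,
         title = sprintf("Screening ROC: train %s, test %s",
                         paste(object$meta$train_cohort, collapse = "+"),
                         paste(object$meta$test_cohort, collapse = "+"))) +
    theme_minimal()
}

#' Export a screening evaluation as JSON
#'
#' Writes AUCs, operating points, confusion metrics and protocol metadata
#' (cohorts, ids used for training, config hash) to a JSON report, plus one
#' `roc_<curve>.csv` of (fpr, tpr, threshold) per reported curve.
#'
#' @param eval A `screening_eval`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
export_report <- function(eval, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    train_cohort = eval$meta$train_cohort, test_cohort = eval$meta$test_cohort,
    config_hash = eval$meta$config_hash, seed = eval$meta$seed,
    n_train = length(eval$meta$train_ids), n_test = length(eval$meta$test_ids),
    train_ids = eval$meta$train_ids,
    auc = lapply(eval$rocs, function(r) if (is.null(r)) NULL else r$auc),
    operating_points = eval$operating_points,
    confusion = eval$confusion
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(eval$rocs)) {
    if (!is.null(eval$rocs[[nm]])) {
      readr::write_csv(eval$rocs[[nm]]$points,
                       file.path(out_dir, sprintf("roc_%s.csv", nm)),
                       progress = FALSE)
    }
  }
  readr::write_csv(eval$screening, file.path(out_dir, "screening.csv"),
                   progress = FALSE)
  invisible(out_dir)
}
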