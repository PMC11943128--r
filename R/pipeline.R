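#' Full pipeline configuration
#'
#' Bundles the HSV band, morphology radii, cropper parameters, assembler
#' parameters and the BF-score tolerance into one object. The defaults
#' reproduce every numeric parameter of the published preprocessing recipe:
#' hue 0.2-0.4, saturation 0.3-1, value 0.1-1, closing disc radius 1,
#' erosion disc radius 2, 150-pixel expansion border and proximity
#' threshold, 90/10 split, x4 rotation augmentation. Every `run_*` command
#' writes the exact configuration it used as a JSON snapshot next to its
#' outputs.
#'
#' @param hsv An [hsv_range()].
#' @param morph A [morph_config()].
#' @param cropper A [cropper_config()].
#' @param assembler An [assembler_config()].
#' @param bf_theta BF-score distance tolerance in pixels, or `NULL` for the
#'   per-image default (0.75% of the image diagonal).
#' @param crop_format Output format for image crops (masks are always PNG).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(hsv = hsv_range(), morph = morph_config(),
                            cropper = cropper_config(),
                            assembler = assembler_config(),
                            bf_theta = NULL, crop_format = "png") {
  structure(
    list(
      hsv = hsv, morph = morph, cropper = cropper, assembler = assembler,
      bf_theta = bf_theta, crop_format = crop_format
    ),
    class = "pipeline_config"
  )
}

config_snapshot <- function(config) {
  lapply(
    list(
      hsv = config$hsv, morph = config$morph, cropper = config$cropper,
      assembler = config$assembler,
      bf_theta = list(bf_theta = config$bf_theta),
      crop_format = list(crop_format = config$crop_format)
    ),
    function(x) lapply(unclass(x), function(v) v)
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may set any subset of the parameter groups (`hsv`, `morph`,
#' `cropper`, `assembler`, `bf_theta`, `crop_format`); unset values keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pipeline_config(
    hsv = do.call(hsv_range, y$hsv %||% list()),
    morph = do.call(morph_config, y$morph %||% list()),
    cropper = do.call(cropper_config, y$cropper %||% list()),
    assembler = do.call(assembler_config, y$assembler %||% list()),
    bf_theta = y$bf_theta,
    crop_format = y$crop_format %||% "png"
  )
}

#' Write phantom images for a synthetic dataset
#'
#' Generates one or more phantoms and writes, per phantom, the marked slice,
#' the raw slice (under `raw/` with the identical basename, matching the
#' pairing convention of [find_raw_partner()]), the combined truth mask, and
#' a JSON sidecar with the true node boxes.
#'
#' @param out_dir Output directory.
#' @param specs A [synthetic_spec()] or list of them.
#' @return Tibble with one row per phantom: `id`, file paths, `n_nodes`.
#' @export
run_synth <- function(out_dir, specs = synthetic_spec()) {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  dir.create(file.path(out_dir, "raw"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(specs), function(i) {
    ph <- generate_phantom(specs[[i]])
    id <- sprintf("phantom%03d", i)
    marked_path <- file.path(out_dir, paste0(id, ".png"))
    raw_path <- file.path(out_dir, "raw", paste0(id, ".png"))
    truth_path <- file.path(out_dir, "truth", paste0(id, "_mask.png"))
    EBImage::writeImage(ras_to_ebi(ph$marked), marked_path, type = "png")
    EBImage::writeImage(ras_to_ebi(ph$raw), raw_path, type = "png")
    EBImage::writeImage(mask_to_ebi(phantom_truth_mask(ph)), truth_path,
                        type = "png")
    jsonlite::write_json(
      list(id = id, spec = unclass(ph$spec), truth_boxes = ph$truth_boxes),
      file.path(out_dir, "truth", paste0(id, "_geometry.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    tibble::tibble(
      id = id, marked_path = marked_path, raw_path = raw_path,
      truth_path = truth_path, n_nodes = length(ph$truth_masks)
    )
  })
  dplyr::bind_rows(rows)
}

#' Crop every annotated image in a directory
#'
#' Runs [build_ground_truth_pairs()] on each image, writes the accepted
#' crop/mask pairs, and returns (and writes) a manifest with one row per
#' detected region, accepted or skipped. Per-image accepted and skipped
#' counts are reported via `message()` — the auditable trace of the
#' duplicate-suppression mechanism.
#'
#' @param input_dir Directory of marked images (PNG/JPEG/TIFF).
#' @param out_dir Output directory for crops, masks and `manifest.csv`.
#' @param raw_dir Optional directory of raw partners (matched by basename).
#' @param config A [pipeline_config()].
#' @return The manifest tibble (zero rows when nothing is annotated).
#' @export
run_crop <- function(input_dir, out_dir, raw_dir = NULL,
                     config = pipeline_config()) {
  if (!dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir, call. = FALSE)
  }
  paths <- list.files(input_dir, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(paths) == 0L) {
    message("no images found in ", input_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(paths, function(p) {
    ann <- load_annotated(p, raw_path = find_raw_partner(p, raw_dir))
    rec <- build_ground_truth_pairs(
      ann,
      range = config$hsv, morph = config$morph, cfg = config$cropper,
      out_dir = out_dir, crop_format = config$crop_format
    )
    message(
      ann$id, ": ", sum(rec$accepted), " accepted, ",
      sum(!rec$accepted), " skipped",
      if (any(!rec$accepted)) {
        paste0(" (", paste(stats::na.omit(rec$skipped_reason), collapse = ", "), ")")
      } else ""
    )
    rec
  })
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0L) {
    manifest <- tibble::tibble(
      source_id = character(), region_id = integer(),
      x0 = integer(), y0 = integer(), width = integer(), height = integer(),
      ex0 = integer(), ey0 = integer(), ewidth = integer(), eheight = integer(),
      accepted = logical(), skipped_reason = character(),
      used_marked = logical(), crop_path = character(), mask_path = character()
    )
  }
  write_manifest(manifest, file.path(out_dir, "manifest.csv"),
                 config = config_snapshot(config))
  manifest
}

#' Build the augmented, split dataset from a crop manifest
#'
#' Reads the manifest written by [run_crop()], keeps the accepted records,
#' draws the seeded 90/10 split, then augments each side by seeded random
#' rotation (split first, so no rotated copy of a validation crop reaches
#' training). Writes rotated copies and the final manifest.
#'
#' @param manifest_path Manifest CSV from [run_crop()].
#' @param out_dir Output directory for rotated copies and
#'   `dataset_manifest.csv`.
#' @param config A [pipeline_config()].
#' @return The dataset manifest tibble with `split`, `parent_id`,
#'   `angle_deg`.
#' @export
run_build <- function(manifest_path, out_dir, config = pipeline_config()) {
  manifest <- read_manifest(manifest_path)
  accepted <- manifest[manifest$accepted, ]
  dataset <- assemble_dataset(accepted, config$assembler, out_dir = out_dir)
  message(
    nrow(accepted), " crops -> ",
    sum(dataset$split == "train"), " train / ",
    sum(dataset$split == "validation"), " validation entries after x",
    config$assembler$augmentation_factor, " augmentation"
  )
  write_manifest(dataset, file.path(out_dir, "dataset_manifest.csv"),
                 config = config_snapshot(config))
  dataset
}

#' Evaluate predicted masks against ground-truth masks on disk
#'
#' Pairs prediction and truth files by basename, computes the confusion
#' matrix and the full metric suite, and (optionally) writes the report as
#' JSON plus the confusion matrix as CSV.
#'
#' @param pred_dir Directory of predicted mask images.
#' @param truth_dir Directory of ground-truth mask images.
#' @param out_dir Optional output directory for `metrics.json` and
#'   `confusion.csv`.
#' @param config A [pipeline_config()] (supplies `bf_theta`).
#' @return A `seg_eval` object.
#' @export
run_evaluate <- function(pred_dir, truth_dir, out_dir = NULL,
                         config = pipeline_config()) {
  list_masks <- function(d) {
    fs <- list.files(d, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                     ignore.case = TRUE)
    stats::setNames(file.path(d, fs), tools::file_path_sans_ext(fs))
  }
  pred_files <- list_masks(pred_dir)
  truth_files <- list_masks(truth_dir)
  only_pred <- setdiff(names(pred_files), names(truth_files))
  only_truth <- setdiff(names(truth_files), names(pred_files))
  if (length(only_pred) > 0L || length(only_truth) > 0L) {
    stop(
      "unmatched mask files",
      if (length(only_pred)) paste0("; prediction only: ",
                                    paste(only_pred, collapse = ", ")),
      if (length(only_truth)) paste0("; truth only: ",
                                     paste(only_truth, collapse = ", ")),
      call. = FALSE
    )
  }
  if (length(pred_files) == 0L) stop("no mask pairs found", call. = FALSE)
  keys <- sort(names(pred_files))
  pred <- lapply(pred_files[keys], read_mask)
  truth <- lapply(truth_files[keys], read_mask)
  ev <- evaluate_segmentation(pred, truth, theta = config$bf_theta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      c(as.list(ev$metrics), list(n_images = ev$n_images)),
      file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(as.data.frame(unclass(ev$confusion)),
                     file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(config_snapshot(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  ev
}
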