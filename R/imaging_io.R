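#' Read an annotated image, optionally paired with its raw counterpart
#'
#' Loads a marked RGB raster (PNG, JPEG or TIFF) in which an expert has drawn
#' closed green contours around lymph nodes, and optionally the unmarked raw
#' slice exported at the identical resolution. The pair must agree in height
#' and width; a mismatch is an error, because downstream cropping cuts both
#' images at the same coordinates.
#'
#' @param path Path to the marked image.
#' @param raw_path Optional path to the unmarked raw slice.
#' @param id Identifier for the image; defaults to the file name without
#'   extension.
#' @return An object of class `annotated_image`: a list with elements `id`,
#'   `marked` (H x W x 3 array, values 0-255), `raw` (matching array or
#'   `NULL`), `source_path` and `raw_path`.
#' @examples
#' \dontrun{
#' ann <- load_annotated("slice_012_marked.png", "raw/slice_012_marked.png")
#' }
#' @export
load_annotated <- function(path, raw_path = NULL, id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read image: ", path, call. = FALSE)
  }
  marked <- read_raster(path)
  if (!is_rgb_raster(marked)) {
    # grayscale exports carry no colour annotation but are structurally valid
    marked <- array(rep(marked, 3L), dim = c(dim(marked), 3L))
  }
  raw <- NULL
  if (!is.null(raw_path)) {
    if (!file.exists(raw_path)) {
      stop("cannot read raw partner: ", raw_path, call. = FALSE)
    }
    raw <- read_raster(raw_path)
    if (!identical(raster_dim(raw), raster_dim(marked))) {
      stop(
        "pairing error: marked ", paste(raster_dim(marked), collapse = "x"),
        " vs raw ", paste(raster_dim(raw), collapse = "x"),
        " (", path, " / ", raw_path, ")",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      id = id %||% tools::file_path_sans_ext(basename(path)),
      marked = marked,
      raw = raw,
      source_path = path,
      raw_path = raw_path
    ),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- raster_dim(x$marked)
  cat(
    "<annotated_image> ", x$id, ": ", d[1], "x", d[2],
    if (is.null(x$raw)) ", no raw partner" else ", raw partner present",
    "\n", sep = ""
  )
  invisible(x)
}

#' Locate the raw partner of a marked image by filename convention
#'
#' The raw, unmarked export of a slice is assumed to live in a sibling
#' directory under the same basename (any of the supported raster
#' extensions). Returns `NULL` when no partner exists.
#'
#' @param path Path to the marked image.
#' @param raw_dir Directory holding raw slices.
#' @return Path to the partner file, or `NULL`.
#' @export
find_raw_partner <- function(path, raw_dir) {
  if (is.null(raw_dir) || !dir.exists(raw_dir)) {
    return(NULL)
  }
  base <- tools::file_path_sans_ext(basename(path))
  hits <- list.files(
    raw_dir,
    pattern = paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", base),
                     "\\.(png|jpg|jpeg|tif|tiff)$"),
    ignore.case = TRUE, full.names = TRUE
  )
  if (length(hits) == 0L) NULL else hits[[1L]]
}

#' Read a raster image as a base-R array
#'
#' @param path PNG, JPEG or TIFF file.
#' @return H x W matrix (grayscale) or H x W x 3 array (RGB), values 0-255.
#' @export
read_raster <- function(path) {
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) stop("cannot read image: ", path, " (", conditionMessage(e), ")", call. = FALSE)
  )
  arr <- ras_from_ebi(img)
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 4L) {
    arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  }
  arr
}

#' Read a binary mask image
#'
#' @param path Mask file; any pixel above half intensity counts as foreground.
#' @return Logical H x W matrix.
#' @export
read_mask <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr > 127.5
}

#' Write a crop / ground-truth mask pair
#'
#' The crop is written in the configured raster format; the mask is always
#' written as PNG with foreground 255 and background 0. A lossy mask would
#' corrupt the training labels, so the mask format is not configurable.
#'
#' @param crop Raster array (grayscale matrix or RGB array, values 0-255).
#' @param mask Logical matrix of identical height and width.
#' @param basename Output basename without extension.
#' @param out_dir Output directory; created if absent.
#' @param crop_format `"png"` (default), `"jpeg"` or `"tiff"`.
#' @return Named character vector `c(crop = path, mask = path)`.
#' @export
write_pair <- function(crop, mask, basename, out_dir, crop_format = "png") {
  if (!identical(raster_dim(crop), dim(mask))) {
    stop(
      "crop (", paste(raster_dim(crop), collapse = "x"),
      ") and mask (", paste(dim(mask), collapse = "x"),
      ") dimensions differ", call. = FALSE
    )
  }
  crop_format <- match.arg(crop_format, c("png", "jpeg", "tiff"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  ext <- c(png = "png", jpeg = "jpg", tiff = "tif")[[crop_format]]
  crop_path <- file.path(out_dir, paste0(basename, ".", ext))
  mask_path <- file.path(out_dir, paste0(basename, "_mask.png"))
  EBImage::writeImage(ras_to_ebi(crop), crop_path, type = crop_format, quality = 95L)
  EBImage::writeImage(mask_to_ebi(mask), mask_path, type = "png")
  c(crop = crop_path, mask = mask_path)
}

#' Write a dataset manifest
#'
#' The manifest is a CSV of crop records plus a JSON snapshot of the full
#' parameter set used to produce them, written next to the CSV as
#' `<name>_config.json`, so that any run can be reproduced from its own
#' record.
#'
#' @param records Tibble of crop records.
#' @param path Output CSV path.
#' @param config Optional named list of parameters to snapshot.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(records, path, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(
      config,
      sub("\\.csv$", "_config.json", path),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV written by [write_manifest()].
#' @return Tibble of crop records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE)
}
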