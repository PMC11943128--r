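#' Dataset-assembly parameters
#'
#' @param train_fraction Fraction of crops assigned to training (default
#'   0.9, i.e. a 90/10 train/validation split).
#' @param augmentation_factor Each original contributes itself plus
#'   `factor - 1` rotated copies (default 4, quadrupling the set).
#' @param seed Integer seed driving both the split and the rotation angles.
#' @return An `assembler_config` list.
#' @export
assembler_config <- function(train_fraction = 0.9, augmentation_factor = 4L,
                             seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (augmentation_factor < 1 || augmentation_factor != round(augmentation_factor)) {
    stop("augmentation_factor must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      train_fraction = train_fraction,
      augmentation_factor = as.integer(augmentation_factor),
      seed = as.integer(seed)
    ),
    class = "assembler_config"
  )
}

#' Split crop records into training and validation sets
#'
#' A uniformly random partition at the crop level with
#' `round(train_fraction * n)` training records (clamped so both sets stay
#' non-empty), deterministic given the seed.
#'
#' @param records Tibble of crop records.
#' @param cfg An [assembler_config()].
#' @return `records` with a `split` column of values `"train"` /
#'   `"validation"`.
#' @export
split_records <- function(records, cfg = assembler_config()) {
  n <- nrow(records)
  if (n < 2L) {
    stop("need at least 2 records to form both a training and a validation set",
         call. = FALSE)
  }
  n_train <- min(max(round(cfg$train_fraction * n), 1L), n - 1L)
  train_idx <- with_seed(cfg$seed, sample.int(n, n_train))
  records$split <- ifelse(seq_len(n) %in% train_idx, "train", "validation")
  records
}

#' Rotate a crop and its mask by the same angle
#'
#' Multiples of 90 degrees are exact array transpositions, so pixel values
#' and mask counts are preserved bit-for-bit. Other angles interpolate the
#' crop bilinearly and the mask nearest-neighbour (so the mask stays strictly
#' binary); the output keeps the input dimensions and corners swung in from
#' outside the original frame are zero-filled.
#'
#' @param crop Grayscale matrix or RGB array, values 0-255.
#' @param mask Logical matrix of the same height and width.
#' @param angle Rotation angle in degrees, counter-clockwise.
#' @return List with rotated `crop` and `mask`.
#' @export
rotate_pair <- function(crop, mask, angle) {
  if (!identical(raster_dim(crop), dim(mask))) {
    stop("crop and mask dimensions differ", call. = FALSE)
  }
  a <- angle %% 360
  if (a %in% c(0, 90, 180, 270)) {
    rot90 <- function(m) { # one 90-degree CCW turn of a matrix
      t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    }
    rot_raster <- function(x, quarter) {
      if (length(dim(x)) == 3L) {
        ch <- lapply(seq_len(dim(x)[3L]), function(k) {
          m <- x[, , k]
          for (q in seq_len(quarter)) m <- rot90(m)
          m
        })
        array(unlist(ch), dim = c(dim(ch[[1L]]), length(ch)))
      } else {
        m <- x
        for (q in seq_len(quarter)) m <- rot90(m)
        m
      }
    }
    q <- a %/% 90
    if (q == 0) {
      return(list(crop = crop, mask = mask))
    }
    return(list(crop = rot_raster(crop, q), mask = rot_raster(mask, q)))
  }
  d <- raster_dim(crop)
  out_dim <- c(d[2L], d[1L]) # EBImage dims are (x, y)
  rc <- EBImage::rotate(ras_to_ebi(crop), angle, filter = "bilinear",
                        bg.col = 0, output.dim = out_dim,
                        output.origin = (out_dim - out_dim) / 2)
  rm_ <- EBImage::rotate(mask_to_ebi(mask), angle, filter = "none",
                         bg.col = 0, output.dim = out_dim,
                         output.origin = (out_dim - out_dim) / 2)
  crop_out <- ras_from_ebi(rc)
  crop_out[crop_out < 0] <- 0
  crop_out[crop_out > 255] <- 255
  list(crop = crop_out, mask = ebi_to_mask(rm_))
}

#' Augment crop records by random rotation
#'
#' Each record contributes itself (angle 0) plus `augmentation_factor - 1`
#' copies rotated by angles drawn uniformly from [-180, 180) degrees; the
#' identical rotation is applied to the crop and its mask. Rotated files are
#' written next to the originals (or into `out_dir`), and every output row
#' records its parent id and angle.
#'
#' @param records Tibble with `crop_path` / `mask_path` columns referencing
#'   existing files, plus an `id` column (created from the crop basename
#'   when absent).
#' @param cfg An [assembler_config()].
#' @param out_dir Directory for rotated copies; defaults to each original's
#'   directory.
#' @return Tibble with `augmentation_factor * nrow(records)` rows and
#'   provenance columns `id`, `parent_id`, `angle_deg`.
#' @export
augment_records <- function(records, cfg = assembler_config(), out_dir = NULL) {
  missing <- c(
    records$crop_path[!file.exists(records$crop_path)],
    records$mask_path[!file.exists(records$mask_path)]
  )
  if (length(missing) > 0L) {
    stop("augment: missing files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(records)) {
    records$id <- tools::file_path_sans_ext(basename(records$crop_path))
  }
  f <- cfg$augmentation_factor
  n <- nrow(records)
  angles <- with_seed(
    cfg$seed + 1L, # distinct stream from the split draw
    stats::runif(n * max(f - 1L, 0L), min = -180, max = 180)
  )
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    base <- rec
    base$parent_id <- rec$id
    base$angle_deg <- 0
    copies <- list(base)
    if (f > 1L) {
      crop <- read_raster(rec$crop_path)
      mask <- read_mask(rec$mask_path)
      dir <- out_dir %||% dirname(rec$crop_path)
      for (k in seq_len(f - 1L)) {
        ang <- angles[(i - 1L) * (f - 1L) + k]
        rot <- rotate_pair(crop, mask, ang)
        paths <- write_pair(
          rot$crop, rot$mask,
          basename = sprintf("%s_rot%d", rec$id, k),
          out_dir = dir,
          crop_format = c(png = "png", jpg = "jpeg", jpeg = "jpeg",
                          tif = "tiff", tiff = "tiff")[[
                            tolower(tools::file_ext(rec$crop_path))]]
        )
        cp <- rec
        cp$id <- sprintf("%s_rot%d", rec$id, k)
        cp$parent_id <- rec$id
        cp$angle_deg <- ang
        cp$crop_path <- paths[["crop"]]
        cp$mask_path <- paths[["mask"]]
        copies[[k + 1L]] <- cp
      }
    }
    out[[i]] <- dplyr::bind_rows(copies)
  }
  dplyr::bind_rows(out)
}

#' Assemble a training-ready dataset: split, then augment
#'
#' The split is drawn first and augmentation is applied within each side, so
#' no rotated copy of a validation original can leak into training: every
#' augmented record inherits its parent's split label.
#'
#' @param records Tibble of accepted crop records with file paths.
#' @param cfg An [assembler_config()].
#' @param out_dir Directory for rotated copies.
#' @return Augmented tibble with `split`, `parent_id` and `angle_deg`.
#' @export
assemble_dataset <- function(records, cfg = assembler_config(), out_dir = NULL) {
  split <- split_records(records, cfg)
  augment_records(split, cfg, out_dir = out_dir)
}
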