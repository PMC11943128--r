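#' Cropper parameters
#'
#' `expansion_border` is added to every side of a tight bounding box before
#' cropping, so each crop extends the annotated region by 300 pixels per
#' axis at the default. `proximity_threshold` is the rectangle-to-rectangle
#' distance under which a newly found region counts as already covered by an
#' earlier crop and is skipped; both default to 150 pixels.
#'
#' @param expansion_border Pixels added per side when expanding a box.
#' @param proximity_threshold Gap (pixels) below which a region is skipped.
#' @return A `cropper_config` list.
#' @export
cropper_config <- function(expansion_border = 150L, proximity_threshold = 150L) {
  if (expansion_border < 0 || proximity_threshold < 0 ||
      expansion_border != round(expansion_border) ||
      proximity_threshold != round(proximity_threshold)) {
    stop("cropper parameters must be non-negative integers", call. = FALSE)
  }
  structure(
    list(
      expansion_border = as.integer(expansion_border),
      proximity_threshold = as.integer(proximity_threshold)
    ),
    class = "cropper_config"
  )
}

#' Construct a bounding-box tibble
#'
#' Boxes are 0-based and half-open: a box covers columns `[x0, x0 + width)`
#' and rows `[y0, y0 + height)`.
#'
#' @param x0,y0 0-based column / row of the top-left corner.
#' @param width,height Positive extents in pixels.
#' @return Tibble with one row per box.
#' @export
bbox <- function(x0, y0, width, height) {
  if (any(width <= 0) || any(height <= 0)) {
    stop("bounding boxes must have positive width and height", call. = FALSE)
  }
  tibble::tibble(
    x0 = as.integer(x0), y0 = as.integer(y0),
    width = as.integer(width), height = as.integer(height)
  )
}

# Label 8-connected foreground components. EBImage::bwlabel is 4-connected,
# so labels that touch diagonally are merged afterwards with a union-find
# over the (small) label graph.
label_components <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(mask_to_ebi(mask))))
  n <- max(lab)
  if (n <= 1L) {
    return(lab)
  }
  h <- nrow(lab); w <- ncol(lab)
  a <- c(lab[-h, -w], lab[-1L, -w]) # pair each pixel with its two
  b <- c(lab[-1L, -1L], lab[-h, -1L]) # diagonal neighbours
  keep <- a > 0L & b > 0L & a != b
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in which(keep)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Find tight bounding boxes of annotated regions
#'
#' One axis-aligned tight box per 8-connected foreground component, ordered
#' by the component's first row, then first column, so downstream
#' deduplication is deterministic.
#'
#' @param mask Logical H x W matrix.
#' @return [bbox()] tibble, empty for an empty mask.
#' @export
find_regions <- function(mask) {
  if (!any(mask)) {
    return(bbox(integer(), integer(), integer() + 1L, integer() + 1L))
  }
  lab <- label_components(mask)
  idx <- which(lab > 0L, arr.ind = TRUE)
  lb <- lab[lab > 0L]
  rmin <- tapply(idx[, 1L], lb, min)
  rmax <- tapply(idx[, 1L], lb, max)
  cmin <- tapply(idx[, 2L], lb, min)
  cmax <- tapply(idx[, 2L], lb, max)
  out <- bbox(
    x0 = cmin - 1L, y0 = rmin - 1L,
    width = cmax - cmin + 1L, height = rmax - rmin + 1L
  )
  out[order(out$y0, out$x0), ]
}

#' Expand a bounding box by a fixed border, clamped to the image
#'
#' Each side moves outward by `border` pixels (so both axes grow by
#' `2 * border` where no clamping occurs), then the box is clamped to the
#' image extent. Crops near the border are therefore smaller than the
#' nominal size; no pixels are fabricated by padding.
#'
#' @param b One-row [bbox()] tibble (or several rows, expanded row-wise).
#' @param border Pixels to add per side.
#' @param extent `c(height, width)` of the image.
#' @return Expanded, clamped [bbox()] tibble.
#' @export
expand_bbox <- function(b, border, extent) {
  h <- extent[[1L]]; w <- extent[[2L]]
  x0 <- pmax(b$x0 - border, 0L)
  y0 <- pmax(b$y0 - border, 0L)
  x1 <- pmin(b$x0 + b$width + border, w)
  y1 <- pmin(b$y0 + b$height + border, h)
  bbox(x0, y0, x1 - x0, y1 - y0)
}

#' Rectangle-to-rectangle gap
#'
#' The gap is `max(gap_x, gap_y)` where each axis gap is the empty distance
#' between the two boxes' projections on that axis (0 when the projections
#' overlap). It is 0 exactly when the boxes touch or overlap. This
#' Chebyshev-style metric matches axis-aligned box expansion: the gap is
#' below a threshold t precisely when expanding either box by t makes them
#' meet.
#'
#' @param a,b One-row [bbox()] tibbles.
#' @return Gap in pixels.
#' @export
bbox_gap <- function(a, b) {
  gx <- max(a$x0, b$x0) - min(a$x0 + a$width, b$x0 + b$width)
  gy <- max(a$y0, b$y0) - min(a$y0 + a$height, b$y0 + b$height)
  max(gx, gy, 0L)
}

bbox_inside <- function(inner, outer) {
  inner$x0 >= outer$x0 && inner$y0 >= outer$y0 &&
    inner$x0 + inner$width <= outer$x0 + outer$width &&
    inner$y0 + inner$height <= outer$y0 + outer$height
}

#' Select crops from tight boxes, suppressing duplicates
#'
#' Iterates over the tight boxes in their [find_regions()] order. A box that
#' lies fully inside a previously accepted expanded box is recorded as
#' skipped (`inside_previous`): that node is already on an earlier crop. A
#' box whose gap to any previously accepted expanded box is at most
#' `proximity_threshold` is recorded as skipped (`near_previous`). Otherwise
#' the box is expanded by `expansion_border`, clamped to the image, and
#' accepted. This is the control mechanism that prevents the same lymph node
#' being cropped twice; skipped rows keep their reason so potential misses
#' can be audited.
#'
#' @param tight_boxes [bbox()] tibble in [find_regions()] order.
#' @param cfg A [cropper_config()].
#' @param extent `c(height, width)` of the image.
#' @return Tibble with one row per input box: `region_id`, tight box
#'   columns, expanded box columns (`ex0`, `ey0`, `ewidth`, `eheight`, `NA`
#'   for skipped rows), `accepted`, and `skipped_reason`
#'   (`NA`, `"inside_previous"` or `"near_previous"`).
#' @export
select_crops <- function(tight_boxes, cfg = cropper_config(),
                         extent) {
  n <- nrow(tight_boxes)
  out <- tibble::tibble(
    region_id = seq_len(n),
    x0 = tight_boxes$x0, y0 = tight_boxes$y0,
    width = tight_boxes$width, height = tight_boxes$height,
    ex0 = NA_integer_, ey0 = NA_integer_,
    ewidth = NA_integer_, eheight = NA_integer_,
    accepted = FALSE,
    skipped_reason = NA_character_
  )
  accepted_idx <- integer()
  for (i in seq_len(n)) {
    tb <- tight_boxes[i, ]
    reason <- NA_character_
    for (j in accepted_idx) {
      eb <- bbox(out$ex0[j], out$ey0[j], out$ewidth[j], out$eheight[j])
      if (bbox_inside(tb, eb)) {
        reason <- "inside_previous"
        break
      }
      if (bbox_gap(tb, eb) <= cfg$proximity_threshold) {
        reason <- "near_previous"
        break
      }
    }
    if (is.na(reason)) {
      eb <- expand_bbox(tb, cfg$expansion_border, extent)
      out$ex0[i] <- eb$x0; out$ey0[i] <- eb$y0
      out$ewidth[i] <- eb$width; out$eheight[i] <- eb$height
      out$accepted[i] <- TRUE
      accepted_idx <- c(accepted_idx, i)
    } else {
      out$skipped_reason[i] <- reason
    }
  }
  out
}

#' Cut a bounding box out of a raster
#'
#' @param image Grayscale matrix or RGB array.
#' @param b One-row [bbox()] tibble inside the image extent.
#' @return Raster of exactly `width x height` pixels copied from the source.
#' @export
cut_bbox <- function(image, b) {
  d <- raster_dim(image)
  if (b$x0 < 0 || b$y0 < 0 ||
      b$x0 + b$width > d[2L] || b$y0 + b$height > d[1L]) {
    stop(
      "bounding box (", b$x0, ",", b$y0, ",", b$width, ",", b$height,
      ") exceeds image extent ", d[1L], "x", d[2L], call. = FALSE
    )
  }
  rows <- (b$y0 + 1L):(b$y0 + b$height)
  cols <- (b$x0 + 1L):(b$x0 + b$width)
  if (length(dim(image)) == 3L) {
    image[rows, cols, , drop = FALSE]
  } else {
    image[rows, cols, drop = FALSE]
  }
}

#' Build matched crop / ground-truth pairs from one annotated image
#'
#' Runs the full per-image pipeline: extract the filled annotation mask,
#' find annotated regions, deduplicate and expand their boxes, then cut the
#' raw image (falling back to the marked image when no raw partner exists,
#' flagged in `used_marked`) and the binary mask at the identical expanded
#' box. Every accepted pair has equal crop and mask dimensions and a
#' strictly positive mask foreground.
#'
#' @param ann An [load_annotated()] image.
#' @param range An [hsv_range()].
#' @param morph A [morph_config()].
#' @param cfg A [cropper_config()].
#' @param out_dir Optional directory; when given, each accepted pair is
#'   written via [write_pair()] and the returned tibble carries `crop_path` /
#'   `mask_path` instead of in-memory rasters.
#' @param crop_format Passed to [write_pair()].
#' @return Tibble of crop records (one row per detected region, accepted or
#'   skipped) with `source_id`, the [select_crops()] columns, `used_marked`,
#'   and either list-columns `crop` / `mask` or file-path columns. An
#'   unannotated image yields zero rows.
#' @export
build_ground_truth_pairs <- function(ann, range = hsv_range(),
                                     morph = morph_config(),
                                     cfg = cropper_config(),
                                     out_dir = NULL, crop_format = "png") {
  mask <- extract_annotation_mask(ann$marked, range, morph)
  boxes <- find_regions(mask)
  sel <- select_crops(boxes, cfg, extent = raster_dim(ann$marked))
  sel <- tibble::add_column(sel, source_id = ann$id, .before = 1L)
  sel$used_marked <- is.null(ann$raw)
  source_img <- ann$raw %||% ann$marked
  if (is.null(out_dir)) {
    sel$crop <- vector("list", nrow(sel))
    sel$mask <- vector("list", nrow(sel))
  } else {
    sel$crop_path <- NA_character_
    sel$mask_path <- NA_character_
  }
  for (i in which(sel$accepted)) {
    eb <- bbox(sel$ex0[i], sel$ey0[i], sel$ewidth[i], sel$eheight[i])
    crop <- cut_bbox(source_img, eb)
    mcrop <- cut_bbox(mask, eb)
    if (is.null(out_dir)) {
      sel$crop[[i]] <- crop
      sel$mask[[i]] <- mcrop
    } else {
      paths <- write_pair(
        crop, mcrop,
        basename = sprintf("%s_region%02d", ann$id, sel$region_id[i]),
        out_dir = out_dir, crop_format = crop_format
      )
      sel$crop_path[i] <- paths[["crop"]]
      sel$mask_path[i] <- paths[["mask"]]
    }
  }
  sel
}
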