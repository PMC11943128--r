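#' HSV threshold band for the annotation colour
#'
#' All six bounds are fractions in `[0, 1]`; hue is normalised (green sits at
#' 1/3), not in degrees. The defaults select the green marking pen used on
#' the MR exports: hue 0.2-0.4 brackets the green band, saturation >= 0.3
#' excludes the grey tissue tones, and value >= 0.1 admits all brightness
#' levels of the pen. All comparisons downstream are inclusive.
#'
#' @param hue_min,hue_max Hue bounds, fractions in `[0, 1]`.
#' @param sat_min,sat_max Saturation bounds.
#' @param val_min,val_max Value (brightness) bounds.
#' @return An `hsv_range` list.
#' @export
hsv_range <- function(hue_min = 0.2, hue_max = 0.4,
                      sat_min = 0.3, sat_max = 1,
                      val_min = 0.1, val_max = 1) {
  rng <- list(
    hue_min = hue_min, hue_max = hue_max,
    sat_min = sat_min, sat_max = sat_max,
    val_min = val_min, val_max = val_max
  )
  vals <- unlist(rng)
  if (any(vals < 0 | vals > 1)) {
    stop("hsv_range bounds must be fractions in [0, 1]", call. = FALSE)
  }
  if (hue_min > hue_max || sat_min > sat_max || val_min > val_max) {
    stop("hsv_range: each min must not exceed its max", call. = FALSE)
  }
  structure(rng, class = "hsv_range")
}

#' Morphology parameters for contour filling
#'
#' Disc radii for the two structuring elements of the mask-extraction chain:
#' a closing that bridges small gaps in the drawn contour, and a final
#' erosion that removes pen speckles and the contour thickening left by hole
#' filling. Radius 0 disables the corresponding step.
#'
#' @param close_disc_radius Disc radius (pixels) for the closing step.
#' @param erode_disc_radius Disc radius (pixels) for the final erosion.
#' @return A `morph_config` list.
#' @export
morph_config <- function(close_disc_radius = 1L, erode_disc_radius = 2L) {
  if (close_disc_radius < 0 || erode_disc_radius < 0 ||
      close_disc_radius != round(close_disc_radius) ||
      erode_disc_radius != round(erode_disc_radius)) {
    stop("disc radii must be non-negative integers", call. = FALSE)
  }
  structure(
    list(
      close_disc_radius = as.integer(close_disc_radius),
      erode_disc_radius = as.integer(erode_disc_radius)
    ),
    class = "morph_config"
  )
}

#' Disc structuring element
#'
#' The disc of radius `r` is the set of integer offsets `(dx, dy)` with
#' Euclidean distance `sqrt(dx^2 + dy^2) <= r`. This discretisation is fixed
#' here because "disc" kernels differ between imaging environments: radius 1
#' is the 5-pixel plus shape (diagonals are at distance sqrt(2) > 1) and
#' radius 2 is the 13-pixel disc that includes the diagonals but not the
#' knight-move offsets (sqrt(5) > 2).
#'
#' @param r Non-negative integer radius.
#' @return A `(2r+1) x (2r+1)` 0/1 matrix.
#' @export
disc_kernel <- function(r) {
  r <- as.integer(r)
  if (r < 0) stop("disc radius must be non-negative", call. = FALSE)
  off <- seq.int(-r, r)
  k <- outer(off^2, off^2, "+") <= r^2
  storage.mode(k) <- "integer"
  k
}

#' Convert an 8-bit RGB raster to HSV fractions
#'
#' @param img H x W x 3 array with values in 0-255.
#' @return H x W x 3 array; channel 1 hue, 2 saturation, 3 value, each a
#'   fraction in `[0, 1]` (hue normalised, green at 1/3).
#' @export
rgb_to_hsv_raster <- function(img) {
  if (!is_rgb_raster(img)) {
    stop("expected an H x W x 3 RGB raster", call. = FALSE)
  }
  check_raster_values(img, "RGB")
  px <- matrix(img, ncol = 3L) # rows = pixels, cols = R, G, B
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
  array(t(hsv), dim = dim(img))
}

#' Threshold an HSV raster against a colour band
#'
#' A pixel is foreground iff all three channels lie inside their bounds,
#' bounds inclusive. Pure grayscale pixels have saturation 0 and so never
#' pass the default band.
#'
#' @param hsv H x W x 3 HSV raster (fractions, as from [rgb_to_hsv_raster()]).
#' @param range An [hsv_range()].
#' @return Logical H x W matrix.
#' @export
green_mask <- function(hsv, range = hsv_range()) {
  if (!is_rgb_raster(hsv)) {
    stop("expected an H x W x 3 HSV raster", call. = FALSE)
  }
  keep <- hsv[, , 1L] >= range$hue_min & hsv[, , 1L] <= range$hue_max &
    hsv[, , 2L] >= range$sat_min & hsv[, , 2L] <= range$sat_max &
    hsv[, , 3L] >= range$val_min & hsv[, , 3L] <= range$val_max
  matrix(keep, dim(hsv)[1L], dim(hsv)[2L])
}

#' Fill enclosed holes in a binary mask
#'
#' Every background region not connected to the image border becomes
#' foreground. Background connectivity is 4-connected and foreground
#' components are 8-connected (the standard duality), so a contour that
#' closes only diagonally still encloses its interior.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!any(mask)) {
    return(mask)
  }
  ebi_to_mask(EBImage::fillHull(mask_to_ebi(mask)))
}

#' Extract the filled annotation mask from a marked RGB image
#'
#' The full contour-to-mask chain: threshold the image in HSV space against
#' the annotation colour band, fill contour interiors, close residual gaps
#' between pen strokes with a disc of radius `close_disc_radius`, fill again
#' to merge the bridged components, and finally erode with a disc of radius
#' `erode_disc_radius` to strip speckles and the stroke thickening. The
#' operation order threshold, fill, close, fill, erode is fixed; the second
#' fill exists because the first may leave interiors open where the drawn
#' contour has gaps that only the closing bridges.
#'
#' @param marked H x W x 3 RGB raster with contour annotations, values 0-255.
#' @param range An [hsv_range()] selecting the annotation colour.
#' @param morph A [morph_config()] with the two disc radii.
#' @return Logical H x W mask of filled annotation interiors (an empty mask
#'   is a valid result for an unannotated image).
#' @export
extract_annotation_mask <- function(marked, range = hsv_range(),
                                    morph = morph_config()) {
  mask <- green_mask(rgb_to_hsv_raster(marked), range)
  mask <- fill_holes(mask)
  if (morph$close_disc_radius > 0L && any(mask)) {
    mask <- ebi_to_mask(
      EBImage::closing(mask_to_ebi(mask), disc_kernel(morph$close_disc_radius))
    )
  }
  mask <- fill_holes(mask)
  if (morph$erode_disc_radius > 0L && any(mask)) {
    mask <- ebi_to_mask(
      EBImage::erode(mask_to_ebi(mask), disc_kernel(morph$erode_disc_radius))
    )
  }
  mask
}
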