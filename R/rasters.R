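# Internal raster conventions
#
# Rasters are base-R arrays indexed [row, col(, channel)] with 8-bit values in
# [0, 255]; binary masks are logical [row, col] matrices. EBImage stores
# images as [x, y(, channel)] in [0, 1], so every crossing of that boundary
# transposes and rescales.

# EBImage Image -> H x W (x C) array of 0..255 values
ras_from_ebi <- function(img) {
  d <- EBImage::imageData(img)
  out <- if (length(dim(d)) == 3L) aperm(d, c(2L, 1L, 3L)) else t(d)
  out * 255
}

# H x W (x C) array of 0..255 -> EBImage Image
ras_to_ebi <- function(arr) {
  if (length(dim(arr)) == 3L) {
    EBImage::Image(aperm(arr, c(2L, 1L, 3L)) / 255, colormode = "Color")
  } else {
    EBImage::Image(t(arr) / 255, colormode = "Grayscale")
  }
}

mask_to_ebi <- function(mask) {
  EBImage::Image(t(mask) * 1, colormode = "Grayscale")
}

ebi_to_mask <- function(img) {
  t(EBImage::imageData(img)) > 0.5
}

raster_dim <- function(arr) dim(arr)[1:2]

is_rgb_raster <- function(arr) {
  is.array(arr) && length(dim(arr)) == 3L && dim(arr)[3L] == 3L
}

check_raster_values <- function(arr, what = "raster") {
  if (any(arr < 0 | arr > 255)) {
    stop(what, " values must lie in [0, 255]", call. = FALSE)
  }
  invisible(arr)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
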