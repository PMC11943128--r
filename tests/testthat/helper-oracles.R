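# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: hole filling
# is an iterative 4-connected flood propagation, morphology is an explicit
# offset loop, and crop selection is a literal re-coding of the dedup rules.

# shift a logical matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# hole filling: background 4-connected flood from the border; anything not
# reached becomes foreground
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reach <- !mask
  reach[2:(h - 1), 2:(w - 1)] <- FALSE
  repeat {
    grown <- reach |
      shift_mat(reach, 1, 0) | shift_mat(reach, -1, 0) |
      shift_mat(reach, 0, 1) | shift_mat(reach, 0, -1)
    grown <- grown & !mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | !reach
}

disc_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, ]
}

# erosion with replicated borders (out-of-bounds offsets are ignored), the
# convention of the imaging backend
oracle_erode <- function(mask, r) {
  offs <- disc_offsets(r)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_mat(mask, offs$dr[k], offs$dc[k], fill = TRUE)
  }
  out
}

oracle_dilate <- function(mask, r) {
  offs <- disc_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_mat(mask, offs$dr[k], offs$dc[k], fill = FALSE)
  }
  out
}

oracle_close <- function(mask, r) {
  oracle_erode(oracle_dilate(mask, r), r)
}

# the full reference chain on an already-thresholded binary mask
oracle_morphology_chain <- function(mask, close_r = 1, erode_r = 2) {
  m <- oracle_fill_holes(mask)
  m <- oracle_close(m, close_r)
  m <- oracle_fill_holes(m)
  oracle_erode(m, erode_r)
}

# literal re-coding of the crop-selection rules: for each tight box in
# order, skip if fully inside an accepted expanded box, skip if within the
# proximity threshold of one, else expand+clamp+accept
oracle_select <- function(boxes, border, prox, extent) {
  acc <- list()
  status <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    b <- as.list(boxes[i, ])
    verdict <- "accept"
    for (e in acc) {
      inside <- b$x0 >= e$x0 && b$y0 >= e$y0 &&
        (b$x0 + b$width) <= (e$x0 + e$width) &&
        (b$y0 + b$height) <= (e$y0 + e$height)
      if (inside) {
        verdict <- "inside_previous"
        break
      }
      gx <- max(b$x0, e$x0) - min(b$x0 + b$width, e$x0 + e$width)
      gy <- max(b$y0, e$y0) - min(b$y0 + b$height, e$y0 + e$height)
      if (max(gx, gy, 0) <= prox) {
        verdict <- "near_previous"
        break
      }
    }
    status[i] <- verdict
    if (verdict == "accept") {
      x0 <- max(b$x0 - border, 0)
      y0 <- max(b$y0 - border, 0)
      x1 <- min(b$x0 + b$width + border, extent[2])
      y1 <- min(b$y0 + b$height + border, extent[1])
      acc[[length(acc) + 1]] <- list(x0 = x0, y0 = y0,
                                     width = x1 - x0, height = y1 - y0)
    }
  }
  list(status = status, accepted = acc)
}

# per-pixel confusion tally by explicit double loop
oracle_confusion <- function(pred, truth) {
  cm <- matrix(0, 2, 2)
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      cm[1 + truth[i, j], 1 + pred[i, j]] <- cm[1 + truth[i, j], 1 + pred[i, j]] + 1
    }
  }
  cm
}

# draw a green circle contour (optionally with an angular gap) on a grey
# background; returns an H x W x 3 raster
make_contour_image <- function(h = 160, w = 160, cx = 80, cy = 80,
                               radius = 40, thickness = 2,
                               gap_at = NULL, gap_px = 0,
                               colour = c(0, 255, 0), bg = 120) {
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  y <- matrix(seq_len(h), h, w)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  ring <- d >= radius - thickness / 2 & d < radius + thickness / 2
  if (!is.null(gap_at)) {
    ang <- atan2(y - cy, x - cx)
    half_width <- (gap_px / 2) / radius # arc length to angle
    ring <- ring & !(abs(ang - gap_at) < half_width)
  }
  img <- array(bg, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ring] <- colour[ch]
    img[, , ch] <- plane
  }
  img
}

random_boxes <- function(n, extent = c(600, 800), max_size = 60) {
  tibble::tibble(
    x0 = sample.int(extent[2] - max_size, n) - 1L,
    y0 = sample.int(extent[1] - max_size, n) - 1L,
    width = sample.int(max_size, n),
    height = sample.int(max_size, n)
  )
}

random_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}

# boundary pixels by explicit neighbour loop: foreground 8-adjacent to
# background, with the outside of the image counting as background
boundary_pixels_ref <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > h || jj < 1 || jj > w || !mask[ii, jj]) {
            out[i, j] <- TRUE
          }
        }
      }
    }
  }
  out
}
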