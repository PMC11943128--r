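#' Specification of a synthetic annotated MR phantom
#'
#' Describes a grayscale MR-like slice containing bright elliptical "lymph
#' nodes" whose boundaries are traced with a green contour, as an expert
#' would draw them. Node placement is rejection-sampled so tight bounding
#' boxes keep a pairwise gap of at least `min_gap` pixels, which lets tests
#' place nodes deliberately farther apart (or closer together) than the
#' cropper's proximity threshold.
#'
#' @param height,width Image extent in pixels.
#' @param n_nodes Number of nodes to place.
#' @param radius_range Two-element range of ellipse semi-axes in pixels.
#' @param min_gap Minimum pairwise gap between node tight boxes (pixels).
#' @param max_gap Optional maximum gap from each node after the first to its
#'   nearest predecessor (pixels, `Inf` to disable); lets tests construct
#'   deliberately crowded layouts, e.g. nodes within the cropper's
#'   proximity threshold.
#' @param contour_rgb 8-bit contour colour; the default pure green falls
#'   inside the default [hsv_range()] band.
#' @param contour_thickness Contour stroke thickness in pixels.
#' @param antialias When `TRUE`, contour edges are blended with the
#'   underlying tissue intensity (supersampled coverage), emulating the
#'   soft edges of viewer exports and stressing the HSV band.
#' @param background_noise_sd Standard deviation of the Gaussian pixel noise
#'   on top of the smooth tissue-intensity field (8-bit intensity units).
#' @param node_intensity_delta How much brighter a node interior is than the
#'   surrounding tissue (8-bit intensity units).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(height = 1024L, width = 1024L, n_nodes = 3L,
                           radius_range = c(20L, 60L), min_gap = 400L,
                           max_gap = Inf,
                           contour_rgb = c(0L, 255L, 0L),
                           contour_thickness = 2L, antialias = FALSE,
                           background_noise_sd = 8, node_intensity_delta = 90,
                           seed = 1L) {
  if (length(radius_range) != 2L || radius_range[1L] > radius_range[2L]) {
    stop("radius_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (contour_thickness < 1L) {
    stop("contour_thickness must be at least 1 pixel", call. = FALSE)
  }
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      n_nodes = as.integer(n_nodes),
      radius_range = as.integer(radius_range),
      min_gap = as.integer(min_gap),
      max_gap = max_gap,
      contour_rgb = as.integer(contour_rgb),
      contour_thickness = as.integer(contour_thickness),
      antialias = isTRUE(antialias),
      background_noise_sd = background_noise_sd,
      node_intensity_delta = node_intensity_delta,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Ellipse interior as a logical mask, optionally on a supersampled grid.
ellipse_mask <- function(h, w, cx, cy, a, b, scale = 1L) {
  x <- (seq_len(w * scale) - 0.5) / scale
  y <- (seq_len(h * scale) - 0.5) / scale
  outer((y - cy)^2 / b^2, (x - cx)^2 / a^2, "+") <= 1
}

# Fractional coverage in [0,1] of a supersampled mask per output pixel:
# the mean over each scale x scale block.
downsample_coverage <- function(mask, scale) {
  h <- nrow(mask) %/% scale
  w <- ncol(mask) %/% scale
  out <- matrix(0, h, w)
  for (i in seq_len(scale)) {
    for (j in seq_len(scale)) {
      out <- out + mask[seq.int(i, by = scale, length.out = h),
                        seq.int(j, by = scale, length.out = w)]
    }
  }
  out / scale^2
}

#' Generate a synthetic annotated phantom
#'
#' Produces the raw grayscale slice (a smooth low-frequency tissue field
#' plus Gaussian noise, with brighter elliptical nodes), the marked RGB
#' slice (raw with a green contour traced around each node boundary), the
#' exact per-node interior masks, and the tight bounding box of each node.
#' Output is deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @param max_attempts Rejection-sampling budget for node placement.
#' @return List with `raw` (H x W matrix, 0-255), `marked` (H x W x 3
#'   array), `truth_masks` (list of logical matrices, one per node),
#'   `truth_boxes` ([bbox()] tibble) and `spec`.
#' @export
generate_phantom <- function(spec = synthetic_spec(), max_attempts = 1000L) {
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    # smooth tissue field: sum of a few broad 2-D cosine components
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    field <- matrix(110, h, w)
    for (k in 1:3) {
      field <- field + 12 *
        cos(2 * pi * (stats::runif(1) * xx / w + stats::runif(1) * yy / h) +
              stats::runif(1, 0, 2 * pi))
    }
    raw <- field + stats::rnorm(h * w, sd = spec$background_noise_sd)

    # place nodes by rejection sampling on the tight-box gap constraint
    nodes <- list()
    boxes <- bbox(integer(), integer(), integer(), integer())
    attempts <- 0L
    restarts <- 0L
    margin <- spec$contour_thickness + 2L
    while (length(nodes) < spec$n_nodes) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        # a partial layout can wedge itself; retry from an empty canvas a
        # few times before declaring the spec unsatisfiable
        if (restarts < 10L) {
          restarts <- restarts + 1L
          attempts <- 0L
          nodes <- list()
          boxes <- bbox(integer(), integer(), integer(), integer())
          next
        }
        stop("could not place ", spec$n_nodes, " nodes with min_gap ",
             spec$min_gap, " in ", h, "x", w, " after ",
             (restarts + 1L) * max_attempts, " attempts", call. = FALSE)
      }
      a <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
      b <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
      cx <- stats::runif(1, a + margin, w - a - margin)
      cy <- stats::runif(1, b + margin, h - b - margin)
      cand <- bbox(
        x0 = floor(cx - a), y0 = floor(cy - b),
        width = ceiling(cx + a) - floor(cx - a),
        height = ceiling(cy + b) - floor(cy - b)
      )
      gaps <- vapply(seq_len(nrow(boxes)),
                     function(j) bbox_gap(cand, boxes[j, ]), numeric(1))
      if (any(gaps < spec$min_gap)) next
      if (length(gaps) > 0L && is.finite(spec$max_gap) &&
          min(gaps) > spec$max_gap) next
      nodes[[length(nodes) + 1L]] <- list(cx = cx, cy = cy, a = a, b = b)
      boxes <- dplyr::bind_rows(boxes, cand)
    }

    truth_masks <- vector("list", length(nodes))
    contour_alpha <- matrix(0, h, w)
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      interior <- ellipse_mask(h, w, nd$cx, nd$cy, nd$a, nd$b)
      truth_masks[[i]] <- interior
      raw[interior] <- raw[interior] + spec$node_intensity_delta
      t_ <- spec$contour_thickness
      if (spec$antialias) {
        sc <- 3L
        ring <- ellipse_mask(h, w, nd$cx, nd$cy, nd$a + t_, nd$b + t_, scale = sc) &
          !ellipse_mask(h, w, nd$cx, nd$cy, nd$a, nd$b, scale = sc)
        contour_alpha <- pmax(contour_alpha, downsample_coverage(ring, sc))
      } else {
        ring <- ellipse_mask(h, w, nd$cx, nd$cy, nd$a + t_, nd$b + t_) & !interior
        contour_alpha[ring] <- 1
      }
    }
    raw <- pmin(pmax(raw, 0), 255)

    marked <- array(rep(raw, 3L), dim = c(h, w, 3L))
    for (ch in 1:3) {
      marked[, , ch] <- (1 - contour_alpha) * marked[, , ch] +
        contour_alpha * spec$contour_rgb[ch]
    }
    marked <- round(marked)

    list(
      raw = round(raw),
      marked = marked,
      truth_masks = truth_masks,
      truth_boxes = boxes,
      spec = spec
    )
  })
}

#' Combined truth mask of a phantom (union of node interiors)
#'
#' @param phantom A [generate_phantom()] result.
#' @return Logical H x W matrix.
#' @export
phantom_truth_mask <- function(phantom) {
  Reduce(`|`, phantom$truth_masks,
         matrix(FALSE, phantom$spec$height, phantom$spec$width))
}
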