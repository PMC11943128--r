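test_that("find_regions returns one tight box per 8-connected component, in scan order", {
  m <- matrix(FALSE, 200, 200)
  m[1:10, 1:10] <- TRUE
  m[101:110, 101:110] <- TRUE
  b <- find_regions(m)
  expect_equal(as.data.frame(b),
               data.frame(x0 = c(0L, 100L), y0 = c(0L, 100L),
                          width = c(10L, 10L), height = c(10L, 10L)))

  expect_equal(nrow(find_regions(matrix(FALSE, 5, 5))), 0)

  # an L-shaped component gets the min/max row-column extent
  L <- matrix(FALSE, 50, 50)
  L[10:40, 10:12] <- TRUE
  L[38:40, 10:30] <- TRUE
  idx <- which(L, arr.ind = TRUE)
  b <- find_regions(L)
  expect_equal(nrow(b), 1)
  expect_equal(b$x0, min(idx[, 2]) - 1L)
  expect_equal(b$y0, min(idx[, 1]) - 1L)
  expect_equal(b$width, diff(range(idx[, 2])) + 1L)
  expect_equal(b$height, diff(range(idx[, 1])) + 1L)

  # diagonal touch joins components (8-connectivity)
  d <- matrix(FALSE, 10, 10)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE; d[4, 4] <- TRUE
  expect_equal(nrow(find_regions(d)), 1)
})

test_that("expand_bbox grows each side by the border and clamps at the image edge", {
  expect_equal(
    as.data.frame(expand_bbox(bbox(200, 200, 50, 40), 150, c(1000, 1000))),
    data.frame(x0 = 50L, y0 = 50L, width = 350L, height = 340L)
  )
  expect_equal(
    as.data.frame(expand_bbox(bbox(10, 10, 50, 50), 150, c(600, 600))),
    data.frame(x0 = 0L, y0 = 0L, width = 210L, height = 210L)
  )
  b <- bbox(37, 12, 20, 30)
  expect_equal(expand_bbox(b, 0, c(100, 100)), b)
})

test_that("bbox_gap is the max per-axis projection gap, 0 iff boxes touch or overlap", {
  expect_equal(bbox_gap(bbox(0, 0, 10, 10), bbox(20, 0, 10, 10)), 10)
  expect_equal(bbox_gap(bbox(0, 0, 10, 10), bbox(5, 5, 10, 10)), 0) # overlap
  expect_equal(bbox_gap(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 0) # identical
  expect_equal(bbox_gap(bbox(0, 0, 10, 10), bbox(10, 0, 5, 5)), 0)  # touching
  expect_equal(bbox_gap(bbox(0, 0, 10, 10), bbox(30, 40, 5, 5)), 30) # diagonal
})

test_that("select_crops accepts well-separated boxes and skips near or contained ones", {
  extent <- c(2000, 2000)
  # three boxes pairwise farther than the threshold even after expansion
  far <- bbox(c(0, 700, 1400), c(0, 700, 1400), c(50, 50, 50), c(50, 50, 50))
  sel <- select_crops(far, cropper_config(), extent)
  expect_true(all(sel$accepted))

  # two small boxes 100 px apart: the second falls inside the first
  # expanded crop and is skipped
  near <- bbox(c(300, 450), c(300, 300), c(50, 50), c(50, 50))
  sel <- select_crops(near, cropper_config(), extent)
  expect_equal(sel$accepted, c(TRUE, FALSE))
  expect_equal(sel$skipped_reason[2], "inside_previous")

  # a box beyond the expanded crop but within the threshold of it
  prox <- bbox(c(300, 600), c(300, 300), c(50, 50), c(50, 50))
  sel <- select_crops(prox, cropper_config(), extent)
  expect_equal(sel$accepted, c(TRUE, FALSE))
  expect_equal(sel$skipped_reason[2], "near_previous")

  single <- select_crops(bbox(10, 10, 20, 20), cropper_config(), extent)
  expect_true(single$accepted)
  expect_true(is.na(single$skipped_reason))
})

test_that("select_crops matches the brute-force reference on random box sets", {
  set.seed(500)
  for (rep in 1:200) {
    n <- sample.int(10, 1)
    boxes <- random_boxes(n)
    cfg <- cropper_config(
      expansion_border = sample(c(0, 50, 150), 1),
      proximity_threshold = sample(c(0, 50, 150), 1)
    )
    got <- select_crops(boxes, cfg, extent = c(600, 800))
    ref <- oracle_select(boxes, cfg$expansion_border, cfg$proximity_threshold,
                         extent = c(600, 800))
    expect_identical(got$accepted, ref$status == "accept")
    expect_identical(got$skipped_reason[!got$accepted],
                     ref$status[ref$status != "accept"])
    if (any(got$accepted)) {
      acc <- got[got$accepted, ]
      ref_acc <- dplyr::bind_rows(lapply(ref$accepted, tibble::as_tibble))
      expect_equal(acc$ex0, ref_acc$x0)
      expect_equal(acc$ey0, ref_acc$y0)
      expect_equal(acc$ewidth, ref_acc$width)
      expect_equal(acc$eheight, ref_acc$height)
    }
    # the selection is a pure function of its inputs
    expect_identical(select_crops(boxes, cfg, extent = c(600, 800)), got)
  }
})

test_that("no accepted tight box is inside or within threshold of an earlier accepted crop", {
  set.seed(900)
  for (rep in 1:50) {
    boxes <- random_boxes(sample.int(8, 1))
    cfg <- cropper_config()
    sel <- select_crops(boxes, cfg, extent = c(600, 800))
    acc <- which(sel$accepted)
    for (k in seq_along(acc)) {
      for (j in seq_len(k - 1)) {
        eb <- bbox(sel$ex0[acc[j]], sel$ey0[acc[j]],
                   sel$ewidth[acc[j]], sel$eheight[acc[j]])
        tb <- bbox(sel$x0[acc[k]], sel$y0[acc[k]],
                   sel$width[acc[k]], sel$height[acc[k]])
        expect_gt(bbox_gap(tb, eb), cfg$proximity_threshold)
      }
    }
  }
})

test_that("cut_bbox copies exactly the requested pixels", {
  set.seed(3)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  expect_identical(cut_bbox(img, bbox(0, 0, 64, 64)), img)
  b <- bbox(5, 10, 20, 15)
  expect_identical(cut_bbox(img, b), img[11:25, 6:25])
  rgb <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), dim = c(32, 32, 3))
  expect_identical(cut_bbox(rgb, bbox(4, 2, 10, 12)), rgb[3:14, 5:14, , drop = FALSE])
  expect_error(cut_bbox(img, bbox(60, 60, 10, 10)), "exceeds image extent")
})

test_that("build_ground_truth_pairs cuts matched crop/mask pairs from phantom geometry", {
  ph <- generate_phantom(synthetic_spec(height = 900, width = 900, n_nodes = 2,
                                        min_gap = 500, radius_range = c(20, 40),
                                        seed = 21))
  ann <- structure(
    list(id = "ph", marked = ph$marked, raw = ph$raw,
         source_path = "ph.png", raw_path = "raw/ph.png"),
    class = "annotated_image"
  )
  rec <- build_ground_truth_pairs(ann)
  expect_equal(sum(rec$accepted), 2)
  expect_false(any(rec$used_marked))
  for (i in which(rec$accepted)) {
    expect_identical(dim(rec$crop[[i]])[1:2], dim(rec$mask[[i]]))
    expect_gt(sum(rec$mask[[i]]), 0) # strictly positive foreground
    expect_lte(rec$ewidth[i], 2 * 150 + rec$width[i])
  }

  # without a raw partner the marked image is cut, and the record says so
  ann2 <- structure(
    list(id = "ph2", marked = ph$marked, raw = NULL,
         source_path = "ph.png", raw_path = NULL),
    class = "annotated_image"
  )
  rec2 <- build_ground_truth_pairs(ann2)
  expect_true(all(rec2$used_marked))
  i <- which(rec2$accepted)[1]
  expect_equal(dim(rec2$crop[[i]])[3], 3) # marked fallback is RGB

  # unannotated image: zero rows
  grey <- structure(
    list(id = "g", marked = array(100, dim = c(300, 300, 3)), raw = NULL,
         source_path = "g.png", raw_path = NULL),
    class = "annotated_image"
  )
  expect_equal(nrow(build_ground_truth_pairs(grey)), 0)
})

test_that("written masks contain exactly the value set {0, 255}", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(synthetic_spec(height = 500, width = 500, n_nodes = 1,
                                        min_gap = 100, seed = 9))
  ann <- structure(
    list(id = "w", marked = ph$marked, raw = ph$raw,
         source_path = "w.png", raw_path = NULL),
    class = "annotated_image"
  )
  rec <- build_ground_truth_pairs(ann, out_dir = dir)
  i <- which(rec$accepted)[1]
  vals <- unique(as.vector(read_raster(rec$mask_path[i])))
  expect_setequal(vals, c(0, 255))
})
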