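p400 <- get_profile("400x")

test_that("a rendered ellipse complex is recovered to within 5% of pi*a*b", {
  crop <- single_stoma_crop(a_px = 20, b_px = 10, theta = 0.4)
  mask <- segment_stoma(crop, p400)
  expect_s3_class(mask, "stoma_mask")
  area_px <- abs(stomapipe:::polygon_area(mask$complex_polygon))
  expect_lt(abs(area_px - 200 * pi) / (200 * pi), 0.05)
  # fitted axes near the true full axes (40, 20 px)
  expect_lt(abs(mask$complex_ellipse$major - 40) / 40, 0.08)
  expect_lt(abs(mask$complex_ellipse$minor - 20) / 20, 0.08)
})

test_that("closed stomata yield no aperture and blank crops fail gracefully", {
  closed <- segment_stoma(single_stoma_crop(16, 9, openness = 0), p400)
  expect_s3_class(closed, "stoma_mask")
  expect_null(closed$aperture_polygon)
  tr <- measure_stoma(closed, p400)
  expect_true(is.na(tr$aperture_length_um))
  expect_true(is.na(tr$openness))
  expect_identical(tr$status, "ok")

  expect_null(segment_stoma(matrix(0.78, 40, 40), p400))
  failed <- measure_stoma(NULL, p400)
  expect_identical(failed$status, "failed")
  expect_true(is.na(failed$complex_area_um2))
})

test_that("open apertures are segmented and measured", {
  crop <- single_stoma_crop(a_px = 18, b_px = 10, openness = 0.4)
  mask <- segment_stoma(crop, p400)
  expect_false(is.null(mask$aperture_polygon))
  tr <- measure_stoma(mask, p400)
  # true aperture: semi-axes 9 x 4 px
  expect_lt(abs(tr$aperture_length_um - px_to_um(18, p400)) /
              px_to_um(18, p400), 0.2)
  expect_gt(tr$openness, 0.25)
  expect_lt(tr$openness, 0.55)
})

test_that("unit-square polygon area converts exactly through the calibration", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  mask <- stoma_mask(sq)
  tr <- measure_stoma(mask, p400)
  expect_equal(tr$complex_area_um2, (1000 / 652)^2)
})

test_that("measurement is invariant to polygon vertex order and start", {
  poly <- stomapipe:::ellipse_polygon(20, 15, 9, 5, 0.7)
  a <- measure_stoma(stoma_mask(poly), p400)
  b <- measure_stoma(stoma_mask(poly[rev(seq_len(nrow(poly))), ]), p400)
  rolled <- poly[c(17:nrow(poly), 1:16), ]
  c_ <- measure_stoma(stoma_mask(rolled), p400)
  for (col in c("complex_area_um2", "complex_length_um", "complex_width_um")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
    expect_equal(a[[col]], c_[[col]], tolerance = 1e-9)
  }
})

test_that("measuring generator ground-truth masks recovers the stored traits", {
  sc <- cached_scene("graminoid_large", 5)
  masks <- truth_to_masks(sc$truth)
  gt <- sc$truth$traits
  for (k in seq_along(masks)) {
    tr <- measure_stoma(masks[[k]], p400)
    expect_lt(abs(tr$complex_area_um2 - gt$complex_area_um2[k]) /
                gt$complex_area_um2[k], 0.05)
    expect_lt(abs(tr$complex_length_um - gt$complex_length_um[k]) /
                gt$complex_length_um[k], 0.05)
    if (!is.na(gt$openness[k])) {
      expect_lt(abs(tr$aperture_width_um - gt$aperture_width_um[k]) /
                  gt$aperture_width_um[k], 0.05)
    }
  }
})

test_that("trait estimates agree across magnification profiles", {
  p200 <- get_profile("200x")
  scale <- p200$px_per_mm / p400$px_per_mm
  tr400 <- measure_stoma(segment_stoma(
    single_stoma_crop(20, 11, openness = 0.35), p400), p400)
  tr200 <- measure_stoma(segment_stoma(
    single_stoma_crop(20 * scale, 11 * scale, openness = 0.35,
                      profile = p200), p200), p200)
  expect_lt(abs(tr400$complex_area_um2 - tr200$complex_area_um2) /
              tr400$complex_area_um2, 0.10)
  expect_lt(abs(tr400$complex_length_um - tr200$complex_length_um) /
              tr400$complex_length_um, 0.10)
})

test_that("image summaries aggregate counts, densities and sizes", {
  empty <- summarize_image(NULL, count = 0, p400, image_id = "e")
  expect_identical(empty$stomata_count, 0)
  expect_equal(empty$density_mm2, 0)
  expect_true(is.na(empty$mean_complex_area_um2))

  traits <- do.call(rbind, lapply(1:47, function(k) {
    tr <- stomapipe:::measurement_failed(k, "im", "ok")
    tr$complex_area_um2 <- 300 + k
    tr
  }))
  s <- summarize_image(traits, count = 47, p400, image_id = "im")
  expect_equal(s$density_mm2, 47 / 0.4275)
  expect_equal(s$mean_complex_area_um2, mean(300 + 1:47))
  expect_equal(s$fraction_open, 0)   # all apertures NA -> all closed
  # count can exceed measured rows (failed/border detections still counted)
  s2 <- summarize_image(traits[1:40, ], count = 47, p400)
  expect_identical(s2$stomata_count, 47)
  expect_identical(s2$n_measured, 40L)
})

test_that("border detections are counted but not measured", {
  sc <- cached_scene("dicot", 3)
  boxes <- detection_boxes(x = c(-2, 50), y = c(10, 60), w = c(16, 16),
                           h = c(13, 13))
  tr <- measure_image(sc$image, boxes, p400)
  expect_identical(tr$status[1], "border")
  expect_true(all(is.na(tr$complex_area_um2[1])))
})

test_that("COCO-style annotations round trip and attach apertures by containment", {
  sc <- cached_scene("dicot", 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_instance_annotations(sc$truth, f, image_size_px = dim(sc$image))
  masks <- read_instance_annotations(f)
  expect_length(masks, sc$truth$count)
  k <- which(!vapply(sc$truth$aperture_polygons, is.null, logical(1)))[1]
  expect_equal(masks[[1]]$complex_polygon, sc$truth$complex_polygons[[1]],
               tolerance = 1e-8)
  got_ap <- which(!vapply(masks, function(m) is.null(m$aperture_polygon),
                          logical(1)))
  expect_identical(length(got_ap),
                   sum(!vapply(sc$truth$aperture_polygons, is.null,
                               logical(1))))
})

test_that("orphan apertures and malformed annotation files are rejected", {
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  f <- withr::local_tempfile(fileext = ".json")
  masks <- list(stoma_mask(sq(0, 0, 10)), stoma_mask(sq(30, 30, 10)))
  write_instance_annotations(masks, f)
  expect_length(read_instance_annotations(f), 2L)

  # aperture centroid inside the first complex -> attached to it
  m2 <- list(stoma_mask(sq(0, 0, 10), sq(2, 2, 3)), stoma_mask(sq(30, 30, 10)))
  write_instance_annotations(m2, f)
  back <- read_instance_annotations(f)
  expect_false(is.null(back[[1]]$aperture_polygon))
  expect_null(back[[2]]$aperture_polygon)

  # orphan aperture: centroid outside all complexes
  doc <- jsonlite::read_json(f, simplifyVector = FALSE)
  doc$annotations[[2]]$segmentation <-
    list(as.numeric(t(sq(100, 100, 3))))
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_instance_annotations(f), "orphan",
               class = "stomapipe_orphan_error")

  # invalid polygon (< 3 vertices)
  doc$annotations[[2]]$segmentation <- list(c(1, 1, 2, 2))
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_instance_annotations(f), class = "stomapipe_parse_error")

  # missing category map
  doc$categories <- NULL
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_instance_annotations(f), class = "stomapipe_parse_error")
})
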