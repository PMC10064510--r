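test_that("identical scene specs render bit-identical images and truth", {
  spec <- scene_spec(archetype = "dicot", seed = 42,
                     image_size_px = c(180, 140))
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_identical(place_stomata(spec), place_stomata(spec))
})

test_that("zero target density yields an empty scene", {
  spec <- scene_spec(archetype = "dicot", seed = 1, target_density_mm2 = 0,
                     image_size_px = c(150, 120))
  expect_identical(nrow(place_stomata(spec)), 0L)
  sc <- render_scene(spec)
  expect_identical(sc$truth$count, 0L)
  expect_identical(nrow(sc$truth$boxes), 0L)
})

test_that("realized counts hit the target density on average", {
  # 1 x 1 mm imaged area at 400 px/mm, target 50 per mm^2, 10 seeds
  prof <- magnification_profile("sq", 400, 1, 1, 2)
  counts <- vapply(1:10, function(s) {
    nrow(place_stomata(scene_spec(archetype = "dicot", profile = prof,
                                  target_density_mm2 = 50,
                                  image_size_px = c(400, 400), seed = s)))
  }, numeric(1))
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * sem)
})

test_that("realized density approaches the target for large imaged areas", {
  prof <- magnification_profile("wide", 400, 3, 3, 2)
  spec <- scene_spec(archetype = "dicot", profile = prof,
                     target_density_mm2 = 60, image_size_px = c(1200, 1200),
                     seed = 7)
  pl <- place_stomata(spec)  # ~540 expected
  expect_lt(abs(nrow(pl) / scene_area_mm2(spec) - 60) / 60, 0.10)
})

test_that("rows mode aligns stomata with the leaf axis up to jitter", {
  arch <- archetype_graminoid_large()
  spec <- scene_spec(archetype = arch, seed = 3)
  pl <- place_stomata(spec)
  expect_gt(nrow(pl), 2)
  expect_true(all(abs(pl$theta) <= 4 * arch$orientation_sd_deg * pi / 180))
  # hard-core inhibition holds
  d2 <- as.matrix(dist(pl[, c("cx", "cy")]))^2
  diag(d2) <- Inf
  dmin <- um_to_px(arch$min_spacing_um, spec$profile)
  expect_true(all(d2 >= dmin^2 - 1e-9))
})

test_that("scattered mode respects the minimum spacing", {
  spec <- scene_spec(archetype = "dicot", seed = 9)
  pl <- place_stomata(spec)
  d2 <- as.matrix(dist(pl[, c("cx", "cy")]))^2
  diag(d2) <- Inf
  dmin <- um_to_px(spec$archetype$min_spacing_um, spec$profile)
  expect_true(all(d2 >= dmin^2 - 1e-9))
})

test_that("infeasible densities raise a packing error naming the achievable maximum", {
  spec <- scene_spec(archetype = "dicot", seed = 1,
                     target_density_mm2 = 5000,
                     image_size_px = c(200, 160))
  expect_error(place_stomata(spec), "achievable maximum",
               class = "stomapipe_packing_error")
})

test_that("ground truth satisfies its geometric invariants", {
  sc <- cached_scene("graminoid_small", 11)
  tr <- sc$truth
  expect_gt(tr$count, 10)
  W <- nrow(sc$image); H <- ncol(sc$image)
  for (k in seq_len(tr$count)) {
    poly <- tr$complex_polygons[[k]]
    # polygons within image bounds (default border policy culls crossers)
    expect_true(all(poly[, 1] >= 0 & poly[, 1] <= W &
                    poly[, 2] >= 0 & poly[, 2] <= H))
    # box is the tight axis-aligned bound of the polygon
    bb <- as.numeric(tr$boxes[k, c("x", "y", "w", "h")])
    expect_equal(bb, unname(stomapipe:::polygon_bbox(poly)), tolerance = 1e-9)
    # polygon area agrees with the stored trait area within 2%
    a_poly <- area_px_to_um2(abs(stomapipe:::polygon_area(poly)), sc$spec$profile)
    expect_lt(abs(a_poly - tr$traits$complex_area_um2[k]) /
                tr$traits$complex_area_um2[k], 0.02)
    # aperture polygon, when present, lies inside the complex polygon
    ap <- tr$aperture_polygons[[k]]
    if (!is.null(ap)) {
      expect_equal(polygon_iou(ap, poly),
                   abs(stomapipe:::polygon_area(ap)) /
                     abs(stomapipe:::polygon_area(poly)),
                   tolerance = 1e-6)
    }
  }
})

test_that("stored GT areas match a pixel-count rasterization oracle", {
  sc <- cached_scene("graminoid_large", 5)
  tr <- sc$truth
  k <- which.max(tr$traits$complex_area_um2)
  poly <- tr$complex_polygons[[k]]
  bb <- stomapipe:::polygon_bbox(poly)
  gx <- seq(floor(bb["x"]), ceiling(bb["x"] + bb["w"])) + 0.5
  gy <- seq(floor(bb["y"]), ceiling(bb["y"] + bb["h"])) + 0.5
  n_in <- sum(vapply(gx, function(x) {
    sum(vapply(gy, function(y) stomapipe:::point_in_polygon(x, y, poly),
               logical(1)))
  }, numeric(1)))
  a_gt_px <- tr$traits$complex_area_um2[k] /
    (1000 / sc$spec$profile$px_per_mm)^2
  expect_lt(abs(n_in - a_gt_px) / a_gt_px, 0.02)
})

test_that("closed-aperture archetypes produce no aperture polygons", {
  arch <- species_archetype("closed", "scattered", 26, 18,
                           aperture_openness = 0, aperture_openness_sd = 0)
  sc <- render_scene(scene_spec(archetype = arch, seed = 2,
                                image_size_px = c(200, 160)))
  expect_gt(sc$truth$count, 0)
  expect_true(all(vapply(sc$truth$aperture_polygons, is.null, logical(1))))
  expect_true(all(is.na(sc$truth$traits$openness)))
})

test_that("border policy culls or clips complexes crossing the image edge", {
  base <- list(archetype = "dicot", seed = 13, image_size_px = c(200, 160),
               inset_margin = FALSE, noise_sd = 0, bubble_count = 0L)
  cull <- render_scene(do.call(scene_spec, c(base, border_policy = "cull")))
  keep <- render_scene(do.call(scene_spec, c(base,
                                             border_policy = "keep-clipped")))
  expect_gte(keep$truth$count, cull$truth$count)
  W <- 200; H <- 160
  for (p in cull$truth$complex_polygons) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H))
  }
  for (p in keep$truth$complex_polygons) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H))
  }
})

test_that("an image too small for one complex is rejected", {
  expect_error(
    place_stomata(scene_spec(archetype = "graminoid_large", seed = 1,
                             image_size_px = c(30, 30))),
    class = "stomapipe_config_error")
})

test_that("archetype parameter validation catches bad inputs", {
  expect_error(species_archetype("x", "rows", -5, 10),
               class = "stomapipe_config_error")
  expect_error(species_archetype("x", "rows", 20, 10, aperture_openness = 2),
               class = "stomapipe_config_error")
})
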