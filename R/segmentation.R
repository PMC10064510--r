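# Delineation of the stomatal complex and aperture from detection crops,
# and physical-unit trait measurement. "Stomatal size" is the area of the
# full complex outline (guard cells plus subsidiary cells where present),
# matching the annotation convention of the measurement workflow.

#' Construct a stoma mask
#'
#' A stoma mask holds the complex outline polygon, the aperture polygon
#' (absent for a closed stoma) and moment-fitted ellipses for both.
#' Ellipses are computed from the polygons when not supplied.
#'
#' @param complex_polygon n x 2 pixel-coordinate matrix (simple polygon,
#'   area > 0).
#' @param aperture_polygon n x 2 matrix or `NULL`.
#' @param stoma_id Identifier.
#' @param complex_ellipse,aperture_ellipse Optional pre-computed ellipses
#'   (lists `cx, cy, major, minor, angle`).
#' @return Object of class `stoma_mask`.
#' @export
stoma_mask <- function(complex_polygon, aperture_polygon = NULL,
                       stoma_id = 1L, complex_ellipse = NULL,
                       aperture_ellipse = NULL) {
  if (is.null(complex_polygon) || nrow(complex_polygon) < 3L) {
    stop_stomapipe("complex polygon needs >= 3 vertices",
                   "stomapipe_geometry_error")
  }
  if (abs(polygon_area(complex_polygon)) <= 0) {
    stop_stomapipe("complex polygon has zero area",
                   "stomapipe_geometry_error")
  }
  if (!is.null(aperture_polygon) && nrow(aperture_polygon) < 3L) {
    stop_stomapipe("aperture polygon needs >= 3 vertices",
                   "stomapipe_geometry_error")
  }
  if (is.null(complex_ellipse)) complex_ellipse <- polygon_ellipse(complex_polygon)
  if (is.null(aperture_ellipse) && !is.null(aperture_polygon)) {
    aperture_ellipse <- polygon_ellipse(aperture_polygon)
  }
  structure(
    list(stoma_id = stoma_id, complex_polygon = complex_polygon,
         aperture_polygon = aperture_polygon,
         complex_ellipse = complex_ellipse,
         aperture_ellipse = aperture_ellipse),
    class = "stoma_mask"
  )
}

#' Segmentation configuration
#'
#' @param smooth_sigma Gaussian pre-smoothing sd in px.
#' @param min_component_px Minimum complex component area in px.
#' @param min_aperture_fraction Aperture accepted only if its area is at
#'   least this fraction of the complex area (suppresses speck artifacts).
#' @param min_aperture_elongation Minimum major/minor axis ratio of the
#'   aperture candidate (true apertures are slit-like).
#' @param max_aperture_contrast Aperture candidate accepted only if its mean
#'   intensity is below this fraction of the complex mean intensity (the
#'   open pore is much darker than the surrounding cells).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(smooth_sigma = 0.6,
                                min_component_px = 12,
                                min_aperture_fraction = 0.02,
                                min_aperture_elongation = 2.0,
                                max_aperture_contrast = 0.7) {
  structure(as.list(environment()), class = "segmentation_config")
}

# Iterative intermeans (Ridler-Calvard / isodata) threshold. Initialized at
# the sample mean it settles on the dominant background/foreground split
# even when the foreground contains several sub-populations (complex fill,
# guard cells, outline, aperture), which defeats a plain between-class
# variance criterion on these crops.
intermeans_threshold <- function(v, max_iter = 50L, tol = 1e-4) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  t <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v < t]
    hi <- v[v >= t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

# Moment ellipse of a set of pixel indices (1-based matrix indices);
# returns centre in 0-based continuous coordinates.
pixel_ellipse <- function(idx) {
  x <- idx[, 1] - 0.5
  y <- idx[, 2] - 0.5
  cx <- mean(x); cy <- mean(y)
  n <- length(x)
  mxx <- sum((x - cx)^2) / n + 1 / 12   # + pixel self-variance
  myy <- sum((y - cy)^2) / n + 1 / 12
  mxy <- sum((x - cx) * (y - cy)) / n
  e <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(cx = cx, cy = cy, major = 4 * sqrt(lam[1]), minor = 4 * sqrt(lam[2]),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

# Sub-pixel iso-intensity contour at `level` enclosing the point (px, py),
# extracted by marching squares on the pixel-centre grid. Returns the
# largest enclosing closed contour as an n x 2 polygon in 0-based
# coordinates, or NULL when no closed contour encloses the point.
subpixel_contour <- function(sm, level, px, py) {
  W <- nrow(sm); H <- ncol(sm)
  cl <- grDevices::contourLines(x = seq_len(W) - 0.5, y = seq_len(H) - 0.5,
                                z = sm, levels = level)
  if (!length(cl)) return(NULL)
  best <- NULL
  best_area <- 0
  for (cc in cl) {
    n <- length(cc$x)
    if (n < 4) next
    # open contours (clipped at the crop edge) cannot bound the complex
    closed <- abs(cc$x[1] - cc$x[n]) < 1e-9 && abs(cc$y[1] - cc$y[n]) < 1e-9
    if (!closed) next
    poly <- cbind(cc$x[-n], cc$y[-n])
    if (!point_in_polygon(px, py, poly)) next
    a <- abs(polygon_area(poly))
    if (a > best_area) { best <- poly; best_area <- a }
  }
  best
}

# Trace the outer contour of a binary mask (matrix of 0/1) and return a
# polygon through the pixel outer edges: the pixel-centre contour from
# EBImage::ocontour, offset outward by half a pixel so that the polygon
# area matches the pixel count.
mask_polygon <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask))
  if (!length(oc)) return(NULL)
  # largest contour
  areas <- vapply(oc, function(p) abs(polygon_area(p + 0.5)), numeric(1))
  p <- oc[[which.max(areas)]] + 0.5   # pixel centres, 0-based frame
  if (nrow(p) < 3L) {
    # degenerate 1-2 px component: make a tiny square around it
    cx <- mean(p[, 1]); cy <- mean(p[, 2])
    return(cbind(cx + c(-0.5, 0.5, 0.5, -0.5), cy + c(-0.5, -0.5, 0.5, 0.5)))
  }
  off <- polyclip::polyoffset(list(poly_to_pc(p)), 0.5,
                              jointype = "round", arctol = 0.05)
  if (!length(off)) return(p)
  areas2 <- vapply(off, function(q) abs(polygon_area(cbind(q$x, q$y))),
                   numeric(1))
  q <- off[[which.max(areas2)]]
  cbind(q$x, q$y)
}

# Threshold, close, fill and label, then return the most central
# sufficiently large dark component as a logical mask (or NULL).
central_dark_component <- function(sm, thr, crop, config) {
  fg <- sm < thr
  if (!any(fg)) return(NULL)
  fgi <- EBImage::Image(fg * 1)
  fgi <- EBImage::closing(fgi, EBImage::makeBrush(5, "disc"))
  fgi <- EBImage::fillHull(fgi)
  labm <- EBImage::imageData(EBImage::bwlabel(fgi))
  nobj <- max(labm)
  if (nobj < 1) return(NULL)
  cx0 <- nrow(crop) / 2; cy0 <- ncol(crop) / 2
  best <- 0L; bestd <- Inf
  for (k in seq_len(nobj)) {
    idx <- which(labm == k, arr.ind = TRUE)
    if (nrow(idx) < config$min_component_px) next
    d <- (mean(idx[, 1]) - cx0)^2 + (mean(idx[, 2]) - cy0)^2
    if (d < bestd) { bestd <- d; best <- k }
  }
  if (best == 0L) return(NULL)
  labm == best
}

measurement_failed <- function(stoma_id = NA_integer_, image_id = "image",
                               status = "failed") {
  data.frame(
    stoma_id = stoma_id, image_id = image_id,
    complex_area_um2 = NA_real_, complex_length_um = NA_real_,
    complex_width_um = NA_real_, aperture_length_um = NA_real_,
    aperture_width_um = NA_real_, aperture_area_um2 = NA_real_,
    openness = NA_real_, status = status
  )
}

#' Delineate the stomatal complex and aperture in a detection crop
#'
#' Smooths the crop, separates the dark stomatal complex from the lighter
#' epidermal background by an automatic threshold (iterative intermeans
#' within the crop), closes small gaps morphologically, fills holes and
#' keeps the most central connected component as the complex. The final
#' outline is then re-extracted at sub-pixel precision as the iso-intensity
#' contour at the midpoint between the local background level and the
#' component's boundary-band level (the 50% crossing of the local edge,
#' which is the unbiased edge location under a symmetric point spread).
#' Within the eroded complex interior a second, stricter dark threshold
#' isolates the aperture candidate, which is accepted only if it is large
#' enough (`min_aperture_fraction`), slit-like (`min_aperture_elongation`)
#' and dark enough (`max_aperture_contrast`). Ellipses are fitted by
#' moments of the outline polygons; coordinates are mapped back to the
#' full-image frame via the crop offset.
#'
#' @param crop Intensity matrix from [crop_for_measurement()].
#' @param profile A [magnification_profile()] (scale bookkeeping only; the
#'   segmentation itself operates in pixels).
#' @param config A [segmentation_config()].
#' @param offset Length-2 pixel offset of the crop in the full image.
#' @param stoma_id Identifier for the output mask.
#' @return A `stoma_mask`, or `NULL` when no foreground component is found
#'   (measurement failed; callers record a flagged trait row).
#' @export
segment_stoma <- function(crop, profile, config = segmentation_config(),
                          offset = c(0, 0), stoma_id = 1L) {
  stopifnot(is.matrix(crop))
  if (length(crop) < 16 || !any(is.finite(crop))) return(NULL)
  sm <- crop
  if (config$smooth_sigma > 0 && min(dim(crop)) > 4) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(crop),
                                   sigma = config$smooth_sigma))
  }
  thr <- intermeans_threshold(as.vector(sm))
  if (!is.finite(thr)) return(NULL)
  cmask <- central_dark_component(sm, thr, crop, config)
  if (is.null(cmask)) return(NULL)
  # edge level: midpoint between the local background and the darkness of
  # the component's boundary band, i.e. the 50% crossing of the actual edge
  dil <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(cmask * 1), EBImage::makeBrush(7, "disc"))) > 0
  ero <- EBImage::imageData(EBImage::erode(
    EBImage::Image(cmask * 1), EBImage::makeBrush(5, "disc"))) > 0
  bg_px <- sm[!dil]
  band <- cmask & !ero
  if (!any(band)) band <- cmask
  level <- thr
  if (length(bg_px) > 10) {
    cand <- (median(bg_px) + median(sm[band])) / 2
    if (is.finite(cand) && cand < median(bg_px)) level <- cand
  }
  refined <- central_dark_component(sm, level, crop, config)
  if (!is.null(refined)) cmask <- refined
  cidx <- which(cmask, arr.ind = TRUE)
  cen <- c(mean(cidx[, 1]) - 0.5, mean(cidx[, 2]) - 0.5)
  cpoly <- subpixel_contour(sm, level, cen[1], cen[2])
  if (is.null(cpoly)) cpoly <- mask_polygon(cmask)
  if (is.null(cpoly)) return(NULL)
  # plausibility guard: the crop is padded around one detection, so an
  # outline spanning almost the whole crop means the component merged with
  # a neighbouring stoma; flag as failed rather than report a fused area
  bb <- polygon_bbox(cpoly)
  if (bb["w"] > 0.92 * nrow(crop) || bb["h"] > 0.92 * ncol(crop)) {
    return(NULL)
  }
  cell <- polygon_ellipse(cpoly)
  c_area <- abs(polygon_area(cpoly))

  # aperture: stricter dark threshold, searched only in the eroded complex
  # interior so the dark outline ring cannot masquerade as a pore
  apoly <- NULL
  aell <- NULL
  core <- if (any(ero)) ero else cmask
  vals <- sm[core]
  thr2 <- (stats::quantile(vals, 0.02, names = FALSE) + median(vals)) / 2
  amask <- core & sm < thr2
  if (any(amask)) {
    alab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(amask * 1)))
    sizes <- tabulate(alab[alab > 0])
    k <- which.max(sizes)
    aidx <- which(alab == k, arr.ind = TRUE)
    acen <- c(mean(aidx[, 1]) - 0.5, mean(aidx[, 2]) - 0.5)
    ap <- subpixel_contour(sm, thr2, acen[1], acen[2])
    if (is.null(ap)) ap <- mask_polygon(alab == k)
    if (!is.null(ap)) {
      aellc <- polygon_ellipse(ap)
      elong <- aellc$major / max(aellc$minor, 1e-9)
      contrast <- mean(sm[alab == k]) / max(mean(vals), 1e-9)
      if (abs(polygon_area(ap)) >= config$min_aperture_fraction * c_area &&
          nrow(aidx) >= 4 &&
          elong >= config$min_aperture_elongation &&
          contrast <= config$max_aperture_contrast) {
        apoly <- ap
        aell <- aellc
      }
    }
  }

  shift <- function(p, e) {
    if (!is.null(p)) { p[, 1] <- p[, 1] + offset[1]; p[, 2] <- p[, 2] + offset[2] }
    p
  }
  if (!is.null(aell)) { aell$cx <- aell$cx + offset[1]; aell$cy <- aell$cy + offset[2] }
  cell$cx <- cell$cx + offset[1]; cell$cy <- cell$cy + offset[2]
  stoma_mask(shift(cpoly), if (is.null(apoly)) NULL else shift(apoly),
             stoma_id = stoma_id, complex_ellipse = cell,
             aperture_ellipse = aell)
}

#' Measure physical-unit traits of a stoma mask
#'
#' Complex area is the shoelace polygon area scaled by
#' `(1000 / px_per_mm)^2`; complex length and width are the full major and
#' minor axes of the moment-fitted ellipse scaled to micrometres; aperture
#' traits analogously; openness is aperture width / complex width. All
#' aperture fields are `NA` for a closed stoma. Deterministic and invariant
#' to polygon vertex order.
#'
#' @param mask A `stoma_mask`, or `NULL` (failed segmentation).
#' @param profile A [magnification_profile()].
#' @param image_id Image label for the output row.
#' @return One-row data frame: `stoma_id, image_id, complex_area_um2,
#'   complex_length_um, complex_width_um, aperture_length_um,
#'   aperture_width_um, aperture_area_um2, openness, status`.
#' @export
measure_stoma <- function(mask, profile, image_id = "image") {
  check_profile(profile)
  if (is.null(mask)) return(measurement_failed(image_id = image_id))
  stopifnot(inherits(mask, "stoma_mask"))
  umpx <- 1000 / profile$px_per_mm
  a_px2 <- abs(polygon_area(mask$complex_polygon))
  if (a_px2 <= 0) {
    return(measurement_failed(mask$stoma_id, image_id, "degenerate"))
  }
  ce <- mask$complex_ellipse
  open <- !is.null(mask$aperture_polygon)
  ap_len <- ap_wid <- ap_area <- openness <- NA_real_
  if (open) {
    ae <- mask$aperture_ellipse
    ap_len <- ae$major * umpx
    ap_wid <- ae$minor * umpx
    ap_area <- abs(polygon_area(mask$aperture_polygon)) * umpx^2
    openness <- clamp(ae$minor / max(ce$minor, 1e-9), 0, 1)
  }
  data.frame(
    stoma_id = mask$stoma_id, image_id = image_id,
    complex_area_um2 = a_px2 * umpx^2,
    complex_length_um = ce$major * umpx,
    complex_width_um = ce$minor * umpx,
    aperture_length_um = ap_len,
    aperture_width_um = ap_wid,
    aperture_area_um2 = ap_area,
    openness = openness,
    status = "ok"
  )
}

#' Aggregate per-stoma traits into a per-image summary
#'
#' The stomatal count (and hence density) may exceed the number of measured
#' trait rows: detections that failed measurement or touch the image border
#' are counted but excluded from size and aperture statistics.
#'
#' @param traits Data frame of trait rows from [measure_stoma()] (possibly
#'   with `status != "ok"` rows).
#' @param count Stomata count for the image (default: number of trait rows).
#' @param profile A [magnification_profile()].
#' @param image_id Image label.
#' @param area_mm2 Optional imaged-area override for the density.
#' @return One-row data frame: `image_id, profile, stomata_count,
#'   density_mm2, mean_complex_area_um2, median_complex_area_um2,
#'   mean_aperture_length_um, fraction_open, n_measured`.
#' @export
summarize_image <- function(traits, count = NULL, profile,
                            image_id = "image", area_mm2 = NULL) {
  check_profile(profile)
  if (is.null(count)) count <- if (is.null(traits)) 0L else nrow(traits)
  ok <- if (!is.null(traits) && nrow(traits)) {
    traits[traits$status == "ok", , drop = FALSE]
  } else {
    traits
  }
  n_ok <- if (is.null(ok)) 0L else nrow(ok)
  open <- if (n_ok) ok[!is.na(ok$aperture_length_um), , drop = FALSE] else NULL
  data.frame(
    image_id = image_id,
    profile = profile$name,
    stomata_count = count,
    density_mm2 = density_per_mm2(count, profile, area_mm2),
    mean_complex_area_um2 = if (n_ok) mean(ok$complex_area_um2) else NA_real_,
    median_complex_area_um2 = if (n_ok) median(ok$complex_area_um2) else NA_real_,
    mean_aperture_length_um = if (!is.null(open) && nrow(open)) {
      mean(open$aperture_length_um)
    } else {
      NA_real_
    },
    fraction_open = if (n_ok) {
      (if (is.null(open)) 0 else nrow(open)) / n_ok
    } else {
      NA_real_
    },
    n_measured = n_ok
  )
}
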