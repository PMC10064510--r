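# Stomatal detection: a classical template-matching backend (band-pass
# normalized cross-correlation against synthetic stoma templates) and
# adapters for externally produced detection files in the normalized
# bounding-box text dialect.
#
# Boxes use 0-based pixel coordinates, origin top-left, half-open
# [x, x+w) x [y, y+h).

#' Construct a detection-box data frame
#'
#' @param x,y,w,h Box coordinates in pixels (0-based, half-open).
#' @param confidence Scores in \[0, 1\].
#' @param image_id Image label.
#' @param label Category label (default `"stoma"`).
#' @return Data frame with columns `image_id, x, y, w, h, confidence, label`.
#' @export
detection_boxes <- function(x, y, w, h, confidence = 1,
                            image_id = "image", label = "stoma") {
  n <- length(x)
  y <- rep_len(y, n)
  w <- rep_len(w, n)
  h <- rep_len(h, n)
  confidence <- rep_len(confidence, n)
  if (n && (any(w <= 0) || any(h <= 0))) {
    stop_stomapipe("detection boxes must have w > 0 and h > 0",
                   "stomapipe_box_error")
  }
  if (n && (any(confidence < 0) || any(confidence > 1))) {
    stop_stomapipe("confidence must lie in [0, 1]", "stomapipe_box_error")
  }
  data.frame(image_id = rep_len(image_id, n), x = x, y = y, w = w, h = h,
             confidence = confidence, label = rep_len(label, n))
}

empty_boxes <- function(image_id = character(0)) {
  data.frame(image_id = character(0), x = numeric(0), y = numeric(0),
             w = numeric(0), h = numeric(0), confidence = numeric(0),
             label = character(0))
}

#' Configuration of the classical template-matching detector
#'
#' The classical backend scores image locations by normalized
#' cross-correlation against a small bank of synthetic stoma templates (one
#' per orientation) rendered at the expected complex size, thresholds the
#' score map, and prunes overlapping candidates by non-maximum suppression.
#' It is a deterministic, CPU-scale stand-in for a trained deep detector;
#' adapters ([read_detection_file()]) consume outputs of external detectors.
#'
#' @param expected_length_um Scale prior: expected complex length.
#' @param expected_width_um Expected complex width (default 0.55 x length).
#' @param orientations Template angles in degrees. Default: `0` for rowed
#'   archetypes whose stomata align with the leaf axis; use
#'   `seq(0, 150, by = 30)` for scattered patterns.
#' @param match_threshold Score cut in \[0, 1\].
#' @param nms_iou Non-maximum suppression IoU threshold in \[0, 1).
#' @param dumbbell Render dumbbell-silhouette templates (graminoid) rather
#'   than elliptical ones.
#' @param template_openness Aperture openness used in the templates.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(expected_length_um,
                            expected_width_um = 0.55 * expected_length_um,
                            orientations = 0,
                            match_threshold = 0.5,
                            nms_iou = 0.3,
                            dumbbell = FALSE,
                            template_openness = 0.3) {
  if (match_threshold < 0 || match_threshold > 1) {
    stop_stomapipe("match_threshold must lie in [0, 1]",
                   "stomapipe_config_error")
  }
  if (nms_iou < 0 || nms_iou >= 1) {
    stop_stomapipe("nms_iou must lie in [0, 1)", "stomapipe_config_error")
  }
  stopifnot(expected_length_um > 0, expected_width_um > 0)
  structure(
    list(expected_length_um = expected_length_um,
         expected_width_um = expected_width_um,
         orientations = orientations,
         match_threshold = match_threshold,
         nms_iou = nms_iou,
         dumbbell = isTRUE(dumbbell),
         template_openness = template_openness),
    class = "detector_config"
  )
}

#' Detector configuration matched to a species archetype
#'
#' @param archetype A [species_archetype()] or built-in archetype name.
#' @param ... Overrides passed to [detector_config()].
#' @return A `detector_config`.
#' @export
detector_config_for <- function(archetype, ...) {
  if (is.character(archetype)) archetype <- get_archetype(archetype)
  rows <- archetype$arrangement == "rows"
  args <- list(
    expected_length_um = archetype$complex_length_um,
    expected_width_um = archetype$complex_width_um,
    orientations = if (rows) 0 else seq(0, 150, by = 30),
    dumbbell = rows,
    template_openness = archetype$aperture_openness
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(detector_config, args)
}

# Render a single noise-free stoma template at the given orientation.
render_stoma_template <- function(profile, length_um, width_um, theta_deg,
                                  dumbbell, openness) {
  umpx <- 1000 / profile$px_per_mm
  a <- (length_um / 2) / umpx
  b <- (width_um / 2) / umpx
  theta <- theta_deg * pi / 180
  bw <- 2 * sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  bh <- 2 * sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  m <- 2  # margin px
  W <- 2 * ceiling(bw / 2 + m) + 1   # odd dims for FFT filtering
  H <- 2 * ceiling(bh / 2 + m) + 1
  img <- matrix(0.78, W, H)
  st <- list(cx = W / 2, cy = H / 2, theta = theta, a_px = a, b_px = b,
             ap_a_px = if (openness > 0) 0.5 * a else NULL,
             ap_b_px = if (openness > 0) openness * b else NULL)
  img <- draw_stoma(img, st, dumbbell)
  sigma <- profile$resolving_power_um * profile$px_per_mm / 1000 / 2
  if (sigma > 0.01) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  }
  list(template = img, box_w = bw, box_h = bh)
}

# Normalized cross-correlation of an image against a zero-mean template,
# computed with FFT filtering and local-variance normalization.
ncc_map <- function(img, template) {
  t0 <- template - mean(template)
  denom_t <- sqrt(sum(t0^2))
  if (denom_t < 1e-12) return(matrix(0, nrow(img), ncol(img)))
  n_t <- length(t0)
  flip <- t0[nrow(t0):1, ncol(t0):1, drop = FALSE]
  num <- as.matrix(EBImage::filter2(EBImage::Image(img), flip,
                                    boundary = "replicate"))
  box <- matrix(1 / n_t, nrow(t0), ncol(t0))
  mu <- as.matrix(EBImage::filter2(EBImage::Image(img), box,
                                   boundary = "replicate"))
  musq <- as.matrix(EBImage::filter2(EBImage::Image(img^2), box,
                                     boundary = "replicate"))
  lvar <- pmax(musq - mu^2, 0)
  lnorm <- sqrt(lvar * n_t)
  score <- num / (denom_t * pmax(lnorm, 1e-6))
  score[lnorm < 1e-4] <- 0
  score
}

#' Detect stomata with the classical template-matching backend
#'
#' Scores every location of a grayscale image by normalized
#' cross-correlation against synthetic stoma templates (one per configured
#' orientation), keeps local maxima above `match_threshold`, forms boxes at
#' the matching template's extent and applies non-maximum suppression.
#' Confidences are the match scores clipped to \[0, 1\]; output is sorted by
#' descending confidence. Deterministic: identical inputs give identical
#' output.
#'
#' @param image Numeric intensity matrix (width x height, values in \[0,1\]).
#' @param profile A [magnification_profile()].
#' @param config A [detector_config()].
#' @param image_id Label for the output rows.
#' @return Detection-box data frame (see [detection_boxes()]).
#' @export
detect_classical <- function(image, profile, config,
                             image_id = "image") {
  check_profile(profile)
  stopifnot(inherits(config, "detector_config"), is.matrix(image))
  len_px <- um_to_px(config$expected_length_um, profile)
  if (len_px < 4) {
    stop_stomapipe(sprintf(
      "expected stomatal length %.0f um maps to %.1f px at profile '%s' (< 4 px): below optical resolvability; use a higher-magnification profile",
      config$expected_length_um, len_px, profile$name),
      "stomapipe_resolution_error")
  }
  W <- nrow(image); H <- ncol(image)
  score <- matrix(-Inf, W, H)
  ang <- matrix(1L, W, H)
  tmpls <- vector("list", length(config$orientations))
  for (i in seq_along(config$orientations)) {
    tm <- render_stoma_template(profile, config$expected_length_um,
                                config$expected_width_um,
                                config$orientations[i],
                                config$dumbbell, config$template_openness)
    tmpls[[i]] <- tm
    s <- ncc_map(image, tm$template)
    upd <- s > score
    score[upd] <- s[upd]
    ang[upd] <- i
  }
  # local maxima within a neighbourhood about half a stoma across
  r <- max(3L, as.integer(round(len_px / 3)))
  if (r %% 2L == 0L) r <- r + 1L
  dil <- as.matrix(EBImage::dilate(EBImage::Image(pmax(score, 0)),
                                   EBImage::makeBrush(r, "box")))
  cand <- which(score >= config$match_threshold & pmax(score, 0) >= dil,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty_boxes())
  cx <- cand[, 1] - 0.5
  cy <- cand[, 2] - 0.5
  ai <- ang[cand]
  bw <- vapply(tmpls, `[[`, numeric(1), "box_w")[ai]
  bh <- vapply(tmpls, `[[`, numeric(1), "box_h")[ai]
  conf <- clamp(score[cand], 0, 1)
  boxes <- detection_boxes(x = cx - bw / 2, y = cy - bh / 2, w = bw, h = bh,
                           confidence = conf, image_id = image_id)
  boxes <- non_max_suppression(boxes, config$nms_iou)
  boxes[order(-boxes$confidence, boxes$x, boxes$y), , drop = FALSE]
}

#' Non-maximum suppression of detection boxes
#'
#' Greedily keeps the highest-confidence box and removes boxes whose IoU
#' with any kept box exceeds `nms_iou`. Confidence ties are broken by larger
#' box area, then input order, so the result is stable under permutation of
#' equally scored inputs.
#'
#' @param boxes Detection-box data frame.
#' @param nms_iou Suppression threshold in \[0, 1).
#' @return Subset of `boxes`, ordered by descending confidence.
#' @export
non_max_suppression <- function(boxes, nms_iou = 0.3) {
  if (nrow(boxes) == 0L) return(boxes)
  area <- boxes$w * boxes$h
  ord <- order(-boxes$confidence, -area, seq_len(nrow(boxes)))
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (box_iou(as.numeric(boxes[i, c("x", "y", "w", "h")]),
                  as.numeric(boxes[j, c("x", "y", "w", "h")])) > nms_iou) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  boxes[keep, , drop = FALSE]
}

#' Read a normalized-bounding-box detection file
#'
#' Parses the one-detection-per-line text dialect
#' `class cx cy w h [confidence]`, with centre coordinates and sizes
#' normalized to \[0, 1\] relative to image width and height, and converts to
#' pixel half-open boxes (`x = (cx - w/2) * W`, ...). A missing confidence
#' defaults to 1.0. Malformed or out-of-range lines raise a parse error
#' citing the line number; an empty file yields an empty box list.
#'
#' @param path Detection file path.
#' @param image_size_px Integer `c(width, height)` of the image.
#' @param image_id Label for the output rows.
#' @return Detection-box data frame.
#' @export
read_detection_file <- function(path, image_size_px, image_id = NULL) {
  if (!file.exists(path)) {
    stop_stomapipe(sprintf("detection file not found: %s", path),
                   "stomapipe_io_error")
  }
  if (is.null(image_id)) image_id <- file_path_sans_ext(basename(path))
  W <- image_size_px[1]; H <- image_size_px[2]
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_boxes())
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (!(length(f) %in% c(5L, 6L))) {
      stop_stomapipe(sprintf(
        "%s:%d: expected 'class cx cy w h [conf]' (5 or 6 fields), got %d",
        path, k, length(f)), "stomapipe_parse_error")
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) {
      stop_stomapipe(sprintf("%s:%d: non-numeric field", path, k),
                     "stomapipe_parse_error")
    }
    cx <- v[2]; cy <- v[3]; w <- v[4]; h <- v[5]
    conf <- if (length(v) == 6L) v[6] else 1.0
    if (any(c(cx, cy, w, h) < 0) || any(c(cx, cy, w, h) > 1) ||
        conf < 0 || conf > 1 || w == 0 || h == 0) {
      stop_stomapipe(sprintf(
        "%s:%d: normalized coordinates or confidence out of range", path, k),
        "stomapipe_parse_error")
    }
    out[[k]] <- data.frame(image_id = image_id,
                           x = (cx - w / 2) * W, y = (cy - h / 2) * H,
                           w = w * W, h = h * H,
                           confidence = conf, label = "stoma")
  }
  do.call(rbind, out)
}

#' Write detection boxes in the normalized-bounding-box text dialect
#'
#' Inverse of [read_detection_file()]; class index is written as 0.
#'
#' @param boxes Detection-box data frame.
#' @param path Output file path.
#' @param image_size_px Integer `c(width, height)` of the image.
#' @return `path`, invisibly.
#' @export
write_detection_file <- function(boxes, path, image_size_px) {
  W <- image_size_px[1]; H <- image_size_px[2]
  lines <- character(nrow(boxes))
  for (k in seq_len(nrow(boxes))) {
    lines[k] <- sprintf("0 %.10f %.10f %.10f %.10f %.6f",
                        (boxes$x[k] + boxes$w[k] / 2) / W,
                        (boxes$y[k] + boxes$h[k] / 2) / H,
                        boxes$w[k] / W, boxes$h[k] / H,
                        boxes$confidence[k])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Crop an image around a detection box for measurement
#'
#' Expands the box by `pad_fraction` of its size per side, clips to image
#' bounds, and returns the crop together with the pixel offset mapping crop
#' coordinates back to full-image coordinates.
#'
#' @param image Numeric intensity matrix.
#' @param box One-row detection-box data frame (or vector `x, y, w, h`).
#' @param pad_fraction Padding per side as a fraction of box size.
#' @return List with `crop` (matrix) and `offset` (`c(x0, y0)`, 0-based):
#'   crop pixel (i, j) covers image pixel (x0 + i - 1, y0 + j - 1).
#' @export
crop_for_measurement <- function(image, box, pad_fraction = 0.25) {
  if (is.data.frame(box)) box <- as.numeric(box[1, c("x", "y", "w", "h")])
  W <- nrow(image); H <- ncol(image)
  x0 <- clamp(floor(box[1] - pad_fraction * box[3]), 0, W - 1)
  y0 <- clamp(floor(box[2] - pad_fraction * box[4]), 0, H - 1)
  x1 <- clamp(ceiling(box[1] + box[3] * (1 + pad_fraction)), x0 + 1, W)
  y1 <- clamp(ceiling(box[2] + box[4] * (1 + pad_fraction)), y0 + 1, H)
  list(crop = image[(x0 + 1):x1, (y0 + 1):y1, drop = FALSE],
       offset = c(x0 = x0, y0 = y0))
}
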