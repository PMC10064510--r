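# Batch orchestration: run the detect -> crop -> segment -> measure ->
# summarize chain over a directory of images, and generate synthetic
# fixture sets. All tabular outputs are CSV; every run writes a manifest
# that suffices to reproduce it.

trait_csv_columns <- c("stoma_id", "image_id", "x", "y", "w", "h",
                       "complex_area_um2", "complex_length_um",
                       "complex_width_um", "aperture_length_um",
                       "aperture_width_um", "aperture_area_um2",
                       "openness", "status")

#' Run configuration for the phenotyping pipeline
#'
#' @param images_dir Directory of input images (PNG/TIFF/JPEG).
#' @param out_dir Output directory (created if missing).
#' @param profile Profile name or [magnification_profile()].
#' @param detector `"classical"` (built-in template matcher) or
#'   `"external-files"` (read per-image normalized-box text files).
#' @param detections_dir Directory of detection text files (same stem as the
#'   image), required for the external backend.
#' @param archetype Archetype (or name) used to configure the classical
#'   detector and segmentation scale.
#' @param match_threshold,nms_iou Classical-detector thresholds.
#' @param iou_eval IoU threshold used by evaluation commands.
#' @param pad_fraction Crop padding per side for measurement.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds simulation commands).
#' @return Object of class `run_config`.
#' @export
run_config <- function(images_dir, out_dir,
                       profile = "400x",
                       detector = c("classical", "external-files"),
                       detections_dir = NULL,
                       archetype = "dicot",
                       match_threshold = 0.5,
                       nms_iou = 0.3,
                       iou_eval = 0.5,
                       pad_fraction = 0.35,
                       seed = 1L) {
  detector <- match.arg(detector)
  if (is.character(profile)) profile <- get_profile(profile)
  check_profile(profile)
  if (is.character(archetype)) archetype <- get_archetype(archetype)
  if (detector == "external-files" &&
      (is.null(detections_dir) || !dir.exists(detections_dir))) {
    stop_stomapipe("external-files detector needs an existing detections_dir",
                   "stomapipe_config_error")
  }
  structure(
    list(images_dir = images_dir, out_dir = out_dir, profile = profile,
         detector = detector, detections_dir = detections_dir,
         archetype = archetype, match_threshold = match_threshold,
         nms_iou = nms_iou, iou_eval = iou_eval,
         pad_fraction = pad_fraction, seed = as.integer(seed)),
    class = "run_config"
  )
}

list_images <- function(dir) {
  sort(list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                  ignore.case = TRUE, full.names = TRUE))
}

box_touches_border <- function(box, W, H, tol = 0.5) {
  box["x"] <= tol || box["y"] <= tol ||
    box["x"] + box["w"] >= W - tol || box["y"] + box["h"] >= H - tol
}

#' Measure all detected stomata of one image
#'
#' Crops each detection, segments complex and aperture and measures traits.
#' Detections touching the image border are counted but flagged
#' `status = "border"` and excluded from measurement (truncated organs bias
#' size statistics; counting them preserves density).
#'
#' @param image Intensity matrix.
#' @param boxes Detection-box data frame for the image.
#' @param profile A [magnification_profile()].
#' @param image_id Image label.
#' @param pad_fraction Crop padding per side.
#' @param seg_config A [segmentation_config()].
#' @return Data frame of trait rows (one per detection) with the box
#'   geometry columns prepended.
#' @export
measure_image <- function(image, boxes, profile, image_id = "image",
                          pad_fraction = 0.35,
                          seg_config = segmentation_config()) {
  W <- nrow(image); H <- ncol(image)
  rows <- lapply(seq_len(nrow(boxes)), function(k) {
    b <- as.numeric(boxes[k, c("x", "y", "w", "h")])
    names(b) <- c("x", "y", "w", "h")
    if (box_touches_border(b, W, H)) {
      tr <- measurement_failed(k, image_id, "border")
    } else {
      cr <- crop_for_measurement(image, b, pad_fraction)
      mask <- segment_stoma(cr$crop, profile, seg_config,
                            offset = cr$offset, stoma_id = k)
      tr <- measure_stoma(mask, profile, image_id)
      tr$stoma_id <- k
    }
    cbind(tr[, c("stoma_id", "image_id")],
          data.frame(x = b["x"], y = b["y"], w = b["w"], h = b["h"],
                     row.names = NULL),
          tr[, setdiff(names(tr), c("stoma_id", "image_id"))])
  })
  if (!length(rows)) {
    out <- measurement_failed(integer(0))[0, ]
    out$x <- numeric(0); out$y <- numeric(0)
    out$w <- numeric(0); out$h <- numeric(0)
    return(out[, trait_csv_columns])
  }
  do.call(rbind, rows)[, trait_csv_columns]
}

#' Run the full phenotyping pipeline over an image directory
#'
#' For each image: detect stomata (classical backend or external detection
#' files), crop, segment, measure and summarize. Writes `stoma_traits.csv`
#' (per-stoma), `image_summaries.csv` (per-image), and `manifest.json`
#' (config, package version, per-image status). A failure on one image is
#' recorded as a status row and does not abort the run.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `traits`, `summaries` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list_images(config$images_dir)
  prof <- config$profile
  det_cfg <- detector_config_for(config$archetype,
                                 match_threshold = config$match_threshold,
                                 nms_iou = config$nms_iou)
  all_traits <- list()
  all_summ <- list()
  status <- list()
  for (f in files) {
    id <- file_path_sans_ext(basename(f))
    res <- tryCatch({
      img <- read_image_matrix(f)
      suppressWarnings(check_image_extent(nrow(img), ncol(img), prof))
      boxes <- if (config$detector == "classical") {
        detect_classical(img, prof, det_cfg, image_id = id)
      } else {
        dpath <- file.path(config$detections_dir, paste0(id, ".txt"))
        read_detection_file(dpath, c(nrow(img), ncol(img)), image_id = id)
      }
      traits <- measure_image(img, boxes, prof, image_id = id,
                              pad_fraction = config$pad_fraction)
      summ <- summarize_image(traits, count = nrow(boxes), prof,
                              image_id = id)
      list(traits = traits, summary = summ, status = "ok")
    }, error = function(e) {
      list(traits = NULL, summary = NULL,
           status = paste0("error: ", conditionMessage(e)))
    })
    status[[id]] <- res$status
    if (!is.null(res$traits)) all_traits[[id]] <- res$traits
    if (!is.null(res$summary)) all_summ[[id]] <- res$summary
    message(sprintf("[stomapipe] %s: %s", id, res$status))
  }
  traits <- if (length(all_traits)) do.call(rbind, all_traits) else
    measure_image(matrix(0.5, 8, 8), empty_boxes(), prof)[0, ]
  summaries <- if (length(all_summ)) do.call(rbind, all_summ) else NULL
  rownames(traits) <- NULL
  write.csv(traits, file.path(config$out_dir, "stoma_traits.csv"),
            row.names = FALSE)
  if (!is.null(summaries)) {
    rownames(summaries) <- NULL
    write.csv(summaries, file.path(config$out_dir, "image_summaries.csv"),
              row.names = FALSE)
  }
  manifest <- list(
    tool = "stomapipe",
    version = as.character(utils::packageVersion("stomapipe")),
    profile = prof[c("name", "px_per_mm", "fov_width_mm", "fov_height_mm",
                     "resolving_power_um")],
    detector = config$detector,
    archetype = config$archetype$name,
    match_threshold = config$match_threshold,
    nms_iou = config$nms_iou,
    pad_fraction = config$pad_fraction,
    seed = config$seed,
    images = status
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(traits = traits, summaries = summaries,
                 manifest = manifest))
}

#' Generate a synthetic fixture set on disk
#'
#' Renders `n_images` scenes deterministically (scene i uses seed
#' `seed + i - 1`), writing for each a PNG image and a COCO-style
#' ground-truth annotation file, plus a pooled ground-truth trait CSV, a
#' per-image ground-truth summary CSV and a manifest.
#'
#' @param out_dir Output directory.
#' @param n_images Number of scenes.
#' @param archetype Archetype or built-in name.
#' @param profile Profile or built-in name.
#' @param seed Base seed.
#' @param ... Further arguments to [scene_spec()].
#' @return Invisibly, a list of the rendered scenes.
#' @export
simulate_scenes <- function(out_dir, n_images = 5L,
                            archetype = "dicot", profile = "400x",
                            seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(archetype)) archetype <- get_archetype(archetype)
  if (is.character(profile)) profile <- get_profile(profile)
  scenes <- vector("list", n_images)
  traits <- list()
  summaries <- list()
  for (i in seq_len(n_images)) {
    spec <- scene_spec(archetype = archetype, profile = profile,
                       seed = seed + i - 1L, ...)
    sc <- render_scene(spec)
    id <- sprintf("scene_%03d", i)
    write_scene_image(sc, file.path(out_dir, paste0(id, ".png")))
    write_instance_annotations(sc$truth,
                               file.path(out_dir, paste0(id, ".json")),
                               image_id = i,
                               file_name = paste0(id, ".png"),
                               image_size_px = spec$image_size_px)
    tr <- sc$truth$traits
    if (nrow(tr)) tr <- cbind(image_id = id, tr)
    traits[[i]] <- tr
    summaries[[i]] <- data.frame(
      image_id = id, profile = profile$name,
      stomata_count = sc$truth$count,
      density_mm2 = sc$truth$density_mm2,
      mean_complex_area_um2 = if (nrow(tr)) mean(tr$complex_area_um2)
                              else NA_real_
    )
    scenes[[i]] <- sc
  }
  tr_all <- do.call(rbind, traits[vapply(traits, NROW, 1L) > 0])
  write.csv(tr_all, file.path(out_dir, "gt_traits.csv"), row.names = FALSE)
  write.csv(do.call(rbind, summaries),
            file.path(out_dir, "gt_summaries.csv"), row.names = FALSE)
  manifest <- list(
    tool = "stomapipe",
    version = as.character(utils::packageVersion("stomapipe")),
    command = "simulate",
    n_images = n_images, archetype = archetype$name,
    profile = profile$name, seed = seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(scenes)
}
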