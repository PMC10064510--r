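# COCO-style instance-annotation reader/writer for stomatal complexes and
# apertures. Two categories: "stomatal_complex" (id 1) and "aperture"
# (id 2); boxes in x,y,w,h pixel convention; polygons as flat coordinate
# lists [x1, y1, x2, y2, ...].

poly_flat <- function(poly) as.numeric(t(poly))

flat_poly <- function(v) matrix(v, ncol = 2, byrow = TRUE)

#' Convert scene ground truth to stoma masks
#'
#' @param truth The `truth` element of a rendered scene ([render_scene()]).
#' @return List of [stoma_mask()] objects.
#' @export
truth_to_masks <- function(truth) {
  lapply(seq_along(truth$complex_polygons), function(k) {
    stoma_mask(truth$complex_polygons[[k]], truth$aperture_polygons[[k]],
               stoma_id = k)
  })
}

#' Write stoma masks as a COCO-style instance annotation file
#'
#' @param masks List of [stoma_mask()] objects (or a scene `truth` list,
#'   converted via [truth_to_masks()]).
#' @param path Output JSON path.
#' @param image_id Numeric image id recorded in the file.
#' @param file_name Image file name recorded in the file.
#' @param image_size_px Integer `c(width, height)`.
#' @return `path`, invisibly.
#' @export
write_instance_annotations <- function(masks, path, image_id = 1L,
                                       file_name = "image.png",
                                       image_size_px = c(NA, NA)) {
  if (!is.null(masks$complex_polygons)) masks <- truth_to_masks(masks)
  anns <- list()
  aid <- 0L
  for (m in masks) {
    aid <- aid + 1L
    bb <- polygon_bbox(m$complex_polygon)
    anns[[length(anns) + 1L]] <- list(
      id = aid, image_id = image_id, category_id = 1L,
      bbox = as.numeric(bb),
      segmentation = list(poly_flat(m$complex_polygon)),
      area = abs(polygon_area(m$complex_polygon))
    )
    if (!is.null(m$aperture_polygon)) {
      aid <- aid + 1L
      bba <- polygon_bbox(m$aperture_polygon)
      anns[[length(anns) + 1L]] <- list(
        id = aid, image_id = image_id, category_id = 2L,
        bbox = as.numeric(bba),
        segmentation = list(poly_flat(m$aperture_polygon)),
        area = abs(polygon_area(m$aperture_polygon))
      )
    }
  }
  doc <- list(
    images = list(list(id = image_id, file_name = file_name,
                       width = image_size_px[1], height = image_size_px[2])),
    categories = list(
      list(id = 1L, name = "stomatal_complex"),
      list(id = 2L, name = "aperture")
    ),
    annotations = anns
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a COCO-style instance annotation file into stoma masks
#'
#' Expects categories `"stomatal_complex"` and `"aperture"`. Each aperture
#' polygon is attached to the complex polygon containing its centroid;
#' apertures whose centroid lies in no complex are rejected with their
#' annotation ids.
#'
#' @param path Annotation JSON path.
#' @return List of [stoma_mask()] objects (stoma ids are the complex
#'   annotation ids).
#' @export
read_instance_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_stomapipe(sprintf("annotation file not found: %s", path),
                   "stomapipe_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$categories)) {
    stop_stomapipe(sprintf("%s: missing category map", path),
                   "stomapipe_parse_error")
  }
  cats <- setNames(
    vapply(doc$categories, function(c) as.integer(c$id), integer(1)),
    vapply(doc$categories, function(c) as.character(c$name), character(1))
  )
  if (!all(c("stomatal_complex", "aperture") %in% names(cats))) {
    stop_stomapipe(sprintf(
      "%s: category map must contain 'stomatal_complex' and 'aperture'",
      path), "stomapipe_parse_error")
  }
  cid <- cats[["stomatal_complex"]]
  aid <- cats[["aperture"]]
  complexes <- list()
  apertures <- list()
  for (a in doc$annotations) {
    seg <- a$segmentation[[1]]
    v <- as.numeric(unlist(seg))
    if (length(v) < 6 || length(v) %% 2 != 0) {
      stop_stomapipe(sprintf(
        "%s: annotation %s has an invalid polygon (< 3 vertices)",
        path, a$id), "stomapipe_parse_error")
    }
    poly <- flat_poly(v)
    if (a$category_id == cid) {
      complexes[[length(complexes) + 1L]] <- list(id = a$id, poly = poly)
    } else if (a$category_id == aid) {
      apertures[[length(apertures) + 1L]] <- list(id = a$id, poly = poly)
    }
  }
  masks <- lapply(complexes, function(cc) {
    stoma_mask(cc$poly, NULL, stoma_id = cc$id)
  })
  orphans <- integer(0)
  for (ap in apertures) {
    cen <- polygon_moments(ap$poly)
    placed <- FALSE
    for (k in seq_along(complexes)) {
      if (point_in_polygon(cen$cx, cen$cy, complexes[[k]]$poly)) {
        masks[[k]] <- stoma_mask(complexes[[k]]$poly, ap$poly,
                                 stoma_id = complexes[[k]]$id)
        placed <- TRUE
        break
      }
    }
    if (!placed) orphans <- c(orphans, ap$id)
  }
  if (length(orphans)) {
    stop_stomapipe(sprintf(
      "%s: orphan aperture annotation(s) with centroid outside all complexes: %s",
      path, paste(orphans, collapse = ", ")), "stomapipe_orphan_error")
  }
  masks
}
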