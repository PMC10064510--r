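#' Recipe for one synthetic leaf-epidermis scene
#'
#' A scene spec fully determines a synthetic brightfield micrograph and its
#' ground truth: the optical profile, the image extent, the intended stomatal
#' density, the species archetype and the degradation model (optical blur,
#' sensor noise, illumination gradient, air-bubble imprint artifacts). Scenes
#' are deterministic: the same spec (including `seed`) renders bit-identical
#' images and ground truth.
#'
#' @param archetype A [species_archetype()] (or the name of a built-in one).
#' @param profile A [magnification_profile()] or built-in profile name.
#' @param target_density_mm2 Intended stomatal density (stomata per mm^2,
#'   >= 0). Defaults per archetype: 50 (graminoid_large), 250
#'   (graminoid_small), 120 (dicot) - model defaults within the range
#'   reported for the respective crop species.
#' @param image_size_px Integer `c(width, height)`; defaults to the
#'   profile's full field of view.
#' @param blur_from_optics Apply a Gaussian point-spread with
#'   `sd_px = resolving_power_um * px_per_mm / 1000 / 2` (half the resolving
#'   power expressed in pixels; resolving power is taken as the FWHM-scale
#'   size of the point spread and halving it is a conservative stand-in for
#'   an unknown exact PSF).
#' @param noise_sd Additive Gaussian sensor noise sd, on the \[0, 1\]
#'   intensity scale.
#' @param illumination_gradient Amplitude in \[0, 1\] of a multiplicative
#'   left-to-right illumination ramp (`1 - a/2` to `1 + a/2`).
#' @param bubble_count Number of bright air-bubble artifacts (>= 0).
#' @param bubble_radius_um Length-2 range of bubble radii, micrometres.
#' @param border_policy `"cull"` (default): stomata whose complex would cross
#'   the image border are dropped from both image and ground truth;
#'   `"keep-clipped"`: they are rendered and kept with polygons clipped to
#'   the image bounds.
#' @param inset_margin Keep complex centres inset from the border so that no
#'   complex crosses it (default). Set `FALSE` to exercise the border policy.
#' @param seed Integer random seed.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(archetype = archetype_dicot(),
                       profile = get_profile("400x"),
                       target_density_mm2 = NULL,
                       image_size_px = NULL,
                       blur_from_optics = TRUE,
                       noise_sd = 0.02,
                       illumination_gradient = 0.15,
                       bubble_count = 1L,
                       bubble_radius_um = c(15, 40),
                       border_policy = c("cull", "keep-clipped"),
                       inset_margin = TRUE,
                       seed = 1L) {
  if (is.character(archetype)) archetype <- get_archetype(archetype)
  if (is.character(profile)) profile <- get_profile(profile)
  check_profile(profile)
  border_policy <- match.arg(border_policy)
  if (is.null(target_density_mm2)) {
    target_density_mm2 <- switch(archetype$name,
      graminoid_large = 50, graminoid_small = 250, dicot = 120, 100)
  }
  if (!is.finite(target_density_mm2) || target_density_mm2 < 0) {
    stop_stomapipe("target_density_mm2 must be >= 0", "stomapipe_config_error")
  }
  if (is.null(image_size_px)) image_size_px <- profile_image_size(profile)
  image_size_px <- as.integer(round(image_size_px))
  if (length(image_size_px) != 2L || any(image_size_px < 8L)) {
    stop_stomapipe("image_size_px must be two integers >= 8",
                   "stomapipe_config_error")
  }
  structure(
    list(archetype = archetype, profile = profile,
         target_density_mm2 = target_density_mm2,
         image_size_px = image_size_px,
         blur_from_optics = isTRUE(blur_from_optics),
         noise_sd = noise_sd,
         illumination_gradient = illumination_gradient,
         bubble_count = as.integer(bubble_count),
         bubble_radius_um = bubble_radius_um,
         border_policy = border_policy,
         inset_margin = isTRUE(inset_margin),
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Imaged area of a scene in square millimetres (pixel extent at the
#' profile's pixel density).
#' @param spec A [scene_spec()].
#' @return Area in mm^2.
#' @export
scene_area_mm2 <- function(spec) {
  prod(spec$image_size_px) / spec$profile$px_per_mm^2
}

# Margin (px) guaranteeing that a complex centred inside it cannot cross the
# border: half the maximum complex length (size draws are truncated at
# 1.6 x mean), plus one blur-safety pixel.
scene_margin_px <- function(spec) {
  um_to_px(1.6 * spec$archetype$complex_length_um / 2, spec$profile) + 1
}

#' Place stomatal complex centres and orientations for a scene
#'
#' Rows mode lays centres on parallel stomatal files spaced `row_pitch_um`
#' apart, with along-file positions drawn to hit the target density and
#' positional jitter; orientations align with the file axis up to Gaussian
#' jitter. Scattered mode places centres by sequential random placement with
#' hard-core (minimum-distance) rejection and uniform orientations. In both
#' modes no two centres lie closer than `min_spacing_um` and the expected
#' count is `target_density_mm2 x imaged area`.
#'
#' @param spec A [scene_spec()].
#' @return Data frame with columns `cx`, `cy` (pixel centre coordinates,
#'   0-based) and `theta` (orientation, radians from the +x axis).
#' @export
place_stomata <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, place_stomata_impl(spec))
}

place_stomata_impl <- function(spec) {
  arch <- spec$archetype
  prof <- spec$profile
  W <- spec$image_size_px[1]
  H <- spec$image_size_px[2]
  margin <- if (spec$inset_margin) scene_margin_px(spec) else 0
  if (W - 2 * margin <= 0 || H - 2 * margin <= 0) {
    stop_stomapipe(
      sprintf("image (%d x %d px) too small to contain one '%s' complex",
              W, H, arch$name),
      "stomapipe_config_error")
  }
  area_mm2 <- scene_area_mm2(spec)
  n_target <- rpois(1L, spec$target_density_mm2 * area_mm2)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), theta = numeric(0))
  if (n_target == 0L) return(empty)

  dmin <- um_to_px(arch$min_spacing_um, prof)
  xs <- ys <- numeric(0)
  max_attempts <- 500L

  if (arch$arrangement == "rows") {
    pitch <- um_to_px(arch$row_pitch_um, prof)
    y0 <- margin + runif(1, 0, pitch)
    row_ys <- seq(y0, H - margin, by = pitch)
    if (length(row_ys) == 0L) row_ys <- (H / 2)
    n_rows <- length(row_ys)
    L <- W - 2 * margin
    # capacity of one file under hard-core spacing dmin
    cap <- if (dmin > 0) floor(L / dmin) + 1L else n_target
    if (spec$target_density_mm2 * area_mm2 > n_rows * cap) {
      # the intended density itself exceeds the packing capacity
      stop_stomapipe(sprintf(
        "cannot place %.0f stomata at min spacing %.0f um in %d files; achievable maximum is %d stomata (%.0f per mm^2)",
        spec$target_density_mm2 * area_mm2, arch$min_spacing_um, n_rows,
        n_rows * cap, n_rows * cap / area_mm2),
        "stomapipe_packing_error")
    }
    # a Poisson fluctuation above capacity saturates at the packing limit
    n_target <- min(n_target, n_rows * cap)
    # spread the count over files, shifting overflow beyond a file's capacity
    counts <- tabulate(sample.int(n_rows, n_target, replace = TRUE), n_rows)
    while (any(counts > cap)) {
      over <- which(counts > cap)[1]
      under <- which(counts < cap)[1]
      shift <- min(counts[over] - cap, cap - counts[under])
      counts[over] <- counts[over] - shift
      counts[under] <- counts[under] + shift
    }
    # exact uniform hard-core placement along each file: sorted uniforms in
    # the spacing-reduced interval, then re-inflated by the minimum gap
    jit_y <- pitch * 0.06
    for (r in seq_len(n_rows)) {
      k <- counts[r]
      if (k == 0L) next
      u <- sort(runif(k, 0, L - (k - 1) * dmin))
      x <- margin + u + (seq_len(k) - 1L) * dmin
      y <- clamp(row_ys[r] + clamp(rnorm(k, 0, jit_y),
                                   -0.1 * pitch, 0.1 * pitch),
                 margin, H - margin)
      xs <- c(xs, x); ys <- c(ys, y)
    }
    theta <- rnorm(n_target, 0, arch$orientation_sd_deg * pi / 180)
  } else {
    for (k in seq_len(n_target)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        x <- runif(1, margin, W - margin)
        y <- runif(1, margin, H - margin)
        if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= dmin^2)) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop_stomapipe(sprintf(
          "cannot place %d stomata at min spacing %.0f um; achievable maximum is about %.0f stomata (%.0f per mm^2)",
          n_target, arch$min_spacing_um, length(xs), length(xs) / area_mm2),
          "stomapipe_packing_error")
      }
    }
    theta <- runif(n_target, 0, pi)
  }
  data.frame(cx = xs, cy = ys, theta = theta)
}

# Paint an ellipse-based value field onto a patch of the image. `fun`
# receives the normalized elliptical radius field and local rotated coords
# and returns a list(mask, value) pairs painted in order.
paint_patch <- function(img, cx, cy, a, b, theta, painter) {
  W <- nrow(img); H <- ncol(img)
  r <- max(a, b) + 2
  i0 <- max(1L, floor(cx - r)); i1 <- min(W, ceiling(cx + r) + 1L)
  j0 <- max(1L, floor(cy - r)); j1 <- min(H, ceiling(cy + r) + 1L)
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  px <- ii - 0.5; py <- jj - 0.5     # pixel centres, 0-based coords
  dx <- outer(px - cx, rep(1, length(jj)))
  dy <- outer(rep(1, length(ii)), py - cy)
  ct <- cos(theta); st <- sin(theta)
  xr <- dx * ct + dy * st            # along major axis
  yr <- -dx * st + dy * ct
  patch <- img[ii, jj, drop = FALSE]
  patch <- painter(patch, xr, yr)
  img[ii, jj] <- patch
  img
}

# Draw one stomatal complex. Graminoid complexes get a dumbbell silhouette
# (end lobes + central bar); dicot complexes an inner guard-cell ellipse.
draw_stoma <- function(img, st, dumbbell) {
  a <- st$a_px; b <- st$b_px
  img <- paint_patch(img, st$cx, st$cy, a, b, st$theta, function(p, xr, yr) {
    rn <- (xr / a)^2 + (yr / b)^2
    p[rn <= 1] <- 0.60                                   # complex fill
    if (dumbbell) {
      lob <- pmin((xr - 0.52 * a)^2 + yr^2, (xr + 0.52 * a)^2 + yr^2)
      p[rn <= 1 & lob <= (0.45 * b)^2] <- 0.50           # guard-cell lobes
      p[rn <= 1 & abs(xr) <= 0.55 * a & abs(yr) <= 0.22 * b] <- 0.50
    } else {
      gn <- (xr / (0.62 * a))^2 + (yr / (0.62 * b))^2
      p[gn <= 1] <- 0.52                                 # guard-cell pair
    }
    p[rn <= 1 & rn >= 0.80] <- 0.42                      # complex outline
    p
  })
  if (!is.null(st$ap_a_px)) {
    aa <- st$ap_a_px; ab <- st$ap_b_px
    img <- paint_patch(img, st$cx, st$cy, aa, ab, st$theta,
      function(p, xr, yr) {
        p[(xr / aa)^2 + (yr / ab)^2 <= 1] <- 0.12        # open aperture
        p
      })
  }
  img
}

draw_bubble <- function(img, cx, cy, r) {
  paint_patch(img, cx, cy, r + 2, r + 2, 0, function(p, xr, yr) {
    d <- sqrt(xr^2 + yr^2)
    soft <- clamp((r - d) / 2 + 0.5, 0, 1)   # soft 2 px edge
    blend <- 0.55 * soft
    p * (1 - blend) + 0.95 * blend
  })
}

#' Render a synthetic leaf-epidermis scene with exact ground truth
#'
#' Draws an epidermal background texture, each stomatal complex (darker
#' outline and fill, dumbbell silhouette for rowed graminoids, elliptical
#' guard-cell pair for scattered dicots) and its dark aperture ellipse whose
#' width is `openness x complex width`; then applies optical Gaussian blur,
#' bright air-bubble artifacts, a multiplicative illumination gradient and
#' additive sensor noise, and quantizes to 8-bit grayscale.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `stoma_scene` with elements
#'   \describe{
#'     \item{image}{numeric `width x height` matrix, intensities in \[0, 1\]
#'       at 8-bit resolution (x along rows, y along columns, 0-based pixel
#'       coordinates).}
#'     \item{truth}{ground truth: `boxes` (data frame `id, x, y, w, h` in
#'       half-open pixel convention), `complex_polygons` / `aperture_polygons`
#'       (lists of n x 2 pixel-coordinate matrices; aperture entries `NULL`
#'       when closed), `traits` (per-stoma physical measurements in um / um^2),
#'       `count` and `density_mm2` (realized values).}
#'     \item{spec}{the input spec.}
#'   }
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  arch <- spec$archetype
  prof <- spec$profile
  W <- spec$image_size_px[1]
  H <- spec$image_size_px[2]
  umpx <- 1000 / prof$px_per_mm   # um per pixel

  pl <- place_stomata_impl(spec)
  n <- nrow(pl)

  # Per-stoma size and openness draws (truncated normals; width kept below
  # length so the major axis is the complex length).
  stomata <- vector("list", n)
  for (k in seq_len(n)) {
    L <- clamp(rnorm(1, arch$complex_length_um, arch$complex_length_sd_um),
               0.6 * arch$complex_length_um, 1.6 * arch$complex_length_um)
    Wd <- clamp(rnorm(1, arch$complex_width_um, arch$complex_width_sd_um),
                0.6 * arch$complex_width_um, 1.6 * arch$complex_width_um)
    Wd <- min(Wd, 0.9 * L)
    op <- clamp(rnorm(1, arch$aperture_openness, arch$aperture_openness_sd),
                0, 0.85)
    a_px <- (L / 2) / umpx
    b_px <- (Wd / 2) / umpx
    ap_a_px <- ap_b_px <- NULL
    if (op > arch$closed_below) {
      ap_a_px <- arch$aperture_length_frac * a_px
      ap_b_px <- op * b_px
      if (2 * ap_b_px < 1.2) { ap_a_px <- ap_b_px <- NULL; op <- 0 }
    } else {
      op <- 0
    }
    stomata[[k]] <- list(
      cx = pl$cx[k], cy = pl$cy[k], theta = pl$theta[k],
      a_px = a_px, b_px = b_px, ap_a_px = ap_a_px, ap_b_px = ap_b_px,
      length_um = L, width_um = Wd, openness = op
    )
  }

  # Border policy: cull or keep-clipped complexes crossing the image edge.
  polys <- lapply(stomata, function(s) {
    ellipse_polygon(s$cx, s$cy, s$a_px, s$b_px, s$theta)
  })
  inside <- vapply(polys, function(p) {
    all(p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H)
  }, logical(1))
  if (spec$border_policy == "cull") {
    stomata <- stomata[inside]
    polys <- polys[inside]
  } else {
    polys <- lapply(polys, function(p) {
      p[, 1] <- clamp(p[, 1], 0, W)
      p[, 2] <- clamp(p[, 2], 0, H)
      p
    })
  }
  n <- length(stomata)

  # Background: light epidermis with smooth low-amplitude texture.
  img <- matrix(0.78, W, H)
  tex <- matrix(rnorm(W * H), W, H)
  tex <- as.matrix(EBImage::gblur(EBImage::Image(tex), sigma = 4))
  if (stats::sd(tex) > 0) tex <- tex / stats::sd(tex)
  img <- img + 0.015 * tex

  dumbbell <- arch$arrangement == "rows"
  for (s in stomata) img <- draw_stoma(img, s, dumbbell)

  if (spec$blur_from_optics) {
    sigma <- prof$resolving_power_um * prof$px_per_mm / 1000 / 2
    if (sigma > 0.01) {
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
    }
  }

  if (spec$bubble_count > 0) {
    rr <- um_to_px(spec$bubble_radius_um, prof)
    for (k in seq_len(spec$bubble_count)) {
      img <- draw_bubble(img, runif(1, 0, W), runif(1, 0, H),
                         runif(1, min(rr), max(rr)))
    }
  }

  if (spec$illumination_gradient > 0) {
    ramp <- 1 + spec$illumination_gradient *
      (((seq_len(W) - 0.5) / W) - 0.5)
    img <- img * ramp
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(W * H, 0, spec$noise_sd), W, H)
  }
  img <- quantize8(img)

  # Ground truth
  area_scale <- umpx^2
  boxes <- do.call(rbind, lapply(seq_len(n), function(k) {
    bb <- polygon_bbox(polys[[k]])
    data.frame(id = k, x = bb["x"], y = bb["y"], w = bb["w"], h = bb["h"],
               row.names = NULL)
  }))
  if (is.null(boxes)) {
    boxes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        w = numeric(0), h = numeric(0))
  }
  ap_polys <- lapply(stomata, function(s) {
    if (is.null(s$ap_a_px)) return(NULL)
    ellipse_polygon(s$cx, s$cy, s$ap_a_px, s$ap_b_px, s$theta)
  })
  traits <- do.call(rbind, lapply(seq_len(n), function(k) {
    s <- stomata[[k]]
    open <- !is.null(s$ap_a_px)
    data.frame(
      id = k, cx = s$cx, cy = s$cy, theta = s$theta,
      complex_area_um2 = pi * s$a_px * s$b_px * area_scale,
      complex_length_um = s$length_um,
      complex_width_um = s$width_um,
      aperture_length_um = if (open) 2 * s$ap_a_px * umpx else NA_real_,
      aperture_width_um = if (open) 2 * s$ap_b_px * umpx else NA_real_,
      aperture_area_um2 = if (open) pi * s$ap_a_px * s$ap_b_px * area_scale
                          else NA_real_,
      openness = if (open) s$openness else NA_real_
    )
  }))
  if (is.null(traits)) {
    traits <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                         theta = numeric(0), complex_area_um2 = numeric(0),
                         complex_length_um = numeric(0),
                         complex_width_um = numeric(0),
                         aperture_length_um = numeric(0),
                         aperture_width_um = numeric(0),
                         aperture_area_um2 = numeric(0),
                         openness = numeric(0))
  }
  structure(
    list(
      image = img,
      truth = list(
        boxes = boxes,
        complex_polygons = polys,
        aperture_polygons = ap_polys,
        traits = traits,
        count = n,
        density_mm2 = n / scene_area_mm2(spec)
      ),
      spec = spec
    ),
    class = "stoma_scene"
  )
}

#' @export
print.stoma_scene <- function(x, ...) {
  cat(sprintf(
    "<stoma_scene: %d x %d px (%s, %s), %d stomata, %.1f per mm^2>\n",
    nrow(x$image), ncol(x$image), x$spec$profile$name, x$spec$archetype$name,
    x$truth$count, x$truth$density_mm2))
  invisible(x)
}

#' Write a scene image to PNG or TIFF
#'
#' @param scene A `stoma_scene` (or a plain intensity matrix).
#' @param path Output path; format from extension (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_scene_image <- function(scene, path) {
  img <- if (inherits(scene, "stoma_scene")) scene$image else scene
  EBImage::writeImage(EBImage::Image(img, colormode = "Grayscale"), path)
  invisible(path)
}

#' Read a grayscale image as an intensity matrix
#'
#' Reads PNG/TIFF/JPEG; colour images are converted to grayscale by channel
#' averaging. Returns a `width x height` matrix with intensities in \[0, 1\].
#'
#' @param path Image file path.
#' @return Numeric matrix.
#' @export
read_image_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_stomapipe(sprintf("image file not found: %s", path),
                   "stomapipe_io_error")
  }
  img <- EBImage::readImage(path)
  img <- EBImage::channel(img, "gray")
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  as.matrix(m)
}
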