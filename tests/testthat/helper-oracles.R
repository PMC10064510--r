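# Shared helpers: independent oracles and small fixture builders.

# Maximum-cardinality IoU-feasible matching by exhaustive search over
# prediction-to-GT assignments (instances are <= 6 x 6). Independent of the
# package's greedy matcher.
brute_force_max_matching <- function(iou_mat, iou_threshold) {
  n_gt <- nrow(iou_mat)
  n_pred <- ncol(iou_mat)
  if (n_gt == 0L || n_pred == 0L) return(0L)
  feasible <- iou_mat >= iou_threshold
  best <- 0L
  recurse <- function(j, used_gt, count) {
    if (count + (n_pred - j + 1L) <= best) return()
    if (j > n_pred) {
      if (count > best) best <<- count
      return()
    }
    for (i in seq_len(n_gt)) {
      if (feasible[i, j] && !used_gt[i]) {
        used_gt[i] <- TRUE
        recurse(j + 1L, used_gt, count + 1L)
        used_gt[i] <- FALSE
      }
    }
    recurse(j + 1L, used_gt, count)
    if (count > best) best <<- count
  }
  recurse(1L, rep(FALSE, n_gt), 0L)
  best
}

# Random matching instance: boxes scattered in a 100 x 100 frame so that
# overlaps of all degrees occur.
random_match_instance <- function(n_gt, n_pred) {
  mk <- function(n) {
    data.frame(x = runif(n, 0, 80), y = runif(n, 0, 80),
               w = runif(n, 8, 25), h = runif(n, 8, 25))
  }
  gt <- mk(n_gt)
  pred <- mk(n_pred)
  # nudge some predictions onto GT boxes so true positives are common
  if (n_gt > 0 && n_pred > 0) {
    k <- min(n_gt, n_pred)
    sel <- sample(seq_len(n_gt), k)
    pred$x[seq_len(k)] <- gt$x[sel] + runif(k, -4, 4)
    pred$y[seq_len(k)] <- gt$y[sel] + runif(k, -4, 4)
    pred$w[seq_len(k)] <- gt$w[sel] * runif(k, 0.8, 1.2)
    pred$h[seq_len(k)] <- gt$h[sel] * runif(k, 0.8, 1.2)
  }
  pred$confidence <- runif(n_pred)
  pred$image_id <- rep("im", n_pred)
  pred$label <- rep("stoma", n_pred)
  list(gt = gt, pred = pred)
}

# Scene cache so expensive renders are shared between tests in one file.
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(archetype, seed, ...) {
  key <- paste(archetype, seed, deparse(list(...)), collapse = "|")
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- render_scene(
      scene_spec(archetype = archetype, seed = seed, ...))
  }
  .scene_cache[[key]]
}

# A noise-free crop containing one rendered stoma, for segmentation tests.
single_stoma_crop <- function(a_px, b_px, theta = 0, openness = 0.3,
                              dumbbell = FALSE, pad = 8,
                              profile = get_profile("400x")) {
  W <- 2 * ceiling(a_px + pad)
  H <- 2 * ceiling(a_px + pad)
  img <- matrix(0.78, W, H)
  st <- list(cx = W / 2, cy = H / 2, theta = theta, a_px = a_px, b_px = b_px,
             ap_a_px = if (openness > 0) 0.5 * a_px else NULL,
             ap_b_px = if (openness > 0) openness * b_px else NULL)
  img <- stomapipe:::draw_stoma(img, st, dumbbell)
  sigma <- profile$resolving_power_um * profile$px_per_mm / 1000 / 2
  if (sigma > 0.01) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  }
  img
}
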