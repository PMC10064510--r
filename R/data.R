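#' Published operating points of deep-learning stomatal detectors
#'
#' Precision and recall reported for trained stomatal detection models on
#' handheld-microscope images of wheat (100x, 200x, 400x), rice (400x) and
#' tomato (400x). These serve as worked examples for the F1 arithmetic
#' ([f1_score()]): the F1 value at each operating point is the harmonic
#' mean of the printed precision and recall.
#'
#' @return Data frame with columns `species`, `magnification`, `precision`,
#'   `recall` and the computed `f1`.
#' @export
detector_operating_points <- function() {
  path <- system.file("extdata", "detector_operating_points.csv",
                      package = "stomapipe")
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$f1 <- f1_score(d$precision, d$recall)
  d
}
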