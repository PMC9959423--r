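# Reference tables bundled from the clinical evaluation of this
# pipeline: the seven-image training set and the 128-image blind test
# set.  They are inputs for arithmetic cross-checks (metric derivations,
# staging-rule behavior), not data this package can regenerate -- the
# underlying photographs are private.

ref_path <- function(name) {
  system.file("extdata", name, package = "fluoroseg", mustWork = TRUE)
}

#' Reference training-set segmentation report
#'
#' Per-image segmentation accuracies, opaque/brown fractions and expert
#' stage for the seven clinical training images.  The fractions feed the
#' staging rule directly; the expert column is the dentist's grading.
#'
#' @return Data frame: id, expert, acc_mask, acc3, r_opaque, r_brown.
#' @export
reference_training_ratios <- function() {
  read.csv(ref_path("reference_ratios.csv"), stringsAsFactors = FALSE,
           check.names = FALSE)
}

#' Reference pixel-class confusion matrix
#'
#' Five-class pixel confusion matrix (rows = actual) of the best
#' prototype model on held-out validation pixels.
#'
#' @return Integer matrix 5 x 5 with class dimnames.
#' @export
reference_pixel_confusion <- function() {
  d <- read.csv(ref_path("pixel_confusion.csv"), check.names = FALSE)
  m <- as.matrix(d[, -1])
  dimnames(m) <- list(actual = d$class, predicted = colnames(d)[-1])
  m
}

#' Reference fluorosis-stage confusion matrix
#'
#' Stage confusion matrix (rows = actual) over the 128 blind test
#' images.
#'
#' @return Integer matrix 4 x 4 with stage dimnames.
#' @export
reference_stage_confusion <- function() {
  d <- read.csv(ref_path("stage_confusion.csv"), check.names = FALSE)
  m <- as.matrix(d[, -1])
  dimnames(m) <- list(actual = d$class, predicted = colnames(d)[-1])
  m
}

#' Reference per-stage segmentation accuracies (blind test set)
#'
#' Image counts and mean mask / three-class accuracies per expert stage
#' over the blind test set; their image-count-weighted means are the
#' headline segmentation accuracies.
#'
#' @return Data frame: stage, n_images, acc_mask, acc3.
#' @export
reference_segmentation_accuracy <- function() {
  read.csv(ref_path("segmentation_accuracy.csv"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference segmented pixel counts for two training images
#'
#' White-yellow / opaque / brown pixel counts of the segmented tooth
#' region for training images F1_2 and F3_1; inputs to the ratio
#' arithmetic.
#'
#' @return Data frame: id, white_yellow, opaque, brown.
#' @export
reference_pixel_counts <- function() {
  read.csv(ref_path("pixel_counts.csv"), stringsAsFactors = FALSE)
}
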