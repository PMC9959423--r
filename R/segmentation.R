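#' Per-pixel five-class map
#'
#' Classifies every pixel of an RGB image against the labeled
#' multi-prototypes with fuzzy k-NN (K = 1).
#'
#' @param img RGB array `height x width x 3` (unit interval or 8-bit).
#' @param prototypes A [prototype_set()].
#' @return Character matrix of class labels, same shape as the image.
#' @export
predict_class_map <- function(img, prototypes) {
  feats <- image_to_features(img, scale_hue = prototypes$scale_hue)
  lab <- classify_batch(feats, prototypes, k = 1)
  vector_to_raster(lab, attr(feats, "img_dim"))
}

# Binary tooth mask: every non-background pixel.
tooth_mask_from_map <- function(class_map) {
  class_map != "background"
}

# Default opening radius: proportional to the image diagonal so the
# cleanup behaves the same across image resolutions.
default_open_radius <- function(dim2) {
  max(1L, as.integer(round(0.002 * sqrt(sum(dim2^2)))))
}

#' Morphological mask cleanup
#'
#' Binary opening with a disc structuring element (removes speckle
#' smaller than the element) followed by a dilation (restores and
#' slightly enhances the tooth areas).
#'
#' @param mask Logical matrix (tooth vs background).
#' @param open_radius Disc radius of the opening; default scales with
#'   the image diagonal (0.2% of it, at least 1).
#' @param dilate_radius Disc radius of the dilation (default 1; 0
#'   disables it).
#' @return Logical matrix.
#' @export
morphological_cleanup <- function(mask, open_radius = NULL,
                                  dilate_radius = 1) {
  m <- mask > 0
  if (is.null(open_radius)) open_radius <- default_open_radius(dim(m))
  storage.mode(m) <- "integer"
  if (open_radius > 0) {
    kern <- EBImage::makeBrush(2 * open_radius + 1, shape = "disc")
    m <- EBImage::opening(m, kern)
  }
  if (dilate_radius > 0) {
    kern <- EBImage::makeBrush(2 * dilate_radius + 1, shape = "disc")
    m <- EBImage::dilate(m, kern)
  }
  matrix(as.vector(m) > 0.5, nrow(mask), ncol(mask))
}

#' Reclassify background pixels enclosed by the tooth region
#'
#' Background-labeled pixels that lie inside the tooth region (the
#' difference between the hole-filled mask and the mask) are usually
#' misclassified enamel; they are re-labeled by fuzzy k-NN with K = 5
#' restricted to the four tooth classes, and the mask is filled
#' accordingly.  Pixels outside the tooth region never change.
#'
#' @param img Source RGB array (for the features of the enclosed
#'   pixels).
#' @param mask Logical tooth mask (after morphology).
#' @param class_map Character class map to update.
#' @param prototypes A [prototype_set()].
#' @param k Neighbor count for the reclassification (default 5).
#' @return List with updated `class_map` and `mask`.
#' @export
reclassify_enclosed_background <- function(img, mask, class_map,
                                           prototypes, k = 5) {
  m <- mask > 0
  storage.mode(m) <- "integer"
  filled <- matrix(as.vector(EBImage::fillHull(m)) > 0.5,
                   nrow(mask), ncol(mask))
  enclosed <- filled & !(mask > 0)
  if (any(enclosed)) {
    feats <- image_to_features(img, scale_hue = prototypes$scale_hue)
    # feature rows are in row-major pixel order
    pix_id <- (row(mask)[enclosed] - 1L) * ncol(mask) + col(mask)[enclosed]
    newlab <- classify_batch(feats[pix_id, , drop = FALSE], prototypes,
                             k = k,
                             classes = setdiff(CLASS_LABELS, "background"))
    class_map[enclosed] <- newlab
  }
  list(class_map = class_map, mask = filled)
}

# Collapse the five-class map to the three tooth classes + background,
# restricted to the mask: white/yellow -> white_yellow; opaque and brown
# kept; anything outside the mask (or still background inside it, e.g.
# a dilation fringe) -> background.
collapse_to_map3 <- function(class_map, mask) {
  out <- matrix("background", nrow(class_map), ncol(class_map))
  inm <- mask > 0
  wy <- inm & (class_map == "white" | class_map == "yellow")
  out[wy] <- "white_yellow"
  out[inm & class_map == "opaque"] <- "opaque"
  out[inm & class_map == "brown"] <- "brown"
  out
}

#' Remove tiny opaque and brown regions
#'
#' Connected components (8-connectivity) of opaque pixels smaller than
#' 0.55% of the tooth area, and of brown pixels smaller than 0.05% of
#' it, are reassigned to the neutral white-yellow class: specks that
#' small are segmentation noise, not disease evidence.
#'
#' @param map3 Character matrix over
#'   `white_yellow/opaque/brown/background`.
#' @param opaque_min_frac,brown_min_frac Minimum component area as a
#'   fraction of the tooth area (defaults 0.0055 and 0.0005).
#' @return Updated three-class map.
#' @export
remove_small_regions <- function(map3, opaque_min_frac = 0.0055,
                                 brown_min_frac = 0.0005) {
  tooth <- sum(map3 != "background")
  if (tooth == 0) stop("zero tooth area")
  for (cls in c("opaque", "brown")) {
    frac <- if (cls == "opaque") opaque_min_frac else brown_min_frac
    sel <- map3 == cls
    if (!any(sel)) next
    cc <- label_components8(sel)
    sizes <- tabulate(cc[sel])
    drop <- which(sizes < frac * tooth)
    if (length(drop)) map3[sel & (cc %in% drop)] <- "white_yellow"
  }
  map3
}

#' Opaque and brown pixel ratios
#'
#' Fractions of opaque and brown pixels within the tooth area, where the
#' tooth area is the total of white-yellow, opaque and brown pixels.
#'
#' @param map3 Three-class map (see [remove_small_regions()]).
#' @return List with `r_opaque` and `r_brown` (fractions in [0, 1]) and
#'   the underlying `counts`.
#' @export
compute_ratios <- function(map3) {
  n_wy <- sum(map3 == "white_yellow")
  n_op <- sum(map3 == "opaque")
  n_br <- sum(map3 == "brown")
  tooth <- n_wy + n_op + n_br
  if (tooth == 0) stop("zero tooth area")
  list(r_opaque = n_op / tooth, r_brown = n_br / tooth,
       counts = c(white_yellow = n_wy, opaque = n_op, brown = n_br,
                  tooth = tooth))
}

#' Segment one mouth image
#'
#' Full per-image pipeline: five-class pixel map (fuzzy k-NN, K = 1),
#' binary tooth mask, morphological cleanup (opening + dilation),
#' reclassification of enclosed background pixels (K = 5, tooth classes
#' only), collapse to the three tooth classes, tiny-region removal, and
#' opaque/brown ratio computation.
#'
#' @param img RGB array `height x width x 3`.
#' @param prototypes A [prototype_set()].
#' @param open_radius,dilate_radius Morphology settings (see
#'   [morphological_cleanup()]).
#' @param opaque_min_frac,brown_min_frac Tiny-region thresholds (see
#'   [remove_small_regions()]).
#' @return Object of class `segmentation_result`: `class_map` (5-class),
#'   `class_map3`, `mask`, `r_opaque`, `r_brown`, `counts`, and the
#'   pre-cleanup map in `raw_class_map`.
#' @export
segment_image <- function(img, prototypes, open_radius = NULL,
                          dilate_radius = 1, opaque_min_frac = 0.0055,
                          brown_min_frac = 0.0005) {
  class_map <- predict_class_map(img, prototypes)
  raw_map <- class_map
  mask <- tooth_mask_from_map(class_map)
  mask <- morphological_cleanup(mask, open_radius, dilate_radius)
  rc <- reclassify_enclosed_background(img, mask, class_map, prototypes)
  class_map <- rc$class_map
  mask <- rc$mask
  map3 <- collapse_to_map3(class_map, mask)
  map3 <- remove_small_regions(map3, opaque_min_frac, brown_min_frac)
  ratios <- compute_ratios(map3)
  structure(list(class_map = class_map, class_map3 = map3, mask = mask,
                 r_opaque = ratios$r_opaque, r_brown = ratios$r_brown,
                 counts = ratios$counts, raw_class_map = raw_map),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: %d x %d, tooth area %d px, r_opaque = %.2f%%, r_brown = %.2f%%\n",
    nrow(x$mask), ncol(x$mask), x$counts[["tooth"]],
    100 * x$r_opaque, 100 * x$r_brown))
  invisible(x)
}
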