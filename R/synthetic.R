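#' Class color model for synthetic pixels
#'
#' Mean RGB and (diagonal, shared) standard deviation per pixel class.
#' The defaults emulate the qualitative appearance of mouth photographs:
#' creamy-white and light-yellow enamel, paper-white opaque patches,
#' brown stains, and pink gum/lip background, with the means separated
#' by well over three pooled standard deviations so that the classes are
#' clusterable.
#'
#' @param means 5 x 3 matrix of unit-interval RGB means (rows in
#'   [class_labels()] order).
#' @param sd Per-channel Gaussian standard deviation.
#' @return List of class `class_color_model`.
#' @export
class_color_model <- function(
    means = rbind(white      = c(0.92, 0.90, 0.86),
                  yellow     = c(0.88, 0.82, 0.58),
                  opaque     = c(0.96, 0.96, 0.97),
                  brown      = c(0.45, 0.30, 0.20),
                  background = c(0.72, 0.42, 0.45)),
    sd = 0.03) {
  stopifnot(nrow(means) == 5, ncol(means) == 3, sd >= 0)
  rownames(means) <- CLASS_LABELS
  structure(list(means = means, sd = sd), class = "class_color_model")
}

#' Sample labeled training pixels
#'
#' Draws per-class RGB values from the truncated Gaussian color model
#' (clipped to [0, 1]) and converts them to six-dimensional feature
#' vectors.  The default counts (4000 white, 4000 yellow, 2000 opaque,
#' 1000 brown, 1800 background) mirror the per-class pixel budget of the
#' clinical training protocol.
#'
#' @param n_per_class Named or positional integer vector of length 5 in
#'   [class_labels()] order.
#' @param model A [class_color_model()].
#' @param seed Integer seed; same seed, identical output.
#' @param scale_hue Logical; see [make_feature_vector()].
#' @return List with `x` (n x 6 feature matrix), `labels` (character),
#'   and `rgb` (n x 3 matrix).
#' @export
sample_labeled_pixels <- function(
    n_per_class = c(white = 4000, yellow = 4000, opaque = 2000,
                    brown = 1000, background = 1800),
    model = class_color_model(), seed = NULL, scale_hue = TRUE) {
  stopifnot(length(n_per_class) == 5, all(n_per_class > 0))
  with_seed(seed, {
    rgb <- NULL; labels <- character(0)
    for (ci in seq_along(CLASS_LABELS)) {
      n <- n_per_class[[ci]]
      draw <- matrix(rnorm(3 * n, mean = rep(model$means[ci, ], each = n),
                           sd = model$sd), ncol = 3)
      draw[draw < 0] <- 0; draw[draw > 1] <- 1
      rgb <- rbind(rgb, draw)
      labels <- c(labels, rep(CLASS_LABELS[ci], n))
    }
    x <- make_feature_vector(rgb[, 1], rgb[, 2], rgb[, 3],
                             scale_hue = scale_hue)
    list(x = x, labels = labels, rgb = rgb)
  })
}

# Random center within the tooth that currently has the most available
# pixels, so blobs land where there is room for a single compact patch.
pick_center <- function(avail, tooth_of) {
  counts <- tabulate(tooth_of[avail])
  roomiest <- which.max(counts)
  cand <- avail[tooth_of[avail] == roomiest]
  cand[sample.int(length(cand), 1)]
}

# Grow one compact blob: the n available pixels nearest to a random
# available center, restricted to the center's tooth.
grow_blob <- function(avail_idx, coords, tooth_of, n, center_idx) {
  same <- avail_idx[tooth_of[avail_idx] == tooth_of[center_idx]]
  d2 <- (coords[same, 1] - coords[center_idx, 1])^2 +
        (coords[same, 2] - coords[center_idx, 2])^2
  same[order(d2)][seq_len(min(n, length(same)))]
}

#' Generate a synthetic mouth image with known ground truth
#'
#' Renders a gum-colored background with a row of elliptical teeth of
#' white/yellow enamel, then places compact opaque patches and brown
#' spots inside the teeth until the requested pixel fractions of the
#' tooth area are met exactly.  Pixel colors are drawn from the class
#' color model with the given noise level (`noise = 0` renders exact
#' class means).
#'
#' @param width,height Image size in pixels.
#' @param r_opaque,r_brown Target fractions of the tooth area.
#' @param n_teeth Number of teeth.
#' @param noise Per-channel color standard deviation (0 = noise-free).
#' @param shadow Optional strength (0-1) of a vertical darkening
#'   gradient emulating intra-oral shading; 0 disables it.
#' @param model A [class_color_model()].
#' @param seed Integer seed.
#' @return List with `img` (height x width x 3 array), `class_map`
#'   (5-class character matrix), `map3`, `mask`, realized `r_opaque`,
#'   `r_brown`, and the implied `stage` under default thresholds.
#' @export
generate_mouth_image <- function(width = 320, height = 240,
                                 r_opaque = 0, r_brown = 0, n_teeth = 4,
                                 noise = 0.03, shadow = 0,
                                 model = class_color_model(),
                                 seed = NULL) {
  stopifnot(r_opaque >= 0, r_brown >= 0, r_opaque <= 1, r_brown <= 1)
  with_seed(seed, {
    cmap <- matrix("background", height, width)
    tooth_of <- matrix(0L, height, width)
    rr <- row(cmap); cc <- col(cmap)
    for (j in seq_len(n_teeth)) {
      cx <- (j - 0.5) * width / n_teeth
      cy <- height / 2
      ax <- 0.42 * width / n_teeth
      ay <- 0.32 * height
      inside <- ((cc - cx) / ax)^2 + ((rr - cy) / ay)^2 <= 1
      cmap[inside] <- if (j %% 2 == 1) "white" else "yellow"
      tooth_of[inside] <- j
    }
    tooth_idx <- which(tooth_of > 0)
    Tn <- length(tooth_idx)
    n_op <- round(r_opaque * Tn)
    n_br <- round(r_brown * Tn)
    if (n_op + n_br > Tn) stop("target ratios exceed the tooth area")
    coords <- cbind(as.vector(rr), as.vector(cc))
    avail <- tooth_idx
    place <- function(n_target, n_blobs) {
      placed <- integer(0)
      left <- n_target
      for (bl in seq_len(n_blobs)) {
        n_this <- if (bl == n_blobs) left else ceiling(n_target / n_blobs)
        n_this <- min(n_this, left)
        if (n_this <= 0) break
        ctr <- pick_center(avail, as.vector(tooth_of))
        blob <- grow_blob(avail, coords, as.vector(tooth_of), n_this, ctr)
        placed <- c(placed, blob)
        avail <<- setdiff(avail, blob)
        left <- left - length(blob)
      }
      # top up from any remaining tooth pixels if a tooth ran out
      while (left > 0 && length(avail)) {
        ctr <- pick_center(avail, as.vector(tooth_of))
        blob <- grow_blob(avail, coords, as.vector(tooth_of), left, ctr)
        placed <- c(placed, blob)
        avail <<- setdiff(avail, blob)
        left <- left - length(blob)
      }
      placed
    }
    if (n_br > 0) cmap[place(n_br, 1L)] <- "brown"
    if (n_op > 0) {
      k <- min(3L, max(1L, ceiling(r_opaque / 0.2)))
      cmap[place(n_op, k)] <- "opaque"
    }
    # render
    cls_id <- match(cmap, CLASS_LABELS)
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      base <- model$means[cls_id, ch]
      if (noise > 0) base <- base + rnorm(length(base), sd = noise)
      img[, , ch] <- matrix(base, height, width)
    }
    if (shadow > 0) {
      grad <- matrix(rep(seq(0, shadow, length.out = height), width),
                     height, width)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - grad)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    mask <- cmap != "background"
    map3 <- collapse_to_map3(cmap, mask)
    ro <- n_op / Tn; rb <- n_br / Tn
    list(img = img, class_map = cmap, map3 = map3, mask = mask,
         r_opaque = ro, r_brown = rb,
         stage = classify_fluorosis(ro, rb))
  })
}

# Scene targets of the standard 12-image fixture suite: three images
# per stage, with brown fractions kept clear of the delta = 0.7%
# boundary so that small segmentation drift cannot flip a stage.
fixture_specs <- function() {
  data.frame(
    id = c("normal_1", "normal_2", "normal_3",
           "stage1_1", "stage1_2", "stage1_3",
           "stage2_1", "stage2_2", "stage2_3",
           "stage3_1", "stage3_2", "stage3_3"),
    r_opaque = c(0.030, 0.045, 0.080,
                 0.150, 0.220, 0.280,
                 0.350, 0.420, 0.500,
                 0.120, 0.300, 0.400),
    r_brown  = c(0.000, 0.010, 0.003,
                 0.000, 0.003, 0.002,
                 0.003, 0.000, 0.005,
                 0.020, 0.015, 0.025),
    stringsAsFactors = FALSE
  )
}

#' Generate the standard synthetic fixture suite
#'
#' Twelve mouth images (three per fluorosis stage) with known masks and
#' opaque/brown fractions, plus a manifest of the ground truth.  With
#' `dir` given, images, indexed class maps, binary masks and the
#' manifest CSV are written there; otherwise everything is returned in
#' memory.
#'
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param dir Optional output directory.
#' @param noise Color noise level (default 0: noise-free renders).
#' @param width,height Image size.
#' @return List with `images` (list of [generate_mouth_image()] results
#'   named by id) and `manifest` (data frame: id, r_opaque, r_brown,
#'   stage, and file names when written).
#' @export
make_fixture_suite <- function(seed = 1, dir = NULL, noise = 0,
                               width = 320, height = 240) {
  specs <- fixture_specs()
  images <- vector("list", nrow(specs))
  names(images) <- specs$id
  for (i in seq_len(nrow(specs))) {
    images[[i]] <- generate_mouth_image(
      width = width, height = height,
      r_opaque = specs$r_opaque[i], r_brown = specs$r_brown[i],
      noise = noise, seed = derive_seed(seed, 101L, i))
  }
  manifest <- data.frame(
    id = specs$id,
    r_opaque = vapply(images, `[[`, numeric(1), "r_opaque"),
    r_brown = vapply(images, `[[`, numeric(1), "r_brown"),
    stage = vapply(images, `[[`, character(1), "stage"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$file <- paste0(specs$id, ".png")
    for (i in seq_len(nrow(specs))) {
      png::writePNG(images[[i]]$img, file.path(dir, manifest$file[i]))
      write_class_map_png(images[[i]]$class_map,
                          file.path(dir, paste0(specs$id[i], "_labels.png")))
      png::writePNG(images[[i]]$mask * 1,
                    file.path(dir, paste0(specs$id[i], "_mask.png")))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}

# Fixed display palette for class maps: white, yellow, opaque -> green,
# brown -> red, background -> black.
CLASS_PALETTE <- rbind(white      = c(1, 1, 1),
                       yellow     = c(1, 1, 0),
                       opaque     = c(0, 1, 0),
                       brown      = c(1, 0, 0),
                       background = c(0, 0, 0))

# Write a class map as a paletted RGB PNG.
write_class_map_png <- function(class_map, path) {
  id <- match(class_map, CLASS_LABELS)
  img <- array(0, dim = c(nrow(class_map), ncol(class_map), 3))
  for (ch in 1:3) img[, , ch] <- matrix(CLASS_PALETTE[id, ch],
                                        nrow(class_map))
  png::writePNG(img, path)
  invisible(path)
}
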