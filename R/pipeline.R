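#' Pipeline configuration
#'
#' Aggregates every tunable of the train / segment / stage workflow.
#' Defaults are the full-scale study configuration (see [upfc_params()],
#' [cs_config()], [stage_thresholds()]); pass a desk-scale `cs` for
#' quick experiments.
#'
#' @param upfc An [upfc_params()].
#' @param cs A [cs_config()].
#' @param fknn_m Fuzzy k-NN distance-scaling exponent.
#' @param thresholds A [stage_thresholds()].
#' @param scale_hue Logical; hue divided by 2*pi in feature vectors.
#' @param open_radius,dilate_radius Morphology settings (NULL = image
#'   size dependent default).
#' @param k_folds Folds for [cross_validate()].
#' @param seed Master seed.
#' @return List of class `fluoro_config`.
#' @export
fluoro_config <- function(upfc = upfc_params(), cs = cs_config(),
                          fknn_m = 1.5,
                          thresholds = stage_thresholds(),
                          scale_hue = TRUE, open_radius = NULL,
                          dilate_radius = 1, k_folds = 10, seed = NULL) {
  stopifnot(inherits(upfc, "upfc_params"), inherits(cs, "cs_config"),
            inherits(thresholds, "stage_thresholds"), fknn_m > 1)
  if (!is.null(seed)) cs$seed <- cs$seed %||% seed
  structure(list(upfc = upfc, cs = cs, fknn_m = fknn_m,
                 thresholds = thresholds, scale_hue = isTRUE(scale_hue),
                 open_radius = open_radius,
                 dilate_radius = dilate_radius,
                 k_folds = as.integer(k_folds), seed = seed),
            class = "fluoro_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Any omitted field keeps its default; unknown fields are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [fluoro_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  known <- c("upfc", "cs", "fknn_m", "thresholds", "scale_hue",
             "open_radius", "dilate_radius", "k_folds", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(raw$upfc)) args$upfc <- do.call(upfc_params, raw$upfc)
  if (!is.null(raw$cs)) args$cs <- do.call(cs_config, raw$cs)
  if (!is.null(raw$thresholds))
    args$thresholds <- do.call(stage_thresholds, raw$thresholds)
  for (f in c("fknn_m", "scale_hue", "open_radius", "dilate_radius",
              "k_folds", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(fluoro_config, args)
}

#' Write a prototype set to CSV (+ JSON sidecar)
#'
#' One row per prototype with the six centroid coordinates (full
#' double precision) and the class label, plus a JSON sidecar recording
#' the feature convention.  A set written and re-read behaves
#' identically.
#'
#' @param prototypes A [prototype_set()].
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_prototypes <- function(prototypes, path) {
  stopifnot(inherits(prototypes, "prototype_set"))
  cn <- colnames(prototypes$centroids)
  if (is.null(cn)) cn <- c("r", "g", "b", "h", "s", "i")[
    seq_len(ncol(prototypes$centroids))]
  header <- paste(c(cn, "label"), collapse = ",")
  rows <- vapply(seq_len(nrow(prototypes$centroids)), function(i) {
    paste(c(sprintf("%.17g", prototypes$centroids[i, ]),
            prototypes$labels[i]), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  jsonlite::write_json(
    list(scale_hue = prototypes$scale_hue,
         n_prototypes = nrow(prototypes$centroids),
         class_counts = as.list(table(factor(prototypes$labels,
                                             levels = CLASS_LABELS)))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a prototype set written by [write_prototypes()]
#'
#' @param path CSV path.
#' @return A [prototype_set()].
#' @export
read_prototypes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(d)) stop("malformed prototype file: no label column")
  side <- paste0(path, ".json")
  scale_hue <- if (file.exists(side))
    isTRUE(jsonlite::fromJSON(side)$scale_hue) else TRUE
  prototype_set(as.matrix(d[, setdiff(names(d), "label"), drop = FALSE]),
                d$label, scale_hue = scale_hue)
}

#' Read labeled pixels from CSV
#'
#' Accepts either `r,g,b,label` (features are derived) or a full
#' `r,g,b,h,s,i,label` table.
#'
#' @param path CSV path.
#' @param scale_hue Hue convention when features must be derived.
#' @return List with `x` (n x 6 matrix) and `labels`.
#' @export
read_pixels_csv <- function(path, scale_hue = TRUE) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("r", "g", "b", "label")
  if (!all(need %in% names(d)))
    stop("malformed pixel CSV: need columns r,g,b,label")
  x <- if (all(c("h", "s", "i") %in% names(d)))
    as.matrix(d[, c("r", "g", "b", "h", "s", "i")])
  else make_feature_vector(d$r, d$g, d$b, scale_hue = scale_hue)
  list(x = x, labels = d$label)
}

#' Train prototypes from labeled pixels (workflow command)
#'
#' Runs cross-validated cuckoo-search training and optionally writes
#' the best prototype set and a fold-accuracy report.
#'
#' @param pixels Either a list with `x` and `labels` (e.g. from
#'   [sample_labeled_pixels()] or [read_pixels_csv()]) or a CSV path.
#' @param config A [fluoro_config()].
#' @param out_dir Optional output directory for `prototypes.csv` and
#'   `training_report.json`.
#' @return The [cross_validate()] result.
#' @export
fluoro_train <- function(pixels, config = fluoro_config(),
                         out_dir = NULL) {
  if (is.character(pixels)) pixels <- read_pixels_csv(pixels,
                                                      config$scale_hue)
  res <- cross_validate(pixels$x, pixels$labels, config$cs,
                        config$upfc, config$k_folds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_prototypes(res$prototypes, file.path(out_dir, "prototypes.csv"))
    jsonlite::write_json(
      list(fold_accuracy = res$fold_accuracy,
           mean_accuracy = res$mean_accuracy,
           best_fold = res$best_fold,
           best_accuracy = res$best_accuracy,
           seed = config$cs$seed),
      file.path(out_dir, "training_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Segment one image and report its ratios (workflow command)
#'
#' @param img RGB array or a PNG file path.
#' @param prototypes A [prototype_set()] or a prototype CSV path.
#' @param config A [fluoro_config()].
#' @param out_dir Optional directory; writes `mask.png`, the paletted
#'   `class_map.png`, and `report.json` with both ratios and the stage.
#' @return A `segmentation_result` with an added `stage` element.
#' @export
fluoro_segment <- function(img, prototypes, config = fluoro_config(),
                           out_dir = NULL) {
  if (is.character(img)) img <- png::readPNG(img)
  if (is.character(prototypes)) prototypes <- read_prototypes(prototypes)
  res <- segment_image(img, prototypes,
                       open_radius = config$open_radius,
                       dilate_radius = config$dilate_radius)
  res$stage <- classify_fluorosis(res$r_opaque, res$r_brown,
                                  config$thresholds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(res$mask * 1, file.path(out_dir, "mask.png"))
    write_class_map_png(res$class_map, file.path(out_dir, "class_map.png"))
    jsonlite::write_json(
      list(r_opaque = res$r_opaque, r_brown = res$r_brown,
           stage = res$stage, counts = as.list(res$counts)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Evaluate predicted stages against expert stages (workflow command)
#'
#' @param predicted,actual Equal-length stage vectors.
#' @return List with the stage confusion matrix (rows = actual), the
#'   per-stage one-vs-rest [metrics_table()], and the overall accuracy
#'   (percent).
#' @export
fluoro_evaluate <- function(predicted, actual) {
  cm <- confusion_matrix(predicted, actual, classes = STAGE_LABELS)
  list(confusion = cm, metrics = metrics_table(cm),
       overall_accuracy = 100 * sum(diag(cm)) / sum(cm))
}
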