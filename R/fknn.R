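#' Labeled multi-prototype set
#'
#' A trained model: cluster centroids in the six-dimensional color
#' feature space, each carrying one of the five pixel-class labels.
#' Internally the prototypes are kept sorted by label (canonical class
#' order, see [class_labels()]) so that exact distance ties resolve to
#' the earlier class deterministically.
#'
#' @param centroids Numeric matrix, one prototype per row.
#' @param labels Character vector of class labels, one per prototype.
#' @param scale_hue Logical flag recording the feature convention the
#'   prototypes were trained under.
#' @return Object of class `prototype_set`.
#' @export
prototype_set <- function(centroids, labels, scale_hue = TRUE) {
  centroids <- as.matrix(centroids)
  labels <- as.character(labels)
  stopifnot(nrow(centroids) == length(labels))
  if (!all(labels %in% CLASS_LABELS))
    stop("unknown class label(s): ",
         paste(setdiff(labels, CLASS_LABELS), collapse = ", "))
  ord <- order(match(labels, CLASS_LABELS))
  structure(list(centroids = centroids[ord, , drop = FALSE],
                 labels = labels[ord],
                 scale_hue = isTRUE(scale_hue)),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat("prototype_set:", nrow(x$centroids), "prototypes\n")
  print(table(factor(x$labels, levels = CLASS_LABELS)))
  invisible(x)
}

#' Fuzzy k-NN class memberships
#'
#' Soft class memberships of a query against the labeled prototypes:
#' among the k nearest prototypes, each neighbor votes for its (crisp)
#' class with weight \eqn{w_j = 1/\|x - x_j\|^{2/(m-1)}} and the
#' memberships are the normalized class-wise weight sums, a convex
#' combination that sums to one.  If the query coincides with one or
#' more prototypes, membership 1 is split equally over the coincident
#' prototypes (the weight is otherwise infinite).
#'
#' @param x Numeric feature vector.
#' @param prototypes A [prototype_set()].
#' @param k Number of neighbors (default 1).
#' @param m Distance-scaling exponent > 1 (default 1.5, giving weight
#'   \eqn{1/d^4}).
#' @return Named numeric vector of memberships over [class_labels()].
#' @export
fknn_memberships <- function(x, prototypes, k = 1, m = 1.5) {
  stopifnot(inherits(prototypes, "prototype_set"), m > 1)
  np <- nrow(prototypes$centroids)
  if (np == 0L) stop("empty prototype set")
  if (k < 1 || k > np) stop("k must be between 1 and the number of prototypes")
  d2 <- pairwise_sq_dists(matrix(x, nrow = 1), prototypes$centroids)[1, ]
  nn <- order(d2)[seq_len(k)]
  u <- stats::setNames(numeric(length(CLASS_LABELS)), CLASS_LABELS)
  dn <- d2[nn]
  if (any(dn == 0)) {
    hit <- prototypes$labels[nn][dn == 0]
    tab <- table(factor(hit, levels = CLASS_LABELS))
    u[] <- as.numeric(tab) / sum(tab)
  } else {
    w <- dn^(-1 / (m - 1))
    for (j in seq_len(k)) u[prototypes$labels[nn[j]]] <-
        u[prototypes$labels[nn[j]]] + w[j]
    u <- u / sum(u)
  }
  u
}

#' Classify one feature vector against the prototypes
#'
#' Assigns the class with maximal fuzzy k-NN membership; exact ties are
#' broken by the canonical class order (see [class_labels()]).
#'
#' @inheritParams fknn_memberships
#' @return Single class label (character).
#' @export
fknn_classify <- function(x, prototypes, k = 1, m = 1.5) {
  u <- fknn_memberships(x, prototypes, k = k, m = m)
  CLASS_LABELS[which.max(u)]
}

#' Classify a batch of feature vectors
#'
#' Order-preserving, vectorized classification.  Distances are computed
#' in blocks so that large pixel sets (1e5+ queries against thousands of
#' prototypes) stay within memory.
#'
#' @param X Numeric matrix of queries (rows).
#' @param prototypes A [prototype_set()].
#' @param k Number of neighbors.
#' @param m Distance-scaling exponent > 1.
#' @param block Number of queries per distance block.
#' @param classes Optional subset of class labels the classifier may
#'   return; prototypes of other classes are ignored (used when
#'   reclassifying enclosed background pixels into tooth classes only).
#' @return Character vector of labels, one per row of `X`.
#' @export
classify_batch <- function(X, prototypes, k = 1, m = 1.5, block = 8192,
                           classes = NULL) {
  stopifnot(inherits(prototypes, "prototype_set"))
  X <- as.matrix(X)
  P <- prototypes$centroids
  lab <- prototypes$labels
  if (!is.null(classes)) {
    keep <- lab %in% classes
    if (!any(keep)) stop("no prototypes in the requested classes")
    P <- P[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  np <- nrow(P)
  k <- min(k, np)
  n <- nrow(X)
  out <- character(n)
  lab_id <- match(lab, CLASS_LABELS)
  for (start in seq(1, n, by = block)) {
    ii <- start:min(start + block - 1, n)
    d2 <- pairwise_sq_dists(X[ii, , drop = FALSE], P)
    if (k == 1L) {
      # prototypes are label-sorted, so the first minimum is the
      # earliest class among exact distance ties
      nn <- max.col(-d2, ties.method = "first")
      out[ii] <- lab[nn]
    } else {
      idx <- apply(d2, 1, function(row) order(row)[seq_len(k)])
      for (q in seq_along(ii)) {
        nn <- idx[, q]
        dn <- d2[q, nn]
        u <- numeric(length(CLASS_LABELS))
        if (any(dn == 0)) {
          tab <- tabulate(lab_id[nn][dn == 0], length(CLASS_LABELS))
          u <- tab / sum(tab)
        } else {
          w <- dn^(-1 / (m - 1))
          for (j in seq_len(k)) u[lab_id[nn[j]]] <- u[lab_id[nn[j]]] + w[j]
        }
        out[ii[q]] <- CLASS_LABELS[which.max(u)]
      }
    }
  }
  out
}
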