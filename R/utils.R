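# Internal helpers shared across modules.

# Pairwise squared Euclidean distances between the rows of A (n x p) and
# the rows of B (m x p), returned as an n x m matrix.  Uses the expansion
# |a-b|^2 = |a|^2 + |b|^2 - 2 a.b; clamped at zero against cancellation.
pairwise_sq_dists <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code does not clobber user seeds.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stream of
# identifiers (nest id, generation, ...).
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1103515245 + as.numeric(v) + 12345) %% 2147483647
  as.integer(h)
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (away from zero), the
#' convention used for all reported percentages; base [round()] rounds
#' halves to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# 8-connected component labeling of a logical matrix.  EBImage::bwlabel
# is 4-connected; blob cleanup here requires diagonal adjacency, so
# components are taken over the pixel graph with king-move edges.
label_components8 <- function(m) {
  m <- m > 0
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  idx <- which(m)
  if (length(idx) == 0L) return(out)
  vid <- integer(H * W)
  vid[idx] <- seq_along(idx)
  pos <- arrayInd(idx, c(H, W))
  edges <- list()
  # offsets covering each undirected 8-neighbor pair once
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- pos[, 1] + off[1]; c2 <- pos[, 2] + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * H + r2[ok]
    keep <- m[nb]
    if (!any(keep)) next
    edges[[length(edges) + 1L]] <-
      cbind(vid[idx[ok][keep]], vid[nb[keep]])
  }
  el <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), 0, 2)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}
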