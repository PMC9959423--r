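#' UPFC parameter set
#'
#' Parameters of the unsupervised possibilistic fuzzy clustering (UPFC)
#' objective: the fuzzifier `m` and typicality exponent `n` control the
#' softness of the fuzzy memberships and possibilistic typicalities, and
#' the weights `a`, `b` set their relative importance.  The defaults
#' (m = n = 1.5, a = b = 0.5) are the study configuration.
#'
#' @param m Fuzzifier, > 1.
#' @param n Typicality exponent, > 1.
#' @param a Weight of the fuzzy-membership term, > 0.
#' @param b Weight of the possibilistic term, >= 0 (b = 0 reduces UPFC
#'   to the pure possibilistic clustering algorithm).
#' @param max_iter Maximum number of update sweeps.
#' @param tol Convergence tolerance on the maximum centroid displacement
#'   (L2 norm per centroid).
#' @return A list of class `upfc_params`.
#' @export
upfc_params <- function(m = 1.5, n = 1.5, a = 0.5, b = 0.5,
                        max_iter = 300, tol = 1e-5) {
  stopifnot(m > 1, n > 1, a > 0, b >= 0, max_iter >= 1, tol > 0)
  structure(list(m = m, n = n, a = a, b = b,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "upfc_params")
}

#' Separation parameter beta
#'
#' The sample variance of the distances from each sample to the data
#' mean: \eqn{\beta = N_S^{-1} \sum_i \|x_i - \bar{x}\|^2}.  It scales
#' the possibilistic exponential so that typicalities adapt to the
#' spread of the data.
#'
#' @param X Numeric matrix, one sample per row.
#' @return Nonnegative scalar.  `beta = 0` (all samples identical) is
#'   returned with a warning; the typicality update rejects it.
#' @export
compute_beta <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("at least one sample required")
  xbar <- colMeans(X)
  beta <- mean(rowSums(sweep(X, 2, xbar)^2))
  if (beta == 0) warning("degenerate data: all samples identical (beta = 0)")
  beta
}

#' Fuzzy (FCM-type) membership update
#'
#' Probabilistic memberships
#' \eqn{\mu_{ij} = [\sum_k (d_{ij}/d_{ik})^{2/(m-1)}]^{-1}}; each row
#' sums to one.  A sample coinciding with one or more centroids gets
#' membership 1 split equally among the coincident centroids.
#'
#' @param X Samples (rows).
#' @param centroids Centroid matrix (rows), same column count as `X`.
#' @param m Fuzzifier > 1.
#' @return `nrow(X) x nrow(centroids)` membership matrix.
#' @export
update_fcm_memberships <- function(X, centroids, m) {
  stopifnot(m > 1)
  if (anyDuplicated(round(as.matrix(centroids), 12)))
    message("coincident centroids detected")
  fcm_memberships_d2(pairwise_sq_dists(X, centroids), m)
}

# Membership update from a precomputed squared-distance matrix.
fcm_memberships_d2 <- function(d2, m) {
  w <- d2^(-1 / (m - 1))         # Inf where d2 == 0
  rs <- rowSums(w)
  sing <- !is.finite(rs)
  u <- w / rs
  if (any(sing)) {
    hit <- d2[sing, , drop = FALSE] == 0
    u[sing, ] <- hit / rowSums(hit)
  }
  u
}

#' Possibilistic typicality update
#'
#' Typicalities \eqn{t_{ij} = \exp(-(b\,n\sqrt{N_C}/\beta)\,d_{ij}^2)},
#' the stationary point of the UPFC objective whose entropy term carries
#' the coefficient \eqn{\beta/(n^2\sqrt{N_C})}.  Values lie in (0, 1],
#' independent per cluster (no row constraint), and decrease
#' monotonically with distance.
#'
#' @param X Samples (rows).
#' @param centroids Centroid matrix.
#' @param beta Positive separation parameter from [compute_beta()].
#' @param params `upfc_params`.
#' @return Typicality matrix, same shape as the membership matrix.
#' @export
update_pca_typicalities <- function(X, centroids, beta, params) {
  if (beta <= 0) stop("beta must be positive (degenerate data)")
  d2 <- pairwise_sq_dists(X, centroids)
  exp(-(params$b * params$n * sqrt(nrow(centroids)) / beta) * d2)
}

#' Centroid update
#'
#' Weighted mean of the samples with weights
#' \eqn{a\mu^m + b\,t^n}.  A cluster whose weight column is entirely
#' zero keeps its previous centroid (with a warning).
#'
#' @param X Samples (rows).
#' @param u_fcm Fuzzy membership matrix.
#' @param u_pca Typicality matrix.
#' @param params `upfc_params`.
#' @param centroids Previous centroids (fallback for all-zero columns).
#' @return Updated centroid matrix.
#' @export
update_centroids <- function(X, u_fcm, u_pca, params, centroids = NULL) {
  W <- params$a * u_fcm^params$m + params$b * u_pca^params$n
  tot <- colSums(W)
  dead <- tot == 0
  if (any(dead)) {
    warning("cluster(s) with all-zero weight kept at previous centroid")
    tot[dead] <- 1
  }
  Cnew <- crossprod(W, as.matrix(X)) / tot
  if (any(dead)) {
    if (is.null(centroids)) stop("all-zero weight column and no previous centroids")
    Cnew[dead, ] <- centroids[dead, , drop = FALSE]
  }
  Cnew
}

# Seeded k-means++-style initialization: distinct data points sampled
# with squared-distance weighting, so every dense region -- including
# minority classes -- tends to receive a starting prototype.  A plain
# uniform draw frequently misses small classes, and the possibilistic
# update keeps centroids near their starts, so coverage at
# initialization matters.
init_centroids_pp <- function(X, n_clusters) {
  Xu <- unique(X)
  nu <- nrow(Xu)
  if (nu <= n_clusters) {
    idx <- sample(nrow(X), n_clusters, replace = nu < n_clusters)
    return(X[idx, , drop = FALSE] +
             matrix(rnorm(n_clusters * ncol(X), sd = 1e-9), n_clusters))
  }
  picked <- integer(n_clusters)
  picked[1] <- sample.int(nu, 1)
  mind2 <- pairwise_sq_dists(Xu, Xu[picked[1], , drop = FALSE])[, 1]
  for (j in seq_len(n_clusters - 1L)) {
    w <- mind2
    if (sum(w) <= 0) w <- rep(1, nu)
    picked[j + 1L] <- sample.int(nu, 1, prob = w)
    d2 <- pairwise_sq_dists(Xu, Xu[picked[j + 1L], , drop = FALSE])[, 1]
    mind2 <- pmin(mind2, d2)
  }
  Xu[picked, , drop = FALSE]
}

# UPFC objective: data term + possibilistic entropy term with
# coefficient beta / (n^2 sqrt(N_C)).
upfc_objective <- function(X, centroids, u_fcm, u_pca, beta, params) {
  d2 <- pairwise_sq_dists(X, centroids)
  tn <- u_pca^params$n
  data_term <- sum((params$a * u_fcm^params$m + params$b * tn) * d2)
  K <- beta / (params$n^2 * sqrt(nrow(centroids)))
  ent <- sum(tn * log(tn) - tn)
  list(objective = data_term + K * ent, data_term = data_term)
}

#' Run unsupervised possibilistic fuzzy clustering
#'
#' Iterates the membership, typicality and centroid updates from a
#' seeded random initialization (distinct data rows sampled with
#' squared-distance weighting, k-means++ style) until the maximum
#' centroid displacement drops below `tol` or `max_iter` sweeps are
#' reached.
#'
#' @param X Numeric matrix of samples (rows).
#' @param n_clusters Number of clusters, with `1 < n_clusters < nrow(X)`.
#' @param params `upfc_params`.
#' @param seed Optional integer seed for the initialization.
#' @return An object of class `upfc` with elements `centroids`, `u_fcm`,
#'   `u_pca`, `beta`, `n_iter`, `objective`, and two per-sweep traces:
#'   `objective_trace` (the full objective, non-increasing under the
#'   alternating updates) and `data_term_trace` (its distance term
#'   alone, which the possibilistic entropy trade-off may let rise).
#' @export
run_upfc <- function(X, n_clusters, params = upfc_params(), seed = NULL) {
  X <- as.matrix(X)
  Ns <- nrow(X)
  if (n_clusters <= 1 || n_clusters >= Ns)
    stop("n_clusters must satisfy 1 < n_clusters < number of samples")
  beta <- compute_beta(X)
  if (beta <= 0) stop("degenerate data: beta = 0")
  centroids <- with_seed(seed, init_centroids_pp(X, n_clusters))
  trace <- obj_trace <- numeric(params$max_iter)
  n_iter <- 0L
  typ_coef <- params$b * params$n * sqrt(n_clusters) / beta
  K_ent <- beta / (params$n^2 * sqrt(n_clusters))
  d2 <- pairwise_sq_dists(X, centroids)
  for (it in seq_len(params$max_iter)) {
    n_iter <- it
    u <- fcm_memberships_d2(d2, params$m)
    t_ <- exp(-typ_coef * d2)
    W <- params$a * u^params$m + params$b * t_^params$n
    tot <- colSums(W)
    dead <- tot == 0
    if (any(dead)) tot[dead] <- 1
    cnew <- crossprod(W, X) / tot
    if (any(dead)) cnew[dead, ] <- centroids[dead, , drop = FALSE]
    d2 <- pairwise_sq_dists(X, cnew)
    trace[it] <- sum(W * d2)   # data term at the updated centroids
    tn <- t_^params$n
    obj_trace[it] <- trace[it] + K_ent * sum(tn * log(tn) - tn)
    shift <- sqrt(max(rowSums((cnew - centroids)^2)))
    centroids <- cnew
    if (shift < params$tol) break
  }
  trace <- trace[seq_len(n_iter)]
  obj_trace <- obj_trace[seq_len(n_iter)]
  u <- fcm_memberships_d2(d2, params$m)
  t_ <- exp(-typ_coef * d2)
  obj <- upfc_objective(X, centroids, u, t_, beta, params)
  structure(list(centroids = centroids, u_fcm = u, u_pca = t_,
                 beta = beta, n_iter = n_iter,
                 objective = obj$objective,
                 data_term = obj$data_term,
                 data_term_trace = trace,
                 objective_trace = obj_trace,
                 params = params),
            class = "upfc")
}

#' @export
print.upfc <- function(x, ...) {
  cat("UPFC fit:", nrow(x$centroids), "clusters,",
      ncol(x$centroids), "features,", x$n_iter, "iterations\n")
  cat("beta =", format(x$beta), " objective =", format(x$objective), "\n")
  invisible(x)
}
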