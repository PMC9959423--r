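#' Cuckoo search configuration
#'
#' Settings of the cuckoo search over the number of clusters.  The
#' defaults are the full-scale study configuration: 30 nests, cluster
#' counts between 1000 and 2500, expected clustering accuracy 0.99,
#' Levy step scale 0.1 with exponent 1.5, discovery probability 0.25,
#' fitness tolerance 0.001 and at most 100 generations.  Tests and the
#' synthetic experiments shrink `bounds` and `n_nests` to desk scale.
#'
#' @param n_nests Number of host nests.
#' @param bounds Integer vector `c(lower, upper)` for the cluster count.
#' @param y_hat Expected (target) clustering accuracy; nest fitness is
#'   the squared error \eqn{(y_i - \hat y)^2}.
#' @param alpha Step-size scale of the Levy flights.
#' @param beta_levy Levy exponent, in (0, 2].
#' @param p_a Discovery probability: each non-best nest is abandoned and
#'   rebuilt with this probability per generation.
#' @param eps Stop when the best fitness falls below this tolerance.
#' @param t_max Maximum number of generations.
#' @param seed Integer seed controlling all randomness of the search.
#' @return List of class `cs_config`.
#' @export
cs_config <- function(n_nests = 30, bounds = c(1000, 2500), y_hat = 0.99,
                      alpha = 0.1, beta_levy = 1.5, p_a = 0.25,
                      eps = 0.001, t_max = 100, seed = NULL) {
  stopifnot(n_nests >= 1, length(bounds) == 2, bounds[1] <= bounds[2],
            beta_levy > 0, beta_levy <= 2, p_a >= 0, p_a <= 1,
            eps >= 0, t_max >= 0)
  structure(list(n_nests = as.integer(n_nests),
                 bounds = as.integer(round(bounds)), y_hat = y_hat,
                 alpha = alpha, beta_levy = beta_levy, p_a = p_a,
                 eps = eps, t_max = as.integer(t_max), seed = seed),
            class = "cs_config")
}

# Mantegna scale sigma_u for the Levy step numerator; sigma_v = 1.
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Levy-flight step (Mantegna's algorithm)
#'
#' Heavy-tailed random steps \eqn{u/|v|^{1/\beta}} with
#' \eqn{u \sim N(0, \sigma_u^2)}, \eqn{v \sim N(0, 1)} and
#' \eqn{\sigma_u} the Mantegna scale for Levy exponent `beta`.
#'
#' @param n Number of draws.
#' @param beta Levy exponent in (0, 2].
#' @return Numeric vector of `n` steps.
#' @export
levy_step <- function(n, beta = 1.5) {
  stopifnot(beta > 0, beta <= 2)
  u <- rnorm(n, sd = levy_sigma(beta))
  v <- rnorm(n)
  u / abs(v)^(1 / beta)
}

#' Propose a cuckoo solution from a nest
#'
#' New cluster count \eqn{\eta' = \mathrm{clamp}(\mathrm{round}(\eta +
#' s))} with step \eqn{s = \alpha(\eta - \eta_{best}) \cdot
#' \mathrm{Levy}(\beta)}.  The best nest itself takes a pure
#' \eqn{\alpha \cdot \mathrm{Levy}} step so the search never freezes at
#' the incumbent.
#'
#' @param eta Current nest value (integer cluster count).
#' @param eta_best Current best nest value.
#' @param cfg A [cs_config()].
#' @return Proposed integer cluster count within `cfg$bounds`.
#' @export
propose_cuckoo <- function(eta, eta_best, cfg) {
  lv <- levy_step(1, cfg$beta_levy)
  s <- if (eta == eta_best) cfg$alpha * lv else cfg$alpha * (eta - eta_best) * lv
  as.integer(min(max(round(eta + s), cfg$bounds[1]), cfg$bounds[2]))
}

#' Label clusters by majority vote
#'
#' Each training pixel is assigned to its nearest centroid; each
#' centroid takes the majority class of its pixels (ties broken by the
#' canonical class order).  Empty clusters inherit the label of the
#' nearest non-empty centroid.
#'
#' @param centroids Centroid matrix (or an `upfc` fit).
#' @param X Training feature matrix.
#' @param labels Ground-truth class labels of the rows of `X`.
#' @param scale_hue Feature convention flag stored in the result.
#' @return A [prototype_set()].
#' @export
label_clusters <- function(centroids, X, labels, scale_hue = TRUE) {
  if (inherits(centroids, "upfc")) centroids <- centroids$centroids
  centroids <- as.matrix(centroids)
  labels <- as.character(labels)
  d2 <- pairwise_sq_dists(as.matrix(X), centroids)
  assign <- max.col(-d2, ties.method = "first")
  lab_id <- match(labels, CLASS_LABELS)
  nC <- nrow(centroids)
  clab <- character(nC)
  for (j in seq_len(nC)) {
    in_j <- assign == j
    if (any(in_j)) {
      counts <- tabulate(lab_id[in_j], length(CLASS_LABELS))
      clab[j] <- CLASS_LABELS[which.max(counts)]
    }
  }
  empty <- clab == ""
  if (any(empty)) {
    full <- which(!empty)
    if (!length(full)) stop("no cluster received any pixel")
    dcc <- pairwise_sq_dists(centroids[empty, , drop = FALSE],
                             centroids[full, , drop = FALSE])
    clab[empty] <- clab[full][max.col(-dcc, ties.method = "first")]
  }
  prototype_set(centroids, clab, scale_hue = scale_hue)
}

#' Fitness of a candidate cluster count
#'
#' Trains UPFC with `eta` clusters on the training pixels, labels the
#' clusters by majority vote, classifies the validation pixels with
#' fuzzy k-NN (K = 1), and returns the squared deviation of the
#' resulting accuracy from the expected accuracy `y_hat`.
#'
#' @param eta Number of clusters.
#' @param x_train,y_train Training features and class labels.
#' @param x_val,y_val Validation features and class labels.
#' @param params `upfc_params`.
#' @param y_hat Expected accuracy.
#' @param seed Seed for the UPFC initialization.
#' @return List with `fitness`, `accuracy` and the trained `prototypes`.
#' @export
nest_fitness <- function(eta, x_train, y_train, x_val, y_val,
                         params = upfc_params(), y_hat = 0.99,
                         seed = NULL) {
  fit <- run_upfc(x_train, eta, params, seed = seed)
  ps <- label_clusters(fit$centroids, x_train, y_train)
  pred <- classify_batch(x_val, ps, k = 1)
  acc <- mean(pred == y_val)
  list(fitness = (acc - y_hat)^2, accuracy = acc, prototypes = ps)
}

#' Cuckoo search over an integer parameter
#'
#' Generic minimizer used for cluster-count selection.  Each nest holds
#' an integer in `cfg$bounds`; per generation every nest proposes a
#' cuckoo by a Levy-flight step (greedy replacement when the fitness
#' improves), then each non-best nest is abandoned and rebuilt uniformly
#' at random with probability `p_a`.  The incumbent best is never
#' abandoned (elitism), so the best fitness is non-increasing.  The
#' search stops when the best fitness drops below `cfg$eps` or after
#' `cfg$t_max` generations.
#'
#' @param fitness Function `(eta, nest_id, generation)` returning a list
#'   with at least `fitness`; extra elements (e.g. trained prototypes)
#'   are carried along with the best solution.
#' @param cfg A [cs_config()].
#' @return List with `best` (the best evaluation, plus `eta`), `trace`
#'   (data frame: generation, best_eta, best_fitness, n_rebuilt) and
#'   `n_evals`.
#' @export
cuckoo_search <- function(fitness, cfg = cs_config()) {
  with_seed(cfg$seed, {
    lo <- cfg$bounds[1]; up <- cfg$bounds[2]
    etas <- as.integer(sample(seq(lo, up), cfg$n_nests, replace = TRUE))
    evals <- vector("list", cfg$n_nests)
    n_evals <- 0L
    for (i in seq_len(cfg$n_nests)) {
      evals[[i]] <- fitness(etas[i], i, 0L)
      n_evals <- n_evals + 1L
    }
    fit <- vapply(evals, `[[`, numeric(1), "fitness")
    best_i <- which.min(fit)
    best <- c(evals[[best_i]], list(eta = etas[best_i]))
    trace <- data.frame(generation = 0L, best_eta = etas[best_i],
                        best_fitness = fit[best_i], n_rebuilt = 0L)
    t <- 0L
    while (t < cfg$t_max && best$fitness >= cfg$eps) {
      t <- t + 1L
      # Levy-flight cuckoo proposals with greedy replacement
      for (i in seq_len(cfg$n_nests)) {
        cand <- propose_cuckoo(etas[i], best$eta, cfg)
        if (cand == etas[i]) next
        ev <- fitness(cand, i, t)
        n_evals <- n_evals + 1L
        if (ev$fitness < fit[i]) {
          etas[i] <- cand; evals[[i]] <- ev; fit[i] <- ev$fitness
          if (ev$fitness < best$fitness) best <- c(ev, list(eta = cand))
        }
      }
      # abandon a fraction p_a of the nests (elite nest protected)
      cur_best <- which.min(fit)
      rebuild <- runif(cfg$n_nests) < cfg$p_a
      rebuild[cur_best] <- FALSE
      for (i in which(rebuild)) {
        etas[i] <- as.integer(sample(seq(lo, up), 1))
        ev <- fitness(etas[i], i, t)
        n_evals <- n_evals + 1L
        evals[[i]] <- ev; fit[i] <- ev$fitness
        if (ev$fitness < best$fitness) best <- c(ev, list(eta = etas[i]))
      }
      trace <- rbind(trace, data.frame(
        generation = t, best_eta = best$eta,
        best_fitness = best$fitness, n_rebuilt = sum(rebuild)))
    }
    list(best = best, trace = trace, n_evals = n_evals)
  })
}

#' Train labeled multi-prototypes by cuckoo-search model selection
#'
#' Runs [cuckoo_search()] where each nest trains UPFC on the training
#' pixels and is scored by fuzzy k-NN (K = 1) accuracy on the validation
#' pixels (see [nest_fitness()]).  UPFC initializations use seeds
#' derived from `(cfg$seed, nest, generation)` for reproducibility.
#'
#' @param x_train,y_train Training features (matrix) and labels.
#' @param x_val,y_val Validation features and labels.
#' @param cfg A [cs_config()].
#' @param params `upfc_params`.
#' @return List with `prototypes` (best [prototype_set()]), `accuracy`,
#'   `eta`, `fitness`, `trace`, `n_evals`.
#' @export
run_cuckoo_search <- function(x_train, y_train, x_val, y_val,
                              cfg = cs_config(), params = upfc_params()) {
  if (nrow(as.matrix(x_train)) == 0L) stop("empty training pixel set")
  if (length(unique(y_train)) < 2L)
    stop("training pixels must cover at least two classes")
  fitness <- function(eta, nest_id, generation) {
    nest_fitness(eta, x_train, y_train, x_val, y_val, params,
                 y_hat = cfg$y_hat,
                 seed = derive_seed(cfg$seed %||% 0, nest_id, generation))
  }
  res <- cuckoo_search(fitness, cfg)
  list(prototypes = res$best$prototypes, accuracy = res$best$accuracy,
       eta = res$best$eta, fitness = res$best$fitness,
       trace = res$trace, n_evals = res$n_evals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated prototype training
#'
#' Splits the labeled pixels into `k_folds` folds (sizes differing by at
#' most one).  Following the study protocol, each round trains on ONE
#' fold and validates on the remaining folds (the inverse of textbook
#' cross-validation, chosen because prototype training scales with the
#' training-set size).  Returns the per-fold validation accuracies and
#' the prototype set of the best fold.
#'
#' @param X Labeled pixel feature matrix.
#' @param labels Class labels for the rows of `X`.
#' @param cfg A [cs_config()]; its `seed` drives the fold assignment and
#'   all searches.
#' @param params `upfc_params`.
#' @param k_folds Number of folds (>= 2), default 10.
#' @return List with `fold_accuracy`, `mean_accuracy`, `best_fold`,
#'   `prototypes` (best fold's), and `fold_id` (per-row fold labels).
#' @export
cross_validate <- function(X, labels, cfg = cs_config(),
                           params = upfc_params(), k_folds = 10) {
  stopifnot(k_folds >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  fold_id <- with_seed(derive_seed(cfg$seed %||% 0, 7L),
                       sample(rep_len(seq_len(k_folds), n)))
  acc <- numeric(k_folds)
  best <- NULL
  for (f in seq_len(k_folds)) {
    tr <- fold_id == f
    if (length(unique(labels[tr])) < length(unique(labels)))
      warning("fold ", f, " does not contain every class")
    fcfg <- cfg
    fcfg$seed <- derive_seed(cfg$seed %||% 0, 11L, f)
    res <- run_cuckoo_search(X[tr, , drop = FALSE], labels[tr],
                             X[!tr, , drop = FALSE], labels[!tr],
                             fcfg, params)
    acc[f] <- res$accuracy
    if (is.null(best) || res$accuracy > best$accuracy)
      best <- c(res, list(fold = f))
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       best_fold = best$fold, prototypes = best$prototypes,
       best_accuracy = best$accuracy, fold_id = fold_id)
}
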