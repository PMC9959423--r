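test_that("Mantegna scale matches its closed form", {
  # frozen from the gamma-function expression evaluated independently
  expect_equal(fluoroseg:::levy_sigma(1.5), 0.696574502557697,
               tolerance = 1e-12)
  expect_equal(fluoroseg:::levy_sigma(1), 1, tolerance = 1e-12)
})

test_that("Levy steps are heavy-tailed but finite", {
  set.seed(71)
  s <- levy_step(1e5, beta = 1.5)
  expect_true(all(is.finite(s)))
  med <- median(abs(s))
  expect_gt(med, 0)
  expect_gt(max(abs(s)), 50 * med)  # heavy tail
  expect_error(levy_step(10, beta = 3), "beta")
})

test_that("cuckoo proposals stay integral and within bounds", {
  cfg <- cs_config(bounds = c(20, 120), seed = 1)
  set.seed(81)
  for (i in 1:1000) {
    eta <- sample(20:120, 1)
    p <- propose_cuckoo(eta, 70, cfg)
    expect_true(p >= 20 && p <= 120 && p == round(p))
  }
  # the best nest takes a pure Levy step and can still move
  set.seed(82)
  moved <- replicate(200, propose_cuckoo(70, 70, cfg)) != 70
  expect_true(any(moved))
})

test_that("majority-vote labeling handles majorities, ties and empties", {
  X <- matrix(c(0, 0.1, 0.2, 0.3, 5, 5.1), 6, 1)
  X <- cbind(X, matrix(0, 6, 5))
  cents <- rbind(c(0.15, rep(0, 5)), c(5.05, rep(0, 5)), c(20, rep(0, 5)))
  lab <- c("white", "white", "white", "yellow", "brown", "brown")
  ps <- label_clusters(cents, X, lab)
  # cluster 1: 3 white vs 1 yellow -> white; cluster 2: brown;
  # cluster 3 empty -> label of nearest non-empty centroid (brown)
  expect_setequal(ps$labels, c("white", "brown", "brown"))
})

test_that("labeling recovers all five classes on separated blobs", {
  pix <- small_pixels(model = separated_model(), seed = 12)
  fit <- run_upfc(pix$x, 5, seed = 1)
  ps <- label_clusters(fit$centroids, pix$x, pix$labels)
  expect_setequal(unique(ps$labels), class_labels())
})

test_that("nest fitness is the squared accuracy error", {
  # arithmetic check against its definition
  expect_equal((0.9196 - 0.99)^2, 0.00495616, tolerance = 1e-10)
  pix <- small_pixels(model = separated_model(), seed = 13)
  set.seed(14)
  tr <- sample(nrow(pix$x)) <= 300
  r <- nest_fitness(8, pix$x[tr, ], pix$labels[tr],
                    pix$x[!tr, ], pix$labels[!tr], seed = 15)
  expect_equal(r$fitness, (r$accuracy - 0.99)^2)
  expect_s3_class(r$prototypes, "prototype_set")
  # fitness invariant under permutation of the validation pixels
  perm <- sample(sum(!tr))
  r2 <- nest_fitness(8, pix$x[tr, ], pix$labels[tr],
                     pix$x[!tr, ][perm, ], pix$labels[!tr][perm], seed = 15)
  expect_equal(r2$fitness, r$fitness)
})

test_that("cuckoo search is elitist and recovers a toy optimum", {
  toy <- function(eta, nest, gen)
    list(fitness = (0.99 - 0.002 * abs(eta - 8) - 0.99)^2)
  hits <- 0
  for (s in 1:20) {
    r <- cuckoo_search(toy, cs_config(n_nests = 10, bounds = c(2, 20),
                                      t_max = 50, eps = 0, seed = s))
    hits <- hits + (r$best$eta == 8)
    expect_true(all(diff(r$trace$best_fitness) <= 1e-15))
  }
  expect_gte(hits, 18)
})

test_that("t_max = 0 returns the best of the initial population", {
  calls <- new.env(); calls$gens <- integer(0)
  f <- function(eta, nest, gen) {
    calls$gens <- c(calls$gens, gen)
    list(fitness = abs(eta - 11))
  }
  r <- cuckoo_search(f, cs_config(n_nests = 8, bounds = c(2, 30),
                                  t_max = 0, seed = 3))
  expect_true(all(calls$gens == 0L))
  expect_equal(nrow(r$trace), 1L)
  expect_equal(r$n_evals, 8L)
})

test_that("abandonment rebuilds about p_a of the nests per generation", {
  r <- cuckoo_search(function(e, n, g) list(fitness = 0.5 + runif(1)),
                     cs_config(n_nests = 20, bounds = c(2, 50),
                               t_max = 200, eps = 0, p_a = 0.25, seed = 4))
  reb <- r$trace$n_rebuilt[-1]
  # binomial(19, 0.25) per generation (elite nest protected)
  expected <- 0.25 * 19
  band <- 3 * sqrt(19 * 0.25 * 0.75 / length(reb))
  expect_lt(abs(mean(reb) - expected), band)
  expect_true(all(reb <= 19))
})

test_that("cross-validation folds partition the data and recover classes", {
  pix <- small_pixels(model = separated_model(), seed = 16)
  cfg <- cs_config(n_nests = 4, bounds = c(8, 25), t_max = 2, seed = 17)
  cv <- cross_validate(pix$x, pix$labels, cfg, k_folds = 3)
  sizes <- table(cv$fold_id)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), nrow(pix$x))
  expect_length(cv$fold_accuracy, 3)
  expect_gt(cv$mean_accuracy, 0.95)
  # deterministic given the seed
  cv2 <- cross_validate(pix$x, pix$labels, cfg, k_folds = 3)
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
})

test_that("selected prototypes classify held-out separated pixels well", {
  pix <- small_pixels(model = separated_model(), seed = 18)
  set.seed(19)
  tr <- sample(rep_len(1:4, nrow(pix$x))) == 1
  cfg <- cs_config(n_nests = 5, bounds = c(10, 40), t_max = 3, seed = 20)
  res <- run_cuckoo_search(pix$x[tr, ], pix$labels[tr],
                           pix$x[!tr, ], pix$labels[!tr], cfg)
  hold <- small_pixels(model = separated_model(), seed = 21)
  acc <- mean(classify_batch(hold$x, res$prototypes) == hold$labels)
  expect_gte(acc, 0.95)
  expect_true(res$eta >= 10 && res$eta <= 40)
  expect_error(run_cuckoo_search(pix$x[tr, ][0, , drop = FALSE],
                                 character(0), pix$x, pix$labels, cfg),
               "empty")
})
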