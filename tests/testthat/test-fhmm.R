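test_that("L2 distance matches closed-form integrals", {
  g <- seq(0, 1, length.out = 1001)
  x <- rep(1, 1001); z <- rep(0, 1001)
  expect_equal(l2_distance(x, x, g), 0)
  expect_equal(l2_distance(x, z, g), 1)
  # integral of t^2 over [0,1] = 1/3
  expect_equal(l2_distance(g, z, g), sqrt(1 / 3), tolerance = 1e-5)
  expect_error(l2_distance(1:3, 1:4, seq(0, 1, length.out = 4)), "length")
})

test_that("emission transforms distance into a regularised similarity", {
  g <- c(0, 1)
  # constant curves differing by c have L2 distance c on a unit domain
  expect_equal(emission(c(2, 2), c(0, 0), g, 1e-15), 0.25, tolerance = 1e-10)
  expect_equal(emission(c(1, 1), c(0, 0), g, 1e-15), 1, tolerance = 1e-10)
  expect_equal(emission(c(1, 1), c(1, 1), g, 1e-12), 1e12)
  expect_error(emission(c(1, 1), c(1, 1), g, 0), "positive")
})

test_that("forward-backward matches brute-force path summation on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    N <- sample(2:3, 1); K <- sample(2:6, 1)
    inst <- random_instance(N, K)
    em <- emission_matrix(inst$curves, inst$model)
    fb <- forward_backward(inst$curves, inst$model)
    expect_equal(fb$log_pseudo_likelihood,
                 bf_log_likelihood(em, inst$model$init, inst$model$trans),
                 tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, K), tolerance = 1e-8)
    if (K > 1)
      expect_equal(apply(fb$xi, 1, sum), rep(1, K - 1), tolerance = 1e-8)
  }
})

test_that("single-state and exchangeable models give degenerate posteriors", {
  g <- seq(0, 1, length.out = 8)
  m1 <- fhmm_model(1, matrix(1, 1, 1), matrix(rnorm(8), 1), g)
  curves <- matrix(rnorm(40), 5)
  fb <- forward_backward(curves, m1)
  em <- emission_matrix(curves, m1)
  expect_equal(fb$log_pseudo_likelihood, sum(log(em)), tolerance = 1e-10)
  expect_true(all(fb$gamma == 1))

  # identical centroids, uniform everything -> gamma = 1/N by exchangeability
  mu <- rep(0.3, 8)
  m2 <- fhmm_model(rep(1 / 3, 3), matrix(1 / 3, 3, 3), rbind(mu, mu, mu), g)
  fb2 <- forward_backward(curves, m2)
  expect_equal(fb2$gamma, matrix(1 / 3, 5, 3), tolerance = 1e-12)
})

test_that("viterbi equals the enumerated argmax and respects forbidden transitions", {
  set.seed(7)
  for (rep in 1:100) {
    N <- sample(2:3, 1); K <- sample(2:6, 1)
    inst <- random_instance(N, K)
    vp <- viterbi(inst$curves, inst$model)
    em <- emission_matrix(inst$curves, inst$model)
    oracle <- bf_viterbi(em, inst$model$init, inst$model$trans)
    expect_equal(vp$path_log_score, oracle$score, tolerance = 1e-10)
    expect_identical(vp$states, oracle$states)
  }

  g <- seq(0, 1, length.out = 6)
  m1 <- fhmm_model(1, matrix(1, 1, 1), matrix(0, 1, 6), g)
  expect_identical(viterbi(matrix(rnorm(18), 3), m1)$states, rep(1L, 3))
  # absorbing start state 2: identity transitions forbid any switch
  m2 <- fhmm_model(c(0, 1), diag(2), rbind(rep(0, 6), rep(5, 6)), g)
  curves <- matrix(rnorm(24), 4)  # emissions favour state 1, path cannot move
  expect_identical(viterbi(curves, m2)$states, rep(2L, 4))
})

test_that("viterbi score dominates random alternative paths", {
  set.seed(13)
  inst <- random_instance(3, 10)
  vp <- viterbi(inst$curves, inst$model)
  em <- emission_matrix(inst$curves, inst$model)
  lognu <- log(inst$model$init); logA <- log(inst$model$trans)
  for (r in 1:100) {
    p <- sample(1:3, 10, replace = TRUE)
    v <- lognu[p[1]] + log(em[1, p[1]])
    for (k in 2:10) v <- v + logA[p[k - 1], p[k]] + log(em[k, p[k]])
    expect_gte(vp$path_log_score, v)
  }
})

test_that("Baum-Welch objective is nondecreasing and keeps valid distributions", {
  truth <- truth_model_4()
  sim <- simulate_fhmm_dataset(truth, 8, 40, noise_sd = 0.15, seed = 19)
  N <- 4
  km <- functional_kmeans(sim$dataset$curves, N, truth$grid, seed = 2)
  init <- fhmm_model(rep(1 / N, N), matrix(1 / N, N, N), km$centroids,
                     truth$grid)
  fit <- baum_welch(sim$dataset, init, max_iter = 40)
  expect_true(all(diff(fit$history) > -1e-9))
  expect_equal(sum(fit$model$init), 1, tolerance = 1e-10)
  expect_equal(rowSums(fit$model$trans), rep(1, N), tolerance = 1e-10)
  expect_true(all(fit$model$init >= 0) && all(fit$model$trans >= 0))
})

test_that("noiseless truth is a Baum-Welch fixed point after one step", {
  truth <- truth_model_4()
  sim <- simulate_fhmm_dataset(truth, 6, 25, noise_sd = 0, seed = 29)
  one <- baum_welch(sim$dataset, truth, max_iter = 1)
  # centroids stay at the truth exactly; chain parameters move to the
  # empirical path frequencies on step one and are then fixed
  expect_equal(one$model$centroids, truth$centroids, tolerance = 1e-10)
  two <- baum_welch(sim$dataset, one$model, max_iter = 1)
  expect_equal(two$model$centroids, one$model$centroids, tolerance = 1e-8)
  expect_equal(two$model$trans, one$model$trans, tolerance = 1e-8)
  expect_equal(two$model$init, one$model$init, tolerance = 1e-8)
})

test_that("fitting is equivariant under a permutation of the initial labels", {
  truth <- truth_model_4()
  sim <- simulate_fhmm_dataset(truth, 5, 30, noise_sd = 0.12, seed = 37)
  N <- 4
  km <- functional_kmeans(sim$dataset$curves, N, truth$grid, seed = 3)
  init1 <- fhmm_model(rep(1 / N, N), matrix(1 / N, N, N), km$centroids,
                      truth$grid)
  perm <- c(3, 1, 4, 2)
  init2 <- fhmm_model(init1$init[perm], init1$trans[perm, perm],
                      init1$centroids[perm, ], truth$grid)
  f1 <- baum_welch(sim$dataset, init1, max_iter = 15)
  f2 <- baum_welch(sim$dataset, init2, max_iter = 15)
  expect_equal(f1$history, f2$history, tolerance = 1e-8)
  inv <- order(perm)
  expect_equal(f2$model$centroids, f1$model$centroids[perm, ],
               tolerance = 1e-8)
  expect_equal(f2$model$trans, f1$model$trans[perm, perm], tolerance = 1e-8)
})

test_that("functional k-means finds bundle means and handles degenerate input", {
  g <- seq(0, 1, length.out = 20)
  set.seed(5)
  # k = 1: centroid is the pointwise mean
  X <- matrix(rnorm(200), 10)
  km1 <- functional_kmeans(X, 1, g, seed = 1)
  expect_equal(as.numeric(km1$centroids), colMeans(X), tolerance = 1e-12)

  # two tight far-apart bundles
  b1 <- matrix(rnorm(300, 0, 0.05), 15, 20)
  b2 <- matrix(rnorm(300, 10, 0.05), 15, 20)
  km2 <- functional_kmeans(rbind(b1, b2), 2, g, seed = 4)
  cents <- km2$centroids[order(km2$centroids[, 1]), ]
  expect_lt(max(abs(cents[1, ] - colMeans(b1))), 0.06)
  expect_lt(max(abs(cents[2, ] - colMeans(b2))), 0.06)

  # identical curves: all centroids coincide, objective zero
  same <- matrix(rep(sin(g), 6), 6, byrow = TRUE)
  km3 <- functional_kmeans(same, 3, g, seed = 6)
  expect_equal(km3$objective, 0)
  for (r in 1:3) expect_equal(as.numeric(km3$centroids[r, ]), sin(g))

  expect_error(functional_kmeans(X, 11, g, seed = 1), "exceeds")
})

test_that("state relabelling orders by allocation and preserves invariants", {
  truth <- truth_model_4()
  sim <- simulate_fhmm_dataset(truth, 6, 30, noise_sd = 0.1, seed = 41)
  paths <- decode_states(sim$dataset, truth)
  rl <- relabel_states(truth, paths)
  alloc <- tabulate(unlist(lapply(rl$paths, `[[`, "states")), 4)
  expect_true(all(diff(alloc) <= 0))
  expect_equal(sort(alloc), sort(tabulate(unlist(lapply(paths, `[[`, "states")), 4)))
  # log pseudo-likelihood invariant under the relabelling
  ll_before <- sum(vapply(split_series(sim$dataset), function(s)
    forward_backward(s$curves, truth)$log_pseudo_likelihood, 0))
  ll_after <- sum(vapply(split_series(sim$dataset), function(s)
    forward_backward(s$curves, rl$model)$log_pseudo_likelihood, 0))
  expect_equal(ll_before, ll_after, tolerance = 1e-8)
  # idempotent: already ordered -> identity permutation
  rl2 <- relabel_states(rl$model, rl$paths)
  expect_identical(rl2$permutation, 1:4)
})
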