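test_that("state subsets select exactly the decoded curves and partition the data", {
  truth <- truth_model_4()
  sim <- simulate_fhmm_dataset(truth, 5, 12, noise_sd = 0.1, seed = 71)
  # constant path: subset for state 1 is everything, state 2 empty
  const_paths <- lapply(split_series(sim$dataset), function(s)
    structure(list(individual_id = s$individual_id,
                   states = rep(1L, nrow(s$curves)),
                   path_log_score = 0), class = "viterbi_path"))
  sub1 <- subset_by_state(sim$dataset, const_paths, 1)
  expect_equal(nrow(sub1$curves), nrow(sim$dataset$curves))
  expect_equal(nrow(subset_by_state(sim$dataset, const_paths, 2)$curves), 0L)

  # decoded paths partition the dataset with no duplicates
  paths <- decode_states(sim$dataset, truth)
  tot <- 0
  for (s in 1:4) tot <- tot + nrow(subset_by_state(sim$dataset, paths, s)$curves)
  expect_equal(tot, nrow(sim$dataset$curves))

  # time provenance follows the path
  p <- list(structure(list(individual_id = "sim001",
                           states = c(1L, 2L, 1L),
                           path_log_score = 0), class = "viterbi_path"))
  d3 <- functional_dataset(truth$grid, sim$dataset$curves[1:3, ],
                           data.frame(individual_id = "sim001", time_index = 1:3))
  s1 <- subset_by_state(d3, p, 1)
  expect_equal(s1$provenance$time_index, c(1L, 3L))
})

test_that("degenerate inputs give degenerate spectra", {
  g <- default_psd_grid()
  same <- matrix(rep(sin(g / 4), 10), 10, byrow = TRUE)
  # zero variance: the retention rule cannot reach its threshold and says so
  expect_warning(
    m <- fit_fpca(same, bspline_basis(g, n_basis = length(g)), penalty = 0),
    "never exceeds")
  expect_equal(m$mean_function, sin(g / 4), tolerance = 1e-8)
  expect_lt(max(m$eigenvalues), 1e-16)
  expect_lt(max(abs(m$scores)), 1e-6)

  # two mirror-symmetric curves: rank-1 covariance
  delta <- cos(g / 5)
  two <- rbind(sin(g / 4) + delta, sin(g / 4) - delta)
  m2 <- fit_fpca(two, grid = g, penalty = 0)
  expect_equal(m2$variance_fractions[1], 1, tolerance = 1e-8)
  expect_lt(m2$eigenvalues[2] / m2$eigenvalues[1], 1e-8)
})

test_that("FPCA recovers planted eigenfunctions and variance shares", {
  g <- default_psd_grid()
  w <- trapezoid_weights(g)
  phi1 <- sin(2 * pi * (g - 1.5) / 28.5)
  phi1 <- phi1 / sqrt(sum(w * phi1^2))
  phi2 <- cos(2 * pi * (g - 1.5) / 28.5)
  phi2 <- phi2 - sum(w * phi1 * phi2) * phi1
  phi2 <- phi2 / sqrt(sum(w * phi2^2))
  set.seed(4)
  a1 <- rnorm(500, 0, 2); a2 <- rnorm(500, 0, 1)
  X <- outer(rep(1, 500), cos(g / 5)) + outer(a1, phi1) + outer(a2, phi2)
  m <- fit_fpca(X, grid = g, penalty = 1e-4)
  expect_equal(m$variance_fractions[1], 0.8, tolerance = 0.03)
  expect_equal(m$variance_fractions[2], 0.2, tolerance = 0.03)
  err1 <- min(sqrt(sum(w * (m$eigenfunctions[1, ] - phi1)^2)),
              sqrt(sum(w * (m$eigenfunctions[1, ] + phi1)^2)))
  err2 <- min(sqrt(sum(w * (m$eigenfunctions[2, ] - phi2)^2)),
              sqrt(sum(w * (m$eigenfunctions[2, ] + phi2)^2)))
  expect_lt(err1, 0.05)
  expect_lt(err2, 0.05)
})

test_that("eigenfunctions are orthonormal and eigenvalues sorted on every fit", {
  g <- default_psd_grid()
  w <- trapezoid_weights(g)
  set.seed(8)
  for (r in 1:5) {
    X <- matrix(rnorm(30 * length(g)), 30) + outer(rnorm(30), sin(g / 3))
    m <- fit_fpca(X, grid = g, penalty = 10^runif(1, -5, -2))
    k <- min(8, nrow(m$eigenfunctions))
    Phi <- m$eigenfunctions[1:k, ]
    gram <- Phi %*% (w * t(Phi))
    expect_lt(max(abs(gram - diag(k))), 1e-6)
    expect_true(all(diff(m$eigenvalues) <= 1e-10))
    expect_true(all(m$eigenvalues >= 0))
    expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-8)
  }
})

test_that("saturated unpenalised FPCA reduces to classical PCA of the discretised curves", {
  g <- default_psd_grid()  # uniform spacing
  w <- trapezoid_weights(g)
  set.seed(2)
  X <- matrix(rnorm(40 * length(g)), 40) + outer(rep(1, 40), sin(g / 3))
  m <- fit_fpca(X, bspline_basis(g, n_basis = length(g)), penalty = 0)
  # classical PCA scores of the quadrature-scaled data (sqrt(h) scaling on
  # the uniform interior) -- an independent route with no basis expansion
  pc <- prcomp(sweep(X, 2, sqrt(w), "*"), center = TRUE)
  k <- 10
  expect_equal(m$eigenvalues[1:k], unname(pc$sdev[1:k]^2), tolerance = 1e-6)
  sc <- pc$x[, 1:5]
  for (j in 1:5) if (sum(sc[, j] * m$scores[, j]) < 0) sc[, j] <- -sc[, j]
  expect_lt(max(abs(m$scores[, 1:5] - sc)), 1e-6)
})

test_that("component retention implements the strict cumulative rule", {
  expect_equal(choose_n_components(c(0.4, 0.25, 0.10, 0.08, 0.05))$n_components, 3L)
  expect_equal(choose_n_components(c(0.71, 0.2, 0.09))$n_components, 1L)
  # five-component EEG-style spectrum: 22.6 + 17.1 + 13.6 + 11.5 + 7.8 = 72.6
  fr <- c(0.226, 0.171, 0.136, 0.115, 0.078)
  res <- choose_n_components(fr, threshold = 0.70)
  expect_equal(res$n_components, 5L)
  expect_equal(res$cumulative, 0.726, tolerance = 1e-12)
  expect_warning(out <- choose_n_components(c(0.1, 0.1), threshold = 0.7),
                 "never exceeds")
  expect_equal(out$n_components, 2L)
  expect_error(choose_n_components(c(0.5, 1.2)), "0, 1")
})

test_that("score projection is exact on training data and respects orthonormality", {
  g <- default_psd_grid()
  set.seed(14)
  X <- matrix(rnorm(50 * length(g)), 50) + outer(rnorm(50, 0, 2), sin(g / 4))
  m <- fit_fpca(X, grid = g, penalty = 1e-4, n_components = 4)
  expect_equal(project_scores(m, X), m$scores[, 1:4], tolerance = 1e-8)
  expect_equal(as.numeric(project_scores(m, m$mean_function)), rep(0, 4),
               tolerance = 1e-8)
  shifted <- m$mean_function + 2 * m$eigenfunctions[1, ]
  expect_equal(as.numeric(project_scores(m, shifted)), c(2, 0, 0, 0),
               tolerance = 1e-8)
  expect_error(project_scores(m, matrix(0, 1, 3)), "grid")
})

test_that("reconstruction error is nonincreasing in the number of components", {
  g <- default_psd_grid()
  w <- trapezoid_weights(g)
  set.seed(16)
  X <- matrix(rnorm(30 * length(g), 0, 0.3), 30) +
    outer(rnorm(30), sin(g / 3)) + outer(rnorm(30), cos(g / 6))
  m <- fit_fpca(X, grid = g, penalty = 1e-4, n_components = 10)
  errs <- vapply(1:10, function(C) {
    Phi <- m$eigenfunctions[1:C, , drop = FALSE]
    recon <- outer(rep(1, 30), m$mean_function) + m$scores[, 1:C, drop = FALSE] %*% Phi
    sum(sqrt(rowSums(sweep((X - recon)^2, 2, w, "*"))))
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("per-individual scores aggregate by the arithmetic mean, order-invariantly", {
  g <- default_psd_grid()
  set.seed(18)
  X <- matrix(rnorm(12 * length(g)), 12) + outer(rnorm(12), sin(g / 3))
  m <- fit_fpca(X, grid = g, penalty = 1e-4, n_components = 2)
  ids <- rep(c("a", "b", "c"), each = 4)
  tab <- individual_mean_scores(m, ids, n_components = 2)
  expect_equal(tab$fpc_score_1[tab$individual_id == "b"],
               mean(m$scores[5:8, 1]))
  # single observation per individual: score passes through
  m1 <- fit_fpca(X[1:3, ], grid = g, penalty = 1e-4, n_components = 1)
  t1 <- individual_mean_scores(m1, c("x", "y", "z"), n_components = 1)
  expect_equal(t1$fpc_score_1, as.numeric(m1$scores[, 1]))
  # permutation invariance
  perm <- sample(12)
  m2 <- m; m2$scores <- m$scores[perm, ]
  tab2 <- individual_mean_scores(m2, ids[perm], n_components = 2)
  expect_equal(tab, tab2)
})
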