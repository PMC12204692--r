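test_that("centroid curves are Gaussian sums with validated peak centers", {
  grid <- default_psd_grid()
  one <- make_psd_centroids(grid, 1, list(rbind(c(10, 1, 1))))
  expect_equal(grid[which.max(one[1, ])], 10)
  expect_equal(max(one[1, ]), 1, tolerance = 1e-12)

  flat <- make_psd_centroids(grid, 2, list(rbind(c(10, 1, 1)), NULL))
  expect_true(all(flat[2, ] == 0))

  expect_error(make_psd_centroids(grid, 1, list(rbind(c(40, 1, 1)))),
               "outside the grid range")

  preset <- make_psd_centroids(grid, 4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(l2_distance(preset[i, ], preset[j, ], grid), 0)
})

test_that("simulated paths follow the Markov chain and emissions the centroids", {
  grid <- seq(0, 1, length.out = 10)
  cent <- rbind(rep(1, 10), rep(-1, 10))
  # deterministic chain stuck in state 1
  m1 <- fhmm_model(c(1, 0), diag(2), cent, grid)
  sim <- simulate_fhmm_dataset(m1, 5, 12, noise_sd = 0.2, seed = 3)
  for (p in sim$truth$paths) expect_equal(p, rep(1L, 12))

  # zero noise collapses emissions onto centroids
  m2 <- fhmm_model(c(.5, .5), matrix(.5, 2, 2), cent, grid)
  sim0 <- simulate_fhmm_dataset(m2, 4, 8, noise_sd = 0, seed = 9)
  states <- sim0$dataset$meta$true_state
  expect_equal(sim0$dataset$curves, cent[states, ], tolerance = 0)

  expect_error(simulate_fhmm_dataset(m2, 3, 5, noise_sd = -1, seed = 1),
               "nonnegative")
  expect_error(simulate_fhmm_dataset(m2, 3, 0, noise_sd = 0, seed = 1),
               "at least 1")
})

test_that("empirical transition frequencies converge to the transition matrix", {
  grid <- seq(0, 1, length.out = 5)
  A <- rbind(c(0.7, 0.3), c(0.3, 0.7))
  m <- fhmm_model(c(.5, .5), A, rbind(rep(0, 5), rep(1, 5)), grid)
  sim <- simulate_fhmm_dataset(m, 200, 100, noise_sd = 0, seed = 21)
  counts <- matrix(0, 2, 2)
  for (p in sim$truth$paths)
    for (k in 2:length(p)) counts[p[k - 1], p[k]] <- counts[p[k - 1], p[k]] + 1
  emp <- counts / rowSums(counts)
  expect_lt(max(abs(emp - A)), 0.02)
})

test_that("long-run state occupancy matches the stationary distribution", {
  grid <- seq(0, 1, length.out = 5)
  A <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  statio <- c(2, 1) / 3  # solves pi A = pi
  m <- fhmm_model(c(.5, .5), A, rbind(rep(0, 5), rep(1, 5)), grid)
  sim <- simulate_fhmm_dataset(m, 40, 500, noise_sd = 0, seed = 31)
  occ <- tabulate(unlist(sim$truth$paths), 2)
  expect_lt(max(abs(occ / sum(occ) - statio)), 0.02)
})

test_that("identical seeds reproduce identical datasets bit for bit", {
  m <- truth_model_4()
  a <- simulate_fhmm_dataset(m, 6, 10, noise_sd = 0.1, seed = 77)
  b <- simulate_fhmm_dataset(m, 6, 10, noise_sd = 0.1, seed = 77)
  expect_identical(a$dataset$curves, b$dataset$curves)
  expect_identical(a$truth$paths, b$truth$paths)
  c <- simulate_fhmm_dataset(m, 6, 10, noise_sd = 0.1, seed = 78)
  expect_false(identical(a$dataset$curves, c$dataset$curves))
})

test_that("raw PSD simulation follows the aperiodic + Gaussian construction", {
  expect_equal(simulate_raw_psd(c(1, 10), 1, 1, NULL, 0)[2], 0)
  g <- default_psd_grid()
  expect_equal(simulate_raw_psd(g, 2.5, 0, NULL, 0), rep(2.5, length(g)))
  with_pk <- simulate_raw_psd(g, 1, 1, rbind(c(10, 0.5, 1.5)), 0)
  aper <- 1 - log10(g)
  expect_equal(with_pk - aper, 0.5 * exp(-(g - 10)^2 / (2 * 1.5^2)),
               tolerance = 1e-12)
  expect_error(simulate_raw_psd(c(-1, 2), 1, 1), "positive")
})
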