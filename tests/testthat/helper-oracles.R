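# Independent oracles and small fixtures shared across tests.

# Brute-force log pseudo-likelihood: explicit sum over all N^K state paths.
bf_log_likelihood <- function(em, init, trans) {
  K <- nrow(em); N <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), K)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    v <- init[p[1]] * em[1, p[1]]
    if (K > 1) for (k in 2:K) v <- v * trans[p[k - 1], p[k]] * em[k, p[k]]
    total <- total + v
  }
  log(total)
}

# Brute-force MAP path: enumerate all N^K paths, argmax of the log score.
bf_viterbi <- function(em, init, trans) {
  K <- nrow(em); N <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), K)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    v <- log(init[p[1]]) + log(em[1, p[1]])
    if (K > 1) for (k in 2:K) v <- v + log(trans[p[k - 1], p[k]]) + log(em[k, p[k]])
    if (v > best) { best <- v; best_path <- p }
  }
  list(states = as.integer(best_path), score = best)
}

# Random valid HMM instance on a small grid.
random_instance <- function(N, K, G = 6) {
  grid <- seq(0, 1, length.out = G)
  init <- runif(N); init <- init / sum(init)
  trans <- matrix(runif(N * N), N); trans <- trans / rowSums(trans)
  model <- fhmm_model(init, trans, matrix(rnorm(N * G), N), grid)
  curves <- matrix(rnorm(K * G), K)
  list(model = model, curves = curves, grid = grid)
}

# Well-separated 4-state generating model on the default PSD grid.
truth_model_4 <- function(self_transition = 0.95) {
  grid <- default_psd_grid()
  mu <- make_psd_centroids(grid, 4)
  A <- matrix((1 - self_transition) / 3, 4, 4)
  diag(A) <- self_transition
  fhmm_model(rep(0.25, 4), A, mu, grid)
}

# Minimum pairwise L2 distance among a model's centroids.
min_pairwise_centroid_dist <- function(model) {
  N <- model$n_states
  d <- c()
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    d <- c(d, l2_distance(model$centroids[i, ], model$centroids[j, ], model$grid))
  min(d)
}

# Match estimated states to true states by nearest centroid (per true state).
match_states <- function(est_centroids, true_model) {
  vapply(seq_len(true_model$n_states), function(j) {
    which.min(vapply(seq_len(nrow(est_centroids)), function(i)
      l2_distance(est_centroids[i, ], true_model$centroids[j, ], true_model$grid),
      0))
  }, 0L)
}
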