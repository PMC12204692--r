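#' Gaussian bump evaluated on a grid
#' @keywords internal
gaussian_bump <- function(grid, center, amplitude, sd) {
  amplitude * exp(-(grid - center)^2 / (2 * sd^2))
}

#' Build latent-state centroid curves as sums of Gaussian peaks
#'
#' Each latent state's centroid is a peak-only spectrum: the pointwise sum of
#' Gaussian bumps, one per oscillatory peak, evaluated on the grid. This is
#' the form the spectral parameteriser produces from real spectra, so
#' simulated centroids live in the same space as prepared data.
#'
#' @param grid strictly increasing numeric vector.
#' @param n_states number of latent states.
#' @param spec list of length `n_states`; element i is a matrix or data frame
#'   with columns (center, amplitude, sd), one row per peak, or an empty
#'   object for a flat (all-zero) centroid. `NULL` selects the built-in
#'   4-state preset (requires `n_states = 4`).
#' @return A `n_states` x `length(grid)` matrix of centroid curves.
#' @details The default preset mimics four qualitatively distinct
#'   resting-state EEG profiles: a delta-dominant state with a high beta-2
#'   shoulder; a theta-plus-slow-alpha state peaking at 9 Hz; a fast-alpha
#'   (11 Hz) plus beta-1 state; and a strong 10 Hz alpha state.
#' @export
#' @examples
#' mu <- make_psd_centroids(default_psd_grid(), 4)
#' dim(mu)
make_psd_centroids <- function(grid, n_states, spec = NULL) {
  validate_grid(grid)
  stopifnot(n_states >= 1)
  if (is.null(spec)) {
    if (n_states != 4L)
      stop("the built-in preset defines 4 states; supply `spec` for n_states = ",
           n_states, call. = FALSE)
    spec <- default_centroid_spec()
  }
  if (length(spec) != n_states)
    stop("`spec` must have one peak set per state", call. = FALSE)
  out <- matrix(0, n_states, length(grid))
  for (i in seq_len(n_states)) {
    pk <- spec[[i]]
    if (is.null(pk) || NROW(pk) == 0L) next
    pk <- as.matrix(pk)
    if (ncol(pk) != 3L)
      stop("each peak set needs columns (center, amplitude, sd)", call. = FALSE)
    bad <- pk[, 1] < min(grid) | pk[, 1] > max(grid)
    if (any(bad))
      stop("peak center ", pk[which(bad)[1], 1], " lies outside the grid range [",
           min(grid), ", ", max(grid), "]", call. = FALSE)
    if (any(pk[, 3] <= 0)) stop("peak sd must be positive", call. = FALSE)
    for (r in seq_len(nrow(pk)))
      out[i, ] <- out[i, ] + gaussian_bump(grid, pk[r, 1], pk[r, 2], pk[r, 3])
  }
  out
}

#' Built-in 4-state centroid peak specification
#'
#' @return List of 4 peak matrices (center Hz, amplitude, sd Hz).
#' @export
default_centroid_spec <- function() {
  list(
    # delta-dominant with high beta-2
    rbind(c(2.5, 0.9, 1.1), c(26, 0.45, 3.0)),
    # theta plus low-frequency (9 Hz) alpha
    rbind(c(5.5, 0.55, 1.3), c(9, 0.6, 1.2)),
    # high-frequency (11 Hz) alpha plus beta-1
    rbind(c(11, 0.6, 1.2), c(18, 0.4, 2.5)),
    # strong 10 Hz alpha
    rbind(c(10, 1.1, 1.5))
  )
}

#' Smooth functional noise on a grid
#'
#' Zero-mean random functions built from `n_basis` evenly spaced cubic
#' B-spline basis functions with i.i.d. standard normal coefficients,
#' rescaled per grid point so the pointwise marginal standard deviation
#' equals `noise_sd` exactly. Emissions of a functional HMM are curves, so
#' their noise must be a random function; i.i.d. pointwise jitter would not
#' be smoothed over the domain.
#'
#' @param n number of noise curves.
#' @param grid evaluation grid.
#' @param noise_sd pointwise marginal standard deviation (>= 0).
#' @param n_basis number of basis functions (default 10).
#' @return `n` x `length(grid)` matrix.
#' @keywords internal
smooth_noise <- function(n, grid, noise_sd, n_basis = 10L) {
  if (noise_sd == 0) return(matrix(0, n, length(grid)))
  B <- splines::bs(grid, df = n_basis, degree = 3L, intercept = TRUE)
  ptwise_sd <- sqrt(rowSums(B^2))
  Z <- matrix(rnorm(n * n_basis), n, n_basis)
  sweep(Z %*% t(B), 2L, noise_sd / ptwise_sd, "*")
}

#' Simulate a multi-individual dataset from a functional HMM
#'
#' For each individual a latent state path is drawn from the model's initial
#' distribution and transition matrix; the emitted curve at each time is the
#' current state's centroid plus smooth zero-mean functional noise. One
#' master generator is seeded per call and split into per-individual seeds,
#' so each individual's draw is reproducible on its own.
#'
#' @param truth_model an [fhmm_model] giving the generating states.
#' @param n_individuals number of independent sequences.
#' @param seq_length length K of each sequence.
#' @param noise_sd pointwise marginal sd of the functional noise (>= 0).
#' @param noise_smoothness number of noise basis functions (larger = rougher);
#'   default 10.
#' @param seed integer seed.
#' @return List with `dataset` (an [functional_dataset]) whose metadata
#'   carries the true generating state per observation, and `truth` (class
#'   `sim_truth`): the generating model, the per-individual state paths, the
#'   noise sd and the seed.
#' @export
#' @examples
#' mod <- fhmm_model(init = c(1, 0), trans = diag(2),
#'                   centroids = rbind(0:1 * 0 + 1, 0:1 * 0),
#'                   grid = c(0, 1))
#' sim <- simulate_fhmm_dataset(mod, n_individuals = 3, seq_length = 4,
#'                              noise_sd = 0, seed = 1)
#' sim$truth$paths
simulate_fhmm_dataset <- function(truth_model, n_individuals, seq_length,
                                  noise_sd, noise_smoothness = 10L, seed) {
  stopifnot(inherits(truth_model, "fhmm_model"))
  if (n_individuals < 1L) stop("n_individuals must be positive", call. = FALSE)
  if (seq_length < 1L) stop("seq_length must be at least 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (noise_smoothness < 1) stop("noise_smoothness must be positive", call. = FALSE)
  grid <- truth_model$grid
  N <- truth_model$n_states
  set.seed(as.integer(seed))
  ind_seeds <- sample.int(.Machine$integer.max - 1L, n_individuals)

  ids <- sprintf("sim%03d", seq_len(n_individuals))
  paths <- vector("list", n_individuals)
  curves <- matrix(NA_real_, n_individuals * seq_length, length(grid))
  for (p in seq_len(n_individuals)) {
    set.seed(ind_seeds[p])
    s <- integer(seq_length)
    s[1] <- sample.int(N, 1L, prob = truth_model$init)
    if (seq_length > 1L) for (k in 2:seq_length)
      s[k] <- sample.int(N, 1L, prob = truth_model$trans[s[k - 1], ])
    eps <- smooth_noise(seq_length, grid, noise_sd, n_basis = noise_smoothness)
    rows <- (p - 1L) * seq_length + seq_len(seq_length)
    curves[rows, ] <- truth_model$centroids[s, , drop = FALSE] + eps
    paths[[p]] <- s
  }
  names(paths) <- ids
  meta <- data.frame(
    individual_id = rep(ids, each = seq_length),
    time_index = rep(seq_len(seq_length), n_individuals),
    segment_id = 1L,
    true_state = unlist(paths, use.names = FALSE)
  )
  dataset <- functional_dataset(grid, curves, meta)
  truth <- structure(list(model = truth_model, paths = paths,
                          noise_sd = noise_sd, seed = as.integer(seed)),
                     class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate one raw log-power spectrum
#'
#' Aperiodic 1/f background plus Gaussian oscillatory peaks plus i.i.d.
#' observation noise, in log10-power units:
#' `offset - exponent * log10(f) + sum of Gaussians + noise`.
#'
#' @param grid positive frequency grid (Hz).
#' @param offset aperiodic offset (log10 power at 1 Hz).
#' @param exponent aperiodic slope in log-log space.
#' @param peaks matrix/data frame with columns (center, amplitude, sd) or
#'   NULL/empty for no peaks.
#' @param noise_sd i.i.d. Gaussian noise sd (>= 0).
#' @param seed integer seed (only consulted when `noise_sd > 0`).
#' @return Numeric vector: the log10-power curve on `grid`.
#' @export
#' @examples
#' f <- default_psd_grid()
#' y <- simulate_raw_psd(f, offset = 1, exponent = 1,
#'                       peaks = rbind(c(10, 0.5, 1.5)), noise_sd = 0, seed = 1)
simulate_raw_psd <- function(grid, offset, exponent, peaks = NULL,
                             noise_sd = 0, seed = 1L) {
  validate_grid(grid)
  if (any(grid <= 0))
    stop("frequencies must be strictly positive (log10 is taken)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  y <- offset - exponent * log10(grid)
  if (!is.null(peaks) && NROW(peaks) > 0L) {
    pk <- as.matrix(peaks)
    for (r in seq_len(nrow(pk)))
      y <- y + gaussian_bump(grid, pk[r, 1], pk[r, 2], pk[r, 3])
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + rnorm(length(grid), 0, noise_sd)
  }
  y
}
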