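#' Construct a functional hidden Markov model
#'
#' A functional HMM couples a discrete Markov chain (initial distribution
#' `init`, transition matrix `trans`) with curve-valued emissions: each
#' latent state i owns a centroid curve, and the emission pseudo-likelihood
#' of an observed curve x under state i is `1 / (d(x, mu_i)^2 + epsilon)`
#' where d is the L2 distance. Small distances mean high similarity;
#' `epsilon` regularises the degenerate case d = 0.
#'
#' @param init initial state distribution (length N, nonnegative, sums to 1).
#' @param trans N x N transition matrix, rows summing to 1.
#' @param centroids N x G matrix of state centroid curves on `grid`.
#' @param grid shared evaluation grid (length G).
#' @param epsilon emission regulariser; default `1e-12 * diff(range(grid))`.
#' @return Object of class `fhmm_model`.
#' @export
#' @examples
#' m <- fhmm_model(c(.5, .5), matrix(.5, 2, 2), rbind(c(0, 0), c(1, 1)), c(0, 1))
#' m
fhmm_model <- function(init, trans, centroids, grid, epsilon = NULL) {
  validate_grid(grid)
  centroids <- as.matrix(centroids)
  trans <- as.matrix(trans)
  N <- length(init)
  tol <- 1e-10
  if (N < 1L) stop("at least one state is required", call. = FALSE)
  if (any(init < -tol) || abs(sum(init) - 1) > tol)
    stop("initial distribution must be nonnegative and sum to 1", call. = FALSE)
  if (!all(dim(trans) == c(N, N)))
    stop("transition matrix must be ", N, " x ", N, call. = FALSE)
  if (any(trans < -tol) || any(abs(rowSums(trans) - 1) > tol))
    stop("each transition-matrix row must be nonnegative and sum to 1",
         call. = FALSE)
  if (nrow(centroids) != N)
    stop("need one centroid curve per state", call. = FALSE)
  if (ncol(centroids) != length(grid))
    stop("centroid curves must be evaluated on the model grid", call. = FALSE)
  if (is.null(epsilon)) epsilon <- 1e-12 * diff(range(grid))
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(n_states = N, init = as.numeric(init), trans = trans,
                 centroids = centroids, grid = as.numeric(grid),
                 epsilon = epsilon),
            class = "fhmm_model")
}

#' @export
print.fhmm_model <- function(x, ...) {
  cat("<fhmm_model> ", x$n_states, " states on ", length(x$grid),
      "-point grid; epsilon = ", format(x$epsilon), "\n", sep = "")
  cat("transition matrix:\n")
  print(round(x$trans, 4))
  invisible(x)
}

#' L2 distance between two curves on a shared grid
#'
#' Square root of the trapezoidal-quadrature integral of the squared
#' pointwise difference. Symmetric, and zero exactly when the curves agree
#' pointwise.
#'
#' @param x,mu numeric vectors of equal length (values on `grid`).
#' @param grid the shared grid.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' g <- seq(0, 1, length.out = 101)
#' l2_distance(rep(1, 101), rep(0, 101), g)  # 1
l2_distance <- function(x, mu, grid) {
  if (length(x) != length(grid) || length(mu) != length(grid))
    stop("curves and grid must share one length", call. = FALSE)
  w <- trapezoid_weights(grid)
  sqrt(sum(w * (x - mu)^2))
}

#' Distance-based emission pseudo-likelihood
#'
#' `h(d) = 1 / (d^2 + epsilon)`, strictly decreasing in the L2 distance d
#' between the observed curve and a state centroid, and finite at d = 0
#' thanks to the regulariser.
#'
#' @inheritParams l2_distance
#' @param epsilon positive regulariser.
#' @return Positive scalar.
#' @export
emission <- function(x, mu, grid, epsilon) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  d <- l2_distance(x, mu, grid)
  1 / (d^2 + epsilon)
}

#' Emission matrix for a curve matrix against all model centroids
#'
#' @param curves K x G matrix.
#' @param model an `fhmm_model`.
#' @return K x N matrix of positive pseudo-likelihoods; the (k, i) entry is
#'   `1 / (d(x_k, mu_i)^2 + epsilon)`.
#' @export
emission_matrix <- function(curves, model) {
  w <- trapezoid_weights(model$grid)
  # squared weighted distances via the expansion |x - mu|^2_w
  Xw <- sweep(curves, 2L, w, "*")
  x2 <- rowSums(Xw * curves)
  m2 <- rowSums(sweep(model$centroids, 2L, w, "*") * model$centroids)
  d2 <- outer(x2, m2, "+") - 2 * Xw %*% t(model$centroids)
  d2[d2 < 0] <- 0  # guard against roundoff
  1 / (d2 + model$epsilon)
}

#' Forward-backward smoothing for one functional series
#'
#' Scaled forward-backward recursions with the distance-based emission
#' pseudo-likelihoods plugged in as the emission terms. Because emissions
#' are unnormalised similarities rather than densities, the returned
#' objective is a log pseudo-likelihood (the sum of log per-step scaling
#' normalisers); state posteriors gamma and pair posteriors xi are proper
#' distributions regardless.
#'
#' @param curves K x G matrix: one individual's time-ordered curves.
#' @param model an `fhmm_model`.
#' @return List of class `fb_result`: `gamma` (K x N, rows sum to 1), `xi`
#'   ((K-1) x N x N array, each time slice sums to 1), `scaling_factors`
#'   (length K), `log_pseudo_likelihood`.
#' @export
forward_backward <- function(curves, model) {
  stopifnot(inherits(model, "fhmm_model"))
  curves <- rbind(curves)  # promote a single curve vector to a 1-row matrix
  if (nrow(curves) < 1L) stop("series must be nonempty", call. = FALSE)
  em <- emission_matrix(curves, model)
  res <- .fb_core(em, model$init, model$trans)
  K <- nrow(curves); N <- model$n_states
  xi <- array(res$xi, dim = c(max(K - 1L, 0L), N, N))
  structure(list(gamma = res$gamma, xi = xi,
                 scaling_factors = res$scaling_factors,
                 log_pseudo_likelihood = res$log_pseudo_likelihood),
            class = "fb_result")
}

#' Baum-Welch estimation over multiple functional series
#'
#' Expectation-maximisation for one shared model across individuals: the
#' E-step runs [forward_backward] per series; the M-step sets the initial
#' distribution to the average first-step posterior, pools transition
#' responsibilities across series, and updates each centroid by a
#' minorise-maximise step: a pointwise mean of all observed curves weighted
#' by `gamma * emission` (responsibility divided by the current squared
#' distance plus epsilon). Because `-log(u)` is convex, this weighted mean
#' maximises a tangent minorant of the expected complete-data objective, so
#' the log pseudo-likelihood is nondecreasing across iterations; the plain
#' responsibility-weighted mean (the k-means-style update) lacks this
#' guarantee under reciprocal-square-distance emissions and can decrease
#' the objective on noisy data.
#'
#' @param dataset an [functional_dataset] or a list of K x G curve matrices.
#' @param init an `fhmm_model` to start from.
#' @param tol stop when the relative change in total log pseudo-likelihood
#'   falls below this (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @param verbose print per-iteration objective.
#' @return List: `model` (fitted `fhmm_model`), `history` (objective per
#'   iteration), `n_iter`, `converged`.
#' @export
baum_welch <- function(dataset, init, tol = 1e-6, max_iter = 200L,
                       verbose = FALSE) {
  stopifnot(inherits(init, "fhmm_model"))
  series <- dataset_curve_list(dataset)
  series <- lapply(series, rbind)
  N <- init$n_states
  G <- length(init$grid)
  X_all <- do.call(rbind, series)
  lens <- vapply(series, nrow, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  model <- init
  history <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  frozen <- rep(FALSE, N)
  for (it in seq_len(max_iter)) {
    em_all <- emission_matrix(X_all, model)
    es <- .fb_multi(em_all, starts - 1L, lens, model$init, model$trans)
    ll <- es$log_pseudo_likelihood
    nu_acc <- es$nu_acc
    xi_acc <- es$xi_acc
    gden_acc <- es$gden_acc         # sum gamma over k < K (transition denom)
    gamma_all <- es$gamma
    resp_sum <- colSums(gamma_all)  # total responsibility per state
    wg <- gamma_all * em_all        # MM weights: gamma / (d^2 + epsilon)
    wsum <- colSums(wg)
    wx <- crossprod(wg, X_all)
    history <- c(history, ll)
    if (verbose) message(sprintf("iter %3d  logPL %.6f", it, ll))

    # M-step
    nu <- nu_acc / length(series)
    trans <- model$trans
    pos <- gden_acc > 0
    trans[pos, ] <- xi_acc[pos, , drop = FALSE] / gden_acc[pos]
    trans <- trans / rowSums(trans)
    centroids <- model$centroids
    floor_resp <- 1e-8
    low <- resp_sum < floor_resp
    if (any(low & !frozen)) {
      warning("state(s) ", paste(which(low & !frozen), collapse = ", "),
              " received negligible responsibility; centroid frozen",
              call. = FALSE)
      frozen <- frozen | low
    }
    upd <- !low
    centroids[upd, ] <- wx[upd, , drop = FALSE] / wsum[upd]
    model <- fhmm_model(nu, trans, centroids, model$grid, model$epsilon)

    if (is.finite(prev)) {
      rel <- abs(ll - prev) / (abs(prev) + 1e-300)
      if (rel < tol) { converged <- TRUE; break }
    }
    prev <- ll
  }
  list(model = model, history = history, n_iter = length(history),
       converged = converged)
}

#' Viterbi decoding of one functional series
#'
#' Maximum a posteriori latent state path by dynamic programming in log
#' space over the initial distribution, transition matrix and log emission
#' pseudo-likelihoods. Ties are broken toward the lowest state index, so
#' output is deterministic.
#'
#' @inheritParams forward_backward
#' @param individual_id optional label carried into the result.
#' @return Object of class `viterbi_path`: `states` (length-K integer
#'   vector, labels 1..N), `path_log_score`, `individual_id`.
#' @export
viterbi <- function(curves, model, individual_id = NA_character_) {
  stopifnot(inherits(model, "fhmm_model"))
  curves <- rbind(curves)
  em <- emission_matrix(curves, model)
  res <- .viterbi_core(log(em), log(model$init), log(model$trans))
  structure(list(individual_id = individual_id,
                 states = as.integer(res$states),
                 path_log_score = res$path_log_score),
            class = "viterbi_path")
}

#' Decode every individual in a dataset
#'
#' @param dataset an [functional_dataset].
#' @param model a fitted `fhmm_model`.
#' @return Named list of [viterbi] paths, one per individual.
#' @export
decode_states <- function(dataset, model) {
  ser <- split_series(dataset)
  lapply(ser, function(s) viterbi(s$curves, model, s$individual_id))
}

#' Coerce supported inputs to a list of curve matrices
#' @keywords internal
dataset_curve_list <- function(dataset) {
  if (inherits(dataset, "fd_dataset"))
    return(lapply(split_series(dataset), `[[`, "curves"))
  if (is.matrix(dataset)) return(list(dataset))
  if (is.list(dataset)) return(lapply(dataset, rbind))
  stop("unsupported dataset type", call. = FALSE)
}

#' Relabel model states by decreasing allocation frequency
#'
#' Permutes state labels so state 1 is the one with the most decoded
#' observations, state 2 the next, and so on (ties broken toward the lower
#' original index); the initial distribution, transition matrix, centroids
#' and all paths are permuted consistently. Quantities invariant under
#' relabelling (log pseudo-likelihood, sorted allocation counts) are
#' unchanged.
#'
#' @param model an `fhmm_model`.
#' @param paths list of `viterbi_path` objects decoded under `model`.
#' @return List: `model`, `paths`, `permutation` (new label for each old
#'   label), `allocations` (per new state).
#' @export
relabel_states <- function(model, paths) {
  stopifnot(inherits(model, "fhmm_model"))
  N <- model$n_states
  counts <- tabulate(unlist(lapply(paths, `[[`, "states")), nbins = N)
  ord <- order(-counts, seq_len(N))      # old labels in new order
  perm <- match(seq_len(N), ord)         # perm[old] = new
  new_model <- fhmm_model(model$init[ord], model$trans[ord, ord, drop = FALSE],
                          model$centroids[ord, , drop = FALSE], model$grid,
                          model$epsilon)
  new_paths <- lapply(paths, function(p) {
    p$states <- perm[p$states]
    p
  })
  list(model = new_model, paths = new_paths, permutation = perm,
       allocations = counts[ord])
}
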