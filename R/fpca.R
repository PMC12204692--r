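#' Subset curves by decoded latent state
#'
#' Returns exactly the curves whose Viterbi-decoded state equals the
#' requested label, with individual/time provenance. Paths are matched to
#' the dataset by individual id and time order; a path whose length differs
#' from its individual's series is an alignment error.
#'
#' @param dataset an [functional_dataset].
#' @param paths list of `viterbi_path` objects covering every individual.
#' @param state state label to extract.
#' @return List: `curves` (n_i x G matrix), `provenance` (data frame:
#'   individual_id, time_index), `grid`.
#' @export
subset_by_state <- function(dataset, paths, state) {
  stopifnot(inherits(dataset, "fd_dataset"))
  ser <- split_series(dataset)
  path_ids <- vapply(paths, function(p) as.character(p$individual_id), "")
  rows <- list(); prov <- list()
  for (s in ser) {
    j <- match(as.character(s$individual_id), path_ids)
    if (is.na(j))
      stop("no decoded path for individual ", s$individual_id, call. = FALSE)
    st <- paths[[j]]$states
    if (length(st) != nrow(s$curves))
      stop("path length ", length(st), " does not match series length ",
           nrow(s$curves), " for individual ", s$individual_id, call. = FALSE)
    sel <- st == state
    if (any(sel)) {
      rows[[length(rows) + 1L]] <- s$curves[sel, , drop = FALSE]
      prov[[length(prov) + 1L]] <- data.frame(
        individual_id = s$individual_id, time_index = s$time_index[sel])
    }
  }
  curves <- if (length(rows)) do.call(rbind, rows)
            else matrix(numeric(0), 0, length(dataset$grid))
  provenance <- if (length(prov)) do.call(rbind, prov)
                else data.frame(individual_id = character(0), time_index = integer(0))
  list(curves = curves, provenance = provenance, grid = dataset$grid)
}

#' Functional principal component analysis with a penalised B-spline basis
#'
#' Each curve is represented by penalised B-spline coefficients
#' ([bspline_smooth]), coefficients are centred at their mean, and the
#' eigenproblem of the coefficient covariance is solved in the basis metric
#' (symmetrised through the Gram matrix) so the returned eigenfunctions are
#' orthonormal under the package's L2 quadrature. Scores are quadrature
#' inner products of the centred raw curves with the eigenfunctions, so
#' [project_scores] on the training curves reproduces them exactly.
#'
#' Sign convention: each eigenfunction is flipped so that its entry of
#' largest magnitude is positive, making output deterministic.
#'
#' @param curves n x G matrix (n >= 2) on the basis grid.
#' @param basis a [bspline_basis]; default built on `grid`.
#' @param penalty roughness penalty for the per-curve smoothing (default
#'   1e-4).
#' @param n_components `"all"` (keep every computed component; retention
#'   count via [choose_n_components] at the default 70% rule) or an integer.
#' @param grid required if `basis` is NULL.
#' @param state_label optional label carried in the result.
#' @param retention_threshold cumulative variance threshold used when
#'   `n_components = "all"`.
#' @return Object of class `fpca_model`: `mean_function` (on the grid),
#'   `eigenfunctions` (M x G matrix, row c = phi_c), `eigenvalues`
#'   (nonincreasing, clipped at 0), `variance_fractions`, `scores`
#'   (n x M), `n_retained`, `basis`, `penalty`, `grid`, `state_label`,
#'   `scree` (data frame: component, fraction, cumulative).
#' @export
fit_fpca <- function(curves, basis = NULL, penalty = 1e-4,
                     n_components = "all", grid = NULL,
                     state_label = NA, retention_threshold = 0.70) {
  curves <- rbind(curves)
  if (nrow(curves) < 2L)
    stop("FPCA needs at least 2 curves", call. = FALSE)
  if (is.null(basis)) {
    if (is.null(grid)) stop("supply `basis` or `grid`", call. = FALSE)
    basis <- bspline_basis(grid)
  }
  grid <- basis$grid
  w <- basis$quad_weights
  sm <- bspline_smooth(curves, basis, penalty)
  Cf <- sm$coefficients                  # n x M
  cbar <- colMeans(Cf)
  Cc <- sweep(Cf, 2L, cbar)
  J <- basis$gram_matrix
  eJ <- eigen(J, symmetric = TRUE)
  if (min(eJ$values) <= 0)
    stop("Gram matrix is not positive definite", call. = FALSE)
  Jh <- eJ$vectors %*% (sqrt(eJ$values) * t(eJ$vectors))      # J^{1/2}
  Jih <- eJ$vectors %*% ((1 / sqrt(eJ$values)) * t(eJ$vectors))
  V <- crossprod(Cc) / (nrow(curves) - 1L)
  A <- Jh %*% V %*% Jh
  A <- (A + t(A)) / 2
  eA <- eigen(A, symmetric = TRUE)
  lambda <- pmax(eA$values, 0)
  Bcoef <- Jih %*% eA$vectors            # eigenfunction coefficients, J-orthonormal
  Phi <- t(basis$design %*% Bcoef)       # M x G, rows are eigenfunctions
  # deterministic sign: largest-magnitude grid entry positive
  for (c in seq_len(nrow(Phi))) {
    i <- which.max(abs(Phi[c, ]))
    if (Phi[c, i] < 0) Phi[c, ] <- -Phi[c, ]
  }
  total <- sum(lambda)
  fractions <- if (total > 0) lambda / total else rep(0, length(lambda))
  mean_function <- as.numeric(basis$design %*% cbar)
  # scores: quadrature inner product of centred raw curves with eigenfunctions
  Xc <- sweep(curves, 2L, mean_function)
  scores <- Xc %*% t(sweep(Phi, 2L, w, "*"))
  n_retained <- if (identical(n_components, "all"))
    choose_n_components(fractions, retention_threshold)$n_components
  else as.integer(n_components)
  scree <- data.frame(component = seq_along(fractions),
                      fraction = fractions, cumulative = cumsum(fractions))
  structure(list(state_label = state_label, mean_function = mean_function,
                 eigenfunctions = Phi, eigenvalues = lambda,
                 variance_fractions = fractions, scores = scores,
                 n_retained = n_retained, basis = basis, penalty = penalty,
                 grid = grid, scree = scree),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat("<fpca_model> ", nrow(x$scores), " curves, ", x$n_retained,
      " retained component(s) of ", length(x$eigenvalues),
      "; cumulative variance ",
      sprintf("%.1f%%", 100 * x$scree$cumulative[x$n_retained]), "\n", sep = "")
  invisible(x)
}

#' Choose how many components to retain
#'
#' The smallest C whose cumulative variance fraction strictly exceeds the
#' threshold (default 70%). Emits the scree data (per-component and
#' cumulative fractions) for visual inspection of the elbow.
#'
#' @param variance_fractions fractions in `[0, 1]` (need not be sorted).
#' @param threshold cumulative fraction to exceed, default 0.70.
#' @return List: `n_components`, `cumulative` (at that C), `scree`
#'   (data frame).
#' @export
#' @examples
#' choose_n_components(c(0.4, 0.25, 0.10, 0.08))$n_components  # 3
choose_n_components <- function(variance_fractions, threshold = 0.70) {
  if (any(variance_fractions < 0 | variance_fractions > 1))
    stop("variance fractions must lie in [0, 1]", call. = FALSE)
  cum <- cumsum(variance_fractions)
  idx <- which(cum > threshold)
  if (length(idx) == 0L) {
    warning("cumulative variance never exceeds ", threshold,
            "; retaining all components", call. = FALSE)
    C <- length(variance_fractions)
  } else C <- idx[1]
  list(n_components = C, cumulative = cum[C],
       scree = data.frame(component = seq_along(variance_fractions),
                          fraction = variance_fractions, cumulative = cum))
}

#' Project curves onto retained eigenfunctions
#'
#' Score of curve x on component c is the quadrature inner product of
#' `x - mean_function` with eigenfunction phi_c, for c = 1..n_retained.
#'
#' @param model an `fpca_model`.
#' @param curves vector or n x G matrix on the model grid.
#' @return n x n_retained score matrix.
#' @export
project_scores <- function(model, curves) {
  stopifnot(inherits(model, "fpca_model"))
  curves <- rbind(curves)
  if (ncol(curves) != length(model$grid))
    stop("curves are not on the model grid", call. = FALSE)
  w <- model$basis$quad_weights
  C <- model$n_retained
  Phi <- model$eigenfunctions[seq_len(C), , drop = FALSE]
  Xc <- sweep(curves, 2L, model$mean_function)
  Xc %*% t(sweep(Phi, 2L, w, "*"))
}

#' Per-individual mean component scores
#'
#' Aggregates observation-level scores to one vector per individual by the
#' arithmetic mean over that individual's observations (first
#' `n_components` entries). Individuals with no observations are absent.
#'
#' @param model an `fpca_model` fitted to within-state curves.
#' @param individual_ids character vector mapping each score row to its
#'   individual.
#' @param n_components how many leading components to keep (default 5,
#'   capped at the model's retained count).
#' @return Data frame: individual_id, fpc_score_1..C.
#' @export
individual_mean_scores <- function(model, individual_ids, n_components = 5L) {
  stopifnot(inherits(model, "fpca_model"))
  if (length(individual_ids) != nrow(model$scores))
    stop("need one individual id per score row", call. = FALSE)
  C <- min(n_components, model$n_retained)
  S <- model$scores[, seq_len(C), drop = FALSE]
  ids <- as.character(individual_ids)
  agg <- rowsum(S, ids) / as.vector(table(ids)[sort(unique(ids))])
  out <- data.frame(individual_id = rownames(agg), agg, row.names = NULL)
  names(out)[-1] <- paste0("fpc_score_", seq_len(C))
  out
}
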