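#' Functional k-means under the L2 metric
#'
#' Lloyd iterations on curves: assign each curve to its nearest centroid in
#' L2 distance, replace each centroid by the pointwise mean of its assigned
#' curves, repeat to convergence. Initial centroids are drawn uniformly
#' without replacement from the curves; the best of `n_restarts` runs by
#' within-cluster sum of squared L2 distances is returned. A cluster that
#' empties is re-seeded from the curve farthest from its centroid.
#'
#' Random restarts are needed because k-means on high-dimensional functional
#' data is sensitive to initial conditions and clusters can collapse onto
#' one local optimum.
#'
#' @param curves n x G matrix of curves.
#' @param k number of clusters (k <= n).
#' @param grid shared grid.
#' @param seed integer seed.
#' @param n_restarts number of random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return List: `centroids` (k x G), `assignment` (length n), `objective`
#'   (within-cluster sum of squared L2 distances).
#' @export
functional_kmeans <- function(curves, k, grid, seed, n_restarts = 10L,
                              max_iter = 100L) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (k > n) stop("k = ", k, " exceeds the number of curves (", n, ")",
                  call. = FALSE)
  w <- trapezoid_weights(grid)
  Xw <- sweep(curves, 2L, w, "*")
  x2 <- rowSums(Xw * curves)
  sqdist <- function(cent) {
    # n x k matrix of squared weighted L2 distances
    c2 <- rowSums(sweep(cent, 2L, w, "*") * cent)
    d2 <- outer(x2, c2, "+") - 2 * tcrossprod(Xw, cent)
    d2[d2 < 0] <- 0
    d2
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cent <- curves[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      d2 <- sqdist(cent)
      assign_new <- max.col(-d2, ties.method = "first")
      counts <- tabulate(assign_new, nbins = k)
      while (any(counts == 0L)) {
        # re-seed an empty cluster from the farthest curve that is not the
        # sole member of its cluster
        j <- which(counts == 0L)[1]
        eligible <- which(counts[assign_new] > 1L)
        far <- eligible[which.max(d2[cbind(eligible, assign_new[eligible])])]
        assign_new[far] <- j
        counts <- tabulate(assign_new, nbins = k)
      }
      cent <- rowsum(curves, assign_new) / counts
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    d2 <- sqdist(cent)
    obj <- sum(d2[cbind(seq_len(n), assign_old)])
    if (is.null(best) || obj < best$objective)
      best <- list(centroids = cent, assignment = assign_old, objective = obj)
  }
  best
}

#' Pool centroids from FHMMs fit to random subsamples
#'
#' Fits `n_models` functional HMMs, each to a random subsample of
#' `subsample_fraction` of the individuals (drawn without replacement within
#' a draw), each with `states_per_model` latent states initialised by
#' [functional_kmeans] and refined by [baum_welch]. Deliberately allowing
#' more states than expected lets redundant near-duplicate states occur in
#' each subsampled fit while the states that recur across subsamples reveal
#' the stable, well-separated centroids; the pooled centroids feed
#' [group_centroids].
#'
#' @param dataset an [functional_dataset].
#' @param n_models number of subsampled fits (default 10).
#' @param subsample_fraction fraction of individuals per fit, in (0, 1)
#'   (default 0.8).
#' @param states_per_model latent states per subsampled fit (default 8).
#' @param seed integer seed.
#' @param epsilon emission regulariser passed to each fit (default as in
#'   [fhmm_model]).
#' @param tol,max_iter Baum-Welch controls for the subsampled fits; looser
#'   than final-fit defaults since only centroids are harvested.
#' @return List of class `centroid_pool`: `centroids`
#'   ((n_models x states_per_model) x G matrix), `provenance` (data frame:
#'   model, state), `grid`, `subsamples` (list of individual id vectors).
#' @export
subsample_initialise <- function(dataset, n_models = 10L,
                                 subsample_fraction = 0.8,
                                 states_per_model = 8L, seed,
                                 epsilon = NULL,
                                 tol = 1e-5, max_iter = 50L) {
  stopifnot(inherits(dataset, "fd_dataset"))
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop("subsample_fraction must lie strictly between 0 and 1", call. = FALSE)
  ids <- unique(dataset$meta$individual_id)
  P <- length(ids)
  n_sub <- floor(subsample_fraction * P)
  if (n_sub < 1L || P < ceiling(1 / (1 - subsample_fraction)))
    stop("too few individuals (", P, ") for subsample fraction ",
         subsample_fraction, call. = FALSE)
  set.seed(as.integer(seed))
  model_seeds <- sample.int(.Machine$integer.max - 1L, n_models)
  grid <- dataset$grid
  pool <- vector("list", n_models)
  subsamples <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    set.seed(model_seeds[m])
    keep <- sample(ids, n_sub)
    subsamples[[m]] <- keep
    rows <- dataset$meta$individual_id %in% keep
    sub <- functional_dataset(grid, dataset$curves[rows, , drop = FALSE],
                              dataset$meta[rows, , drop = FALSE])
    km <- functional_kmeans(sub$curves, states_per_model, grid,
                            seed = model_seeds[m])
    N <- states_per_model
    init <- fhmm_model(rep(1 / N, N), matrix(1 / N, N, N), km$centroids,
                       grid, epsilon)
    fit <- baum_welch(sub, init, tol = tol, max_iter = max_iter)
    pool[[m]] <- fit$model$centroids
  }
  centroids <- do.call(rbind, pool)
  provenance <- data.frame(model = rep(seq_len(n_models), each = states_per_model),
                           state = rep(seq_len(states_per_model), n_models))
  structure(list(centroids = centroids, provenance = provenance,
                 grid = grid, subsamples = subsamples),
            class = "centroid_pool")
}

#' Group pooled centroids and average each group into an initial centroid
#'
#' Agglomerative average-linkage clustering on the pairwise L2 distances
#' between pooled centroids, cut either at a requested number of groups or
#' at a distance threshold; alternatively a manual label vector assigns
#' groups verbatim (mirroring heuristic visual grouping of overlaid
#' centroids). Each group's initial centroid is the pointwise mean of its
#' members.
#'
#' @param pool a `centroid_pool` from [subsample_initialise], or a plain
#'   matrix of centroid curves (then supply `grid`).
#' @param method "agglomerative" or "manual".
#' @param n_groups number of groups (agglomerative cut); supply exactly one
#'   of `n_groups`, `distance_threshold`, `manual_labels`.
#' @param distance_threshold linkage height at which to cut instead.
#' @param manual_labels integer/character vector, one label per pooled
#'   centroid (manual mode).
#' @param grid grid when `pool` is a bare matrix.
#' @return List: `groups` (label per pooled centroid), `centroids` (one
#'   averaged curve per group, ordered by label), `distance_matrix`
#'   (pairwise L2), `sizes`.
#' @export
group_centroids <- function(pool, method = c("agglomerative", "manual"),
                            n_groups = NULL, distance_threshold = NULL,
                            manual_labels = NULL, grid = NULL) {
  method <- match.arg(method)
  if (inherits(pool, "centroid_pool")) {
    mat <- pool$centroids
    grid <- pool$grid
  } else {
    mat <- as.matrix(pool)
    if (is.null(grid)) stop("supply `grid` with a bare centroid matrix",
                            call. = FALSE)
  }
  supplied <- !c(is.null(n_groups), is.null(distance_threshold),
                 is.null(manual_labels))
  if (sum(supplied) != 1L)
    stop("supply exactly one of n_groups, distance_threshold, manual_labels",
         call. = FALSE)
  n <- nrow(mat)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- l2_distance(mat[i, ], mat[j, ], grid)

  if (method == "manual" || !is.null(manual_labels)) {
    if (is.null(manual_labels))
      stop("manual grouping requires `manual_labels`", call. = FALSE)
    if (length(manual_labels) != n)
      stop("manual_labels must label every pooled centroid (need ", n,
           " labels)", call. = FALSE)
    groups <- as.integer(factor(manual_labels))
  } else {
    hc <- hclust(as.dist(D), method = "average")
    groups <- if (!is.null(n_groups)) cutree(hc, k = n_groups)
              else cutree(hc, h = distance_threshold)
  }
  sizes <- tabulate(groups)
  if (any(sizes == 0L)) stop("empty centroid group", call. = FALSE)
  k <- max(groups)
  cent <- matrix(NA_real_, k, ncol(mat))
  for (g in seq_len(k))
    cent[g, ] <- colMeans(mat[groups == g, , drop = FALSE])
  list(groups = groups, centroids = cent, distance_matrix = D, sizes = sizes)
}

#' Fit a functional HMM with consensus-initialised centroids
#'
#' Convenience wrapper chaining [subsample_initialise], [group_centroids]
#' (cut at `n_states` groups) and a final [baum_welch] fit on the full data,
#' started from uniform initial/transition distributions and the averaged
#' group centroids.
#'
#' @inheritParams subsample_initialise
#' @param n_states number of states for the final model.
#' @param ... further arguments to [subsample_initialise].
#' @param final_tol,final_max_iter Baum-Welch controls for the final fit.
#' @return As [baum_welch], plus `pool` and `grouping`.
#' @export
fit_fhmm_consensus <- function(dataset, n_states, seed, ...,
                               final_tol = 1e-6, final_max_iter = 200L) {
  pool <- subsample_initialise(dataset, seed = seed, ...)
  grouping <- group_centroids(pool, n_groups = n_states)
  N <- n_states
  init <- fhmm_model(rep(1 / N, N), matrix(1 / N, N, N), grouping$centroids,
                     dataset$grid)
  fit <- baum_welch(dataset, init, tol = final_tol, max_iter = final_max_iter)
  fit$pool <- pool
  fit$grouping <- grouping
  fit
}
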