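#' B-spline basis system with Gram and roughness-penalty matrices
#'
#' Builds an order-`order` (default cubic, order 4) B-spline basis spanning
#' the grid range, together with (i) the design matrix of basis values on
#' the grid, (ii) the Gram matrix of pairwise basis inner products under
#' trapezoidal quadrature on the evaluation grid (the same inner product
#' used throughout the package), and (iii) the second-derivative roughness
#' penalty matrix, integrated on a refined grid (for cubic splines the
#' second derivatives are piecewise linear, so a modestly refined trapezoid
#' rule is accurate).
#'
#' @param grid evaluation grid (strictly increasing).
#' @param n_basis number of basis functions; default places an interior
#'   knot at every other grid point. Must satisfy `order <= n_basis <=
#'   length(grid)`.
#' @param order polynomial order (degree + 1), default 4 (cubic).
#' @param penalty_refine subdivision factor for the penalty quadrature.
#' @return Object of class `basis_system`: `grid`, `order`, `knots` (full
#'   knot vector with repeated boundary knots), `design` (G x M),
#'   `gram_matrix` (M x M, symmetric positive definite), `penalty_matrix`
#'   (M x M, symmetric positive semidefinite), `quad_weights`.
#' @export
#' @examples
#' b <- bspline_basis(default_psd_grid())
#' dim(b$design)
bspline_basis <- function(grid, n_basis = NULL, order = 4L,
                          penalty_refine = 8L) {
  validate_grid(grid)
  G <- length(grid)
  degree <- order - 1L
  if (is.null(n_basis)) {
    interior <- grid[seq(3, G - 2, by = 2)]
    n_basis <- length(interior) + order
  } else {
    if (n_basis < order) stop("n_basis must be at least the order", call. = FALSE)
    if (n_basis > G) stop("n_basis must not exceed the number of grid points",
                          call. = FALSE)
    n_int <- n_basis - order
    interior <- if (n_int > 0)
      seq(min(grid), max(grid), length.out = n_int + 2L)[-c(1L, n_int + 2L)]
    else numeric(0)
  }
  knots <- c(rep(min(grid), order), sort(interior), rep(max(grid), order))
  design <- splines::splineDesign(knots, grid, ord = order,
                                  outer.ok = FALSE)
  w <- trapezoid_weights(grid)
  gram <- crossprod(design * sqrt(w))
  gram <- (gram + t(gram)) / 2

  # roughness penalty on a refined grid
  fine <- unique(sort(c(grid, unlist(lapply(seq_len(G - 1), function(i)
    seq(grid[i], grid[i + 1], length.out = penalty_refine + 1L))))))
  d2 <- splines::splineDesign(knots, fine, ord = order, derivs = 2L)
  wf <- trapezoid_weights(fine)
  pen <- crossprod(d2 * sqrt(wf))
  pen <- (pen + t(pen)) / 2

  structure(list(grid = as.numeric(grid), order = order, knots = knots,
                 design = design, gram_matrix = gram, penalty_matrix = pen,
                 quad_weights = w, n_basis = ncol(design)),
            class = "basis_system")
}

#' @export
print.basis_system <- function(x, ...) {
  cat("<basis_system> order ", x$order, ", ", x$n_basis,
      " basis functions on [", format(min(x$grid)), ", ",
      format(max(x$grid)), "]\n", sep = "")
  invisible(x)
}

#' Penalised B-spline smoothing of curves
#'
#' Minimises `||y - B c||^2 + penalty * c' P c` where B is the basis design
#' matrix on the grid and P the second-derivative roughness penalty.
#' Constants are reproduced exactly for any penalty (they are in the spline
#' space and unpenalised); with zero penalty and a saturated basis the
#' smoother interpolates.
#'
#' @param curves numeric vector (one curve) or n x G matrix.
#' @param basis a [bspline_basis].
#' @param penalty nonnegative roughness penalty weight.
#' @return List: `coefficients` (n x M), `smoothed` (n x G fitted values).
#' @export
bspline_smooth <- function(curves, basis, penalty = 0) {
  stopifnot(inherits(basis, "basis_system"))
  if (penalty < 0) stop("penalty must be nonnegative", call. = FALSE)
  Y <- rbind(curves)
  if (ncol(Y) != nrow(basis$design))
    stop("curves must be evaluated on the basis grid", call. = FALSE)
  B <- basis$design
  M <- crossprod(B) + penalty * basis$penalty_matrix
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop("singular smoothing system: too many basis functions for this grid ",
         "with penalty ", penalty, call. = FALSE)
  coefs <- t(backsolve(ch, forwardsolve(t(ch), crossprod(B, t(Y)))))
  smoothed <- coefs %*% t(B)
  list(coefficients = coefs, smoothed = smoothed)
}
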