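#' Uniform cubic B-spline basis weights
#'
#' The four nonzero uniform cubic B-spline basis functions at local
#' coordinate `t` within a knot cell:
#' `B0 = (1-t)^3/6`, `B1 = (3t^3 - 6t^2 + 4)/6`,
#' `B2 = (-3t^3 + 3t^2 + 3t + 1)/6`, `B3 = t^3/6`.
#' They are non-negative and sum to one (partition of unity).
#'
#' @param t local coordinates in `[0, 1]` (1 is accepted as the closing edge
#'   of the last cell).
#' @return `length(t)` x 4 matrix of weights.
#' @export
cubic_basis <- function(t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

#' @rdname cubic_basis
#' @details `cubic_basis_deriv()` returns the derivatives with respect to
#'   `t`; they sum to zero for every `t`. Divide by the knot spacing to get
#'   derivatives with respect to physical position.
#' @export
cubic_basis_deriv <- function(t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  cbind(-(1 - t)^2 / 2,
        (9 * t^2 - 12 * t) / 6,
        (-9 * t^2 + 6 * t + 3) / 6,
        t^2 / 2)
}

# sparse basis matrix over a set of 1D coordinates: n_pts x n_ctrl with 4
# nonzeros per row; deriv = TRUE gives d/dx (already divided by spacing)
basis_matrix_1d <- function(x, origin, spacing, n_ctrl, deriv = FALSE) {
  s <- (x - origin) / spacing
  if (any(s < -1e-9 | s > n_ctrl - 3 + 1e-9))
    stop("coordinates outside the knot support")
  i <- pmin(pmax(floor(s + 1e-12), 0), n_ctrl - 4)   # cell index, 0-based
  t <- pmin(pmax(s - i, 0), 1)                       # snap fp dust into [0, 1]
  W <- if (deriv) cubic_basis_deriv(t) / spacing else cubic_basis(t)
  Matrix::sparseMatrix(
    i = rep(seq_along(x), 4),
    j = as.vector(outer(i, 1:4, `+`)),
    x = as.vector(W),
    dims = c(length(x), n_ctrl))
}

#' Bicubic B-spline displacement model (free-form deformation)
#'
#' Smooth axial (`V`) and lateral (`U`) displacement fields parameterized by
#' control grids `a` and `b` on uniformly spaced knots:
#' `V(x, y) = sum_mn Bm(p) Bn(q) a[j+n, i+m]`, with `p`, `q` the fractional
#' positions inside the knot cell, and `U` likewise with `b`. The knot grid
#' covers the region of interest plus the one-cell margin required by the
#' cubic support.
#'
#' @param a axial control parameters, `n_cy x n_cx` matrix.
#' @param b lateral control parameters, same shape (or `NULL` when not yet
#'   derived).
#' @param spacing knot spacing `(lateral, axial)` in mm; defaults
#'   `c(4.75, 4.82)`.
#' @param origin `(x0, y0)` of the first knot (mm).
#' @return object of class `bspline_disp_model`.
#' @export
bspline_model <- function(a, b = NULL, spacing = c(4.75, 4.82),
                          origin = c(0, 0)) {
  a <- as.matrix(a)
  if (!is.null(b)) {
    b <- as.matrix(b)
    stopifnot(all(dim(b) == dim(a)))
  }
  stopifnot(nrow(a) >= 4, ncol(a) >= 4, length(spacing) == 2,
            all(spacing > 0))
  structure(list(a = a, b = b, spacing = spacing, origin = origin),
            class = "bspline_disp_model")
}

#' @export
print.bspline_disp_model <- function(x, ...) {
  cat(sprintf("<bspline_disp_model> %d x %d control grid, knot spacing %.3g x %.3g mm%s\n",
              nrow(x$a), ncol(x$a), x$spacing[1], x$spacing[2],
              if (is.null(x$b)) " (axial only)" else ""))
  invisible(x)
}

# spatial support of the model: list(x = c(lo, hi), y = c(lo, hi))
model_support <- function(model) {
  list(x = model$origin[1] + c(0, (ncol(model$a) - 3) * model$spacing[1]),
       y = model$origin[2] + c(0, (nrow(model$a) - 3) * model$spacing[2]))
}

#' Evaluate a B-spline displacement model on a grid
#'
#' Returns displacements and the analytic strain fields (derivatives of the
#' spline, not finite differences).
#'
#' @param model a [bspline_disp_model()] (with `b` present if lateral output
#'   is needed).
#' @param x,y grid line coordinates (mm), inside the knot support.
#' @return list with `field` (a [disp_field()]) and strain matrices `exx`,
#'   `eyy`, `exy` indexed `[y, x]`; lateral entries are zero when `b` is
#'   absent.
#' @export
evaluate_model <- function(model, x, y) {
  n_cx <- ncol(model$a); n_cy <- nrow(model$a)
  Bx <- basis_matrix_1d(x, model$origin[1], model$spacing[1], n_cx)
  Bxd <- basis_matrix_1d(x, model$origin[1], model$spacing[1], n_cx, deriv = TRUE)
  By <- basis_matrix_1d(y, model$origin[2], model$spacing[2], n_cy)
  Byd <- basis_matrix_1d(y, model$origin[2], model$spacing[2], n_cy, deriv = TRUE)
  V <- as.matrix(By %*% model$a %*% Matrix::t(Bx))
  eyy <- as.matrix(Byd %*% model$a %*% Matrix::t(Bx))
  dVdx <- as.matrix(By %*% model$a %*% Matrix::t(Bxd))
  if (!is.null(model$b)) {
    U <- as.matrix(By %*% model$b %*% Matrix::t(Bx))
    exx <- as.matrix(By %*% model$b %*% Matrix::t(Bxd))
    dUdy <- as.matrix(Byd %*% model$b %*% Matrix::t(Bx))
  } else {
    U <- exx <- dUdy <- matrix(0, length(y), length(x))
  }
  list(field = disp_field(x = x, y = y, u = U, v = V),
       exx = exx, eyy = eyy, exy = 0.5 * (dUdy + dVdx))
}

#' @export
displacement_at.bspline_disp_model <- function(object, x, y) {
  n_cx <- ncol(object$a); n_cy <- nrow(object$a)
  Bx <- basis_matrix_1d(x, object$origin[1], object$spacing[1], n_cx)
  By <- basis_matrix_1d(y, object$origin[2], object$spacing[2], n_cy)
  # pointwise (not tensor-grid): row-wise product of the two basis rows
  v <- Matrix::rowSums((By %*% object$a) * Bx)
  u <- if (is.null(object$b)) rep(0, length(x)) else
    Matrix::rowSums((By %*% object$b) * Bx)
  list(u = as.numeric(u), v = as.numeric(v))
}

# control-grid geometry covering [lo, hi] with one-cell cubic margin
knot_grid_1d <- function(lo, hi, spacing) {
  n_cells <- max(1L, ceiling((hi - lo) / spacing - 1e-9))
  list(origin = lo, n_ctrl = n_cells + 3L)
}

#' Fit the axial control parameters to tracked displacements
#'
#' Least-squares fit of the bicubic spline's axial field `V(x, y)` to the
#' tracked axial displacements `V0` on the estimation grid, excluding masked
#' (invalid) samples. The normal equations are solved by sparse Cholesky
#' factorization.
#'
#' @param field a [disp_field()] with tracked axial displacements `v` and an
#'   optional validity `mask`.
#' @param spacing knot spacing `(lateral, axial)` mm.
#' @param support optional list `(x = c(lo, hi), y = c(lo, hi))` the knot
#'   grid must cover (defaults to the data extent); widen it when the model
#'   will be evaluated beyond the estimation grid.
#' @return a [bspline_model()] with fitted `a` (and `b = NULL`).
#' @export
fit_axial <- function(field, spacing = c(4.75, 4.82), support = NULL) {
  if (is.null(support))
    support <- list(x = range(field$x), y = range(field$y))
  gx <- knot_grid_1d(support$x[1], support$x[2], spacing[1])
  gy <- knot_grid_1d(support$y[1], support$y[2], spacing[2])
  valid <- !is.na(field$v)
  if (!is.null(field$mask)) valid <- valid & field$mask
  Bx <- basis_matrix_1d(field$x, gx$origin, spacing[1], gx$n_ctrl)
  By <- basis_matrix_1d(field$y, gy$origin, spacing[2], gy$n_ctrl)
  # grid design, x fastest; control vector ordered x-fastest within rows
  A <- Matrix::kronecker(By, Bx)
  pts <- as.vector(t(field$v))        # x fastest to match kron ordering
  ok <- as.vector(t(valid))
  A <- A[ok, , drop = FALSE]
  rhs <- pts[ok]
  unsupported <- which(Matrix::colSums(A != 0) == 0)
  if (length(unsupported) > 0) {
    jx <- (unsupported - 1) %% gx$n_ctrl + 1
    jy <- (unsupported - 1) %/% gx$n_ctrl + 1
    stop("rank-deficient fit: no data under control cells ",
         paste(sprintf("(%d,%d)", jy, jx), collapse = " "))
  }
  AtA <- Matrix::crossprod(A)
  coef <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(AtA),
                                              LDL = FALSE, perm = TRUE),
                             Matrix::crossprod(A, rhs))),
    error = function(e) stop("rank-deficient spline fit: ", conditionMessage(e)))
  a <- matrix(coef, gy$n_ctrl, gx$n_ctrl, byrow = TRUE)
  bspline_model(a, b = NULL, spacing = spacing,
                origin = c(gx$origin, gy$origin))
}

#' Derive the lateral control parameters from incompressibility
#'
#' Under plane strain with tissue incompressibility the normal strains
#' cancel, `exx + eyy = 0`. Given the fitted axial parameters, the lateral
#' control parameters `b` are the least-squares minimizer of the
#' incompressibility residual `sum (dU/dx + dV/dy)^2` over the evaluation
#' grid. The lateral field is determined only up to an additive function of
#' depth (a gauge); the gauge is fixed by constraining the mean of `U` along
#' each grid row to zero, appended as weighted rows of the least-squares
#' system. The inversion is insensitive to this choice.
#'
#' @param model a [bspline_model()] with fitted `a`.
#' @param x,y evaluation grid (mm) inside the knot support; defaults to a
#'   grid at half-knot resolution over the support.
#' @param gauge_weight weight of the zero-row-mean gauge rows.
#' @return the model with `b` filled in.
#' @export
derive_lateral <- function(model, x = NULL, y = NULL, gauge_weight = 1) {
  sup <- model_support(model)
  if (is.null(x)) x <- seq(sup$x[1], sup$x[2], by = model$spacing[1] / 4)
  if (is.null(y)) y <- seq(sup$y[1], sup$y[2], by = model$spacing[2] / 4)
  n_cx <- ncol(model$a); n_cy <- nrow(model$a)
  Bx <- basis_matrix_1d(x, model$origin[1], model$spacing[1], n_cx)
  Bxd <- basis_matrix_1d(x, model$origin[1], model$spacing[1], n_cx, deriv = TRUE)
  By <- basis_matrix_1d(y, model$origin[2], model$spacing[2], n_cy)
  Byd <- basis_matrix_1d(y, model$origin[2], model$spacing[2], n_cy, deriv = TRUE)
  eyy <- as.vector(t(as.matrix(Byd %*% model$a %*% Matrix::t(Bx)))) # x fastest
  S <- Matrix::kronecker(By, Bxd)                # dU/dx rows
  G <- Matrix::kronecker(By, Matrix::Matrix(matrix(Matrix::colMeans(Bx), 1),
                                            sparse = TRUE))
  A <- rbind(S, gauge_weight * G)
  rhs <- c(-eyy, rep(0, nrow(G)))
  AtA <- Matrix::crossprod(A)
  coef <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(AtA),
                                              LDL = FALSE, perm = TRUE),
                             Matrix::crossprod(A, rhs))),
    error = function(e) stop("rank-deficient lateral system beyond the gauge: ",
                             conditionMessage(e)))
  model$b <- matrix(coef, n_cy, n_cx, byrow = TRUE)
  model
}
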