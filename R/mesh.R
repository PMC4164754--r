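#' Regular quadrilateral mesh
#'
#' Builds a structured mesh of uniform bilinear quadrilateral elements over a
#' rectangular domain. Coordinates follow the imaging convention used
#' throughout the package: `x` is lateral (image width), `y` is axial (depth,
#' increasing downward, the compression direction). Lengths are in mm.
#'
#' Node and element indices are 1-based. Element `(i, j)` (column `i`, row
#' `j`) covers the cell `[x0 + (i-1) w, x0 + i w] x [y0 + (j-1) h, y0 + j h]`.
#' Element connectivity is counter-clockwise in the `(x, y)` plane starting
#' from the top-left corner of the cell.
#'
#' @param extent numeric length-2, `(height, width)` of the domain in mm.
#' @param element_size numeric length-2, `(height, width)` of one element in
#'   mm. Must divide `extent` to within rounding.
#' @param origin numeric length-2, `(x0, y0)` of the top-left corner (mm).
#' @return an object of class `quad_mesh`: a list with `nodes` (N x 2 matrix
#'   of `(x, y)` mm), `elems` (E x 4 integer connectivity), `nx`, `ny`
#'   (elements per direction), `element_size`, `origin`.
#' @export
quad_mesh <- function(extent, element_size, origin = c(0, 0)) {
  stopifnot(length(extent) == 2, length(element_size) == 2, all(extent > 0),
            all(element_size > 0))
  h <- element_size[1]; w <- element_size[2]
  ny <- round(extent[1] / h)
  nx <- round(extent[2] / w)
  if (abs(ny * h - extent[1]) > 1e-6 || abs(nx * w - extent[2]) > 1e-6)
    stop("element_size does not divide extent")
  xs <- origin[1] + (0:nx) * w
  ys <- origin[2] + (0:ny) * h
  # node (ix, iy) -> index: column-of-constant-y fastest in x
  nodes <- cbind(x = rep(xs, times = ny + 1), y = rep(ys, each = nx + 1))
  nid <- function(ix, iy) (iy - 1L) * (nx + 1L) + ix
  ei <- rep(1:nx, times = ny)
  ej <- rep(1:ny, each = nx)
  # counter-clockwise with y downward on screen: (TL, TR, BR, BL) traversed
  # so that the Jacobian is positive in the (x, y) frame
  elems <- cbind(nid(ei, ej), nid(ei + 1L, ej), nid(ei + 1L, ej + 1L),
                 nid(ei, ej + 1L))
  structure(list(nodes = nodes, elems = elems, nx = nx, ny = ny,
                 element_size = c(h, w), origin = origin),
            class = "quad_mesh")
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf("<quad_mesh> %d x %d elements (%g x %g mm), %d nodes\n",
              x$nx, x$ny, x$element_size[2], x$element_size[1],
              nrow(x$nodes)))
  invisible(x)
}

#' Element centers of a mesh
#'
#' @param mesh a [quad_mesh()].
#' @return E x 2 matrix of `(x, y)` element-center coordinates (mm).
#' @export
element_centers <- function(mesh) {
  xy <- (mesh$nodes[mesh$elems[, 1], , drop = FALSE] +
         mesh$nodes[mesh$elems[, 3], , drop = FALSE]) / 2
  colnames(xy) <- c("x", "y")
  xy
}

#' Plane-strain material description
#'
#' @param youngs_modulus per-element Young's modulus (kPa, or dimensionless
#'   when relative); recycled to the element count when scalar.
#' @param poisson_ratio Poisson ratio in (0, 0.5); defaults to 0.495, the
#'   near-incompressible value used for soft tissue.
#' @return object of class `plane_strain_material`.
#' @export
plane_strain_material <- function(youngs_modulus, poisson_ratio = 0.495) {
  if (any(youngs_modulus <= 0)) stop("youngs_modulus must be > 0")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (0, 0.5)")
  structure(list(E = as.numeric(youngs_modulus), nu = poisson_ratio),
            class = "plane_strain_material")
}

# plane-strain constitutive matrix for unit Young's modulus
plane_strain_C <- function(nu) {
  f <- 1 / ((1 + nu) * (1 - 2 * nu))
  f * matrix(c(1 - nu, nu, 0,
               nu, 1 - nu, 0,
               0, 0, (1 - 2 * nu) / 2), 3, 3, byrow = TRUE)
}

#' Bilinear quadrilateral element stiffness (plane strain)
#'
#' Computes the 8 x 8 stiffness matrix of a 4-node bilinear quadrilateral in
#' plane strain. Degrees of freedom are interleaved `(x1, y1, x2, y2, ...)`
#' in connectivity order. The matrix is linear in the Young's modulus:
#' `K(E) = E * K(1)`.
#'
#' With `integration = "selective"` (the default) the deviatoric (shear)
#' part is integrated with the 2 x 2 Gauss rule and the volumetric (lambda)
#' part with the 1-point rule — the standard selective-reduced-integration
#' element for near-incompressible material. At the Poisson ratio 0.495 used
#' for soft tissue the fully integrated bilinear quad locks volumetrically,
#' which makes the direct modulus inversion hypersensitive to any
#' displacement input that is not an exact equilibrium solution of the very
#' same mesh; selective reduced integration removes that failure mode.
#' `integration = "full"` (2 x 2 on everything) is kept for reference.
#'
#' @param corner_coords 4 x 2 matrix of corner `(x, y)` coordinates (mm),
#'   counter-clockwise.
#' @param modulus Young's modulus (> 0).
#' @param poisson Poisson ratio in (0, 0.5).
#' @param integration `"selective"` or `"full"`.
#' @param n_gauss points per direction of the Gauss rule used for the
#'   deviatoric part (and everything under `"full"`).
#' @return 8 x 8 symmetric stiffness matrix.
#' @export
element_stiffness <- function(corner_coords, modulus = 1, poisson = 0.495,
                              integration = c("selective", "full"),
                              n_gauss = 2) {
  stopifnot(nrow(corner_coords) == 4, ncol(corner_coords) == 2, modulus > 0)
  integration <- match.arg(integration)
  mu <- modulus / (2 * (1 + poisson))
  lambda <- modulus * poisson / ((1 + poisson) * (1 - 2 * poisson))
  C_mu <- mu * diag(c(2, 2, 1))
  C_lam <- lambda * matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  quad_B <- function(xi, eta) {
    dN <- matrix(c(-(1 - eta), -(1 - xi),
                    (1 - eta), -(1 + xi),
                    (1 + eta),  (1 + xi),
                   -(1 + eta),  (1 - xi)) / 4, 4, 2, byrow = TRUE)
    J <- t(dN) %*% corner_coords          # 2x2 Jacobian
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (detJ <= 0) stop("degenerate element geometry: non-positive Jacobian")
    dNxy <- dN %*% solve(t(J))            # derivatives wrt (x, y)
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNxy[, 1]
    B[2, seq(2, 8, 2)] <- dNxy[, 2]
    B[3, seq(1, 8, 2)] <- dNxy[, 2]
    B[3, seq(2, 8, 2)] <- dNxy[, 1]
    list(B = B, detJ = detJ)
  }
  integrate_K <- function(C, n) {
    gp <- gauss_points_1d(n)
    K <- matrix(0, 8, 8)
    for (a in seq_along(gp$x)) for (b in seq_along(gp$x)) {
      bb <- quad_B(gp$x[a], gp$x[b])
      K <- K + gp$w[a] * gp$w[b] * bb$detJ * (t(bb$B) %*% C %*% bb$B)
    }
    K
  }
  K <- if (integration == "full") {
    integrate_K(C_mu + C_lam, n_gauss)
  } else {
    integrate_K(C_mu, n_gauss) + integrate_K(C_lam, 1)
  }
  (K + t(K)) / 2
}

gauss_points_1d <- function(n) {
  switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
      b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    stop("unsupported Gauss rule"))
}

# interleaved dof indices for a set of nodes: node k -> (2k-1, 2k)
node_dofs <- function(nodes) {
  d <- rbind(2L * nodes - 1L, 2L * nodes)
  as.vector(d)
}

# dof index matrix for all elements: E x 8, interleaved (x,y) per node
element_dof_matrix <- function(elems) {
  E <- nrow(elems)
  out <- matrix(0L, E, 8)
  for (k in 1:4) {
    out[, 2 * k - 1] <- 2L * elems[, k] - 1L
    out[, 2 * k] <- 2L * elems[, k]
  }
  out
}

# TRUE when all elements share identical geometry up to translation
uniform_geometry <- function(mesh) {
  e1 <- mesh$elems[1, ]
  ref <- sweep(mesh$nodes[e1, , drop = FALSE], 2,
               mesh$nodes[e1[1], ], "-")
  for (k in 2:4) {
    d <- mesh$nodes[mesh$elems[, k], , drop = FALSE] -
      mesh$nodes[mesh$elems[, 1], , drop = FALSE]
    if (max(abs(sweep(d, 2, ref[k, ], "-"))) > 1e-9) return(FALSE)
  }
  TRUE
}

#' Assemble the global stiffness matrix
#'
#' Scatter-adds per-element stiffness into a sparse symmetric
#' `2 N_node x 2 N_node` matrix with interleaved `(x, y)` dofs. For uniform
#' meshes the unit element stiffness is computed once and scaled by each
#' element's modulus.
#'
#' @param mesh a [quad_mesh()].
#' @param material a [plane_strain_material()]; `E` scalar or per-element.
#' @param elements optional integer vector of element indices to assemble
#'   (default all); used by the inversion to assemble the boundary ring only.
#' @return sparse `dsCMatrix` global stiffness.
#' @export
assemble_global <- function(mesh, material, elements = NULL) {
  E <- material$E
  ne <- nrow(mesh$elems)
  if (length(E) == 1) E <- rep(E, ne)
  if (length(E) != ne) stop("modulus vector length does not match element count")
  if (is.null(elements)) elements <- seq_len(ne)
  dofs <- element_dof_matrix(mesh$elems[elements, , drop = FALSE])
  Ee <- E[elements]
  ndof <- 2L * nrow(mesh$nodes)
  if (uniform_geometry(mesh)) {
    K1 <- element_stiffness(mesh$nodes[mesh$elems[1, ], ], 1, material$nu)
    ii <- jj <- xx <- vector("list", 64)
    idx <- 1
    for (a in 1:8) for (b in 1:8) {
      ii[[idx]] <- dofs[, a]
      jj[[idx]] <- dofs[, b]
      xx[[idx]] <- Ee * K1[a, b]
      idx <- idx + 1
    }
    K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(ndof, ndof))
  } else {
    trip_i <- trip_j <- trip_x <- vector("list", length(elements))
    for (m in seq_along(elements)) {
      e <- elements[m]
      Ke <- element_stiffness(mesh$nodes[mesh$elems[e, ], ], Ee[m], material$nu)
      d <- dofs[m, ]
      trip_i[[m]] <- rep(d, times = 8)
      trip_j[[m]] <- rep(d, each = 8)
      trip_x[[m]] <- as.vector(Ke)
    }
    K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(ndof, ndof))
  }
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Boundary condition: prescribed nodal displacements
#'
#' @param node integer node indices.
#' @param axis `"x"` or `"y"` per entry (recycled).
#' @param value prescribed displacement in mm (recycled).
#' @return a `boundary_condition` tibble with one row per constrained dof.
#' @export
boundary_condition <- function(node, axis, value) {
  bc <- tibble::tibble(node = as.integer(node), axis = axis,
                       value = as.numeric(value))
  if (anyDuplicated(bc[c("node", "axis")]))
    stop("duplicate constrained degree of freedom")
  class(bc) <- c("boundary_condition", class(bc))
  bc
}

bc_dofs <- function(bc) {
  ifelse(bc$axis == "x", 2L * bc$node - 1L, 2L * bc$node)
}

#' Solve the forward plane-strain problem
#'
#' Direct sparse solve of `K d = f` under prescribed-displacement boundary
#' conditions (free dofs solved, prescribed dofs honored exactly).
#'
#' @param mesh a [quad_mesh()].
#' @param material a [plane_strain_material()].
#' @param bc a [boundary_condition()]; must remove all rigid-body modes.
#' @param f optional external force vector (length `2 N_node`, default zero).
#' @return list with `d` (nodal displacement vector, mm, interleaved dofs),
#'   `reactions` (forces at constrained dofs), `K` (assembled stiffness).
#' @export
solve_forward <- function(mesh, material, bc, f = NULL) {
  if (nrow(bc) < 3) stop("insufficient constraints: rigid-body modes remain")
  K <- assemble_global(mesh, material)
  ndof <- nrow(K)
  if (is.null(f)) f <- numeric(ndof)
  fixed <- bc_dofs(bc)
  if (anyDuplicated(fixed)) stop("duplicate constrained degree of freedom")
  free <- setdiff(seq_len(ndof), fixed)
  d <- numeric(ndof)
  d[fixed] <- bc$value
  rhs <- f[free] - K[free, fixed, drop = FALSE] %*% d[fixed]
  Kff <- K[free, free]
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                                   perm = TRUE),
                  rhs),
    error = function(e) stop("singular constrained system: ", conditionMessage(e)))
  d[free] <- as.numeric(sol)
  reac <- as.numeric(K[fixed, , drop = FALSE] %*% d) - f[fixed]
  list(d = d, reactions = stats::setNames(reac, fixed), K = K)
}

#' Interpolate a nodal displacement field
#'
#' Bilinear interpolation of interleaved nodal displacements of a uniform
#' [quad_mesh()] at arbitrary points inside the mesh. Exact for fields that
#' are bilinear per element.
#'
#' @param mesh a uniform [quad_mesh()].
#' @param d displacement vector (length `2 N_node`, interleaved).
#' @param x,y query coordinates (mm), equal length.
#' @return list with `u` (lateral) and `v` (axial) displacement at the points.
#' @export
interp_displacement <- function(mesh, d, x, y) {
  h <- mesh$element_size[1]; w <- mesh$element_size[2]
  lx <- (x - mesh$origin[1]) / w
  ly <- (y - mesh$origin[2]) / h
  eps <- 1e-9
  if (any(lx < -eps | lx > mesh$nx + eps | ly < -eps | ly > mesh$ny + eps))
    stop("query point outside mesh")
  ix <- pmin(pmax(floor(lx), 0), mesh$nx - 1)
  iy <- pmin(pmax(floor(ly), 0), mesh$ny - 1)
  tx <- lx - ix; ty <- ly - iy
  n00 <- (iy) * (mesh$nx + 1L) + ix + 1L      # top-left node of the cell
  n10 <- n00 + 1L
  n01 <- n00 + (mesh$nx + 1L)
  n11 <- n01 + 1L
  wgt <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  ux <- cbind(d[2 * n00 - 1], d[2 * n10 - 1], d[2 * n01 - 1], d[2 * n11 - 1])
  vy <- cbind(d[2 * n00], d[2 * n10], d[2 * n01], d[2 * n11])
  list(u = rowSums(wgt * ux), v = rowSums(wgt * vy))
}
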