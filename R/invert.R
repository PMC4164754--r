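#' Reconstruction region of interest
#'
#' Rectangle (mm) within the displacement-field support over which the
#' relative Young's modulus is reconstructed, plus the inversion element
#' size. A one-element-thick boundary ring around the rectangle must also
#' fit inside the displacement support; its elements are assigned unit
#' modulus (the modulus boundary condition).
#'
#' @param top,left position of the ROI's top-left corner (mm).
#' @param height,width ROI size (mm); rounded to whole elements.
#' @param element_size `(height, width)` of an inversion element, mm;
#'   default 0.48 x 0.48.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(top, left, height, width, element_size = c(0.48, 0.48)) {
  if (length(element_size) == 1) element_size <- rep(element_size, 2)
  structure(list(top = top, left = left, height = height, width = width,
                 element_size = element_size),
            class = "roi_spec")
}

# mesh over ROI + one-element ring, with element/node bookkeeping
roi_ring_mesh <- function(roi) {
  h <- roi$element_size[1]; w <- roi$element_size[2]
  ny <- round(roi$height / h); nx <- round(roi$width / w)
  if (ny < 2 || nx < 2) stop("ROI too small")
  mesh <- quad_mesh(extent = c((ny + 2) * h, (nx + 2) * w),
                    element_size = c(h, w),
                    origin = c(roi$left - w, roi$top - h))
  ei <- rep(1:(nx + 2), times = ny + 2)
  ej <- rep(1:(ny + 2), each = nx + 2)
  ring <- which(ei == 1 | ei == nx + 2 | ej == 1 | ej == ny + 2)
  roi_el <- setdiff(seq_len(nrow(mesh$elems)), ring)
  # nodes: outer perimeter of the full mesh vs nodes of ROI elements
  nxn <- mesh$nx + 1L; nyn <- mesh$ny + 1L
  ixn <- (seq_len(nxn * nyn) - 1L) %% nxn + 1L
  iyn <- (seq_len(nxn * nyn) - 1L) %/% nxn + 1L
  outer_nodes <- which(ixn == 1 | ixn == nxn | iyn == 1 | iyn == nyn)
  roi_nodes <- sort(unique(as.vector(mesh$elems[roi_el, ])))
  interface_nodes <- which((ixn == 2 | ixn == nxn - 1L) & iyn >= 2 & iyn <= nyn - 1L |
                           (iyn == 2 | iyn == nyn - 1L) & ixn >= 2 & ixn <= nxn - 1L)
  list(mesh = mesh, nx = nx, ny = ny, ring_elements = ring,
       roi_elements = roi_el, outer_nodes = outer_nodes,
       roi_nodes = roi_nodes, interface_nodes = interface_nodes)
}

# nodal displacement vector (interleaved) of a displacement source at the
# mesh nodes
nodal_displacements <- function(source, mesh) {
  uv <- displacement_at(source, mesh$nodes[, 1], mesh$nodes[, 2])
  d <- numeric(2 * nrow(mesh$nodes))
  d[seq(1, length(d), 2)] <- uv$u
  d[seq(2, length(d), 2)] <- uv$v
  d
}

#' Nodal forces from the unit-modulus boundary ring
#'
#' Assembles the stiffness of the one-element ring around the ROI with unit
#' Young's modulus and multiplies it by the ring's nodal displacements:
#' `f = K_ring d`. The result lives on the ring nodes — the outer perimeter
#' and the ROI interface — and vanishes elsewhere.
#'
#' @param roi a [roi_spec()].
#' @param source displacement source (see [displacement_at()]): typically a
#'   fitted [bspline_model()] or a forward `compression_solution`.
#' @param poisson Poisson ratio.
#' @return list with `f` (length `2 N_node` force vector over the ROI+ring
#'   mesh), `geom` (mesh bookkeeping), `d` (nodal displacements).
#' @export
boundary_forces <- function(roi, source, poisson = 0.495) {
  geom <- roi_ring_mesh(roi)
  d <- nodal_displacements(source, geom$mesh)
  K_ring <- assemble_global(geom$mesh, plane_strain_material(1, poisson),
                            elements = geom$ring_elements)
  f <- as.numeric(K_ring %*% d)
  list(f = f, geom = geom, d = d)
}

#' Modulus sensitivity matrix D
#'
#' For a fixed displacement field, nodal forces are linear in the per-element
#' moduli: column `e` of `D` is the global scatter of `K_e(1) d_e`, so that
#' `D E = K(E) d` for any modulus vector `E`. Rows are the interleaved dofs
#' of the ROI+ring mesh.
#'
#' @param geom ROI mesh bookkeeping from [boundary_forces()] (or
#'   `roi_ring_mesh`).
#' @param d nodal displacement vector over the mesh.
#' @param poisson Poisson ratio.
#' @return sparse `2 N_node x N_element` matrix over the ROI elements.
#' @export
assemble_D <- function(geom, d, poisson = 0.495) {
  mesh <- geom$mesh
  K1 <- element_stiffness(mesh$nodes[mesh$elems[1, ], ], 1, poisson)
  dofs <- element_dof_matrix(mesh$elems[geom$roi_elements, , drop = FALSE])
  Ue <- matrix(d[dofs], nrow(dofs), 8)     # element displacement vectors
  Fe <- Ue %*% K1                          # unit-modulus element forces
  ne <- length(geom$roi_elements)
  Matrix::sparseMatrix(i = as.vector(dofs),
                       j = rep(seq_len(ne), times = 8),
                       x = as.vector(Fe),
                       dims = c(2 * nrow(mesh$nodes), ne))
}

#' Least-squares modulus solve
#'
#' Solves `E = argmin || D E - f_full ||` with no regularization of any
#' kind. `f_full` carries the ring-derived interface forces (negated:
#' Newton's third law at the ring/ROI interface) and zeros at strictly
#' interior ROI nodes (static equilibrium, no body force); outer-perimeter
#' ring dofs are excluded from the system.
#'
#' @param D sensitivity matrix from [assemble_D()].
#' @param f_ring ring force vector from [boundary_forces()].
#' @param geom mesh bookkeeping.
#' @return numeric vector of relative Young's moduli, one per ROI element.
#' @export
solve_modulus <- function(D, f_ring, geom) {
  rows <- node_dofs(geom$roi_nodes)
  Dr <- D[rows, , drop = FALSE]
  f_full <- -f_ring[rows]
  DtD <- Matrix::crossprod(Dr)
  E <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(DtD),
                                              LDL = FALSE, perm = TRUE),
                             Matrix::crossprod(Dr, f_full))),
    error = function(e) {
      kappa <- tryCatch(Matrix::condest(DtD)$est, error = function(e2) NA)
      stop(sprintf(paste0("rank-deficient least-squares system ",
                          "(condition estimate %.3g): ROI too small or ",
                          "degenerate displacement field"), kappa))
    })
  if (any(E <= 0))
    warning(sprintf("%d non-positive moduli in the least-squares solution; reported as-is",
                    sum(E <= 0)))
  E
}

# unit-modulus deviatoric element stiffness: mu = 1/(2(1+nu)), lambda = 0
deviatoric_unit_stiffness <- function(corner_coords, poisson) {
  element_stiffness(corner_coords, modulus = 1 / (1 + poisson),
                    poisson = 1e-9)
}

# discrete pressure-gradient block: 2N_dof x N_node sparse matrix mapping a
# bilinear nodal pressure field to the nodal forces it exerts,
# f += int B_vol^T p dA per element, 2x2 quadrature
assemble_pressure_gradient <- function(mesh) {
  h <- mesh$element_size[1]; w <- mesh$element_size[2]
  dofs <- element_dof_matrix(mesh$elems)
  gp <- c(-1, 1) / sqrt(3); detJ <- h * w / 4
  nel <- nrow(mesh$elems); nn <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 128)
  idx <- 1
  for (a in 1:2) for (b in 1:2) {
    xi <- gp[a]; eta <- gp[b]
    dN <- matrix(c(-(1 - eta), -(1 - xi),
                    (1 - eta), -(1 + xi),
                    (1 + eta),  (1 + xi),
                   -(1 + eta),  (1 - xi)) / 4, 4, 2, byrow = TRUE)
    dNxy <- dN %*% diag(c(2 / w, 2 / h))
    Bvol <- numeric(8)
    Bvol[seq(1, 8, 2)] <- dNxy[, 1]
    Bvol[seq(2, 8, 2)] <- dNxy[, 2]
    N <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
    for (ldof in 1:8) for (jn in 1:4) {
      ii[[idx]] <- dofs[, ldof]
      jj[[idx]] <- mesh$elems[, jn]
      xx[[idx]] <- rep(detJ * Bvol[ldof] * N[jn], nel)
      idx <- idx + 1
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2 * nn, nn))
}

sparse_lsq <- function(A, b, context) {
  sol <- tryCatch(Matrix::qr.coef(Matrix::qr(A), b),
                  error = function(e) stop(context, ": ", conditionMessage(e)))
  if (anyNA(sol))
    stop(context, ": rank-deficient least-squares system (ROI too small or ",
         "degenerate displacement field)")
  as.numeric(sol)
}

#' Reconstruct a relative Young's modulus image
#'
#' Regularization-free FEM direct inversion: evaluate the displacement
#' source at the nodes of the ROI+ring mesh, anchor the scale with the
#' unit-modulus boundary ring, and solve an overdetermined linear system
#' for the per-element relative modulus by least squares.
#'
#' Two formulations of the element equilibrium are available:
#'
#' * `"mixed"` (default): the incompressible-limit mixed model. Element
#'   forces split into a deviatoric part, `2 mu eps_dev` with
#'   `mu = E / (2 (1 + nu))`, and a hydrostatic pressure field discretized
#'   as bilinear nodal values; the pressure values join the modulus vector
#'   as least-squares unknowns. This is the numerically sound treatment for
#'   near-incompressible tissue: the displacement data carry no usable
#'   volumetric-strain information (at nu = 0.495 the true `div u` is only
#'   ~3% of the strain scale, and the incompressibility-derived lateral
#'   field is divergence-free by construction), so the pressure must be
#'   treated as an unknown rather than penalized out of `div u`.
#' * `"penalty"`: the displacement-only formulation in which each element's
#'   full near-incompressible stiffness `K_e(E, nu)` acts on the data. It
#'   is exact when the displacement input is an equilibrium solution of the
#'   same mesh, and is the formulation the exact-recovery tests exercise;
#'   on any other input at nu near 0.5 its lambda-weighted volumetric term
#'   amplifies small inconsistencies catastrophically (see the package
#'   vignette).
#'
#' Neither formulation contains a regularization term; the only unknowns
#' are physical fields.
#'
#' @inheritParams boundary_forces
#' @param formulation `"mixed"` or `"penalty"` (see Details).
#' @return object of class `modulus_image`: list with `E` (ny x nx matrix of
#'   relative moduli over the ROI), `x`, `y` (element-center coordinates,
#'   mm), `roi`, `poisson`, `formulation`.
#' @export
reconstruct_modulus <- function(roi, source, poisson = 0.495,
                                formulation = c("mixed", "penalty")) {
  formulation <- match.arg(formulation)
  if (formulation == "penalty") {
    bf <- boundary_forces(roi, source, poisson)
    D <- assemble_D(bf$geom, bf$d, poisson)
    E <- solve_modulus(D, bf$f, bf$geom)
    geom <- bf$geom
  } else {
    geom <- roi_ring_mesh(roi)
    mesh <- geom$mesh
    nn <- nrow(mesh$nodes)
    d <- nodal_displacements(source, mesh)
    K_mu <- deviatoric_unit_stiffness(mesh$nodes[mesh$elems[1, ], ], poisson)
    dofs_all <- element_dof_matrix(mesh$elems)
    Fe <- matrix(d[dofs_all], nrow(dofs_all), 8) %*% K_mu
    ne_roi <- length(geom$roi_elements)
    D_mu <- Matrix::sparseMatrix(
      i = as.vector(dofs_all[geom$roi_elements, ]),
      j = rep(seq_len(ne_roi), times = 8),
      x = as.vector(Fe[geom$roi_elements, ]),
      dims = c(2 * nn, ne_roi))
    ring_dofs <- as.vector(dofs_all[geom$ring_elements, ])
    f_ring <- numeric(2 * nn)
    acc <- rowsum(as.vector(Fe[geom$ring_elements, ]), ring_dofs)
    f_ring[as.integer(rownames(acc))] <- acc[, 1]
    G <- assemble_pressure_gradient(mesh)
    # pressure unknowns at interior mesh nodes (outer perimeter excluded)
    nxn <- mesh$nx + 1L; nyn <- mesh$ny + 1L
    ixn <- (seq_len(nn) - 1L) %% nxn + 1L
    iyn <- (seq_len(nn) - 1L) %/% nxn + 1L
    p_sel <- which(ixn > 1 & ixn < nxn & iyn > 1 & iyn < nyn)
    rows <- node_dofs(geom$roi_nodes)
    A <- cbind(D_mu[rows, , drop = FALSE], G[rows, p_sel, drop = FALSE])
    coef <- sparse_lsq(A, -f_ring[rows], "modulus inversion")
    E <- coef[seq_len(ne_roi)]
    if (any(E <= 0))
      warning(sprintf("%d non-positive moduli in the least-squares solution; reported as-is",
                      sum(E <= 0)))
  }
  ctr <- element_centers(geom$mesh)[geom$roi_elements, , drop = FALSE]
  xs <- sort(unique(round(ctr[, 1], 9)))
  ys <- sort(unique(round(ctr[, 2], 9)))
  structure(list(E = matrix(E, geom$ny, geom$nx, byrow = TRUE),
                 x = xs, y = ys, roi = roi, poisson = poisson,
                 formulation = formulation),
            class = "modulus_image")
}

#' @export
print.modulus_image <- function(x, ...) {
  cat(sprintf("<modulus_image> %d x %d elements (%g x %g mm), relative modulus range [%.3g, %.3g]\n",
              ncol(x$E), nrow(x$E), x$roi$element_size[2],
              x$roi$element_size[1], min(x$E), max(x$E)))
  invisible(x)
}
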