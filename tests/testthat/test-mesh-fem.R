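test_that("element stiffness has the rigid-body null space and is linear in E", {
  co <- matrix(c(0, 0, 1.3, 0.1, 1.2, 1.1, -0.1, 0.9), 4, 2, byrow = TRUE)
  K <- element_stiffness(co, modulus = 3.7, poisson = 0.3)
  # pure x-translation and pure y-translation produce zero force
  tx <- rep(c(1, 0), 4); ty <- rep(c(0, 1), 4)
  expect_lt(max(abs(K %*% tx)), 1e-12)
  expect_lt(max(abs(K %*% ty)), 1e-12)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_equal(element_stiffness(co, 2, 0.3), 2 * element_stiffness(co, 1, 0.3))
  # both integration rules share these properties
  Ks <- element_stiffness(co, 1, 0.495, integration = "selective")
  expect_lt(max(abs(Ks %*% tx)), 1e-12)
  expect_lt(max(abs(Ks - t(Ks))), 1e-12)
})

test_that("fully integrated stiffness matches brute-force B'CB integration", {
  # independent oracle: 4x4 Gauss quadrature assembled from first principles
  brute_force_K <- function(co, E, nu) {
    C <- E / ((1 + nu) * (1 - 2 * nu)) *
      matrix(c(1 - nu, nu, 0, nu, 1 - nu, 0, 0, 0, (1 - 2 * nu) / 2), 3, 3)
    a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)); b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
    gx <- c(-b, -a, a, b)
    gw <- c(18 - sqrt(30), 18 + sqrt(30), 18 + sqrt(30), 18 - sqrt(30)) / 36
    K <- matrix(0, 8, 8)
    for (i in 1:4) for (j in 1:4) {
      xi <- gx[i]; eta <- gx[j]
      dN <- matrix(c(-(1 - eta), -(1 - xi), (1 - eta), -(1 + xi),
                     (1 + eta), (1 + xi), -(1 + eta), (1 - xi)) / 4,
                   4, 2, byrow = TRUE)
      J <- t(dN) %*% co
      dNxy <- dN %*% solve(t(J))
      B <- matrix(0, 3, 8)
      B[1, seq(1, 8, 2)] <- dNxy[, 1]; B[2, seq(2, 8, 2)] <- dNxy[, 2]
      B[3, seq(1, 8, 2)] <- dNxy[, 2]; B[3, seq(2, 8, 2)] <- dNxy[, 1]
      K <- K + gw[i] * gw[j] * det(J) * t(B) %*% C %*% B
    }
    K
  }
  co <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)  # unit square
  K <- element_stiffness(co, 1, 0.3, integration = "full")
  expect_lt(max(abs(K - brute_force_K(co, 1, 0.3))), 1e-12)
})

test_that("degenerate element geometry is rejected", {
  co <- matrix(c(0, 0, 1, 0, 2, 0, 3, 0), 4, 2, byrow = TRUE)  # collinear
  expect_error(element_stiffness(co, 1, 0.3), "Jacobian")
})

test_that("global assembly matches a dense scatter-add oracle", {
  mesh <- quad_mesh(c(2, 2), c(1, 1))
  mat <- plane_strain_material(c(1, 2, 3, 4), 0.4)
  K <- as.matrix(assemble_global(mesh, mat))
  ndof <- 2 * nrow(mesh$nodes)
  K_oracle <- matrix(0, ndof, ndof)
  for (e in seq_len(nrow(mesh$elems))) {
    Ke <- element_stiffness(mesh$nodes[mesh$elems[e, ], ], mat$E[e], mat$nu)
    dofs <- as.vector(rbind(2 * mesh$elems[e, ] - 1, 2 * mesh$elems[e, ]))
    K_oracle[dofs, dofs] <- K_oracle[dofs, dofs] + Ke
  }
  expect_lt(max(abs(K - K_oracle)), 1e-12)
  # single element mesh: global equals element matrix (connectivity dofs)
  m1 <- quad_mesh(c(1, 1), c(1, 1))
  K1 <- as.matrix(assemble_global(m1, plane_strain_material(2, 0.3)))
  dofs1 <- as.vector(rbind(2 * m1$elems[1, ] - 1, 2 * m1$elems[1, ]))
  expect_lt(max(abs(K1[dofs1, dofs1] -
                    element_stiffness(m1$nodes[m1$elems[1, ], ], 2, 0.3))),
            1e-12)
})

test_that("assembled stiffness has exactly three rigid-body modes", {
  mesh <- quad_mesh(c(3, 3), c(1, 1))
  K <- as.matrix(assemble_global(mesh, plane_strain_material(1, 0.3)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 3)
  # translation invariance: row sums over x-dofs and y-dofs vanish
  tx <- rep(c(1, 0), nrow(mesh$nodes))
  expect_lt(max(abs(K %*% tx)), 1e-9)
})

test_that("forward solve reproduces the homogeneous plane-strain closed form", {
  nu <- 0.495
  ph <- homogeneous_phantom(extent = c(10, 10), element = 0.5, nu = nu)
  sol <- simulate_compression(ph, 0.02)
  f <- sample_compression(sol, x = seq(1, 9, 0.5), y = seq(1, 9, 0.5))
  eyy <- diff(f$v[, 1]) / 0.5
  exx <- diff(f$u[1, ]) / 0.5
  expect_lt(max(abs(eyy + 0.02)), 1e-8 * 0.02 + 1e-10)
  expect_lt(max(abs(exx - nu / (1 - nu) * 0.02)), 1e-8)
  # zero applied displacement: zero field
  sol0 <- simulate_compression(ph, 0)
  expect_equal(max(abs(sol0$d)), 0)
})

test_that("forward solve honors constraints, equilibrium and modulus scaling", {
  ph <- homogeneous_phantom(extent = c(4, 4), element = 0.5, E = 2)
  mesh <- ph$mesh
  top <- which(abs(mesh$nodes[, 2]) < 1e-9)
  bottom <- which(abs(mesh$nodes[, 2] - 4) < 1e-9)
  bc <- boundary_condition(node = c(top, bottom, bottom[1]),
                           axis = c(rep("y", length(top) + length(bottom)), "x"),
                           value = c(rep(0.05, length(top)),
                                     rep(0, length(bottom) + 1)))
  s1 <- solve_forward(mesh, ph$material, bc)
  expect_equal(s1$d[2 * top], rep(0.05, length(top)))
  # reactions balance: sum of axial reactions is zero
  ry <- s1$reactions[names(s1$reactions) %in% as.character(2 * c(top, bottom))]
  expect_lt(abs(sum(ry)), 1e-9 * max(abs(ry)))
  # scaling all moduli leaves displacements unchanged, scales reactions
  mat2 <- plane_strain_material(ph$material$E * 3, ph$material$nu)
  s2 <- solve_forward(mesh, mat2, bc)
  expect_equal(s2$d, s1$d, tolerance = 1e-9)
  expect_equal(as.numeric(s2$reactions), 3 * as.numeric(s1$reactions),
               tolerance = 1e-9)
})

test_that("insufficient constraints raise an explicit error", {
  ph <- homogeneous_phantom(extent = c(2, 2), element = 1)
  bc <- boundary_condition(node = c(1, 1), axis = c("x", "y"), value = 0)
  expect_error(solve_forward(ph$mesh, ph$material, bc))
})

test_that("distorted-mesh patch test reproduces a linear field exactly", {
  mesh <- quad_mesh(c(3, 3), c(1, 1))
  nx <- mesh$nx
  interior <- which(mesh$nodes[, 1] > 0 & mesh$nodes[, 1] < 3 &
                    mesh$nodes[, 2] > 0 & mesh$nodes[, 2] < 3)
  set.seed(11)
  mesh$nodes[interior, ] <- mesh$nodes[interior, ] +
    matrix(stats::runif(2 * length(interior), -0.18, 0.18),
           length(interior), 2)
  lin_u <- function(x, y) 0.01 * x + 0.003 * y + 0.002
  lin_v <- function(x, y) -0.004 * x + 0.008 * y - 0.001
  boundary <- setdiff(seq_len(nrow(mesh$nodes)), interior)
  bc <- boundary_condition(
    node = rep(boundary, each = 2),
    axis = rep(c("x", "y"), length(boundary)),
    value = as.vector(rbind(lin_u(mesh$nodes[boundary, 1], mesh$nodes[boundary, 2]),
                            lin_v(mesh$nodes[boundary, 1], mesh$nodes[boundary, 2]))))
  sol <- solve_forward(mesh, plane_strain_material(1, 0.3), bc)
  expect_lt(max(abs(sol$d[2 * interior - 1] -
                    lin_u(mesh$nodes[interior, 1], mesh$nodes[interior, 2]))), 1e-10)
  expect_lt(max(abs(sol$d[2 * interior] -
                    lin_v(mesh$nodes[interior, 1], mesh$nodes[interior, 2]))), 1e-10)
})

test_that("forward solutions converge under mesh refinement", {
  spec <- phantom_spec(extent = c(9.6, 9.6),
                       inclusions = tibble::tibble(x = 4.8, y = 4.8,
                                                   diameter = 3, modulus = 75))
  probe_x <- seq(1.2, 8.4, 0.6); probe_y <- seq(1.2, 8.4, 0.6)
  sols <- lapply(c(0.6, 0.3, 0.15), function(h) {
    ph <- build_phantom(spec, h)
    sample_compression(simulate_compression(ph, 0.02), probe_x, probe_y)
  })
  d21 <- sqrt(mean((sols[[2]]$v - sols[[1]]$v)^2 + (sols[[2]]$u - sols[[1]]$u)^2))
  d32 <- sqrt(mean((sols[[3]]$v - sols[[2]]$v)^2 + (sols[[3]]$u - sols[[2]]$u)^2))
  expect_lt(d32, d21)
})
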