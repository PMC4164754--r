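test_that("boundary forces vanish for rigid motion and scale linearly", {
  sc <- small_scene()
  rigid <- uniform_field(0.3, -0.2, extent = c(10, 10))
  bf <- boundary_forces(sc$roi, rigid, 0.495)
  expect_lt(max(abs(bf$f)), 1e-10)
  bf1 <- boundary_forces(sc$roi, sc$sol, 0.495)
  sol2 <- sc$sol; sol2$d <- 2.5 * sc$sol$d
  bf2 <- boundary_forces(sc$roi, sol2, 0.495)
  expect_equal(bf2$f, 2.5 * bf1$f, tolerance = 1e-12)
})

test_that("ring forces match an independent per-element oracle", {
  sc <- small_scene()
  bf <- boundary_forces(sc$roi, sc$sol, 0.495)
  geom <- bf$geom
  f_oracle <- numeric(length(bf$f))
  for (e in geom$ring_elements) {
    nodes <- geom$mesh$elems[e, ]
    Ke <- element_stiffness(geom$mesh$nodes[nodes, ], 1, 0.495)
    dofs <- as.vector(rbind(2 * nodes - 1, 2 * nodes))
    f_oracle[dofs] <- f_oracle[dofs] + as.numeric(Ke %*% bf$d[dofs])
  }
  expect_lt(max(abs(bf$f - f_oracle)), 1e-10)
  # forces live on ring nodes only
  ring_nodes <- sort(unique(as.vector(geom$mesh$elems[geom$ring_elements, ])))
  off_ring <- setdiff(seq_len(nrow(geom$mesh$nodes)), ring_nodes)
  expect_lt(max(abs(bf$f[elastofem:::node_dofs(off_ring)])), 1e-14)
})

test_that("D matrix satisfies D E = K(E) d and structural properties", {
  sc <- small_scene()
  bf <- boundary_forces(sc$roi, sc$sol, 0.495)
  D <- assemble_D(bf$geom, bf$d, 0.495)
  geom <- bf$geom
  set.seed(31)
  for (k in 1:5) {
    E <- stats::runif(length(geom$roi_elements), 0.5, 3)
    K <- assemble_global(geom$mesh,
                         plane_strain_material(
                           replace(rep(1e-9, nrow(geom$mesh$elems)),
                                   geom$roi_elements, E), 0.495),
                         elements = geom$roi_elements)
    lhs <- as.numeric(D %*% E)
    rhs <- as.numeric(K %*% bf$d)
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-12)
  }
  # zero displacement -> zero D
  D0 <- assemble_D(geom, bf$d * 0, 0.495)
  expect_equal(Matrix::nnzero(D0), 0)
  # uniform elements: identical column sparsity pattern up to index shift
  expect_equal(length(unique(diff(D@p))), 1)
})

test_that("penalty inversion exactly recovers moduli on coincident meshes", {
  sc <- small_scene()
  img <- reconstruct_modulus(sc$roi, sc$sol, 0.495, formulation = "penalty")
  truth <- true_modulus_image(sc$spec, sc$roi)
  expect_lt(max(abs(img$E - truth) / truth), 1e-6)
})

test_that("homogeneous medium with closed-form displacements inverts to unity", {
  nu <- 0.495; eps <- 0.02
  # plane-strain slip-compression closed form is linear in (x, y), so a
  # bilinear field on corner points represents it exactly
  xs <- c(0, 10); ys <- c(0, 10)
  closed <- disp_field(x = xs, y = ys,
                       u = outer(rep(1, 2), nu / (1 - nu) * eps * (xs - 5)),
                       v = outer(eps * (10 - ys), rep(1, 2)))
  roi <- roi_spec(top = 2, left = 2, height = 6, width = 6,
                  element_size = c(1, 1))
  for (form in c("penalty", "mixed")) {
    img <- reconstruct_modulus(roi, closed, nu, formulation = form)
    expect_lt(max(abs(img$E - 1)), 1e-4)
  }
})

test_that("reconstruction is invariant to displacement scale", {
  sc <- small_scene()
  img1 <- suppressWarnings(reconstruct_modulus(sc$roi, sc$sol, 0.495))
  sol2 <- sc$sol; sol2$d <- 3 * sc$sol$d
  img2 <- suppressWarnings(reconstruct_modulus(sc$roi, sol2, 0.495))
  expect_lt(max(abs(img1$E - img2$E)), 1e-8)
})

test_that("degenerate inversion inputs raise explicit errors", {
  sc <- small_scene()
  zero <- uniform_field(0, 0, extent = c(10, 10))
  expect_error(reconstruct_modulus(sc$roi, zero, 0.495),
               "rank-deficient|degenerate")
  # ROI touching the field edge: no room for the ring
  roi_edge <- roi_spec(top = 0, left = 0, height = 6, width = 6,
                       element_size = c(1, 1))
  expect_error(reconstruct_modulus(roi_edge, sc$sol, 0.495))
})

test_that("mixed inversion tolerates cross-mesh data where penalty collapses", {
  # fine-mesh forward solve, coarse inversion mesh: the near-incompressible
  # penalty operator amplifies the discretization mismatch catastrophically,
  # the mixed (explicit-pressure) formulation does not
  spec <- phantom_spec(extent = c(19.2, 19.2),
                       inclusions = tibble::tibble(x = 9.6, y = 9.6,
                                                   diameter = 5, modulus = 75))
  ph <- build_phantom(spec, 0.24)
  sol <- simulate_compression(ph, 0.02)
  roi <- roi_spec(top = 4.8, left = 4.8, height = 9.6, width = 9.6)
  truth <- true_modulus_image(spec, roi)
  img_mixed <- suppressWarnings(
    reconstruct_modulus(roi, sol, 0.495, formulation = "mixed"))
  img_pen <- suppressWarnings(
    reconstruct_modulus(roi, sol, 0.495, formulation = "penalty"))
  expect_lt(abs(mean_relative_error(img_mixed$E, truth)), 10)
  expect_gt(abs(mean_relative_error(img_pen$E, truth)), 20)
  # mixed formulation preserves the stiff-inclusion contrast
  expect_gt(mean(img_mixed$E[truth > 1]), 1.5)
})
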