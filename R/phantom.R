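#' Inclusion phantom specification
#'
#' Describes a rectangular soft-tissue phantom with circular stiff inclusions
#' embedded in a homogeneous background, the standard test object of
#' quasi-static elastography simulation studies. The default reproduces the
#' two-inclusion study phantom: 38 x 38 mm, two 6.5 mm inclusions of 75 kPa
#' in a 25 kPa background, Poisson ratio 0.495.
#'
#' @param extent `(height, width)` mm.
#' @param background_modulus background Young's modulus (kPa).
#' @param inclusions data frame with columns `x`, `y` (center, mm),
#'   `diameter` (mm), `modulus` (kPa); may have zero rows.
#' @param poisson_ratio Poisson ratio in (0, 0.5).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent = c(38, 38),
                         background_modulus = 25,
                         inclusions = tibble::tibble(
                           x = c(13, 25), y = c(19, 19),
                           diameter = c(6.5, 6.5), modulus = c(75, 75)),
                         poisson_ratio = 0.495) {
  inclusions <- tibble::as_tibble(inclusions)
  if (nrow(inclusions) > 0) {
    if (any(inclusions$modulus <= 0)) stop("inclusion moduli must be > 0")
    r <- inclusions$diameter / 2
    inside <- inclusions$x - r >= 0 & inclusions$x + r <= extent[2] &
      inclusions$y - r >= 0 & inclusions$y + r <= extent[1]
    if (!all(inside)) stop("inclusion extends outside the phantom extent")
  }
  if (background_modulus <= 0) stop("background modulus must be > 0")
  structure(list(extent = extent, background_modulus = background_modulus,
                 inclusions = inclusions, poisson_ratio = poisson_ratio),
            class = "phantom_spec")
}

#' Build the FEM phantom
#'
#' Meshes a [phantom_spec()] with uniform quadrilateral elements and assigns
#' each element the inclusion modulus iff its center lies inside an inclusion
#' circle, else the background modulus.
#'
#' @param spec a [phantom_spec()].
#' @param element_size element `(height, width)` mm (scalar recycled).
#' @return list with `mesh` ([quad_mesh()]) and `material`
#'   ([plane_strain_material()]).
#' @export
build_phantom <- function(spec, element_size) {
  if (length(element_size) == 1) element_size <- rep(element_size, 2)
  mesh <- quad_mesh(spec$extent, element_size)
  ctr <- element_centers(mesh)
  E <- rep(spec$background_modulus, nrow(mesh$elems))
  if (nrow(spec$inclusions) > 0) {
    for (k in seq_len(nrow(spec$inclusions))) {
      inc <- spec$inclusions[k, ]
      r2 <- (ctr[, 1] - inc$x)^2 + (ctr[, 2] - inc$y)^2
      E[r2 < (inc$diameter / 2)^2] <- inc$modulus
    }
  }
  list(mesh = mesh,
       material = plane_strain_material(E, spec$poisson_ratio))
}

#' Simulate quasi-static compression of a phantom
#'
#' Solves the plane-strain forward problem for an axial compression applied
#' between perfect-slip surfaces: the top surface is displaced downward by
#' `strain * height` with free lateral motion, the bottom surface is fixed
#' axially (slip), and the sides are free. One lateral dof at the bottom
#' center is pinned to remove the lateral rigid-body mode.
#'
#' `contact_width` narrower than the phantom models a finite compressor: the
#' axial displacement is prescribed only on top nodes within the contact,
#' which produces the depth-decaying stress field responsible for the
#' target-hardening artifact in strain images.
#'
#' @param phantom list `(mesh, material)` from [build_phantom()].
#' @param applied_strain compressional axial strain as a fraction in (0, 0.05].
#' @param contact_width width of the compressing surface (mm); default the
#'   full phantom width (perfect slip over the whole surface).
#' @return list with `d` (nodal displacements, mm), `mesh`, `material`,
#'   `applied_strain`, and `field(x, y)` accessor via [interp_displacement()].
#' @export
simulate_compression <- function(phantom, applied_strain,
                                 contact_width = NULL) {
  if (applied_strain < 0 || applied_strain > 0.05)
    stop("applied_strain must lie in [0, 0.05]")
  mesh <- phantom$mesh
  height <- mesh$ny * mesh$element_size[1]
  width <- mesh$nx * mesh$element_size[2]
  if (is.null(contact_width)) contact_width <- width
  xs <- mesh$nodes[, 1]; ys <- mesh$nodes[, 2]
  top <- which(abs(ys - mesh$origin[2]) < 1e-9)
  bottom <- which(abs(ys - (mesh$origin[2] + height)) < 1e-9)
  cx <- mesh$origin[1] + width / 2
  top_contact <- top[abs(xs[top] - cx) <= contact_width / 2 + 1e-9]
  pin <- bottom[which.min(abs(xs[bottom] - cx))]
  bc <- boundary_condition(
    node = c(top_contact, bottom, pin),
    axis = c(rep("y", length(top_contact)), rep("y", length(bottom)), "x"),
    value = c(rep(applied_strain * height, length(top_contact)),
              rep(0, length(bottom)), 0))
  sol <- if (applied_strain == 0) {
    list(d = numeric(2 * nrow(mesh$nodes)))
  } else {
    solve_forward(mesh, phantom$material, bc)
  }
  out <- list(d = sol$d, mesh = mesh, material = phantom$material,
              applied_strain = applied_strain)
  class(out) <- "compression_solution"
  out
}

#' Sample a compression solution onto a regular imaging grid
#'
#' @param sol a `compression_solution` from [simulate_compression()].
#' @param x,y grid line coordinates (mm).
#' @return a `disp_field` (see [disp_field()]) with matrices indexed
#'   `[y, x]`.
#' @export
sample_compression <- function(sol, x, y) {
  g <- expand.grid(x = x, y = y)
  uv <- interp_displacement(sol$mesh, sol$d, g$x, g$y)
  disp_field(x = x, y = y,
             u = matrix(uv$u, length(y), length(x), byrow = TRUE),
             v = matrix(uv$v, length(y), length(x), byrow = TRUE))
}

#' Displacement field on a regular grid
#'
#' Container for axial (`v`) and lateral (`u`) displacement components
#' sampled on a regular 2D grid with physical coordinates in mm. Matrices are
#' indexed `[y, x]` (row = depth).
#'
#' @param x,y grid coordinates (mm).
#' @param u,v lateral and axial displacement matrices (mm), `length(y)` rows
#'   by `length(x)` columns.
#' @param mask optional logical matrix of valid entries.
#' @param correlation optional matching-quality matrix.
#' @return object of class `disp_field`.
#' @export
disp_field <- function(x, y, u, v, mask = NULL, correlation = NULL) {
  stopifnot(all(dim(v) == c(length(y), length(x))), all(dim(u) == dim(v)))
  structure(list(x = x, y = y, u = u, v = v,
                 mask = mask, correlation = correlation),
            class = "disp_field")
}

#' @export
print.disp_field <- function(x, ...) {
  cat(sprintf("<disp_field> %d x %d grid, x in [%.2f, %.2f] mm, y in [%.2f, %.2f] mm\n",
              length(x$y), length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Random scatterer population
#'
#' Draws uniformly distributed point scatterers with standard-normal
#' amplitudes, the standard fully-developed-speckle model. Reproducible under
#' a fixed seed.
#'
#' @param extent `(height, width)` mm.
#' @param density scatterers per mm^2 (default 200, above the
#'   fully-developed-speckle threshold).
#' @param seed integer RNG seed.
#' @return tibble with columns `x`, `y` (mm) and `amplitude`.
#' @export
make_scatterers <- function(extent, density = 200, seed = 1L) {
  if (density <= 0) stop("density must be > 0")
  n <- round(density * extent[1] * extent[2])
  rng <- local_rng(seed)
  tibble::tibble(x = rng$runif(n, 0, extent[2]),
                 y = rng$runif(n, 0, extent[1]),
                 amplitude = rng$rnorm(n))
}

# private RNG stream that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  run <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = run(stats::runif), rnorm = run(stats::rnorm))
}

#' Linear-array transducer description
#'
#' Defaults follow a 320-element linear array: 6 MHz center frequency, 50%
#' -3 dB fractional bandwidth, 32 MHz sampling, 0.12 mm pitch, 1540 m/s sound
#' speed, focal depth 19 mm, F-number 0.5.
#'
#' @param center_frequency MHz.
#' @param fractional_bandwidth -3 dB bandwidth as a fraction of the center
#'   frequency.
#' @param sampling_frequency MHz; must exceed twice the center frequency.
#' @param pitch element pitch (mm).
#' @param n_lines number of image lines.
#' @param sound_speed m/s.
#' @param focal_depth mm (sets the lateral beam width via the F-number).
#' @param f_number focal depth / aperture.
#' @return object of class `transducer_spec`.
#' @export
transducer_spec <- function(center_frequency = 6, fractional_bandwidth = 0.5,
                            sampling_frequency = 32, pitch = 0.12,
                            n_lines = 320, sound_speed = 1540,
                            focal_depth = 19, f_number = 0.5) {
  if (sampling_frequency <= 2 * center_frequency)
    stop("sampling frequency must exceed twice the center frequency")
  structure(list(f0 = center_frequency, bw = fractional_bandwidth,
                 fs = sampling_frequency, pitch = pitch, n_lines = n_lines,
                 c = sound_speed, focal_depth = focal_depth,
                 f_number = f_number),
            class = "transducer_spec")
}

# axial mm per RF sample: c/(2 fs), c in m/s and fs in MHz
axial_sample_spacing <- function(td) td$c / (2 * td$fs * 1e3)
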