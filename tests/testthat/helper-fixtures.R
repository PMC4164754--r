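# shared fixtures; expensive study-scale objects are computed once per run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, fn(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# homogeneous block phantom without inclusions
homogeneous_phantom <- function(extent = c(10, 10), element = 0.5,
                                E = 25, nu = 0.495) {
  spec <- phantom_spec(extent = extent, background_modulus = E,
                       inclusions = tibble::tibble(
                         x = numeric(), y = numeric(),
                         diameter = numeric(), modulus = numeric()),
                       poisson_ratio = nu)
  build_phantom(spec, element)
}

# small RF scene: 12 mm deep, 48 lines, used by rf/tracking tests
small_transducer <- function() transducer_spec(n_lines = 48)

small_rf_frame <- function(displacement = NULL, snr_db = NULL, seed = 5L) {
  scat <- fixture("small_scatterers", function()
    make_scatterers(c(12, 48 * 0.12), 200, seed = 42))
  synthesize_rf(scat, displacement, small_transducer(), depth = 12,
                snr_db = snr_db, seed = seed)
}

rf_pair_from <- function(pre, post) {
  structure(list(pre = pre$rf, post = post$rf, dz = pre$dz,
                 pitch = pre$pitch), class = "rf_frame_pair")
}

uniform_field <- function(u_mm, v_mm, extent = c(12, 5.76)) {
  disp_field(x = c(0, extent[2]), y = c(0, extent[1]),
             u = matrix(u_mm, 2, 2), v = matrix(v_mm, 2, 2))
}

# default-conditions study runs shared by the acceptance tests
theoretical_study <- function() fixture("theoretical_study", function()
  suppressWarnings(run_study(study_config(paths = "theoretical"))))

estimated_study <- function() fixture("estimated_study", function()
  suppressWarnings(run_study(study_config(paths = "estimated", seed = 1))))

hardening_study <- function() fixture("hardening_study", function()
  suppressWarnings(run_hardening_study(seed = 1)))

fine_solution <- function() fixture("fine_solution", function() {
  ph <- build_phantom(phantom_spec(), 38 / 320)
  simulate_compression(ph, 0.02)
})

# small embedded scene reused across inversion tests: 10 x 10 mm phantom with
# one stiff inclusion, meshed at 1 mm so the ROI+ring mesh can coincide
small_scene <- function(strain = 0.02) {
  spec <- phantom_spec(extent = c(10, 10),
                       inclusions = tibble::tibble(x = 5, y = 5, diameter = 3,
                                                   modulus = 75))
  ph <- build_phantom(spec, 1)
  list(spec = spec, ph = ph, sol = simulate_compression(ph, strain),
       roi = roi_spec(top = 2, left = 2, height = 6, width = 6,
                      element_size = c(1, 1)))
}

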