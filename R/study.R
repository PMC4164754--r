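#' Simulation-study configuration
#'
#' Bundles every knob of the end-to-end simulation study: phantom, applied
#' strains, transducer, scatterer density, RF SNR, tracking window, knot
#' spacings, inversion ROI, and the forward-mesh resolution. Defaults
#' reproduce the two-inclusion study conditions.
#'
#' @param phantom a [phantom_spec()].
#' @param strains applied compressional axial strains (fractions).
#' @param transducer a [transducer_spec()].
#' @param density scatterers per mm^2.
#' @param snr_db RF signal-to-noise ratio (dB).
#' @param seed base RNG seed for scatterers and noise.
#' @param window tracking window `(height, width)` mm.
#' @param knot_spacing B-spline knot spacing `(lateral, axial)` mm.
#' @param roi inversion [roi_spec()]; default a 28.8 x 28.8 mm square of
#'   0.48 mm elements centered in the phantom.
#' @param forward_element forward-mesh element size (mm); default
#'   `height / 320`, four times finer than the inversion elements.
#' @param paths subset of `c("theoretical", "estimated")`.
#' @return a `study_config` list.
#' @export
study_config <- function(phantom = phantom_spec(),
                         strains = c(0.005, 0.010, 0.015, 0.020),
                         transducer = transducer_spec(),
                         density = 200, snr_db = 30, seed = 1L,
                         window = c(2.2, 1.8),
                         knot_spacing = c(4.75, 4.82),
                         roi = NULL, forward_element = NULL,
                         paths = c("theoretical", "estimated")) {
  if (is.null(roi)) {
    side <- 60 * 0.48
    roi <- roi_spec(top = (phantom$extent[1] - side) / 2,
                    left = (phantom$extent[2] - side) / 2,
                    height = side, width = side)
  }
  if (is.null(forward_element)) forward_element <- phantom$extent[1] / 320
  structure(list(phantom = phantom, strains = strains,
                 transducer = transducer, density = density,
                 snr_db = snr_db, seed = as.integer(seed), window = window,
                 knot_spacing = knot_spacing, roi = roi,
                 forward_element = forward_element,
                 paths = match.arg(paths, several.ok = TRUE)),
            class = "study_config")
}

# scale a forward solution to a different applied strain (linearity of the
# prescribed-displacement problem)
scale_solution <- function(sol, strain) {
  out <- sol
  out$d <- sol$d * (strain / sol$applied_strain)
  out$applied_strain <- strain
  out
}

#' Run the end-to-end simulation study
#'
#' For each applied strain: solve the forward plane-strain problem on the
#' fine uniform mesh (one factorization, scaled across strains by
#' linearity); on the estimated path synthesize the pre/post RF pair from
#' advected scatterers, track displacements, fit the bicubic B-spline axial
#' field, derive the lateral field from incompressibility, and invert; on
#' the theoretical path feed the interpolated forward displacements straight
#' to the inversion (scale-invariant, so computed once). Reports mean
#' relative error and RMSE of the relative modulus per strain and summarized
#' across strains.
#'
#' @param config a [study_config()].
#' @param keep_details keep per-strain tracked fields, spline models and
#'   modulus images in the result (default `TRUE`).
#' @return object of class `elasto_study`: `report` (per-strain tibble),
#'   `summary` (per-path mean ± sd across strains), `truth`, `images`,
#'   `details`, `config`.
#' @export
run_study <- function(config = study_config(), keep_details = TRUE) {
  spec <- config$phantom
  fwd <- build_phantom(spec, config$forward_element)
  s_ref <- max(config$strains)
  sol_ref <- simulate_compression(fwd, s_ref)
  E_true <- true_modulus_image(spec, config$roi)
  report <- list(); images <- list(); details <- list()

  if ("theoretical" %in% config$paths) {
    img <- reconstruct_modulus(config$roi, sol_ref, spec$poisson_ratio)
    images$theoretical <- img
    report$theoretical <- tibble::tibble(
      path = "theoretical", strain = config$strains,
      mean_relative_error = mean_relative_error(img$E, E_true),
      rmse = rmse_relative(img$E, E_true))
  }

  if ("estimated" %in% config$paths) {
    td <- config$transducer
    depth <- spec$extent[1]
    scat <- make_scatterers(spec$extent, config$density, seed = config$seed)
    pre_clean <- synthesize_rf(scat, NULL, td, depth, snr_db = NULL,
                               seed = config$seed)
    rows <- vector("list", length(config$strains))
    for (k in seq_along(config$strains)) {
      s <- config$strains[k]
      sol <- scale_solution(sol_ref, s)
      post_clean <- synthesize_rf(scat, sol, td, depth, snr_db = NULL,
                                  seed = config$seed)
      pair <- structure(list(
        pre = add_rf_noise(pre_clean$rf, config$snr_db,
                           config$seed + 1000L * k),
        post = add_rf_noise(post_clean$rf, config$snr_db,
                            config$seed + 1000L * k + 500L),
        dz = pre_clean$dz, pitch = pre_clean$pitch),
        class = "rf_frame_pair")
      cfg <- tracking_config(window = config$window,
                             axial_search = c(-0.08, s * depth + 0.1),
                             lateral_search = 0.45)
      tracked <- track(pair, cfg)
      sup <- ring_support(config$roi, tracked)
      model <- fit_axial(tracked, spacing = config$knot_spacing, support = sup)
      model <- derive_lateral(model)
      img <- reconstruct_modulus(config$roi, model, spec$poisson_ratio)
      rows[[k]] <- tibble::tibble(
        path = "estimated", strain = s,
        mean_relative_error = mean_relative_error(img$E, E_true),
        rmse = rmse_relative(img$E, E_true))
      images[[sprintf("estimated_%g", s)]] <- img
      if (keep_details)
        details[[sprintf("strain_%g", s)]] <-
          list(tracked = tracked, model = model, solution = sol)
    }
    report$estimated <- dplyr::bind_rows(rows)
  }

  report <- dplyr::bind_rows(report)
  summary <- report |>
    dplyr::group_by(.data$path) |>
    dplyr::summarise(
      mre_sd = stats::sd(.data$mean_relative_error),
      mean_relative_error = mean(.data$mean_relative_error),
      rmse_sd = stats::sd(.data$rmse),
      rmse = mean(.data$rmse),
      n_strains = dplyr::n(), .groups = "drop") |>
    dplyr::select("path", "mean_relative_error", "mre_sd", "rmse",
                  "rmse_sd", "n_strains")
  structure(list(report = report, summary = summary, truth = E_true,
                 images = images, details = details, config = config),
            class = "elasto_study")
}

#' Target-hardening suppression study
#'
#' Emulates the freehand-scan phantom experiment in which strain images show
#' the target-hardening artifact (apparent stiffening with depth from stress
#' decay) while modulus images do not: a transducer-wide compressor acts on
#' a phantom wider than the imaged region, so stress spreads into the
#' un-imaged wings and the axial strain varies with depth. The full
#' estimated pipeline (RF synthesis, tracking, B-spline fit, inversion) is
#' run and top/bottom background statistics of the strain and modulus
#' images are compared.
#'
#' @param applied_strain compressional strain under the transducer.
#' @param seed RNG seed.
#' @param phantom_width width of the wide phantom (mm); must exceed the
#'   transducer footprint.
#' @param config optional [study_config()] supplying transducer, window,
#'   knots, ROI and forward-mesh settings.
#' @return list with `strain_stats` and `modulus_stats` (top/bottom region
#'   tibbles from [roi_statistics()]), `strain_change_pct`,
#'   `modulus_change_pct`, `suppression_ratio`, `image`, `model`.
#' @export
run_hardening_study <- function(applied_strain = 0.02, seed = 1L,
                                phantom_width = 60.8,
                                config = study_config(seed = seed)) {
  td <- config$transducer
  footprint <- td$n_lines * td$pitch
  stopifnot(phantom_width > footprint)
  offset <- (phantom_width - footprint) / 2
  depth <- config$phantom$extent[1]
  inc <- config$phantom$inclusions
  inc$x <- inc$x + offset          # keep inclusions centered under the array
  spec <- phantom_spec(extent = c(depth, phantom_width),
                       background_modulus = config$phantom$background_modulus,
                       inclusions = inc,
                       poisson_ratio = config$phantom$poisson_ratio)
  ph <- build_phantom(spec, config$forward_element)
  sol <- simulate_compression(ph, applied_strain, contact_width = footprint)
  scat <- make_scatterers(spec$extent, config$density, seed = seed)
  pre <- synthesize_rf(scat, NULL, td, depth, snr_db = NULL, seed = seed,
                       lateral_offset = offset)
  post <- synthesize_rf(scat, sol, td, depth, snr_db = NULL, seed = seed,
                        lateral_offset = offset)
  pair <- structure(list(pre = add_rf_noise(pre$rf, config$snr_db, seed + 11L),
                         post = add_rf_noise(post$rf, config$snr_db, seed + 12L),
                         dz = pre$dz, pitch = pre$pitch),
                    class = "rf_frame_pair")
  cfg <- tracking_config(window = config$window,
                         axial_search = c(-0.15, applied_strain * depth + 0.15),
                         lateral_search = 0.45)
  tracked <- track(pair, cfg)
  model <- fit_axial(tracked, spacing = config$knot_spacing,
                     support = ring_support(config$roi, tracked))
  model <- derive_lateral(model)
  image <- reconstruct_modulus(config$roi, model, spec$poisson_ratio)
  roi <- config$roi
  regions <- tibble::tibble(
    name = c("top", "bottom"), shape = "rect",
    top = c(roi$top + 1.4, roi$top + roi$height - 4.4),
    left = roi$left + roi$width / 2 - 4, height = 3, width = 8)
  gx <- seq(roi$left + 0.4, roi$left + roi$width - 0.4, by = 0.4)
  gy <- seq(roi$top + 0.4, roi$top + roi$height - 0.4, by = 0.4)
  ev <- evaluate_model(model, gx, gy)
  strain_stats <- roi_statistics(ev$eyy, regions, xs = gx, ys = gy)
  modulus_stats <- roi_statistics(image, regions)
  dstrain <- 100 * abs(strain_stats$mean[2] - strain_stats$mean[1]) /
    abs(strain_stats$mean[1])
  dmod <- 100 * abs(modulus_stats$mean[2] - modulus_stats$mean[1]) /
    abs(modulus_stats$mean[1])
  list(strain_stats = strain_stats, modulus_stats = modulus_stats,
       strain_change_pct = dstrain, modulus_change_pct = dmod,
       suppression_ratio = dstrain / dmod, image = image, model = model)
}

# spline support covering both the tracked data and the ROI + ring box
ring_support <- function(roi, tracked) {
  ex <- roi$element_size
  list(x = range(c(tracked$x, roi$left - ex[2], roi$left + roi$width + ex[2])),
       y = range(c(tracked$y, roi$top - ex[1], roi$top + roi$height + ex[1])))
}

#' @export
print.elasto_study <- function(x, ...) {
  cat("<elasto_study>\n")
  print(x$summary)
  invisible(x)
}
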