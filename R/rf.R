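#' Synthesize an RF echo frame from point scatterers
#'
#' Convolution point-spread-function model of pulse-echo imaging: scatterers
#' are deposited on an oversampled reflectivity grid with bilinear weights
#' (preserving subsample position), convolved with a separable PSF — an
#' axial Gaussian-envelope modulated cosine at the transducer center
#' frequency and a lateral Gaussian beam profile whose width at focus is
#' `lambda * F-number` (FWHM) — and decimated to the RF sampling grid.
#' Optional white Gaussian noise is added at a prescribed SNR.
#'
#' @param scatterers tibble from [make_scatterers()] (`x`, `y` mm,
#'   `amplitude`).
#' @param displacement optional displacement source used to advect the
#'   scatterers before imaging: a `compression_solution`, a `disp_field`, or
#'   `NULL` (no motion).
#' @param transducer a [transducer_spec()].
#' @param depth imaged depth (mm).
#' @param snr_db signal-to-noise ratio in dB, or `NULL` for a noise-free
#'   frame.
#' @param seed RNG seed for the noise.
#' @param oversample PSF-grid oversampling factor (per axis) relative to the
#'   RF sampling grid; must be even.
#' @param lateral_offset lateral position (mm) of the transducer's left edge
#'   in scatterer coordinates; lets a narrow transducer image the center of
#'   a wider phantom.
#' @return object of class `rf_frame`: list with `rf` (samples x lines
#'   matrix), `dz` (axial mm/sample), `pitch`, `line_x` (lateral line
#'   centers, mm), `n_dropped` (scatterers displaced outside the grid).
#' @export
synthesize_rf <- function(scatterers, displacement = NULL, transducer = transducer_spec(),
                          depth = 38, snr_db = NULL, seed = 1L, oversample = 4L,
                          lateral_offset = 0) {
  td <- transducer
  if (oversample %% 2 != 0) stop("oversample must be even")
  sx <- scatterers$x; sy <- scatterers$y; amp <- scatterers$amplitude
  if (!is.null(displacement)) {
    uv <- displacement_at(displacement, sx, sy)
    sx <- sx + uv$u
    sy <- sy + uv$v
  }
  sx <- sx - lateral_offset
  dz <- axial_sample_spacing(td)
  dzf <- dz / oversample
  dxf <- td$pitch / oversample
  n_samp <- floor(depth / dz) + 1L
  width <- td$n_lines * td$pitch
  nzf <- (n_samp - 1L) * oversample + 1L
  nxf <- round(width / dxf) + 1L
  # keep scatterers on the fine grid; displaced ones outside are dropped
  keep <- sy >= 0 & sy <= (nzf - 1) * dzf & sx >= 0 & sx <= (nxf - 1) * dxf
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("synthesize_rf: dropped %d scatterers outside the grid", n_dropped))
  sx <- sx[keep]; sy <- sy[keep]; amp <- amp[keep]

  # bilinear binning onto the fine reflectivity grid
  refl <- matrix(0, nzf, nxf)
  gz <- sy / dzf; gx <- sx / dxf
  iz <- pmin(floor(gz), nzf - 2); ix <- pmin(floor(gx), nxf - 2)
  tz <- gz - iz; tx <- gx - ix
  add_at <- function(rows, cols, w) {
    idx <- rows + (cols) * nzf + 1L     # 0-based rows/cols -> linear index
    acc <- rowsum(w, idx)
    refl[as.integer(rownames(acc))] <<- refl[as.integer(rownames(acc))] + acc[, 1]
  }
  add_at(iz,     ix,     amp * (1 - tz) * (1 - tx))
  add_at(iz + 1, ix,     amp * tz * (1 - tx))
  add_at(iz,     ix + 1, amp * (1 - tz) * tx)
  add_at(iz + 1, ix + 1, amp * tz * tx)

  # axial kernel: Gaussian envelope x cosine at the RF spatial frequency
  bw_hz <- td$bw * td$f0                 # -3 dB full bandwidth, MHz
  sigma_f <- bw_hz / (2 * sqrt(log(2)))  # MHz
  sigma_t <- 1 / (2 * pi * sigma_f * 1e6)          # s
  sigma_z <- td$c * sigma_t / 2 * 1000             # mm (pulse-echo depth)
  kz_half <- ceiling(3.5 * sigma_z / dzf)
  zk <- (-kz_half:kz_half) * dzf
  k_rf <- 2 * td$f0 * 1e6 / td$c / 1000            # cycles per mm of depth
  ker_z <- exp(-zk^2 / (2 * sigma_z^2)) * cos(2 * pi * k_rf * zk)
  # lateral kernel: Gaussian beam, FWHM = lambda * F-number at focus
  lambda <- td$c / (td$f0 * 1e6) * 1000            # mm
  fwhm_x <- lambda * td$f_number
  sigma_x <- fwhm_x / (2 * sqrt(2 * log(2)))
  kx_half <- ceiling(3 * sigma_x / dxf)
  ker_x <- exp(-((-kx_half:kx_half) * dxf)^2 / (2 * sigma_x^2))

  rf_fine <- stats::filter(refl, ker_z, method = "convolution", sides = 2)
  rf_fine[is.na(rf_fine)] <- 0
  out <- matrix(0, nzf, nxf)
  for (s in seq_along(ker_x)) {         # lateral shift-add convolution
    sh <- s - kx_half - 1L
    src <- max(1, 1 - sh):min(nxf, nxf - sh)
    out[, src] <- out[, src] + ker_x[s] * rf_fine[, src + sh]
  }
  # decimate to the RF grid; line centers at (l - 1/2) * pitch
  rows <- seq(1L, nzf, by = oversample)
  cols <- as.integer(round((seq_len(td$n_lines) - 0.5) * oversample)) + 1L
  rf <- out[rows, cols]
  if (!is.null(snr_db)) {
    p_sig <- mean(rf^2)
    sd_n <- sqrt(p_sig * 10^(-snr_db / 10))
    rng <- local_rng(seed)
    rf <- rf + matrix(rng$rnorm(length(rf), 0, sd_n), nrow(rf), ncol(rf))
  }
  structure(list(rf = rf, dz = dz, pitch = td$pitch,
                 line_x = (seq_len(td$n_lines) - 0.5) * td$pitch,
                 depth = depth, n_dropped = n_dropped),
            class = "rf_frame")
}

#' Pre/post-deformation RF frame pair
#'
#' Convenience wrapper: images the same scatterer population before and after
#' advection by a deformation field, with independent noise realizations.
#'
#' @inheritParams synthesize_rf
#' @param displacement deformation applied for the post frame.
#' @return object of class `rf_frame_pair`: `pre`, `post` matrices plus
#'   shared `dz`, `pitch`, `line_x`.
#' @export
synthesize_rf_pair <- function(scatterers, displacement, transducer = transducer_spec(),
                               depth = 38, snr_db = 30, seed = 1L, oversample = 4L) {
  pre <- synthesize_rf(scatterers, NULL, transducer, depth, snr_db,
                       seed = seed, oversample = oversample)
  post <- synthesize_rf(scatterers, displacement, transducer, depth, snr_db,
                        seed = seed + 104729L, oversample = oversample)
  structure(list(pre = pre$rf, post = post$rf, dz = pre$dz,
                 pitch = pre$pitch, line_x = pre$line_x, depth = depth),
            class = "rf_frame_pair")
}

# add white Gaussian noise at a prescribed SNR (dB) re the frame's own power
add_rf_noise <- function(rf, snr_db, seed) {
  sd_n <- sqrt(mean(rf^2) * 10^(-snr_db / 10))
  rng <- local_rng(seed)
  rf + matrix(rng$rnorm(length(rf), 0, sd_n), nrow(rf), ncol(rf))
}

#' Displacement lookup generic
#'
#' Evaluates a displacement source at arbitrary points (mm). Methods exist
#' for FEM solutions (`compression_solution`, bilinear within elements),
#' gridded fields (`disp_field`, bilinear), and B-spline models
#' (`bspline_disp_model`, analytic).
#'
#' @param object displacement source.
#' @param x,y query coordinates (mm).
#' @return list with components `u` (lateral) and `v` (axial), mm.
#' @export
displacement_at <- function(object, x, y) UseMethod("displacement_at")

#' @export
displacement_at.compression_solution <- function(object, x, y) {
  interp_displacement(object$mesh, object$d, x, y)
}

#' @export
displacement_at.disp_field <- function(object, x, y) {
  gx <- object$x; gy <- object$y
  fx <- (x - gx[1]) / (gx[2] - gx[1])
  fy <- (y - gy[1]) / (gy[2] - gy[1])
  if (any(fx < -1e-9 | fx > length(gx) - 1 + 1e-9 |
          fy < -1e-9 | fy > length(gy) - 1 + 1e-9))
    stop("query point outside field support")
  ix <- pmin(pmax(floor(fx), 0), length(gx) - 2)
  iy <- pmin(pmax(floor(fy), 0), length(gy) - 2)
  tx <- fx - ix; ty <- fy - iy
  bil <- function(m) {
    m[cbind(iy + 1, ix + 1)] * (1 - tx) * (1 - ty) +
      m[cbind(iy + 1, ix + 2)] * tx * (1 - ty) +
      m[cbind(iy + 2, ix + 1)] * (1 - tx) * ty +
      m[cbind(iy + 2, ix + 2)] * tx * ty
  }
  list(u = bil(object$u), v = bil(object$v))
}
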