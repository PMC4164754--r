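#' Speckle-tracking configuration
#'
#' @param window `(height, width)` of the matching window in mm; the default
#'   2.2 x 1.8 mm^2 suits 6 MHz RF data.
#' @param axial_search `(min, max)` axial displacement searched, mm. Should
#'   cover the maximum expected displacement (applied strain x depth).
#' @param lateral_search half-range of the lateral search, mm.
#' @param stride fraction of the window used as estimation-grid step per axis
#'   (0.25 = 75% overlap).
#' @param min_correlation estimates with a peak NCC below this are masked
#'   out as invalid.
#' @param median_tol axial estimates further than this (mm) from their 3 x 3
#'   neighborhood median are masked as peak-hopping outliers; `Inf` disables.
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(window = c(2.2, 1.8),
                            axial_search = c(-0.1, 1.0),
                            lateral_search = 0.5,
                            stride = 0.25,
                            min_correlation = 0.3,
                            median_tol = 0.1) {
  stopifnot(length(window) == 2, all(window > 0), length(axial_search) == 2,
            axial_search[1] < axial_search[2], lateral_search >= 0,
            stride > 0, stride <= 1)
  structure(list(window = window, axial_search = axial_search,
                 lateral_search = lateral_search, stride = stride,
                 min_correlation = min_correlation, median_tol = median_tol),
            class = "tracking_config")
}

# 3x3 neighborhood median (NA-tolerant), used for outlier screening
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  stack <- array(NA_real_, c(nr, nc, 9))
  k <- 1
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    ci <- max(1, 1 + dj):min(nc, nc + dj)
    stack[ri - di, ci - dj, k] <- m[ri, ci]
    k <- k + 1
  }
  apply(stack, c(1, 2), stats::median, na.rm = TRUE)
}

# exclusive-prefix 2D integral image with a zero first row/column, so that
# the sum over rows r0..r0+h-1, cols c0..c0+w-1 is
# S[r0+h, c0+w] - S[r0, c0+w] - S[r0+h, c0] + S[r0, c0]  (1-based into S)
integral_image <- function(m) {
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- cs
  S
}

window_sums <- function(S, r0, c0, h, w) {
  S[cbind(r0 + h, c0 + w)] - S[cbind(r0, c0 + w)] -
    S[cbind(r0 + h, c0)] + S[cbind(r0, c0)]
}

# analytic signal per RF line (FFT Hilbert transform)
rf_analytic <- function(rf) {
  n <- nrow(rf)
  H <- stats::mvfft(rf)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(H * w, inverse = TRUE) / n
}

rf_envelope <- function(rf) Mod(rf_analytic(rf))

# mean carrier frequency in cycles/sample from the lag-1 autocorrelation
# phase of the analytic signal
center_freq_cps <- function(za) {
  n <- nrow(za)
  Arg(sum(Conj(za[-n, ]) * za[-1, ])) / (2 * pi)
}

# windowed NCC of (pre, post) for every window position and integer offset,
# via integral images; returns n_win x n_offsets matrix (-Inf out of range)
ncc_all_offsets <- function(pre, post, grid, offs, wy, wx) {
  R <- nrow(pre); C <- ncol(pre)
  nwin <- wy * wx
  n_win <- nrow(grid)
  Sp <- integral_image(pre)
  Spp <- integral_image(pre^2)
  Sq <- integral_image(post)
  Sqq <- integral_image(post^2)
  sum_p <- window_sums(Sp, grid$r0, grid$c0, wy, wx)
  sum_pp <- window_sums(Spp, grid$r0, grid$c0, wy, wx)
  var_p <- sum_pp - sum_p^2 / nwin
  corr <- matrix(-Inf, n_win, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dv <- offs$dv[k]; du <- offs$du[k]
    rs <- max(1, 1 - dv):min(R, R - dv)   # rows where post[r+dv] exists
    cs <- max(1, 1 - du):min(C, C - du)
    if (length(rs) < wy || length(cs) < wx) next
    prod <- matrix(0, R, C)
    prod[rs, cs] <- pre[rs, cs] * post[rs + dv, cs + du]
    Spq <- integral_image(prod)
    ok <- grid$r0 >= rs[1] & grid$r0 + wy - 1L <= rs[length(rs)] &
      grid$c0 >= cs[1] & grid$c0 + wx - 1L <= cs[length(cs)]
    if (!any(ok)) next
    g <- grid[ok, , drop = FALSE]
    sum_q <- window_sums(Sq, g$r0 + dv, g$c0 + du, wy, wx)
    sum_qq <- window_sums(Sqq, g$r0 + dv, g$c0 + du, wy, wx)
    var_q <- sum_qq - sum_q^2 / nwin
    spq <- window_sums(Spq, g$r0, g$c0, wy, wx)
    num <- spq - sum_p[ok] * sum_q / nwin
    den <- sqrt(pmax(var_p[ok], 0) * pmax(var_q, 0))
    cc <- ifelse(den > 0, num / den, NA_real_)
    corr[ok, k] <- cc
  }
  corr[!is.finite(corr) & !is.na(corr)] <- -Inf
  corr
}

#' Block-matching speckle tracking of an RF frame pair
#'
#' Two-step coarse-to-fine displacement estimation. Step one matches
#' envelope (demodulated) windows over the full integer search range by
#' normalized cross-correlation (NCC), which is free of RF phase ambiguity
#' and provides a robust integer displacement per window. Step two
#' re-matches the phase-rich RF windows, constrained to a small
#' neighborhood of the envelope peak (no half-wavelength peak hopping), and
#' refines the peak to subsample precision with a parabolic fit in each
#' axis. All window positions are evaluated at once per offset via integral
#' images. Axial estimates are subsample-accurate thanks to the RF phase;
#' lateral estimates are markedly noisier (no lateral phase), which is the
#' property the incompressibility-derived lateral field downstream exists
#' to fix.
#'
#' @param pair an `rf_frame_pair` (see [synthesize_rf_pair()]) or a list with
#'   `pre`, `post` matrices and `dz`, `pitch` spacings (mm).
#' @param config a [tracking_config()].
#' @return a [disp_field()] on the estimation grid, with `u`/`v` in mm, the
#'   peak `correlation`, and a `mask` of valid estimates (all-zero or
#'   out-of-range windows are `NA` and masked out).
#' @export
track <- function(pair, config = tracking_config()) {
  pre <- pair$pre; post <- pair$post
  if (!all(dim(pre) == dim(post))) stop("frames must share shape")
  dz <- pair$dz; pitch <- pair$pitch
  R <- nrow(pre); C <- ncol(pre)
  wy <- round(config$window[1] / dz)
  wx <- max(3L, round(config$window[2] / pitch))
  if (wy >= R || wx >= C) stop("window exceeds frame")
  sy <- max(1L, round(config$stride * wy))
  sx <- max(1L, round(config$stride * wx))
  r0s <- seq(1L, R - wy + 1L, by = sy)
  c0s <- seq(1L, C - wx + 1L, by = sx)
  nwy <- length(r0s); nwx <- length(c0s)
  grid <- expand.grid(r0 = r0s, c0 = c0s)   # r fastest
  n_win <- nrow(grid)

  dvs <- seq(floor(config$axial_search[1] / dz),
             ceiling(config$axial_search[2] / dz))
  dul <- ceiling(config$lateral_search / pitch)
  dus <- seq(-dul, dul)
  offs <- expand.grid(dv = dvs, du = dus)   # dv fastest

  za_pre <- rf_analytic(pre)
  za_post <- rf_analytic(post)
  corr_env <- ncc_all_offsets(Mod(za_pre), Mod(za_post), grid, offs, wy, wx)
  corr <- ncc_all_offsets(pre, post, grid, offs, wy, wx)

  # step 1: integer peak of the envelope correlation
  best_env <- max.col(replace(corr_env, is.na(corr_env), -Inf),
                      ties.method = "first")
  iv_env <- (best_env - 1L) %% length(dvs) + 1L
  iu_env <- (best_env - 1L) %/% length(dvs) + 1L
  # step 2: RF peak within +/-2 samples axially, +/-1 line laterally of it
  iv_k <- rep(seq_along(dvs), times = length(dus))
  iu_k <- rep(seq_along(dus), each = length(dvs))
  guard <- outer(iv_k, iv_env, function(i, j) abs(i - j) <= 2) &
    outer(iu_k, iu_env, function(i, j) abs(i - j) <= 1)
  corr_g <- corr
  corr_g[t(!guard)] <- -Inf
  corr_g[is.na(corr_g)] <- -Inf
  best <- max.col(corr_g, ties.method = "first")
  peak <- corr[cbind(seq_len(n_win), best)]
  iv <- (best - 1L) %% length(dvs) + 1L       # index into dvs
  iu <- (best - 1L) %/% length(dvs) + 1L
  # subsample refinement around the integer peak, per axis.
  # Parabola for the (smooth) lateral/envelope direction; for the axial RF
  # direction the correlation oscillates at the carrier, so a cosine fit at
  # the carrier frequency is used (bias far below the parabola's sawtooth).
  refine <- function(cm, cc, cp) {
    den <- cm - 2 * cc + cp
    d <- ifelse(is.finite(cm) & is.finite(cp) & den < 0,
                0.5 * (cm - cp) / den, 0)
    pmax(pmin(d, 0.5), -0.5)
  }
  refine_cos <- function(cm, cc, cp, omega) {
    ok <- is.finite(cm) & is.finite(cp)
    num <- (cp - cm) * cos(omega)
    den <- (cp + cm) * sin(omega)
    d <- ifelse(ok & (abs(num) + abs(den)) > 0,
                atan2(num, den) / omega, 0)
    fallback <- refine(cm, cc, cp)
    out <- ifelse(abs(d) <= 0.75, d, fallback)
    pmax(pmin(out, 0.75), -0.75)
  }
  at <- function(ivv, iuu) {
    inside <- ivv >= 1 & ivv <= length(dvs) & iuu >= 1 & iuu <= length(dus)
    out <- rep(-Inf, n_win)
    idx <- (iuu - 1L) * length(dvs) + ivv
    out[inside] <- corr[cbind(which(inside), idx[inside])]
    out
  }
  omega <- 2 * pi * center_freq_cps(za_pre)
  dv_sub <- refine_cos(at(iv - 1L, iu), peak, at(iv + 1L, iu), omega)
  du_sub <- refine(at(iv, iu - 1L), peak, at(iv, iu + 1L))
  # phase refinement: the residual delay of the post window relative to the
  # integer-aligned pre window is read off the phase of the complex
  # cross-correlation of the analytic signals, delta = -arg(C)/(2 pi f0).
  # Near-exact for a band-limited delay; replaces the cosine fit wherever
  # it lands inside the half-sample capture range.
  zc <- Conj(za_pre)
  dv_phase <- rep(NA_real_, n_win)
  key <- (iv - 1L) + 1000L * (iu - 1L)
  for (ky in unique(key)) {
    sel <- which(key == ky)
    dv <- dvs[iv[sel[1]]]; du <- dus[iu[sel[1]]]
    rs <- max(1, 1 - dv):min(R, R - dv)
    cs <- max(1, 1 - du):min(C, C - du)
    if (length(rs) < wy || length(cs) < wx) next
    prod <- matrix(0i, R, C)
    prod[rs, cs] <- zc[rs, cs] * za_post[rs + dv, cs + du]
    Sre <- integral_image(Re(prod))
    Sim <- integral_image(Im(prod))
    inside <- grid$r0[sel] >= rs[1] &
      grid$r0[sel] + wy - 1L <= rs[length(rs)] &
      grid$c0[sel] >= cs[1] & grid$c0[sel] + wx - 1L <= cs[length(cs)]
    s2 <- sel[inside]
    if (!length(s2)) next
    cre <- window_sums(Sre, grid$r0[s2], grid$c0[s2], wy, wx)
    cim <- window_sums(Sim, grid$r0[s2], grid$c0[s2], wy, wx)
    dv_phase[s2] <- -atan2(cim, cre) / omega
  }
  usable <- !is.na(dv_phase) & abs(dv_phase) <= 0.6
  dv_sub[usable] <- dv_phase[usable]
  v_mm <- (dvs[iv] + dv_sub) * dz
  u_mm <- (dus[iu] + du_sub) * pitch
  valid <- is.finite(peak) & !is.na(peak) & peak >= config$min_correlation
  v_mm[!valid] <- NA_real_; u_mm[!valid] <- NA_real_
  if (is.finite(config$median_tol)) {
    vm <- matrix(v_mm, nwy, nwx)
    dev <- abs(vm - median3x3(vm))
    valid <- valid & (is.na(dev) | as.vector(dev) <= config$median_tol)
    v_mm[!valid] <- NA_real_; u_mm[!valid] <- NA_real_
  }

  # window centers in mm; RF sample n (1-based) sits at depth (n-1)*dz,
  # line c at lateral (c-1/2)*pitch
  yc <- (r0s - 1 + (wy - 1) / 2) * dz
  xc <- (c0s - 1 + (wx - 1) / 2 + 0.5) * pitch
  shape <- function(vec) matrix(vec, nwy, nwx)   # r fastest in grid
  disp_field(x = xc, y = yc, u = shape(u_mm), v = shape(v_mm),
             mask = shape(valid), correlation = shape(peak))
}
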