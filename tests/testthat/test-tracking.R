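test_that("integer-sample axial shifts are recovered exactly", {
  pre <- small_rf_frame()
  k <- 7L
  post_rf <- rbind(matrix(0, k, ncol(pre$rf)), pre$rf[1:(nrow(pre$rf) - k), ])
  pair <- list(pre = pre$rf, post = post_rf, dz = pre$dz, pitch = pre$pitch)
  tr <- track(pair, tracking_config(window = c(1.5, 1.0),
                                    axial_search = c(-0.1, 0.3),
                                    lateral_search = 0.24))
  inner <- tr$mask
  inner[c(1, nrow(inner)), ] <- FALSE
  expect_lt(max(abs(tr$v[inner] - k * pre$dz)), 1e-3)
  expect_lt(max(abs(tr$u[inner])), 0.01)
  expect_gt(min(tr$correlation[inner]), 0.999)
  # symmetry: swapping the frames negates the field
  tr_rev <- track(list(pre = post_rf, post = pre$rf, dz = pre$dz,
                       pitch = pre$pitch),
                  tracking_config(window = c(1.5, 1.0),
                                  axial_search = c(-0.3, 0.1),
                                  lateral_search = 0.24))
  inner2 <- tr_rev$mask; inner2[c(1, nrow(inner2)), ] <- FALSE
  expect_lt(max(abs(tr_rev$v[inner2] + k * pre$dz)), 1e-3)
})

test_that("subsample axial shifts are recovered to better than 0.1 sample", {
  pre <- small_rf_frame()
  shift <- 0.3 * pre$dz
  post <- small_rf_frame(displacement = uniform_field(0, shift))
  tr <- track(rf_pair_from(pre, post),
              tracking_config(window = c(1.5, 1.0),
                              axial_search = c(-0.1, 0.2),
                              lateral_search = 0.24))
  err <- abs(tr$v[tr$mask] - shift)
  expect_lt(stats::median(err), 0.1 * pre$dz)
})

test_that("lateral shifts are recovered but more noisily than axial", {
  pre <- small_rf_frame()
  post <- small_rf_frame(displacement = uniform_field(0.12, 0.05))
  tr <- track(rf_pair_from(pre, post),
              tracking_config(window = c(1.5, 1.0),
                              axial_search = c(-0.1, 0.2),
                              lateral_search = 0.3))
  expect_lt(abs(stats::median(tr$u[tr$mask]) - 0.12), 0.05)
  ax_err <- stats::sd(tr$v[tr$mask] - 0.05)
  lat_err <- stats::sd(tr$u[tr$mask] - 0.12)
  expect_lt(ax_err, lat_err)
})

test_that("estimation error grows with added RF noise", {
  pre_clean <- small_rf_frame()
  post_clean <- small_rf_frame(displacement = uniform_field(0, 0.05))
  err_at <- function(snr) {
    pair <- list(pre = elastofem:::add_rf_noise(pre_clean$rf, snr, 31),
                 post = elastofem:::add_rf_noise(post_clean$rf, snr, 32),
                 dz = pre_clean$dz, pitch = pre_clean$pitch)
    tr <- track(pair, tracking_config(window = c(1.5, 1.0),
                                      axial_search = c(-0.1, 0.2),
                                      lateral_search = 0.24,
                                      min_correlation = 0.1))
    stats::var(tr$v[tr$mask] - 0.05)
  }
  v <- sapply(c(35, 15, 5), err_at)
  expect_gt(v[2], 0.8 * v[1])
  expect_gt(v[3], 0.8 * v[2])
  expect_gt(v[3], v[1])
})

test_that("degenerate tracking inputs are handled explicitly", {
  pre <- small_rf_frame()
  expect_error(track(rf_pair_from(pre, pre),
                     tracking_config(window = c(20, 10))), "window")
  z <- matrix(0, 120, 16)
  tr0 <- track(list(pre = z, post = z, dz = 0.024, pitch = 0.12),
               tracking_config(window = c(1.0, 0.6),
                               axial_search = c(-0.05, 0.05),
                               lateral_search = 0.12))
  expect_true(all(!tr0$mask))
  expect_true(all(is.na(tr0$v)))
})
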