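test_that("cubic basis closed forms, partition of unity, derivative sums", {
  expect_equal(cubic_basis(0), matrix(c(1 / 6, 2 / 3, 1 / 6, 0), 1),
               ignore_attr = TRUE)
  t <- c(0, 0.12, 0.37, 0.5, 0.83, 0.999)
  expect_lt(max(abs(rowSums(cubic_basis(t)) - 1)), 1e-14)
  expect_lt(max(abs(rowSums(cubic_basis_deriv(t)))), 1e-13)
  # finite-difference check of the derivative at t = 0.37
  h <- 1e-6
  fd <- (cubic_basis(0.37 + h) - cubic_basis(0.37 - h)) / (2 * h)
  expect_lt(max(abs(fd - cubic_basis_deriv(0.37))), 1e-6)
  expect_error(cubic_basis(-0.1), "\\[0, 1\\]")
  expect_error(cubic_basis_deriv(1.2), "\\[0, 1\\]")
})

test_that("spline evaluation reproduces constants and linear ramps", {
  a_const <- matrix(4.2, 6, 7)
  m <- bspline_model(a_const, b = a_const * 0, spacing = c(2, 3))
  ev <- evaluate_model(m, x = seq(0.5, 7.5, 0.5), y = seq(0.5, 8.5, 0.5))
  expect_lt(max(abs(ev$field$v - 4.2)), 1e-12)
  expect_lt(max(abs(ev$eyy)), 1e-12)
  expect_lt(max(abs(ev$exy)), 1e-12)
  # linear ramp in control values -> exactly linear field, constant strain
  a_lin <- outer(seq_len(6), rep(1, 7)) * 0.5   # ramp in y index
  m2 <- bspline_model(a_lin, spacing = c(2, 3))
  ev2 <- evaluate_model(m2, x = seq(1, 7, 1), y = seq(0.5, 8.5, 1))
  expect_lt(max(abs(ev2$eyy - 0.5 / 3)), 1e-12)
  expect_lt(diff(range(ev2$field$v[, 1] - ev2$field$v[, 2])), 1e-12)
})

test_that("analytic strains match finite differences of the evaluated field", {
  set.seed(21)
  m <- bspline_model(matrix(stats::rnorm(42), 6, 7),
                     b = matrix(stats::rnorm(42), 6, 7), spacing = c(2, 3))
  x <- seq(1, 7, 0.5); y <- seq(1, 8, 0.5)
  ev <- evaluate_model(m, x, y)
  h <- 1e-5
  evp <- evaluate_model(m, x, y + h)
  evm <- evaluate_model(m, x, y - h)
  fd_eyy <- (evp$field$v - evm$field$v) / (2 * h)
  expect_lt(max(abs(fd_eyy - ev$eyy)) / max(abs(ev$eyy)), 1e-6)
  evxp <- evaluate_model(m, x + h, y)
  evxm <- evaluate_model(m, x - h, y)
  fd_exx <- (evxp$field$u - evxm$field$u) / (2 * h)
  expect_lt(max(abs(fd_exx - ev$exx)) / max(abs(ev$exx)), 1e-6)
})

test_that("axial fitting recovers a known spline and is linear", {
  set.seed(5)
  gen <- bspline_model(matrix(stats::rnorm(56, sd = 0.1), 7, 8),
                       spacing = c(2.5, 2.2), origin = c(0, 0))
  x <- seq(0.2, 12.2, 0.35); y <- seq(0.2, 8.6, 0.3)
  ev <- evaluate_model(gen, x, y)
  field <- disp_field(x = x, y = y, u = ev$field$u * 0, v = ev$field$v)
  fit <- fit_axial(field, spacing = c(2.5, 2.2),
                   support = list(x = c(0, 12.5), y = c(0, 8.8)))
  evf <- evaluate_model(fit, x, y)
  expect_lt(max(abs(evf$field$v - ev$field$v)), 1e-8)
  # linearity of the fit
  field2 <- field; field2$v <- 3 * field$v
  fit2 <- fit_axial(field2, spacing = c(2.5, 2.2),
                    support = list(x = c(0, 12.5), y = c(0, 8.8)))
  expect_equal(fit2$a, 3 * fit$a, tolerance = 1e-9)
})

test_that("fitting smooths white noise below its input level", {
  set.seed(9)
  gen <- bspline_model(matrix(stats::rnorm(30, sd = 0.05), 5, 6),
                       spacing = c(3, 3))
  x <- seq(0.2, 8.8, 0.28); y <- seq(0.2, 5.8, 0.24)
  ev <- evaluate_model(gen, x, y)
  sigma <- 0.01
  rmse <- sapply(1:20, function(s) {
    set.seed(100 + s)
    noisy <- ev$field$v + matrix(stats::rnorm(length(ev$field$v), 0, sigma),
                                 nrow(ev$field$v))
    f <- disp_field(x = x, y = y, u = noisy * 0, v = noisy)
    fit <- fit_axial(f, spacing = c(3, 3),
                     support = list(x = c(0, 9), y = c(0, 6)))
    sqrt(mean((evaluate_model(fit, x, y)$field$v - ev$field$v)^2))
  })
  expect_lt(mean(rmse), sigma)
})

test_that("empty knot cells produce an explicit error naming the cells", {
  x <- seq(0.2, 3.8, 0.2); y <- seq(0.2, 3.8, 0.2)
  v <- matrix(1, length(y), length(x))
  f <- disp_field(x = x, y = y, u = v * 0, v = v)
  expect_error(fit_axial(f, spacing = c(1, 1),
                         support = list(x = c(0, 12), y = c(0, 4))),
               "no data under control cells")
})

test_that("incompressibility-derived lateral field closes uniform compression", {
  # V = -eps * y  ->  U with exx = +eps (area-preserving stretch)
  eps <- 0.02
  x <- seq(0, 12, 0.4); y <- seq(0, 10, 0.4)
  f <- disp_field(x = x, y = y, u = matrix(0, length(y), length(x)),
                  v = outer(-eps * y, rep(1, length(x))))
  m <- fit_axial(f, spacing = c(3, 3))
  m <- derive_lateral(m)
  ev <- evaluate_model(m, seq(1, 11, 0.5), seq(1, 9, 0.5))
  expect_lt(max(abs(ev$exx - eps)), 1e-6)
  expect_lt(max(abs(ev$exx + ev$eyy)), 1e-6)
  # gauge: row means of U are pinned at zero
  expect_lt(max(abs(rowMeans(ev$field$u))), 1e-6)
  # zero axial parameters -> zero lateral parameters in the fixed gauge
  m0 <- bspline_model(matrix(0, nrow(m$a), ncol(m$a)), spacing = m$spacing,
                      origin = m$origin)
  m0 <- derive_lateral(m0)
  expect_lt(max(abs(m0$b)), 1e-10)
})

test_that("derived lateral parameters minimize the incompressibility residual", {
  set.seed(3)
  gen <- bspline_model(matrix(stats::rnorm(36, sd = 0.05), 6, 6),
                       spacing = c(2.5, 2.5))
  sup <- elastofem:::model_support(gen)
  x <- seq(sup$x[1], sup$x[2], length.out = 40)
  y <- seq(sup$y[1], sup$y[2], length.out = 40)
  m <- derive_lateral(gen, x = x, y = y)
  resid <- function(mm) {
    ev <- evaluate_model(mm, x, y)
    sum((ev$exx + ev$eyy)^2)
  }
  r0 <- resid(m)
  for (k in 1:5) {
    set.seed(k)
    mp <- m
    mp$b <- m$b + matrix(stats::rnorm(length(m$b), 0, 1e-2), nrow(m$b))
    expect_gt(resid(mp), r0)
  }
})
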