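#' Mean relative error of a modulus reconstruction (percent)
#'
#' `100 * mean((E_hat - E_true) / E_true)` over all ROI elements, both
#' images on the relative-modulus scale (truth normalized so the background
#' is 1, reconstruction normalized by the unit boundary ring).
#'
#' @param E_hat reconstructed relative moduli (vector or matrix).
#' @param E_true true relative moduli, same shape, all > 0.
#' @return signed percentage.
#' @export
mean_relative_error <- function(E_hat, E_true) {
  if (!all(dim(as.matrix(E_hat)) == dim(as.matrix(E_true))))
    stop("shape mismatch")
  if (any(E_true <= 0)) stop("E_true must be > 0")
  100 * mean((E_hat - E_true) / E_true)
}

#' Root-mean-square relative error of a modulus reconstruction (percent)
#'
#' `100 * sqrt(mean(((E_hat - E_true) / E_true)^2))`.
#'
#' @inheritParams mean_relative_error
#' @return percentage (non-negative).
#' @export
rmse_relative <- function(E_hat, E_true) {
  if (!all(dim(as.matrix(E_hat)) == dim(as.matrix(E_true))))
    stop("shape mismatch")
  if (any(E_true <= 0)) stop("E_true must be > 0")
  100 * sqrt(mean(((E_hat - E_true) / E_true)^2))
}

#' Region statistics of a gridded image
#'
#' Mean and standard deviation of image values inside named rectangular or
#' circular regions, the ROI bookkeeping used to quantify artifacts (e.g.
#' top-vs-bottom background bands for target hardening, or a 2 mm disk at an
#' inclusion center).
#'
#' @param x a `modulus_image`, a [disp_field()] component, or a plain matrix
#'   with accompanying `xs`/`ys` coordinates.
#' @param regions tibble with columns `name`, `shape` (`"rect"` or
#'   `"disk"`), and geometry: rectangles use `top`, `left`, `height`,
#'   `width` (mm), disks use `cx`, `cy`, `radius` (mm).
#' @param values for matrix input, the matrix of values; ignored otherwise.
#' @param xs,ys coordinates of matrix columns/rows (mm); ignored for
#'   `modulus_image`.
#' @return tibble with `name`, `n`, `mean`, `sd`.
#' @export
roi_statistics <- function(x, regions, values = NULL, xs = NULL, ys = NULL) {
  if (inherits(x, "modulus_image")) {
    values <- x$E; xs <- x$x; ys <- x$y
  } else if (is.matrix(x)) {
    values <- x
    if (is.null(xs) || is.null(ys)) stop("xs and ys required for matrix input")
  } else stop("unsupported input")
  regions <- tibble::as_tibble(regions)
  g <- expand.grid(x = xs, y = ys)
  vals <- as.vector(t(values))          # x fastest, matching expand.grid
  purrr::pmap_dfr(regions, function(name, shape, ...) {
    p <- list(...)
    inside <- if (shape == "rect") {
      g$x >= p$left & g$x <= p$left + p$width &
        g$y >= p$top & g$y <= p$top + p$height
    } else if (shape == "disk") {
      (g$x - p$cx)^2 + (g$y - p$cy)^2 <= p$radius^2
    } else stop("unknown region shape: ", shape)
    if (!any(inside)) stop("empty region: ", name)
    tibble::tibble(name = name, n = sum(inside),
                   mean = mean(vals[inside]), sd = stats::sd(vals[inside]))
  })
}

#' True relative modulus on the inversion grid
#'
#' Rasterizes a [phantom_spec()] onto the element centers of a [roi_spec()],
#' normalized so the background is 1.
#'
#' @param spec a [phantom_spec()].
#' @param roi a [roi_spec()].
#' @return ny x nx matrix of relative moduli.
#' @export
true_modulus_image <- function(spec, roi) {
  h <- roi$element_size[1]; w <- roi$element_size[2]
  ny <- round(roi$height / h); nx <- round(roi$width / w)
  xs <- roi$left + (seq_len(nx) - 0.5) * w
  ys <- roi$top + (seq_len(ny) - 0.5) * h
  g <- expand.grid(x = xs, y = ys)
  E <- rep(1, nrow(g))
  if (nrow(spec$inclusions) > 0) {
    for (k in seq_len(nrow(spec$inclusions))) {
      inc <- spec$inclusions[k, ]
      hit <- (g$x - inc$x)^2 + (g$y - inc$y)^2 < (inc$diameter / 2)^2
      E[hit] <- inc$modulus / spec$background_modulus
    }
  }
  matrix(E, ny, nx, byrow = TRUE)
}
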