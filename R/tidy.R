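#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a displacement field into a long tibble
#'
#' @param x a [disp_field()].
#' @param ... unused.
#' @return tibble with `x`, `y` (mm), `u`, `v` (mm), and, when present,
#'   `correlation` and `valid`.
#' @export
tidy.disp_field <- function(x, ...) {
  xs <- rep(x$x, each = length(x$y))
  ys <- rep(x$y, times = length(x$x))
  uu <- as.vector(x$u); vv <- as.vector(x$v)
  out <- tibble::tibble(x = xs, y = ys, u = uu, v = vv)
  if (!is.null(x$correlation)) out$correlation <- as.vector(x$correlation)
  if (!is.null(x$mask)) out$valid <- as.vector(x$mask)
  out
}

#' Tidy a modulus image into a long tibble
#'
#' @param x a `modulus_image`.
#' @param ... unused.
#' @return tibble with element-center `x`, `y` (mm) and relative `modulus`.
#' @export
tidy.modulus_image <- function(x, ...) {
  xs <- rep(x$x, each = length(x$y))
  ys <- rep(x$y, times = length(x$x))
  ee <- as.vector(x$E)
  tibble::tibble(x = xs, y = ys, modulus = ee)
}

#' Per-strain report of a simulation study
#'
#' @param x an `elasto_study` from [run_study()].
#' @param ... unused.
#' @return tibble with one row per path and applied strain.
#' @export
tidy.elasto_study <- function(x, ...) x$report

#' One-row summary of a simulation study
#'
#' @param x an `elasto_study`.
#' @param ... unused.
#' @return one-row tibble (the estimated path when present, else the
#'   theoretical path): mean relative error and RMSE with their standard
#'   deviations across applied strains.
#' @export
glance.elasto_study <- function(x, ...) {
  s <- x$summary
  s[order(s$path != "estimated"), ][1, ]
}

#' Plot a modulus image
#'
#' Raster display of the relative Young's modulus. For display only, values
#' are clipped to `limits` (the saved values are never clipped); the default
#' upper limit 2 follows the practice of fixing the color scale around a
#' contrast of 2.
#'
#' @param object a `modulus_image`.
#' @param limits display range of the color scale.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.modulus_image <- function(object, limits = c(0, 2), ...) {
  df <- tidy.modulus_image(object)
  df$modulus <- pmin(pmax(df$modulus, limits[1]), limits[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$modulus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = limits, name = "E (rel.)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)")
}

#' Plot a displacement field
#'
#' @param object a [disp_field()].
#' @param component `"v"` (axial), `"u"` (lateral), or `"both"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.disp_field <- function(object, component = c("both", "v", "u"), ...) {
  component <- match.arg(component)
  df <- tidy.disp_field(object)
  df <- tidyr::pivot_longer(df, dplyr::any_of(c("u", "v")),
                            names_to = "component", values_to = "mm")
  if (component != "both") df <- df[df$component == component, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_viridis_c(name = "mm") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)")
}

#' Plot study error metrics across applied strains
#'
#' @param object an `elasto_study`.
#' @param ... unused.
#' @return a ggplot of mean relative error and RMSE vs applied strain.
#' @export
autoplot.elasto_study <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report,
                            c("mean_relative_error", "rmse"),
                            names_to = "metric", values_to = "percent")
  ggplot2::ggplot(df, ggplot2::aes(100 * .data$strain, .data$percent,
                                   color = .data$path)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "applied strain (%)", y = "error (%)")
}
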