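#' Write / read a displacement field as CSV
#'
#' Plain-text serialization: one row per grid point (`x`, `y`, `u`, `v`,
#' optional `correlation`, `valid`), reconstructable to the gridded form.
#'
#' @param field a [disp_field()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_disp_field <- function(field, path) {
  utils::write.csv(tidy.disp_field(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_disp_field
#' @export
read_disp_field <- function(path) {
  df <- utils::read.csv(path)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  df <- df[order(df$x, df$y), ]
  shape <- function(v) matrix(v, length(ys), length(xs))
  disp_field(x = xs, y = ys, u = shape(df$u), v = shape(df$v),
             mask = if ("valid" %in% names(df)) shape(df$valid),
             correlation = if ("correlation" %in% names(df)) shape(df$correlation))
}

#' Write / read a modulus image as CSV + JSON sidecar
#'
#' The CSV holds one row per element (`x`, `y`, `modulus`); the JSON sidecar
#' (`<path>.json`) records provenance: ROI rectangle, element size and
#' Poisson ratio. Saved modulus values are never clipped.
#'
#' @param image a `modulus_image`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_modulus_image <- function(image, path) {
  utils::write.csv(tidy.modulus_image(image), path, row.names = FALSE)
  meta <- list(roi = image$roi[c("top", "left", "height", "width",
                                 "element_size")],
               poisson = image$poisson)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_modulus_image
#' @export
read_modulus_image <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  df <- df[order(df$x, df$y), ]
  roi <- roi_spec(meta$roi$top, meta$roi$left, meta$roi$height,
                  meta$roi$width, meta$roi$element_size)
  structure(list(E = matrix(df$modulus, length(ys), length(xs)),
                 x = xs, y = ys, roi = roi, poisson = meta$poisson),
            class = "modulus_image")
}

#' Write / read a quadrilateral mesh as CSV
#'
#' Two files: `<prefix>_nodes.csv` (node coordinates, mm) and
#' `<prefix>_elems.csv` (1-based connectivity).
#'
#' @param mesh a [quad_mesh()].
#' @param prefix file-path prefix.
#' @return `prefix`, invisibly.
#' @export
write_quad_mesh <- function(mesh, prefix) {
  utils::write.csv(as.data.frame(mesh$nodes),
                   paste0(prefix, "_nodes.csv"), row.names = FALSE)
  el <- as.data.frame(mesh$elems)
  names(el) <- paste0("n", 1:4)
  utils::write.csv(el, paste0(prefix, "_elems.csv"), row.names = FALSE)
  jsonlite::write_json(list(nx = mesh$nx, ny = mesh$ny,
                            element_size = mesh$element_size,
                            origin = mesh$origin),
                       paste0(prefix, "_mesh.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_quad_mesh
#' @export
read_quad_mesh <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_mesh.json"),
                              simplifyVector = TRUE)
  quad_mesh(extent = c(meta$ny * meta$element_size[1],
                       meta$nx * meta$element_size[2]),
            element_size = meta$element_size, origin = meta$origin)
}
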