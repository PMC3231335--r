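#' Multiband reflectance image
#'
#' A `spectral_image` is a light container for a georeferenced multiband
#' raster: a numeric array indexed `[row, col, band]` holding reflectance in
#' `[0, 1]`, plus an affine geotransform. The geotransform convention is the
#' usual north-up one: map x increases eastward with column index, map y
#' increases northward, the origin is the outer corner of the top-left pixel,
#' and [pixel_centers()] reports pixel-center coordinates.
#'
#' @param values Numeric array `[row, col, band]`, finite, typically in
#'   `[0, 1]`.
#' @param origin Map coordinates `c(x, y)` of the top-left corner of the
#'   raster (meters).
#' @param pixel_size Pixel edge length in meters (> 0).
#' @param band_names Character vector, one name per band.
#'
#' @return A `spectral_image` object.
#' @export
spectral_image <- function(values, origin = c(0, 0), pixel_size = 2.4,
                           band_names = NULL) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) {
    abort("`values` must be a [row, col, band] array.")
  }
  if (!all(is.finite(values))) abort("Image values must all be finite.")
  stopifnot_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  nb <- dim(values)[3]
  if (is.null(band_names)) band_names <- paste0("band", seq_len(nb))
  if (length(band_names) != nb) abort("One band name per band required.")
  structure(
    list(values = values,
         origin = as.numeric(origin),
         pixel_size = pixel_size,
         band_names = band_names),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<spectral_image> %d x %d pixels, %d band(s) [%s]\n  pixel size %.3g m, origin (%.6g, %.6g)\n",
    d[1], d[2], d[3], paste(x$band_names, collapse = ", "),
    x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$values)

n_bands <- function(image) dim(image$values)[3]

#' Pixel-center map coordinates
#'
#' @param image A [spectral_image()].
#' @param row,col 1-based raster indices (vectors of equal length).
#' @return A two-column matrix of map `x`, `y` in meters.
#' @export
pixel_centers <- function(image, row, col) {
  ps <- image$pixel_size
  cbind(x = image$origin[1] + (col - 0.5) * ps,
        y = image$origin[2] - (row - 0.5) * ps)
}

# Inverse of pixel_centers(): map coordinates -> (row, col) indices of the
# containing pixel.
map_to_rowcol <- function(image, x, y) {
  ps <- image$pixel_size
  cbind(row = floor((image$origin[2] - y) / ps) + 1,
        col = floor((x - image$origin[1]) / ps) + 1)
}

# Pixels as an n x bands matrix, row-major over (row, col) in column-major
# raster order (col varies slowest); used by every per-pixel spectral stage.
pixel_matrix <- function(image) {
  d <- dim(image$values)
  m <- matrix(image$values, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- image$band_names
  m
}

# Rebuild a single-band raster (matrix) from a vector in pixel_matrix() order.
vector_to_raster <- function(v, image) {
  d <- dim(image$values)
  matrix(v, nrow = d[1], ncol = d[2])
}

#' Tidy a spectral image into a pixel tibble
#'
#' @param x A [spectral_image()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, map `x`, `y` (pixel centers) and one
#'   reflectance column per band.
#' @method as_tibble spectral_image
#' @export
as_tibble.spectral_image <- function(x, ...) {
  d <- dim(x$values)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  xy <- pixel_centers(x, idx$row, idx$col)
  out <- tibble(row = idx$row, col = idx$col, x = xy[, 1], y = xy[, 2])
  px <- pixel_matrix(x)
  for (b in seq_len(d[3])) out[[x$band_names[b]]] <- px[, b]
  out
}
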