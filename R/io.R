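#' Read and write multiband reflectance rasters
#'
#' Images are stored as multiband TIFF (32-bit float samples) with the
#' geotransform carried in an ESRI world file (`.tfw`) next to the image —
#' the standard sidecar convention for georeferenced TIFFs. Band names go
#' in a `.bands` text sidecar, one name per line.
#'
#' @param image A [spectral_image()].
#' @param path Output `.tif` path; the world file replaces the extension
#'   with `.tfw`.
#' @return `write_spectral_image()` returns `path` invisibly;
#'   `read_spectral_image()` returns a [spectral_image()].
#' @export
write_spectral_image <- function(image, path) {
  d <- dim(image$values)
  arr <- image$values
  tiff::writeTIFF(arr, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  writeLines(image$band_names, band_file_path(path))
  ps <- image$pixel_size
  # world file: pixel size, rotations, and the CENTER of the top-left pixel
  wf <- c(ps, 0, 0, -ps,
          image$origin[1] + ps / 2,
          image$origin[2] - ps / 2)
  writeLines(formatC(wf, format = "fg", digits = 12), world_file_path(path))
  invisible(path)
}

#' @rdname write_spectral_image
#' @export
read_spectral_image <- function(path) {
  # libtiff flags the 4th (NIR) sample of an RGB-interpreted image as an
  # extra sample; that is exactly how multiband data is stored here
  img <- withCallingHandlers(
    tiff::readTIFF(path, info = TRUE, as.is = FALSE),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  bf <- band_file_path(path)
  bands <- if (file.exists(bf)) {
    readLines(bf)
  } else {
    paste0("band", seq_len(dim(img)[3]))
  }
  tfw <- world_file_path(path)
  if (file.exists(tfw)) {
    wf <- as.numeric(readLines(tfw))
    ps <- wf[1]
    origin <- c(wf[5] - ps / 2, wf[6] + ps / 2)
  } else {
    ps <- 1
    origin <- c(0, 0)
  }
  spectral_image(array(as.numeric(img), dim = dim(img)),
                 origin = origin, pixel_size = ps, band_names = bands)
}

world_file_path <- function(path) sub("\\.[^.]+$", ".tfw", path)

band_file_path <- function(path) sub("\\.[^.]+$", ".bands", path)

#' Write point tables as GeoJSON
#'
#' Writes any tibble carrying `x`/`y` map-coordinate columns as a GeoJSON
#' FeatureCollection of points; remaining columns become feature properties.
#'
#' @param points A data frame with numeric `x` and `y` columns (meters,
#'   projected coordinates).
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(points, path) {
  props <- points[, setdiff(names(points), c("x", "y")), drop = FALSE]
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = as.list(props[i, , drop = FALSE])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
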