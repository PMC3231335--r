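#' Endmember spectral library
#'
#' An endmember library holds one reference ("pure") reflectance spectrum per
#' land-cover class, in a fixed band order (blue, green, red, NIR for the
#' default Quickbird-like configuration). The flower class is the detection
#' target: it supplies the target spectrum for spectral angle mapping and one
#' column of the linear mixing matrix; the remaining classes are background.
#'
#' @param spectra A data frame (or tibble) with a `class` character column and
#'   one numeric column per band, reflectances in `[0, 1]`. Must contain a
#'   `"flower"` row and at least one background class.
#' @param band_names Character vector naming the band columns, in band order.
#'
#' @return An `endmember_library`: a tibble with class `endmember_library`,
#'   one row per endmember.
#' @examples
#' lib <- default_endmembers()
#' lib
#' endmember_matrix(lib)  # bands x endmembers mixing matrix
#' @export
endmember_library <- function(spectra,
                              band_names = c("blue", "green", "red", "nir")) {
  spectra <- as_tibble(spectra)
  if (!"class" %in% names(spectra)) {
    abort("`spectra` must have a `class` column.")
  }
  missing_bands <- setdiff(band_names, names(spectra))
  if (length(missing_bands) > 0) {
    abort(paste0("Missing band columns: ", paste(missing_bands, collapse = ", ")))
  }
  spectra <- spectra[, c("class", band_names)]
  vals <- as.matrix(spectra[, band_names])
  if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
    abort("All endmember reflectances must be finite and in [0, 1].")
  }
  if (any(rowSums(vals^2) == 0)) {
    abort("Endmember spectra must be nonzero vectors.")
  }
  if (anyDuplicated(spectra$class)) {
    abort("Endmember class names must be unique.")
  }
  if (!"flower" %in% spectra$class) {
    abort("The library must contain a \"flower\" endmember.")
  }
  structure(spectra,
            band_names = band_names,
            class = c("endmember_library", class(spectra)))
}

#' Default Quickbird-like endmember library
#'
#' Package-constant reflectance spectra for the synthetic scenes: a bright
#' yellow-flower canopy target whose reflectance peaks in the green/red bands,
#' plus four background covers (green vegetation, bare soil, open water,
#' man-made surfaces). Values are plausible 4-band surface reflectances for a
#' moist tropical scene; they are design constants of the generator, not
#' measurements.
#'
#' @return An [endmember_library()] with five classes.
#' @export
default_endmembers <- function() {
  endmember_library(tibble(
    class = c("flower", "vegetation", "soil", "water", "manmade"),
    blue  = c(0.08, 0.04, 0.20, 0.06, 0.30),
    green = c(0.45, 0.08, 0.28, 0.05, 0.32),
    red   = c(0.50, 0.05, 0.33, 0.03, 0.34),
    nir   = c(0.60, 0.45, 0.40, 0.01, 0.35)
  ))
}

#' Mixing matrix of an endmember library
#'
#' @param library An [endmember_library()].
#' @param classes Optional subset (and ordering) of class names.
#' @return A bands x endmembers numeric matrix with band rownames and class
#'   colnames (the `R_ib` mixing matrix of linear unmixing).
#' @export
endmember_matrix <- function(library, classes = NULL) {
  bands <- attr(library, "band_names")
  if (is.null(classes)) classes <- library$class
  idx <- match(classes, library$class)
  if (anyNA(idx)) abort("Unknown endmember class requested.")
  m <- t(as.matrix(library[idx, bands, drop = FALSE]))
  dimnames(m) <- list(bands, classes)
  m
}

#' Extract one endmember spectrum
#'
#' @param library An [endmember_library()].
#' @param class Class name.
#' @return Named numeric vector of per-band reflectance.
#' @export
endmember_spectrum <- function(library, class = "flower") {
  endmember_matrix(library, classes = class)[, 1]
}

#' Replace the flower spectrum of a library
#'
#' Used by the pipeline to substitute the image-derived flower endmember
#' (average of OCSVM pure pixels) for the generator's true flower spectrum,
#' so unmixing never sees ground-truth knowledge.
#'
#' @param library An [endmember_library()].
#' @param spectrum Numeric per-band reflectance vector.
#' @return A new `endmember_library`.
#' @export
set_flower_spectrum <- function(library, spectrum) {
  bands <- attr(library, "band_names")
  if (length(spectrum) != length(bands)) {
    abort("`spectrum` length must equal the library band count.")
  }
  library[library$class == "flower", bands] <- as.list(pmin(pmax(spectrum, 0), 1))
  endmember_library(as_tibble(library), band_names = bands)
}
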