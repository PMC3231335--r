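#' @importFrom ggplot2 ggplot aes geom_raster geom_point geom_hline
#'   geom_vline scale_fill_viridis_c coord_equal labs theme_minimal autoplot
NULL

#' Plot a band or false-colour composite of a scene
#'
#' @param image A [spectral_image()].
#' @param band Band name to display (single-band heat map).
#' @return A ggplot.
#' @export
plot_band <- function(image, band = "nir") {
  df <- as_tibble(image)
  if (!band %in% names(df)) abort("Unknown band.")
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data[[band]])) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(title = paste0("Reflectance: ", band), x = "easting (m)",
         y = "northing (m)") +
    theme_minimal()
}

#' Abundance-vs-angle diagnostic plot
#'
#' The joint decision space of the pipeline: each pixel's flower fractional
#' abundance against its spectral angle to the target, coloured by region
#' label, with the pure/mixed thresholds drawn in.
#'
#' @param object An `abundance_angle_maps` object.
#' @param max_points Subsample cap for plotting speed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abundance_angle_maps
#' @export
autoplot.abundance_angle_maps <- function(object, max_points = 20000, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  th <- object$thresholds
  ggplot(df, aes(x = .data$fraction, y = .data$theta,
                 colour = .data$region)) +
    geom_point(alpha = 0.4, size = 0.6) +
    geom_vline(xintercept = c(th$fraction_mixed_low, th$fraction_pure),
               linetype = "dashed") +
    geom_hline(yintercept = th$angle_max, linetype = "dashed") +
    labs(x = "flower fractional abundance F",
         y = "spectral angle θ (rad)", colour = NULL) +
    theme_minimal()
}

#' Plot a crown set over the scene extent
#'
#' @param object A `crown_set`.
#' @param ... Unused.
#' @return A ggplot of centroid positions sized by contributing pixels.
#' @method autoplot crown_set
#' @export
autoplot.crown_set <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$x, y = .data$y, size = .data$n_pixels)) +
    geom_point(shape = 21, fill = "gold", colour = "grey20") +
    coord_equal() +
    labs(x = "easting (m)", y = "northing (m)", size = "pixels") +
    theme_minimal()
}

#' Plot a two-date change report
#'
#' Needs the two crown sets to place the points; common, lost and new
#' crowns are coloured by status.
#'
#' @param report A `change_report`.
#' @param a,b The crown sets that produced it.
#' @return A ggplot.
#' @export
plot_change <- function(report, a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  df <- bind_rows(
    a |> mutate(status = ifelse(.data$id %in% report$common$id_a,
                                "common", "lost")),
    b |> filter(.data$id %in% report$new) |> mutate(status = "new")
  )
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$status)) +
    geom_point(size = 2) +
    coord_equal() +
    labs(x = "easting (m)", y = "northing (m)", colour = NULL) +
    theme_minimal()
}
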