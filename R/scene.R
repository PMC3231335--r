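#' Synthetic scene parameters
#'
#' Parameters of the Quickbird-like synthetic reflectance scene generator.
#' Defaults describe the study conditions the pipeline is validated under:
#' a 256 x 256 pixel scene at 2.4 m resolution with 50 bright-flowering
#' crowns of 1-2 pixel radius over a blocky multi-cover background.
#'
#' @param width,height Scene size in pixels.
#' @param pixel_size Pixel edge length in meters.
#' @param n_crowns Number of flowering crowns to plant.
#' @param crown_radius_range Crown radius range in meters (uniform draw);
#'   the default 1.2-4.8 m corresponds to 2.4-9.6 m crown diameters.
#' @param flower_fraction_range Per-crown peak flower abundance at the
#'   centroid pixel, in `(0, 1]`.
#' @param min_separation Minimum distance between crown centroids in meters.
#'   The default (12 m) keeps distinct crowns farther apart than twice the
#'   5 m merge radius, so the buffer merge never fuses two true crowns.
#' @param noise_sd Standard deviation of the additive, per-band, zero-mean
#'   Gaussian reflectance noise.
#' @param background_patch_size Edge length (pixels) of the square patches of
#'   the background land-cover mosaic.
#' @param background_weights Named sampling weights for the background
#'   mosaic classes. The default emulates a forested island: vegetation
#'   dominant, thin strips of water and soil, man-made cover rare. Classes
#'   present in the library but missing from the weights get weight 0;
#'   `NULL` draws all background classes uniformly.
#' @param max_placement_tries Total rejection-sampling budget for crown
#'   placement before giving up with an error.
#' @param seed Integer seed; every stochastic choice in the generator is
#'   derived from it.
#'
#' @return A `scene_params` list.
#' @export
scene_params <- function(width = 256, height = 256, pixel_size = 2.4,
                         n_crowns = 50,
                         crown_radius_range = c(1.2, 4.8),
                         flower_fraction_range = c(0.85, 1.0),
                         min_separation = 12,
                         noise_sd = 0.01,
                         background_patch_size = 8,
                         background_weights = c(vegetation = 0.85,
                                                soil = 0.06, water = 0.06,
                                                manmade = 0.03),
                         max_placement_tries = 10000L,
                         seed = 1L) {
  stopifnot_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(n_crowns, "n_crowns", min = 0)
  if (crown_radius_range[1] < pixel_size / 2) {
    abort("Crown radii must be at least half a pixel.")
  }
  if (flower_fraction_range[1] <= 0 || flower_fraction_range[2] > 1) {
    abort("`flower_fraction_range` must lie in (0, 1].")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, n_crowns = as.integer(n_crowns),
    crown_radius_range = crown_radius_range,
    flower_fraction_range = flower_fraction_range,
    min_separation = min_separation,
    noise_sd = noise_sd,
    background_patch_size = as.integer(background_patch_size),
    background_weights = background_weights,
    max_placement_tries = as.integer(max_placement_tries),
    seed = as.integer(seed)
  ), class = "scene_params")
}

# Draw crown centers (snapped to pixel centers), radii and peak fractions.
# Centers snap to pixel centers so a peak-1 crown has an exactly pure pixel.
place_crowns <- function(params) {
  n <- params$n_crowns
  ps <- params$pixel_size
  if (n == 0) {
    return(tibble(id = integer(), row = integer(), col = integer(),
                  x = numeric(), y = numeric(), radius_m = numeric(),
                  peak_fraction = numeric()))
  }
  rows <- integer(n); cols <- integer(n)
  placed <- 0L; tries <- 0L
  # keep crowns off the scene border by their own radius
  radii <- stats::runif(n, params$crown_radius_range[1],
                        params$crown_radius_range[2])
  peaks <- stats::runif(n, params$flower_fraction_range[1],
                        params$flower_fraction_range[2])
  min_sep_px <- params$min_separation / ps
  while (placed < n) {
    tries <- tries + 1L
    if (tries > params$max_placement_tries) {
      abort(sprintf(
        "Could not place %d crowns with %.1f m separation in a %d x %d scene (budget %d tries).",
        n, params$min_separation, params$width, params$height,
        params$max_placement_tries))
    }
    margin <- ceiling(radii[placed + 1L] / ps) + 1L
    r <- sample.int(params$height - 2L * margin, 1L) + margin
    cc <- sample.int(params$width - 2L * margin, 1L) + margin
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - cc)^2
      if (min(d2) < min_sep_px^2) next
    }
    placed <- placed + 1L
    rows[placed] <- r; cols[placed] <- cc
  }
  tibble(id = seq_len(n), row = rows, col = cols,
         radius_m = radii, peak_fraction = peaks)
}

# Blocky mosaic of background classes: a coarse patch grid, each patch a
# random background endmember. Returns an integer matrix of library row ids.
background_mosaic <- function(params, library) {
  bg_classes <- which(library$class != "flower")
  w <- params$background_weights
  prob <- if (is.null(w)) {
    NULL
  } else {
    p <- w[library$class[bg_classes]]
    p[is.na(p)] <- 0
    if (sum(p) <= 0) abort("No background class has positive weight.")
    p / sum(p)
  }
  n_pr <- ceiling(params$height / params$background_patch_size)
  n_pc <- ceiling(params$width / params$background_patch_size)
  patch <- matrix(sample(bg_classes, n_pr * n_pc, replace = TRUE,
                         prob = prob),
                  nrow = n_pr)
  pr <- ((seq_len(params$height) - 1L) %/% params$background_patch_size) + 1L
  pc <- ((seq_len(params$width) - 1L) %/% params$background_patch_size) + 1L
  patch[pr, pc, drop = FALSE]
}

# Per-pixel flower abundance from planted crowns: radially linear taper from
# the peak at the centroid pixel to zero at the crown radius.
flower_fraction_raster <- function(params, crowns) {
  f <- matrix(0, nrow = params$height, ncol = params$width)
  ps <- params$pixel_size
  for (i in seq_len(nrow(crowns))) {
    rad_px <- crowns$radius_m[i] / ps
    r0 <- crowns$row[i]; c0 <- crowns$col[i]
    rr <- max(1L, floor(r0 - rad_px)):min(params$height, ceiling(r0 + rad_px))
    cc <- max(1L, floor(c0 - rad_px)):min(params$width, ceiling(c0 + rad_px))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    contrib <- crowns$peak_fraction[i] * pmax(0, 1 - d / rad_px)
    f[rr, cc] <- pmax(f[rr, cc], contrib)
  }
  f
}

#' Generate a synthetic flowering scene
#'
#' Builds a 4-band reflectance image in which each pixel is a linear mixture
#' of the flower endmember (abundance from the planted crown taper) and one
#' background endmember (from a blocky land-cover mosaic), plus additive
#' Gaussian noise, clipped to `[0, 1]`. Per-pixel abundances sum to one
#' before noise. The returned ground truth lists every planted crown with
#' its pixel-center centroid in map coordinates.
#'
#' @param params A [scene_params()].
#' @param library An [endmember_library()] with the flower class and at least
#'   one background class.
#' @param .noise_seed Internal override for the noise stream (used by
#'   [generate_scene_pair()] to share crown/background layout across dates
#'   while drawing independent noise).
#'
#' @return A list with elements `image` (a [spectral_image()]), `truth` (a
#'   tibble: `id`, `x`, `y`, `radius_m`, `peak_fraction`, `in_date1`,
#'   `in_date2`), `fractions` (the true flower-abundance matrix) and
#'   `clipping_rate` (share of samples clipped by the `[0,1]` bound).
#' @examples
#' sc <- generate_scene(scene_params(n_crowns = 5, width = 64, height = 64))
#' sc$truth
#' @export
generate_scene <- function(params = scene_params(),
                           library = default_endmembers(),
                           .noise_seed = NULL) {
  if (nrow(library) < 2) abort("Library needs the flower class plus background.")
  with_seed(params$seed, {
    crowns <- place_crowns(params)
    bg <- background_mosaic(params, library)
    f <- flower_fraction_raster(params, crowns)
    build_scene(params, library, crowns, bg, f,
                noise_seed = .noise_seed %||% (params$seed + 1L),
                in1 = rep(TRUE, nrow(crowns)),
                in2 = rep(TRUE, nrow(crowns)))
  })
}

build_scene <- function(params, library, crowns, bg, f, noise_seed,
                        in1, in2) {
  bands <- attr(library, "band_names")
  em <- endmember_matrix(library)            # bands x classes
  flower <- em[, "flower"]
  npx <- params$height * params$width
  vals <- array(0, dim = c(params$height, params$width, length(bands)))
  fv <- as.vector(f)
  bgv <- as.vector(bg)
  for (b in seq_along(bands)) {
    vals[, , b] <- matrix(fv * flower[b] + (1 - fv) * em[b, ][bgv],
                          nrow = params$height)
  }
  clipped <- 0
  if (params$noise_sd > 0) {
    with_seed(noise_seed, {
      noise <- array(stats::rnorm(length(vals), 0, params$noise_sd),
                     dim = dim(vals))
      vals <- vals + noise
    })
  }
  clipped <- mean(vals < 0 | vals > 1)
  vals <- pmin(pmax(vals, 0), 1)
  image <- spectral_image(vals, origin = c(0, params$height * params$pixel_size),
                          pixel_size = params$pixel_size, band_names = bands)
  xy <- pixel_centers(image, crowns$row, crowns$col)
  truth <- tibble(id = crowns$id, x = xy[, 1], y = xy[, 2],
                  radius_m = crowns$radius_m,
                  peak_fraction = crowns$peak_fraction,
                  in_date1 = in1, in_date2 = in2)
  list(image = image, truth = truth, fractions = f, clipping_rate = clipped)
}

#' Generate a matched two-date scene pair
#'
#' Plants one crown population and splits it across two acquisition dates:
#' a `shared_fraction` of crowns flowers on both dates, and the remainder is
#' divided between date-1-only crowns (fallen, died or non-reproducing by
#' date 2) and date-2-only crowns (newly reproductive). The background
#' mosaic is identical across dates; reflectance noise is drawn
#' independently per date.
#'
#' @inheritParams generate_scene
#' @param shared_fraction Proportion of crowns present on both dates, in
#'   `[0, 1]`. The shared count is `round(shared_fraction * n_crowns)`.
#'
#' @return A list `image1`, `image2` ([spectral_image()]s), `truth` (tibble
#'   with per-date presence flags), `clipping_rate` (max over dates).
#' @export
generate_scene_pair <- function(params = scene_params(),
                                library = default_endmembers(),
                                shared_fraction = 0.5) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1].")
  }
  with_seed(params$seed, {
    crowns <- place_crowns(params)
    bg <- background_mosaic(params, library)
    n <- nrow(crowns)
    n_shared <- as.integer(round_half_up(shared_fraction * n))
    rest <- n - n_shared
    n_lost <- ceiling(rest / 2)
    status <- rep("new", n)
    if (n > 0) {
      ord <- sample.int(n)   # random assignment of crowns to fates
      status[ord[seq_len(n_shared)]] <- "shared"
      if (n_lost > 0) status[ord[n_shared + seq_len(n_lost)]] <- "lost"
    }
    in1 <- status %in% c("shared", "lost")
    in2 <- status %in% c("shared", "new")
    f1 <- flower_fraction_raster(params, crowns[in1, , drop = FALSE])
    f2 <- flower_fraction_raster(params, crowns[in2, , drop = FALSE])
    s1 <- build_scene(params, library, crowns, bg, f1,
                      noise_seed = params$seed + 1L, in1 = in1, in2 = in2)
    s2 <- build_scene(params, library, crowns, bg, f2,
                      noise_seed = params$seed + 2L, in1 = in1, in2 = in2)
    list(image1 = s1$image, image2 = s2$image, truth = s1$truth,
         fractions1 = f1, fractions2 = f2,
         clipping_rate = max(s1$clipping_rate, s2$clipping_rate))
  })
}

#' Write a generated scene to disk
#'
#' Writes the image as multiband TIFF + world file, and the ground truth as
#' CSV and GeoJSON points.
#'
#' @param scene Result of [generate_scene()] or a single date of a pair.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectral_image(scene$image, file.path(dir, paste0(stem, ".tif")))
  utils::write.csv(scene$truth, file.path(dir, paste0(stem, "_truth.csv")),
                   row.names = FALSE)
  write_points_geojson(scene$truth, file.path(dir, paste0(stem, "_truth.geojson")))
  invisible(dir)
}
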