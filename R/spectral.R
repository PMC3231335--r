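#' Spectral angle between two spectra
#'
#' The spectral angle mapper (SAM) similarity: the angle between two spectra
#' treated as vectors, `theta = acos((t . r) / (|t| |r|))`, in radians in
#' `[0, pi]`. Because only vector direction enters, the angle is invariant
#' to positive scaling of either spectrum, i.e. insensitive to illumination
#' differences.
#'
#' @param target,pixel Numeric vectors of equal length, neither all-zero.
#' @return The angle in radians.
#' @examples
#' spectral_angle(c(1, 0), c(1, 1))  # pi/4
#' @export
spectral_angle <- function(target, pixel) {
  if (length(target) != length(pixel)) {
    abort("Spectra must have equal length.")
  }
  nt <- sqrt(sum(target^2)); np <- sqrt(sum(pixel^2))
  if (nt == 0 || np == 0) abort("Spectral angle is undefined for zero vectors.")
  cosv <- sum(target * pixel) / (nt * np)
  acos(pmin(1, pmax(-1, cosv)))   # clamp for float safety
}

# Vectorized SAM of every row of `pixels` (n x bands) against one target.
# Zero-norm pixel rows get NA (handled by the region rule as background).
spectral_angle_rows <- function(target, pixels) {
  nt <- sqrt(sum(target^2))
  np <- sqrt(rowSums(pixels^2))
  cosv <- as.vector(pixels %*% target) / (nt * np)
  theta <- acos(pmin(1, pmax(-1, cosv)))
  theta[np == 0] <- NA_real_
  theta
}

#' Linear spectral unmixing of one pixel
#'
#' Decomposes a pixel reflectance spectrum into fractional abundances of the
#' library endmembers under the linear mixing model
#' `r_b = sum_i F_i R_ib + E_b`, solved by least squares subject to the
#' sum-to-one constraint `sum_i F_i = 1` and (by default) nonnegativity
#' `F_i >= 0`. The nonnegative problem is solved exactly by enumerating
#' active sets, which is cheap at the 4-band / <= 5-endmember sizes this
#' package targets.
#'
#' @param pixel Numeric per-band reflectance vector.
#' @param endmembers An [endmember_library()] or a bands x endmembers
#'   mixing matrix.
#' @param nonneg Enforce `F_i >= 0` (default `TRUE`).
#' @return A list with `fractions` (named abundance vector), `residual`
#'   (per-band fit error `E_b`) and `rmse`.
#' @examples
#' lib <- default_endmembers()
#' em <- endmember_matrix(lib)
#' mix <- 0.5 * em[, "flower"] + 0.5 * em[, "vegetation"]
#' unmix(mix, lib)$fractions
#' @export
unmix <- function(pixel, endmembers, nonneg = TRUE) {
  em <- if (inherits(endmembers, "endmember_library")) {
    endmember_matrix(endmembers)
  } else {
    as.matrix(endmembers)
  }
  if (length(pixel) != nrow(em)) {
    abort("Pixel band count must match the endmember matrix.")
  }
  if (ncol(em) > nrow(em) + 1) {
    abort("At most n_bands + 1 endmembers are identifiable with sum-to-one.")
  }
  if (qr(rbind(em, 1))$rank < ncol(em)) {
    abort("Endmember matrix is rank deficient; unmixing is not identifiable.")
  }
  F <- fcls_solve(em, matrix(pixel, ncol = 1), nonneg = nonneg)[, 1]
  resid <- as.vector(pixel - em %*% F)
  list(fractions = stats::setNames(F, colnames(em)),
       residual = stats::setNames(resid, rownames(em)),
       rmse = sqrt(mean(resid^2)))
}

# Sum-to-one constrained least squares for all columns of R (bands x npix),
# solved exactly through the KKT system
#   [ E'E  1 ] [F]   [E'r]
#   [ 1'   0 ] [l] = [ 1 ]
# which stays well-posed with n_endmembers = n_bands + 1 (where E'E alone
# is singular but the equality constraint restores identifiability).
scls_solve <- function(em, R) {
  k <- ncol(em)
  A <- rbind(cbind(crossprod(em), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(crossprod(em, R), rep(1, ncol(R)))
  solve(A, rhs)[seq_len(k), , drop = FALSE]
}

# Fully constrained LS (sum-to-one + optional nonnegativity), exact via
# active-set subset enumeration, batched over all offending pixels. With
# k <= bands + 1 endmembers the 2^k - 1 candidate supports are enumerable,
# so the solution is the true constrained optimum, not a descent heuristic.
fcls_solve <- function(em, R, nonneg = TRUE, tol = 1e-10) {
  k <- ncol(em)
  F <- scls_solve(em, R)
  if (!nonneg) return(F)
  bad <- which(matrixStats_colMins(F) < -tol)
  if (length(bad) == 0) return(F)
  Rb <- R[, bad, drop = FALSE]
  bestF <- matrix(0, nrow = k, ncol = length(bad))
  best_sse <- rep(Inf, length(bad))
  for (keep in active_subsets(k)) {
    Fs <- tryCatch(scls_solve(em[, keep, drop = FALSE], Rb),
                   error = function(e) NULL)   # singular subset: skip
    if (is.null(Fs)) next
    feasible <- matrixStats_colMins(Fs) >= -tol
    if (!any(feasible)) next
    sse <- colSums((Rb - em[, keep, drop = FALSE] %*% Fs)^2)
    improve <- feasible & (sse < best_sse - 1e-12)
    if (any(improve)) {
      best_sse[improve] <- sse[improve]
      bestF[, improve] <- 0
      bestF[keep, improve] <- Fs[, improve, drop = FALSE]
    }
  }
  F[, bad] <- pmax(bestF, 0)
  F
}

matrixStats_colMins <- function(m) {
  # column minima without an extra dependency
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

# Nonempty subsets of endmember indices, largest first so the unconstrained
# optimum wins when feasible.
active_subsets <- function(k) {
  subs <- unlist(lapply(seq(k, 1), function(sz) {
    utils::combn(k, sz, simplify = FALSE)
  }), recursive = FALSE)
  subs
}

#' Classify a pixel into the pure/mixed/background regions
#'
#' The joint abundance/angle decision rule: a pixel is a pure flower pixel
#' (region A) when its flower abundance exceeds `fraction_pure`; a mixed
#' crown-edge pixel (region B) when the abundance lies in
#' `(fraction_mixed_low, fraction_pure]` *and* the spectral angle to the
#' flower target is below `angle_max`; anything else (including undefined
#' angles from zero-reflectance pixels) is background.
#'
#' @param fraction Flower fractional abundance (vectorized).
#' @param theta Spectral angle to the flower target, radians (vectorized).
#' @param thresholds A [region_thresholds()] list.
#' @return A factor with levels `PURE_A`, `MIXED_B`, `BACKGROUND`.
#' @examples
#' classify_region(c(0.85, 0.5, 0.5, 0.2), c(0.2, 0.03, 0.06, 0.01))
#' @export
classify_region <- function(fraction, theta, thresholds = region_thresholds()) {
  a <- thresholds$fraction_pure
  lo <- thresholds$fraction_mixed_low
  th <- thresholds$angle_max
  lab <- rep("BACKGROUND", length(fraction))
  pure <- !is.na(fraction) & fraction > a
  if (isTRUE(thresholds$angle_applies_to_pure)) {
    pure <- pure & !is.na(theta) & theta < th
  }
  mixed <- !is.na(fraction) & !is.na(theta) &
    fraction > lo & fraction <= a & theta < th
  lab[mixed] <- "MIXED_B"
  lab[pure] <- "PURE_A"
  factor(lab, levels = c("PURE_A", "MIXED_B", "BACKGROUND"))
}

#' Region thresholds
#'
#' The fraction/angle thresholds of the joint decision rule. Defaults are
#' the operational values for Quickbird flowering-crown detection:
#' `F > 0.80` for pure pixels and `0.25 < F <= 0.80` with `theta < 0.05` rad
#' for mixed crown edges. The boundary `F = 0.80` belongs to the mixed
#' region so the rule is total and non-overlapping.
#'
#' @param fraction_pure Pure-region abundance threshold.
#' @param fraction_mixed_low Lower abundance bound of the mixed region.
#' @param angle_max Spectral-angle ceiling (radians) of the mixed region.
#' @param angle_applies_to_pure Also require `theta < angle_max` in the pure
#'   region (off by default; the pure region is abundance-only).
#' @return A `region_thresholds` list.
#' @export
region_thresholds <- function(fraction_pure = 0.80, fraction_mixed_low = 0.25,
                              angle_max = 0.05, angle_applies_to_pure = FALSE) {
  if (!(fraction_mixed_low > 0 && fraction_mixed_low < fraction_pure &&
        fraction_pure <= 1)) {
    abort("Require 0 < fraction_mixed_low < fraction_pure <= 1.")
  }
  stopifnot_scalar_number(angle_max, "angle_max", min = 0, strict_min = TRUE)
  structure(list(fraction_pure = fraction_pure,
                 fraction_mixed_low = fraction_mixed_low,
                 angle_max = angle_max,
                 angle_applies_to_pure = angle_applies_to_pure),
            class = "region_thresholds")
}

#' Map flower abundance, spectral angle and region labels over a scene
#'
#' Runs SAM (against the target spectrum) and fully constrained linear
#' unmixing (against the full library) for every pixel, then applies the
#' joint region rule. The target spectrum is used both as the SAM reference
#' and as the flower column of the mixing matrix.
#'
#' @param image A [spectral_image()].
#' @param target Flower target spectrum (e.g. from [derive_endmember()]).
#' @param endmembers An [endmember_library()]; its flower spectrum is
#'   replaced by `target`.
#' @param thresholds A [region_thresholds()].
#' @return An `abundance_angle_maps` list: matrices `fraction`, `theta`,
#'   factor matrix `region` (stored as character), the `image` geotransform
#'   fields, and a `summary` tibble of per-region pixel counts.
#' @export
map_scene <- function(image, target, endmembers = default_endmembers(),
                      thresholds = region_thresholds()) {
  lib <- set_flower_spectrum(endmembers, target)
  em <- endmember_matrix(lib)
  px <- pixel_matrix(image)
  theta <- spectral_angle_rows(target, px)
  F <- fcls_solve(em, t(px), nonneg = TRUE)
  flower_f <- F[match("flower", colnames(em)), ]
  region <- classify_region(flower_f, theta, thresholds)
  region_counts <- as.integer(table(region))
  resid <- t(px) - em %*% F
  rmse <- sqrt(colMeans(resid^2))
  out <- list(
    fraction = vector_to_raster(flower_f, image),
    theta = vector_to_raster(theta, image),
    rmse = vector_to_raster(rmse, image),
    region = vector_to_raster(as.character(region), image),
    origin = image$origin, pixel_size = image$pixel_size,
    thresholds = thresholds,
    summary = tibble(region = levels(region), n_pixels = region_counts)
  )
  class(out) <- "abundance_angle_maps"
  out
}

#' @export
print.abundance_angle_maps <- function(x, ...) {
  cat("<abundance_angle_maps>", nrow(x$fraction), "x", ncol(x$fraction),
      "pixels\n")
  print(x$summary)
  invisible(x)
}

#' Tidy abundance/angle maps into a pixel tibble
#'
#' @param x An `abundance_angle_maps` object.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `fraction`, `theta`,
#'   `rmse`, `region`.
#' @method as_tibble abundance_angle_maps
#' @export
as_tibble.abundance_angle_maps <- function(x, ...) {
  d <- dim(x$fraction)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ps <- x$pixel_size
  tibble(row = idx$row, col = idx$col,
         x = x$origin[1] + (idx$col - 0.5) * ps,
         y = x$origin[2] - (idx$row - 0.5) * ps,
         fraction = as.vector(x$fraction),
         theta = as.vector(x$theta),
         rmse = as.vector(x$rmse),
         region = factor(as.vector(x$region),
                         levels = c("PURE_A", "MIXED_B", "BACKGROUND")))
}
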