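#' Gaussian RBF kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`, the kernel of the one-class SVM.
#' Values lie in `(0, 1]`, with 1 exactly at zero distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive kernel width parameter.
#' @return The kernel value.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) abort("Kernel inputs must have equal length.")
  stopifnot_scalar_number(gamma, "gamma", min = 0, strict_min = TRUE)
  exp(-gamma * sum((x - y)^2))
}

# Full RBF Gram matrix between row sets A (n x d) and B (m x d).
rbf_gram <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a one-class SVM (RBF kernel) on flower candidate spectra
#'
#' Solves the one-class SVM dual
#' \deqn{\min_\alpha \tfrac12 \alpha^\top K \alpha \quad
#'       \text{s.t.}\; 0 \le \alpha_i \le 1/(\nu l),\; \sum_i \alpha_i = 1,}
#' by a working-set (SMO-style) coordinate scheme on the full kernel matrix.
#' `nu` bounds the fraction of training spectra treated as outliers (and
#' lower-bounds the support-vector fraction); `gamma` sets the RBF width in
#' squared-reflectance units. The decision function is
#' `f(x) = sum_i alpha_i K(x_i, x) - b`, with `x` an inlier when
#' `f(x) >= 0`; the bias `b` is the average of `sum_j alpha_j K(x_j, x_i)`
#' over unbounded support vectors (`0 < alpha_i < 1/(nu l)`).
#'
#' @param training Numeric matrix of training spectra, one row per pixel
#'   (or a data frame of numeric columns).
#' @param nu Outlier-fraction trade-off, in `(0, 1]`; `nu * l` must be
#'   `>= 1` for the box constraint to be feasible.
#' @param gamma RBF width, `> 0`.
#' @param feature_scale Multiplier applied to the spectra before entering
#'   the kernel (default 1). The pipeline fits with `feature_scale = 100`,
#'   i.e. percent reflectance, the scale on which an RBF width of
#'   `gamma = 0.1` resolves flower/background contrasts; the scale is
#'   recorded in the model and re-applied to prediction inputs.
#' @param tol Duality-gap tolerance of the solver.
#' @param max_iter Iteration cap; exceeding it is an error, not a warning.
#' @return An `ocsvm` model: support vectors, `alpha`, `bias`, `nu`,
#'   `gamma`, training size `l`, and diagnostics.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60, mean = 0.5, sd = 0.05), ncol = 3)
#' m <- fit_ocsvm(x, nu = 0.2, gamma = 10)
#' glance(m)
#' @export
fit_ocsvm <- function(training, nu = 0.1, gamma = 0.1, feature_scale = 1,
                      tol = 1e-8, max_iter = 200000L) {
  stopifnot_scalar_number(feature_scale, "feature_scale", min = 0,
                          strict_min = TRUE)
  X <- as.matrix(training) * feature_scale
  storage.mode(X) <- "double"
  l <- nrow(X)
  if (l < 2) abort("Need at least two training spectra.")
  if (!(nu > 0 && nu <= 1)) abort("`nu` must be in (0, 1].")
  stopifnot_scalar_number(gamma, "gamma", min = 0, strict_min = TRUE)
  C <- 1 / (nu * l)
  if (nu * l < 1) {
    abort(sprintf(
      "Infeasible nu: nu * l = %.3f < 1, the box constraint cannot sum to 1.",
      nu * l))
  }
  K <- rbf_gram(X, X, gamma)
  alpha <- rep(1 / l, l)            # uniform start: feasible, order-symmetric
  g <- as.vector(K %*% alpha)       # gradient of 1/2 a'Ka
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      abort(sprintf("One-class SVM solver did not converge in %d iterations.",
                    max_iter))
    }
    up <- alpha < C - 1e-12         # can increase
    down <- alpha > 1e-12           # can decrease
    if (!any(up) || !any(down)) { gap <- 0; break }
    i <- which(up)[which.min(g[up])]
    j <- which(down)[which.max(g[down])]
    gap <- g[j] - g[i]
    if (gap < tol) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    delta <- if (eta > 1e-12) gap / eta else Inf
    delta <- min(delta, C - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + delta
    alpha[j] <- alpha[j] - delta
    g <- g + delta * (K[, i] - K[, j])
  }
  sv <- alpha > 1e-9
  unbounded <- sv & (alpha < C - 1e-9)
  bias <- if (any(unbounded)) {
    mean(g[unbounded])
  } else {
    # all SVs at the bound (e.g. nu = 1): midpoint of the decision values
    mean(range(g[sv]))
  }
  structure(list(
    support_vectors = X[sv, , drop = FALSE],
    alpha = alpha[sv],
    alpha_full = alpha,
    bias = bias,
    nu = nu, gamma = gamma, l = l, C = C,
    feature_scale = feature_scale,
    iterations = it, gap = gap,
    band_names = colnames(X)
  ), class = "ocsvm")
}

#' @export
print.ocsvm <- function(x, ...) {
  cat(sprintf(
    "<ocsvm> nu=%.3g gamma=%.3g  l=%d  support vectors=%d  bias=%.5g\n",
    x$nu, x$gamma, x$l, length(x$alpha), x$bias))
  invisible(x)
}

#' Decision values of a one-class SVM
#'
#' `f(x) = sum_i alpha_i K(x_i, x) - b`; nonnegative values are inliers
#' (pure flower pixels), negative values anomalies.
#'
#' @param model An [fit_ocsvm()] model.
#' @param newdata Matrix of spectra, one row each.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, newdata) {
  X <- as.matrix(newdata) * (model$feature_scale %||% 1)
  if (ncol(X) != ncol(model$support_vectors)) {
    abort("Band count of `newdata` must match the training spectra.")
  }
  Kx <- rbf_gram(X, model$support_vectors, model$gamma)
  as.vector(Kx %*% model$alpha) - model$bias
}

#' Classify scene pixels as pure flower pixels
#'
#' Applies the one-class decision function to every pixel and returns the
#' binary pure-pixel mask aligned to the image grid.
#'
#' @param model An [fit_ocsvm()] model.
#' @param image A [spectral_image()] with matching band count.
#' @return A logical matrix (`TRUE` = pure flower pixel) with the image's
#'   dimensions.
#' @export
classify_pixels <- function(model, image) {
  f <- decision_values(model, pixel_matrix(image))
  vector_to_raster(f >= 0, image)
}

#' Average masked pixels into a target endmember spectrum
#'
#' The flower target endmember is the per-band arithmetic mean of the pixels
#' flagged pure by the one-class SVM.
#'
#' @param image A [spectral_image()].
#' @param mask Logical matrix from [classify_pixels()] (same grid).
#' @return Named per-band mean reflectance vector.
#' @export
derive_endmember <- function(image, mask) {
  if (!any(mask)) abort("Cannot derive an endmember from an empty mask.")
  px <- pixel_matrix(image)
  colMeans(px[as.vector(mask), , drop = FALSE])
}

#' Select training spectra by flower-likeness brightness
#'
#' Automated stand-in for manual candidate picking: ranks pixels by a
#' yellowness index — mean reflectance in the flower-dominant bands (green
#' and red for yellow blossoms) minus the blue reflectance, which bright
#' yellow flowers lack and gray man-made surfaces retain — and keeps the
#' top `quantile` share as one-class training spectra.
#'
#' @param image A [spectral_image()].
#' @param quantile Share of pixels to keep (default 0.002, i.e. the top
#'   0.2%, commensurate with the pure-pixel count tens of small crowns can
#'   contribute to a scene).
#' @param bands Flower-dominant band names.
#' @param penalty_band Band subtracted from the index (`NULL` for plain
#'   brightness).
#' @return Matrix of training spectra (rows), with an `index` attribute of
#'   pixel indices in raster order.
#' @export
select_training_pixels <- function(image, quantile = 0.002,
                                   bands = c("green", "red"),
                                   penalty_band = "blue") {
  px <- pixel_matrix(image)
  bi <- match(bands, image$band_names)
  if (anyNA(bi)) abort("Flower-likeness bands not present in the image.")
  score <- rowMeans(px[, bi, drop = FALSE])
  if (!is.null(penalty_band)) {
    pi <- match(penalty_band, image$band_names)
    if (is.na(pi)) abort("`penalty_band` not present in the image.")
    score <- score - px[, pi]
  }
  n_keep <- max(2L, ceiling(quantile * nrow(px)))
  idx <- order(score, decreasing = TRUE)[seq_len(n_keep)]
  out <- px[idx, , drop = FALSE]
  attr(out, "index") <- idx
  out
}

#' @rdname fit_ocsvm
#' @param x An `ocsvm` model.
#' @param ... Unused.
#' @method tidy ocsvm
#' @export
tidy.ocsvm <- function(x, ...) {
  sv <- as_tibble(as.data.frame(x$support_vectors))
  dplyr::bind_cols(tibble(alpha = x$alpha), sv)
}

#' @rdname fit_ocsvm
#' @method glance ocsvm
#' @export
glance.ocsvm <- function(x, ...) {
  tibble(nu = x$nu, gamma = x$gamma, l = x$l,
         n_support = length(x$alpha), bias = x$bias,
         iterations = x$iterations, gap = x$gap)
}

#' Serialize / restore a one-class SVM model as plain text
#'
#' A self-describing single-file format: a JSON object holding the
#' parameters, bias, alphas and support-vector spectra, so a model fitted
#' on one date can be reused on another.
#'
#' @param model An `ocsvm` model.
#' @param path Output path.
#' @return `write_ocsvm()` returns `path` invisibly; `read_ocsvm()` the
#'   model.
#' @export
write_ocsvm <- function(model, path) {
  obj <- list(format = "phenocrown-ocsvm-1",
              nu = model$nu, gamma = model$gamma, l = model$l,
              feature_scale = model$feature_scale %||% 1,
              bias = model$bias, alpha = model$alpha,
              band_names = model$band_names,
              support_vectors = apply(model$support_vectors, 1, identity,
                                      simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ocsvm
#' @export
read_ocsvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- obj$support_vectors
  if (is.list(sv)) sv <- do.call(rbind, sv)
  if (is.null(dim(sv))) sv <- matrix(sv, nrow = 1)
  structure(list(
    support_vectors = sv, alpha = obj$alpha, alpha_full = NULL,
    bias = obj$bias, nu = obj$nu, gamma = obj$gamma, l = obj$l,
    feature_scale = obj$feature_scale %||% 1,
    C = 1 / (obj$nu * obj$l), iterations = NA_integer_, gap = NA_real_,
    band_names = obj$band_names
  ), class = "ocsvm")
}
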