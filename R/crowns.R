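#' ISODATA-style unsupervised clustering of scene pixels
#'
#' Iterative self-organizing clustering of pixel spectra: k-means-style
#' reassignment/recentering with empty classes dropped as they arise, so the
#' final class count may be below `n_classes`. Centers are initialized at
#' quantile-spaced positions along the first principal axis of the pixel
#' cloud (the actual pixels nearest those quantiles), which makes the result
#' deterministic for a given image; `seed` is reserved for tie-breaking.
#'
#' @param image A [spectral_image()].
#' @param n_classes Number of spectral classes requested (default 25).
#' @param max_iter Iteration cap.
#' @param tol Stop when the share of pixels changing class drops below this.
#' @param seed Integer seed (tie-breaking only; the default initialization
#'   is deterministic).
#' @return A list `labels` (integer matrix on the image grid), `centers`
#'   (classes x bands), `iterations`, `n_classes` (final count).
#' @export
isodata_cluster <- function(image, n_classes = 25, max_iter = 100,
                            tol = 1e-4, seed = 1L) {
  if (n_classes < 1) abort("`n_classes` must be >= 1.")
  px <- pixel_matrix(image)
  n <- nrow(px)
  k <- min(as.integer(n_classes), n)
  with_seed(seed, {
    # first principal axis via SVD of the centered cloud
    ctr <- colMeans(px)
    sv <- svd(sweep(px, 2, ctr), nu = 0, nv = 1)
    proj <- as.vector(sweep(px, 2, ctr) %*% sv$v[, 1])
    # means spaced evenly along the principal-axis range (covering both
    # extremes, so rare but spectrally distinct classes get a seed; classes
    # that attract no pixels are dropped by the iteration)
    ts <- seq(min(proj), max(proj), length.out = k)
    centers <- sweep(outer(ts, sv$v[, 1]), 2, ctr, `+`)
    labels <- integer(n)
    iterations <- 0L
    repeat {
      iterations <- iterations + 1L
      d2 <- outer(rowSums(px^2), rowSums(centers^2), `+`) -
        2 * tcrossprod(px, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      counts <- tabulate(new_labels, nbins = nrow(centers))
      if (any(counts == 0)) {
        keep <- which(counts > 0)
        warn(sprintf("Dropping %d empty class(es); %d remain.",
                     sum(counts == 0), length(keep)))
        centers <- centers[keep, , drop = FALSE]
        next
      }
      change <- mean(new_labels != labels)
      labels <- new_labels
      centers <- rowsum(px, labels) / counts
      if (change < tol || iterations >= max_iter) break
    }
    list(labels = vector_to_raster(labels, image),
         centers = centers, iterations = iterations,
         n_classes = nrow(centers))
  })
}

#' Select flower-dominated spectral classes
#'
#' A clustering class is flower-positive when the majority of its pixels
#' carry region label `PURE_A` or `MIXED_B` from the joint abundance/angle
#' rule; the returned binary raster is the union of flower-positive classes.
#'
#' @param labels Integer class raster from [isodata_cluster()] (`$labels`).
#' @param maps An `abundance_angle_maps` object from [map_scene()], on the
#'   same grid.
#' @param majority Share of flower-region pixels required (default 0.5,
#'   strict majority).
#' @return Logical flower raster; all-`FALSE` when no class qualifies.
#' @export
select_flower_classes <- function(labels, maps, majority = 0.5) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  if (!all(dim(labels) == dim(maps$region))) {
    abort("Class raster and region maps are not aligned.")
  }
  flowerish <- maps$region %in% c("PURE_A", "MIXED_B")
  share <- tapply(as.vector(flowerish), as.vector(labels), mean)
  positive <- as.integer(names(share))[share > majority]
  matrix(labels %in% positive, nrow = nrow(labels))
}

# 8-connected component labeling of a logical matrix via union-find.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(matrix(0L, nr, nc))
  uf <- uf_make(length(idx))
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  # union each foreground pixel with its already-visited 8-neighbours
  offsets <- list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
  for (o in offsets) {
    nrw <- rows + o[1]; ncl <- cols + o[2]
    ok <- nrw >= 1L & nrw <= nr & ncl >= 1L & ncl <= nc
    nidx <- (ncl[ok] - 1L) * nr + nrw[ok]
    has <- pos[nidx] > 0L
    a <- which(ok)[has]; b <- pos[nidx[has]]
    for (t in seq_along(a)) uf_union(uf, a[t], b[t])
  }
  comp <- uf_groups(uf)
  out <- matrix(0L, nr, nc)
  out[idx] <- comp
  out
}

#' Extract crown centroids from a binary flower raster
#'
#' One centroid per 8-connected component of the flower raster; the
#' centroid is the unweighted mean of the member pixels' center map
#' coordinates.
#'
#' @param flower Logical flower raster.
#' @param image The [spectral_image()] supplying the geotransform (or any
#'   object with `origin`/`pixel_size`).
#' @param fraction Optional flower-abundance matrix used to attach each
#'   centroid's `mean_fraction`.
#' @return A tibble: `id`, `x`, `y`, `n_pixels`, `mean_fraction`.
#' @export
extract_centroids <- function(flower, image, fraction = NULL) {
  comp <- label_components(flower)
  if (all(comp == 0L)) {
    return(tibble(id = integer(), x = numeric(), y = numeric(),
                  n_pixels = integer(), mean_fraction = numeric()))
  }
  idx <- which(comp > 0L)
  rows <- ((idx - 1L) %% nrow(comp)) + 1L
  cols <- ((idx - 1L) %/% nrow(comp)) + 1L
  xy <- pixel_centers(image, rows, cols)
  grp <- comp[idx]
  n <- tabulate(grp)
  fr <- if (is.null(fraction)) rep(NA_real_, length(idx)) else fraction[idx]
  tibble(id = seq_len(max(grp)),
         x = as.vector(tapply(xy[, 1], grp, mean)),
         y = as.vector(tapply(xy[, 2], grp, mean)),
         n_pixels = n,
         mean_fraction = as.vector(tapply(fr, grp, mean)))
}

#' Consolidate centroids into crowns by buffer merge
#'
#' Centroids closer than `radius` are considered fragments of a single tree
#' crown: groups are formed by the transitive closure of the pairwise
#' "within radius" relation (union-find) and each group is replaced by its
#' `n_pixels`-weighted mean position. The merge is iterated to a fixed
#' point, so the returned crowns are pairwise farther apart than `radius`
#' and the operation is idempotent. An audit log records which raw
#' centroids merged into which crown, replacing manual visual inspection
#' with a reviewable automatic rule.
#'
#' @param centroids Tibble from [extract_centroids()] (columns `id`, `x`,
#'   `y`, `n_pixels`; `mean_fraction` optional).
#' @param radius Merge radius in meters (default 5.0).
#' @param date Optional date tag carried on the result.
#' @return A `crown_set` tibble (`id`, `x`, `y`, `n_pixels`,
#'   `mean_fraction`) with attributes `merge_log` (tibble raw id ->
#'   crown id), `radius`, `date`.
#' @examples
#' pts <- tibble::tibble(id = 1:3, x = c(0, 4, 8), y = 0, n_pixels = 1,
#'                       mean_fraction = 1)
#' buffer_merge(pts, radius = 5)  # one crown: chain merged transitively
#' @export
buffer_merge <- function(centroids, radius = 5.0, date = NULL) {
  stopifnot_scalar_number(radius, "radius", min = 0)
  cent <- as_tibble(centroids)
  if (!"n_pixels" %in% names(cent)) cent$n_pixels <- 1L
  if (!"mean_fraction" %in% names(cent)) cent$mean_fraction <- NA_real_
  n <- nrow(cent)
  if (n == 0) {
    out <- tibble(id = integer(), x = numeric(), y = numeric(),
                  n_pixels = integer(), mean_fraction = numeric())
    return(new_crown_set(out, merge_log = tibble(raw_id = integer(),
                                                 crown_id = integer()),
                         radius = radius, date = date))
  }
  group <- seq_len(n)
  repeat {
    pos <- cent |>
      mutate(.group = group) |>
      group_by(.data$.group) |>
      summarise(x = sum(.data$x * .data$n_pixels) / sum(.data$n_pixels),
                y = sum(.data$y * .data$n_pixels) / sum(.data$n_pixels),
                .groups = "drop")
    m <- nrow(pos)
    if (m == 1) break
    uf <- uf_make(m)
    d <- as.matrix(stats::dist(pos[, c("x", "y")]))
    pairs <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    if (nrow(pairs) == 0) break
    for (t in seq_len(nrow(pairs))) uf_union(uf, pairs[t, 1], pairs[t, 2])
    g2 <- uf_groups(uf)
    group <- g2[match(group, pos$.group)]
  }
  crowns <- cent |>
    mutate(.group = group) |>
    group_by(.data$.group) |>
    summarise(
      x = sum(.data$x * .data$n_pixels) / sum(.data$n_pixels),
      y = sum(.data$y * .data$n_pixels) / sum(.data$n_pixels),
      mean_fraction = if (all(is.na(.data$mean_fraction))) NA_real_ else {
        stats::weighted.mean(.data$mean_fraction, .data$n_pixels,
                             na.rm = TRUE)
      },
      n_pixels = as.integer(sum(.data$n_pixels)),
      .groups = "drop") |>
    arrange(.data$.group)
  crown_ids <- seq_len(nrow(crowns))
  log <- tibble(raw_id = cent$id,
                crown_id = crown_ids[match(group, crowns$.group)])
  out <- crowns |>
    mutate(id = crown_ids) |>
    select("id", "x", "y", "n_pixels", "mean_fraction")
  new_crown_set(out, merge_log = log, radius = radius, date = date)
}

new_crown_set <- function(tbl, merge_log, radius, date) {
  structure(tbl,
            merge_log = merge_log, radius = radius, date = date,
            class = c("crown_set", class(tbl)))
}

#' @export
print.crown_set <- function(x, ...) {
  cat(sprintf("<crown_set>%s %d crown(s), merge radius %.1f m\n",
              if (is.null(attr(x, "date"))) "" else
                paste0(" [", attr(x, "date"), "]"),
              nrow(x), attr(x, "radius") %||% NA_real_))
  NextMethod()
}

#' Write a crown set as CSV and GeoJSON
#'
#' @param crowns A `crown_set` (or centroid tibble with `x`, `y`).
#' @param dir Output directory.
#' @param stem File name stem.
#' @return The directory, invisibly.
#' @export
write_crown_set <- function(crowns, dir, stem = "crowns") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(crowns),
                   file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
  write_points_geojson(as.data.frame(crowns),
                       file.path(dir, paste0(stem, ".geojson")))
  log <- attr(crowns, "merge_log")
  if (!is.null(log)) {
    utils::write.csv(log, file.path(dir, paste0(stem, "_merge_log.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
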