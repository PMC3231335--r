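make_1band_image <- function(values_matrix, pixel_size = 2.4) {
  spectral_image(array(values_matrix, dim = c(dim(values_matrix), 1)),
                 origin = c(0, nrow(values_matrix) * pixel_size),
                 pixel_size = pixel_size, band_names = "b1")
}

test_that("clustering separates well-separated values into their means", {
  img <- make_1band_image(matrix(c(0, 0, 0, 10, 10, 10) / 10, nrow = 2))
  cl <- isodata_cluster(img, n_classes = 2)
  expect_identical(cl$n_classes, 2L)
  expect_setequal(round(as.vector(cl$centers), 6), c(0, 1))
  # one class per value level
  expect_identical(length(unique(cl$labels[img$values[, , 1] == 0])), 1L)
  expect_identical(length(unique(cl$labels[img$values[, , 1] == 1])), 1L)

  cl1 <- isodata_cluster(img, n_classes = 1)
  expect_identical(cl1$n_classes, 1L)
  expect_equal(as.vector(cl1$centers), mean(img$values), tolerance = 1e-12)
})

test_that("clustering is deterministic for a fixed seed", {
  sc <- generate_scene(scene_params(width = 48, height = 48, n_crowns = 4,
                                    seed = 14L))
  a <- suppressWarnings(isodata_cluster(sc$image, 10, seed = 1L))
  b <- suppressWarnings(isodata_cluster(sc$image, 10, seed = 1L))
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})

test_that("flower-positive classes are selected by region majority", {
  # build a 2-class label raster and a region raster where class 2 is pure
  labels <- matrix(c(1, 1, 1, 2, 2, 2), nrow = 2)
  region <- matrix(c("BACKGROUND", "BACKGROUND", "BACKGROUND",
                     "PURE_A", "PURE_A", "BACKGROUND"), nrow = 2)
  maps <- structure(list(region = region), class = "abundance_angle_maps")
  flower <- select_flower_classes(labels, maps)
  expect_identical(flower, labels == 2)

  # no qualifying class: empty raster, not an error
  region0 <- matrix("BACKGROUND", 2, 3)
  maps0 <- structure(list(region = region0), class = "abundance_angle_maps")
  expect_true(!any(select_flower_classes(labels, maps0)))
})

test_that("on a synthetic scene the flower raster covers the truth pure pixels", {
  sc <- generate_scene(scene_params(width = 144, height = 144, n_crowns = 20,
                                    seed = 15L))
  res <- suppressWarnings(run_detection(sc$image, run_config(seed = 15L)))
  pure_truth <- sc$fractions > 0.85
  flower <- select_flower_classes(res$clusters, res$maps)
  expect_gte(mean(flower[pure_truth]), 0.95)
})

test_that("centroids come from 8-connected components at pixel centers", {
  m <- matrix(FALSE, 9, 9)
  m[4:6, 4:6] <- TRUE                      # 3x3 block
  img <- make_1band_image(matrix(0, 9, 9))
  cen <- extract_centroids(m, img)
  expect_identical(nrow(cen), 1L)
  expect_equal(cen$x, (5 - 0.5) * 2.4)     # block centre = pixel (5,5)
  expect_equal(cen$y, 9 * 2.4 - (5 - 0.5) * 2.4)
  expect_identical(cen$n_pixels, 9L)

  # two diagonal-touching pixels are ONE component under 8-connectivity
  m2 <- matrix(FALSE, 4, 4)
  m2[1, 1] <- TRUE; m2[2, 2] <- TRUE
  img2 <- make_1band_image(matrix(0, 4, 4))
  expect_identical(nrow(extract_centroids(m2, img2)), 1L)

  # two separated blobs -> two centroids; empty raster -> none
  m3 <- matrix(FALSE, 8, 8)
  m3[1:2, 1:2] <- TRUE; m3[6:7, 6:7] <- TRUE
  img3 <- make_1band_image(matrix(0, 8, 8))
  expect_identical(nrow(extract_centroids(m3, img3)), 2L)
  expect_identical(nrow(extract_centroids(matrix(FALSE, 3, 3), img2)), 0L)
})

test_that("buffer merge follows the transitive-closure rule", {
  pts <- tibble::tibble(id = 1:2, x = c(0, 3), y = c(0, 0), n_pixels = 1L)
  merged <- buffer_merge(pts, radius = 5)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$x, 1.5)

  apart <- tibble::tibble(id = 1:2, x = c(0, 10), y = c(0, 0), n_pixels = 1L)
  expect_identical(nrow(buffer_merge(apart, radius = 5)), 2L)

  chain <- tibble::tibble(id = 1:3, x = c(0, 4, 8), y = 0, n_pixels = 1L)
  m <- buffer_merge(chain, radius = 5)
  expect_identical(nrow(m), 1L)          # 0 and 8 joined through 4
  expect_equal(m$x, 4)
  expect_identical(sort(attr(m, "merge_log")$raw_id), 1:3)
})

test_that("merged positions are n_pixels-weighted means", {
  pts <- tibble::tibble(id = 1:2, x = c(0, 3), y = c(0, 0),
                        n_pixels = c(3L, 1L))
  m <- buffer_merge(pts, radius = 5)
  expect_equal(m$x, 0.75)
  expect_identical(m$n_pixels, 4L)
})

test_that("buffer merge is idempotent and enforces minimum spacing", {
  withr::with_seed(97, {
    for (rep in 1:10) {
      n <- sample(5:25, 1)
      pts <- tibble::tibble(id = seq_len(n),
                            x = stats::runif(n, 0, 60),
                            y = stats::runif(n, 0, 60),
                            n_pixels = sample(1:9, n, replace = TRUE))
      m1 <- buffer_merge(pts, radius = 5)
      if (nrow(m1) > 1) {
        expect_gt(min(stats::dist(m1[, c("x", "y")])), 5)
      }
      m2 <- buffer_merge(m1, radius = 5)
      expect_equal(nrow(m2), nrow(m1))
      expect_equal(m2$x, m1$x, tolerance = 1e-12)
      expect_equal(m2$y, m1$y, tolerance = 1e-12)
    }
  })
})

test_that("crown count is non-increasing in the merge radius", {
  withr::with_seed(57, {
    pts <- tibble::tibble(id = 1:30, x = stats::runif(30, 0, 100),
                          y = stats::runif(30, 0, 100), n_pixels = 1L)
    radii <- c(0, 2, 5, 10, 20, 50)
    counts <- vapply(radii, function(r) nrow(buffer_merge(pts, r)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
    expect_identical(counts[1], 30L)     # radius 0 merges nothing distinct
  })
})
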