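test_that("crown matching handles the elementary cases", {
  a <- tibble::tibble(id = 1L, x = 0, y = 0)
  b <- tibble::tibble(id = 1L, x = 1, y = 0)
  r <- match_crowns(a, b, tolerance = 5)
  expect_identical(nrow(r$common), 1L)
  expect_identical(length(r$lost), 0L)
  expect_identical(length(r$new), 0L)

  b2 <- tibble::tibble(id = 1L, x = 20, y = 0)
  r2 <- match_crowns(a, b2, tolerance = 5)
  expect_identical(nrow(r2$common), 0L)
  expect_identical(r2$lost, 1L)
  expect_identical(r2$new, 1L)

  # equidistant competitor: exactly one match regardless of tie branch
  a3 <- tibble::tibble(id = 1:2, x = c(0, 6), y = 0)
  b3 <- tibble::tibble(id = 1L, x = 3, y = 0)
  r3 <- match_crowns(a3, b3, tolerance = 5)
  expect_identical(nrow(r3$common), 1L)
  expect_identical(length(r3$lost), 1L)
  expect_identical(length(r3$new), 0L)
})

test_that("change reports reconcile their counts", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      a <- spread_points(sample(3:10, 1), extent = 100, min_sep = 15)
      b <- spread_points(sample(3:10, 1), extent = 100, min_sep = 15)
      r <- match_crowns(a, b, tolerance = 5)
      expect_identical(r$n_date1, nrow(r$common) + length(r$lost))
      expect_identical(r$n_date2, nrow(r$common) + length(r$new))
      expect_lte(nrow(r$common), min(r$n_date1, r$n_date2))
      expect_true(all(r$common$distance <= 5))
      expect_identical(anyDuplicated(r$common$id_a), 0L)
      expect_identical(anyDuplicated(r$common$id_b), 0L)
    }
  })
})

test_that("matching is symmetric in cardinality", {
  withr::with_seed(83, {
    for (rep in 1:10) {
      a <- spread_points(6, extent = 80, min_sep = 12)
      b <- dplyr::mutate(a[sample(6, 4), ],
                         x = x + stats::rnorm(4, 0, 1),
                         y = y + stats::rnorm(4, 0, 1))
      b <- dplyr::bind_rows(b, spread_points(2, extent = 80, min_sep = 12) |>
                              dplyr::mutate(id = id + 100L))
      fwd <- match_crowns(a, b, tolerance = 5)
      rev <- match_crowns(b, a, tolerance = 5)
      expect_identical(nrow(fwd$common), nrow(rev$common))
      expect_setequal(fwd$lost, rev$new)
      expect_setequal(fwd$new, rev$lost)
    }
  })
})

test_that("greedy matching agrees with the exhaustive oracle on small sets", {
  withr::with_seed(59, {
    for (rep in 1:20) {
      na <- sample(2:8, 1); nb <- sample(2:8, 1)
      a <- spread_points(na, extent = 90, min_sep = 12)
      # b: jittered copies of some of a plus fresh points, post-merge style
      take <- sample(na, min(nb, na))
      b <- dplyr::mutate(a[take, ],
                         x = x + stats::rnorm(length(take), 0, 1.5),
                         y = y + stats::rnorm(length(take), 0, 1.5))
      extra <- nb - length(take)
      if (extra > 0) {
        b <- dplyr::bind_rows(
          b, spread_points(extra, extent = 90, min_sep = 12) |>
            dplyr::mutate(id = id + 100L))
      }
      r <- match_crowns(a, b, tolerance = 5)
      oracle <- brute_match_oracle(a, b, tol = 5)
      expect_identical(nrow(r$common), oracle$n)
      expect_equal(sum(r$common$distance), oracle$total, tolerance = 1e-9)
    }
  })
})

test_that("tidy and glance views of a change report are consistent", {
  a <- tibble::tibble(id = 1:3, x = c(0, 20, 40), y = 0)
  b <- tibble::tibble(id = 1:3, x = c(1, 21, 80), y = 0)
  r <- match_crowns(a, b, tolerance = 5)
  td <- tidy(r)
  expect_identical(sum(td$status == "common"), 2L)
  expect_identical(sum(td$status == "lost"), 1L)
  expect_identical(sum(td$status == "new"), 1L)
  g <- glance(r)
  expect_identical(g$n_common, 2L)
  expect_identical(g$n_date1, 3L)
})

test_that("the aerial-photo table reproduces the reference match rates", {
  tab <- aerial_photo_counts()
  expect_identical(nrow(tab), 18L)
  expect_identical(sum(tab$detected_2002), 96L)
  expect_identical(sum(tab$matched_2002), 84L)
  expect_identical(match_rate(tab, "2002"), 88L)
  # the second acquisition's rate from the same column sums
  expect_identical(sum(tab$detected_2004), 143L)
  expect_identical(sum(tab$matched_2004), 97L)
  expect_identical(match_rate(tab, "2004"), 68L)
})

test_that("match_rate handles degenerate tables", {
  one <- tibble::tibble(detected_2002 = 5, matched_2002 = 5)
  expect_identical(match_rate(one, "2002"), 100L)
  zero <- tibble::tibble(detected_2002 = c(3, 4), matched_2002 = c(0, 0))
  expect_identical(match_rate(zero, "2002"), 0L)
  none <- tibble::tibble(detected_2002 = 0, matched_2002 = 0)
  expect_error(match_rate(none, "2002"), "undefined")
  expect_error(match_rate(one, "2004"), "lacks")
})
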