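#' Match crown centroids across two acquisition dates
#'
#' Greedy nearest-pair one-to-one matching: the globally closest unmatched
#' cross-date pair within `tolerance` is matched repeatedly until none
#' remains (ties broken by id order). Matched pairs are crowns common to
#' both dates and assumed to be the same trees; unmatched date-1 crowns are
#' "lost" (fallen, died, or not reproducing on date 2) and unmatched
#' date-2 crowns are "new" (newly reproductive individuals).
#'
#' @param a,b `crown_set`s (or tibbles with `id`, `x`, `y`) for date 1 and
#'   date 2, in the same projected coordinate system.
#' @param tolerance Maximum centroid distance (meters) for two crowns to be
#'   the same tree; defaults to the 5 m crown-scale buffer radius.
#' @return A `change_report` list: `common` (tibble `id_a`, `id_b`,
#'   `distance`), `lost` / `new` (id vectors), counts `n_date1`, `n_date2`,
#'   and `tolerance`.
#' @examples
#' a <- tibble::tibble(id = 1:2, x = c(0, 20), y = 0)
#' b <- tibble::tibble(id = 1L, x = 1, y = 0)
#' match_crowns(a, b, tolerance = 5)
#' @export
match_crowns <- function(a, b, tolerance = 5.0) {
  stopifnot_scalar_number(tolerance, "tolerance", min = 0)
  crs_a <- attr(a, "crs"); crs_b <- attr(b, "crs")
  if (!is.null(crs_a) && !is.null(crs_b) && !identical(crs_a, crs_b)) {
    abort("Crown sets are in different coordinate reference systems.")
  }
  a <- as_tibble(a); b <- as_tibble(b)
  na <- nrow(a); nb <- nrow(b)
  pairs <- NULL
  if (na > 0 && nb > 0) {
    d <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2)
    cand <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- tibble(i = cand[, 1], j = cand[, 2], distance = d[cand],
                     ord_a = a$id[cand[, 1]], ord_b = b$id[cand[, 2]]) |>
        arrange(.data$distance, .data$ord_a, .data$ord_b)
      used_a <- logical(na); used_b <- logical(nb)
      keep <- logical(nrow(cand))
      for (t in seq_len(nrow(cand))) {
        i <- cand$i[t]; j <- cand$j[t]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE; keep[t] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- tibble(id_a = a$id[cand$i], id_b = b$id[cand$j],
                      distance = cand$distance)
    }
  }
  if (is.null(pairs)) {
    pairs <- tibble(id_a = integer(), id_b = integer(), distance = numeric())
  }
  structure(list(
    common = pairs,
    lost = setdiff(a$id, pairs$id_a),
    new = setdiff(b$id, pairs$id_b),
    n_date1 = na, n_date2 = nb,
    tolerance = tolerance
  ), class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf(
    "<change_report> date1: %d, date2: %d crowns | common %d, lost %d, new %d (tolerance %.1f m)\n",
    x$n_date1, x$n_date2, nrow(x$common), length(x$lost), length(x$new),
    x$tolerance))
  invisible(x)
}

#' Tidy a change report into one row per crown
#'
#' @param x A `change_report`.
#' @param ... Unused.
#' @return A tibble with `date`, `id`, `status` (`common`/`lost`/`new`) and
#'   for common crowns the matched id and distance.
#' @method tidy change_report
#' @export
tidy.change_report <- function(x, ...) {
  bind_rows(
    tibble(date = 1L, id = x$common$id_a, status = "common",
           matched_id = x$common$id_b, distance = x$common$distance),
    tibble(date = 1L, id = x$lost, status = "lost",
           matched_id = NA_integer_, distance = NA_real_),
    tibble(date = 2L, id = x$new, status = "new",
           matched_id = NA_integer_, distance = NA_real_)
  )
}

#' @rdname tidy.change_report
#' @method glance change_report
#' @export
glance.change_report <- function(x, ...) {
  tibble(n_date1 = x$n_date1, n_date2 = x$n_date2,
         n_common = nrow(x$common), n_lost = length(x$lost),
         n_new = length(x$new), tolerance = x$tolerance)
}

#' Write a change report as CSV + JSON summary
#'
#' @param report A `change_report`.
#' @param dir Output directory.
#' @param stem File name stem.
#' @return The directory, invisibly.
#' @export
write_change_report <- function(report, dir, stem = "change") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tidy(report), file.path(dir, paste0(stem, "_crowns.csv")),
                   row.names = FALSE)
  jsonlite::write_json(as.list(glance(report)),
                       file.path(dir, paste0(stem, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Aerial-photo comparison counts
#'
#' Per-photo counts of flowering crowns detected in the two satellite
#' acquisitions and in reference aerial photography, with the number of
#' individuals matched between each acquisition and the reference. Columns
#' `nonflowering_2002` / `nonflowering_2004` hold the parenthetical counts
#' of trees that flowered in the satellite year but not in the reference
#' year; they are retained for completeness and excluded from
#' [match_rate()].
#'
#' @return A tibble with one row per reference photo.
#' @export
aerial_photo_counts <- function() {
  path <- system.file("extdata", "aerial_photo_counts.csv",
                      package = "phenocrown", mustWork = TRUE)
  as_tibble(utils::read.csv(path))
}

#' Detection match rate against a reference survey
#'
#' The percentage of crowns detected in one acquisition that were also
#' found in the reference survey: `100 * sum(matched) / sum(detected)`,
#' rounded half-up to the nearest integer.
#'
#' @param table A match table as returned by [aerial_photo_counts()]:
#'   needs columns `detected_<date>` and `matched_<date>`.
#' @param date Which acquisition to score (e.g. `"2002"` or `"2004"`).
#' @return Integer percentage.
#' @examples
#' match_rate(aerial_photo_counts(), "2002")
#' @export
match_rate <- function(table, date) {
  det_col <- paste0("detected_", date)
  mat_col <- paste0("matched_", date)
  if (!all(c(det_col, mat_col) %in% names(table))) {
    abort(sprintf("Table lacks `%s`/`%s` columns.", det_col, mat_col))
  }
  detected <- sum(table[[det_col]])
  matched <- sum(table[[mat_col]])
  if (detected == 0) abort("Zero crowns detected; match rate undefined.")
  as.integer(round_half_up(100 * matched / detected))
}
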