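#' Pipeline run configuration
#'
#' Every tunable of the detection pipeline with its operational default:
#' the one-class SVM trade-off `nu = 0.1` and RBF width `gamma = 0.1`
#' (scene-dependent; 7.5 was appropriate for one of the original
#' acquisitions), the region thresholds (`F > 0.80` pure; `0.25 < F <= 0.80`
#' with `theta < 0.05` rad mixed), 25 ISODATA classes, the 5 m crown buffer
#' merge radius and the 5 m bi-temporal match tolerance, and the 0.2%
#' training-pixel flower-likeness quantile. `gamma2` optionally overrides the
#' RBF width for the second date of a two-date run.
#'
#' @param nu,gamma One-class SVM parameters.
#' @param gamma2 RBF width for date 2 (defaults to `gamma`).
#' @param fraction_pure,fraction_mixed_low,angle_max Region thresholds,
#'   see [region_thresholds()].
#' @param n_classes ISODATA class count.
#' @param merge_radius Crown buffer merge radius, meters.
#' @param match_tolerance Bi-temporal centroid match tolerance, meters.
#' @param train_quantile Share of top flower-likeness pixels used as
#'   one-class training spectra (see [select_training_pixels()]).
#' @param feature_scale Reflectance multiplier for the OCSVM kernel
#'   features (default 100: percent reflectance, the scale on which
#'   `gamma = 0.1` is a useful RBF width; see [fit_ocsvm()]).
#' @param majority Flower-class majority share, see
#'   [select_flower_classes()].
#' @param seed Integer seed for the (few) stochastic stages.
#' @param endmembers Background [endmember_library()]; its flower spectrum
#'   is replaced by the image-derived endmember at run time.
#' @return A `run_config` list.
#' @export
run_config <- function(nu = 0.1, gamma = 0.1, gamma2 = gamma,
                       fraction_pure = 0.80, fraction_mixed_low = 0.25,
                       angle_max = 0.05, n_classes = 25,
                       merge_radius = 5.0, match_tolerance = 5.0,
                       train_quantile = 0.002, majority = 0.5,
                       feature_scale = 100, seed = 1L,
                       endmembers = default_endmembers()) {
  thresholds <- region_thresholds(fraction_pure, fraction_mixed_low,
                                  angle_max)
  stopifnot_scalar_number(merge_radius, "merge_radius", min = 0)
  stopifnot_scalar_number(match_tolerance, "match_tolerance", min = 0)
  structure(list(nu = nu, gamma = gamma, gamma2 = gamma2,
                 thresholds = thresholds, n_classes = n_classes,
                 merge_radius = merge_radius,
                 match_tolerance = match_tolerance,
                 train_quantile = train_quantile, majority = majority,
                 feature_scale = feature_scale,
                 seed = as.integer(seed), endmembers = endmembers),
            class = "run_config")
}

#' Run the single-date crown detection pipeline
#'
#' Executes the full chain on one reflectance image: select bright training
#' pixels, fit the one-class SVM, derive the flower endmember from the pure
#' pixel mask, map per-pixel abundance/angle and region labels, cluster the
#' scene (ISODATA), select flower-dominated classes, extract component
#' centroids, and consolidate them with the buffer merge.
#'
#' @param image A [spectral_image()].
#' @param config A [run_config()].
#' @param gamma Optional per-date override of the RBF width.
#' @param date Optional date tag for the crown set.
#' @param out_dir Optional directory; when given, intermediate products
#'   (mask, model, maps summary, crowns) are written there.
#' @return A list: `crowns` (a `crown_set`), `maps`, `model`, `endmember`,
#'   `mask`, and `manifest` (config snapshot, seed, stage timings and
#'   pixel-count summaries sufficient to reproduce the run).
#' @export
run_detection <- function(image, config = run_config(), gamma = NULL,
                          date = NULL, out_dir = NULL) {
  gamma <- gamma %||% config$gamma
  stage <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
    stage[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  training <- tick("select_training", select_training_pixels(
    image, quantile = config$train_quantile))
  model <- tick("fit_ocsvm", fit_ocsvm(training, nu = config$nu,
                                       gamma = gamma,
                                       feature_scale = config$feature_scale))
  mask <- tick("classify_pixels", classify_pixels(model, image))
  target <- tick("derive_endmember", derive_endmember(image, mask))
  # Flower-free guard: a derived endmember whose spectral angle to some
  # configured background cover is inside the mixed-region angle threshold
  # is indistinguishable from background — the brightness candidates were
  # background, and the scene holds no flowering crowns.
  bg_rows <- config$endmembers$class != "flower"
  bg_mat <- endmember_matrix(config$endmembers,
                             classes = config$endmembers$class[bg_rows])
  bg_angles <- apply(bg_mat, 2, spectral_angle, target = target)
  if (min(bg_angles) < config$thresholds$angle_max) {
    crowns <- buffer_merge(
      tibble(id = integer(), x = numeric(), y = numeric(),
             n_pixels = integer(), mean_fraction = numeric()),
      radius = config$merge_radius, date = date)
    manifest <- list(
      package_version = as.character(utils::packageVersion("phenocrown")),
      date = date, seed = config$seed, nu = config$nu, gamma = gamma,
      flower_free_scene = TRUE,
      min_background_angle = min(bg_angles),
      n_training = nrow(training), n_pure_mask = sum(mask),
      n_crowns = 0L, stage_seconds = stage)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ocsvm(model, file.path(out_dir, "ocsvm_model.json"))
      write_crown_set(crowns, out_dir)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    return(list(crowns = crowns, maps = NULL, model = model,
                endmember = target, mask = mask, clusters = NULL,
                manifest = manifest))
  }
  maps <- tick("map_scene", map_scene(image, target,
                                      endmembers = config$endmembers,
                                      thresholds = config$thresholds))
  clusters <- tick("isodata", isodata_cluster(image,
                                              n_classes = config$n_classes,
                                              seed = config$seed))
  flower <- tick("select_classes", select_flower_classes(
    clusters, maps, majority = config$majority))
  centroids <- tick("extract_centroids", extract_centroids(
    flower, image, fraction = maps$fraction))
  crowns <- tick("buffer_merge", buffer_merge(
    centroids, radius = config$merge_radius, date = date))
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenocrown")),
    date = date,
    seed = config$seed,
    nu = config$nu, gamma = gamma,
    flower_free_scene = FALSE,
    min_background_angle = min(bg_angles),
    thresholds = unclass(config$thresholds),
    n_classes_requested = config$n_classes,
    n_classes_final = clusters$n_classes,
    merge_radius = config$merge_radius,
    train_quantile = config$train_quantile,
    n_training = nrow(training),
    n_pure_mask = sum(mask),
    region_pixels = stats::setNames(as.list(maps$summary$n_pixels),
                                    maps$summary$region),
    n_raw_centroids = nrow(centroids),
    n_crowns = nrow(crowns),
    stage_seconds = stage
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ocsvm(model, file.path(out_dir, "ocsvm_model.json"))
    write_crown_set(crowns, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(crowns = crowns, maps = maps, model = model, endmember = target,
       mask = mask, clusters = clusters, manifest = manifest)
}

#' Run the two-date detection and change analysis
#'
#' Runs [run_detection()] on each date (a per-date RBF width is allowed,
#' since the kernel scale is scene-dependent) and matches the two crown
#' sets with [match_crowns()].
#'
#' @param image1,image2 [spectral_image()]s on the same grid.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list: `report` (a `change_report`), `detection1`,
#'   `detection2`, and a combined `manifest`.
#' @export
run_two_date <- function(image1, image2, config = run_config(),
                         out_dir = NULL) {
  if (!all(dim(image1) == dim(image2)) ||
      !isTRUE(all.equal(image1$origin, image2$origin)) ||
      image1$pixel_size != image2$pixel_size) {
    abort("The two images are not on the same grid.")
  }
  d1 <- run_detection(image1, config, gamma = config$gamma, date = "date1",
                      out_dir = if (is.null(out_dir)) NULL else
                        file.path(out_dir, "date1"))
  d2 <- run_detection(image2, config, gamma = config$gamma2, date = "date2",
                      out_dir = if (is.null(out_dir)) NULL else
                        file.path(out_dir, "date2"))
  report <- match_crowns(d1$crowns, d2$crowns,
                         tolerance = config$match_tolerance)
  if (!is.null(out_dir)) write_change_report(report, out_dir)
  list(report = report, detection1 = d1, detection2 = d2,
       manifest = list(date1 = d1$manifest, date2 = d2$manifest,
                       match_tolerance = config$match_tolerance,
                       summary = as.list(glance(report))))
}
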