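#' Population summary: lesion counts, proportions and sizes per location
#'
#' Per arm and location at baseline: lesion counts and percentages; pooled
#' counts and percentages; the inter-arm proportion test per location
#' (Pearson chi-square on the location-vs-rest 2 x 2 table, no continuity
#' correction) and the overall r x c test; and size distribution summaries
#' (diameter in mm, volume in cm^3) per location. With a single arm the
#' proportion tests are skipped with a notice.
#'
#' @param dataset A [trial_dataset()].
#'
#' @return List of class `population_report` with `counts`, `pooled`,
#'   `proportion_tests` (NULL for one arm), `overall_p`, `sizes`.
#' @export
report_population <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  m <- dataset$measurements
  base <- m[m$timepoint == "baseline", ]
  if (nrow(base) == 0) {
    abort("No baseline measurements to summarise",
          class = "stratburden_integrity_error")
  }
  arms <- sort(unique(base$arm))
  locs <- unique(base$location)
  locs <- LOCATIONS[LOCATIONS %in% locs]

  counts <- base |>
    dplyr::count(.data$arm, .data$location, name = "n") |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()

  pooled <- base |>
    dplyr::count(.data$location, name = "n") |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 0))

  proportion_tests <- NULL
  overall_p <- NA_real_
  if (length(arms) == 2) {
    tab <- table(factor(base$location, levels = locs),
                 factor(base$arm, levels = arms))
    per_loc_p <- vapply(locs, function(loc) {
      two_by_two <- rbind(tab[loc, ], colSums(tab) - tab[loc, ])
      pearson_chi_square(t(two_by_two))$p
    }, numeric(1))
    proportion_tests <- tibble::tibble(location = locs, p = unname(per_loc_p))
    if (length(locs) >= 2) overall_p <- pearson_chi_square(tab)$p
  } else {
    inform("Single arm: inter-arm proportion tests skipped")
  }

  base$diameter_mm <- response_axis(base, "diameter")
  sizes <- base |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      n = dplyr::n(),
      diameter_median_mm = median(.data$diameter_mm),
      diameter_q1_mm = quantile(.data$diameter_mm, 0.25, names = FALSE),
      diameter_q3_mm = quantile(.data$diameter_mm, 0.75, names = FALSE),
      volume_median_cm3 = if (dataset$metadata$volume_available)
        median(.data$volume_mm3) / 1000 else NA_real_,
      .groups = "drop"
    )

  structure(
    list(counts = counts, pooled = pooled,
         proportion_tests = proportion_tests, overall_p = overall_p,
         sizes = sizes, arms = arms),
    class = "population_report"
  )
}

#' @export
print.population_report <- function(x, ...) {
  cat("<population_report>\n")
  cat("Baseline lesion counts per location:\n")
  print(x$counts, n = Inf)
  if (!is.null(x$proportion_tests)) {
    cat(sprintf("Overall inter-arm proportion test p = %.3g\n", x$overall_p))
  }
  invisible(x)
}

#' Response tables at the three analysis levels
#'
#' Computes, for each requested metric, the RECIST per-patient burden
#' changes, the per-patient per-location stratified changes, and the
#' lesion-level independent changes, together with per-arm/per-location
#' summaries, inter-arm Wilcoxon p-values at each level, and waterfall data
#' (changes sorted in decreasing order).
#'
#' @param dataset A [trial_dataset()].
#' @param metric `"diameter"`, `"volume"` or `"both"`.
#'
#' @return List of class `response_report`, one entry per metric, each with
#'   `recist`, `stratified`, `lesion`, `summaries`, `tests` and
#'   `waterfall`.
#' @export
report_responses <- function(dataset, metric = c("diameter", "volume", "both")) {
  metric <- match.arg(metric)
  metrics <- if (metric == "both") c("diameter", "volume") else metric
  arms <- dataset$metadata$arms

  one_metric <- function(met) {
    recist <- recist_burden_change(dataset, met)
    strat <- stratified_burden_change(dataset, met)
    lesion <- lesion_level_changes(dataset, met)

    tests <- NULL
    if (length(arms) == 2) {
      interarm <- function(r) {
        if (length(unique(r$arm)) < 2) return(NA_real_)
        mann_whitney(r$change[r$arm == arms[1]], r$change[r$arm == arms[2]])
      }
      per_loc <- vapply(split(strat, strat$location), interarm, numeric(1))
      tests <- list(
        recist_p = interarm(recist),
        lesion_p = interarm(lesion),
        stratified_p = tibble::tibble(location = names(per_loc),
                                      p = unname(per_loc))
      )
    }
    list(
      metric = met, recist = recist, stratified = strat, lesion = lesion,
      summaries = location_summaries(lesion), tests = tests,
      waterfall = list(patient = waterfall_data(recist),
                       stratified = waterfall_data(strat))
    )
  }
  structure(setNames(lapply(metrics, one_metric), metrics),
            class = "response_report")
}

#' Weighted-model report for a dataset
#'
#' Fits the count-weighted stratified response model per arm on the
#' lesion-level changes and runs the inter-arm comparison (stratified
#' permutation test plus responder chi-square).
#'
#' @param dataset A [trial_dataset()].
#' @param metric `"diameter"` or `"volume"`.
#' @param n_permutations Permutations for the inter-arm test.
#' @param seed Integer seed recorded in the report.
#'
#' @return List with `model` ([weighted_model()]), `comparison`
#'   ([compare_arms_weighted()]), `metric` and `seed`.
#' @export
report_weighted_model <- function(dataset, metric = c("diameter", "volume"),
                                  n_permutations = 1000, seed = NULL) {
  metric <- match.arg(metric)
  records <- lesion_level_changes(dataset, metric)
  list(
    metric = metric,
    model = weighted_model(records),
    comparison = compare_arms_weighted(records, n_permutations, seed),
    seed = seed
  )
}

#' Sensitivity report for a dataset
#'
#' Runs the outlier-exclusion re-test at the patient and lesion levels and
#' both rebalancing schemes (lesion counts, patient counts per location).
#'
#' @param dataset A [trial_dataset()].
#' @param metric `"diameter"` or `"volume"`.
#' @param n_resamples Resamples for the rebalancing analyses.
#' @param seed Integer seed.
#'
#' @return List of `sensitivity_report` objects: `outliers_patient`,
#'   `outliers_lesion`, `rebalance_lesions`, `rebalance_patients`.
#' @export
report_sensitivity <- function(dataset, metric = c("diameter", "volume"),
                               n_resamples = 1000, seed = NULL) {
  metric <- match.arg(metric)
  lesion <- lesion_level_changes(dataset, metric)
  recist <- recist_burden_change(dataset, metric)
  strat <- stratified_burden_change(dataset, metric)
  list(
    outliers_patient = remove_outliers_and_retest(recist, level = "patient"),
    outliers_lesion = remove_outliers_and_retest(lesion, level = "lesion"),
    rebalance_lesions = rebalance_lesion_counts(lesion, n_resamples, seed),
    rebalance_patients = rebalance_patient_counts(strat, n_resamples, seed)
  )
}

#' Write an analysis artifact with provenance
#'
#' Serialises a report (list or tibble) to JSON or CSV, embedding the seed,
#' a configuration hash and the package version so every artifact is
#' reproducible from its own metadata.
#'
#' @param x A tibble (CSV) or list (JSON).
#' @param path Output file path; the extension picks the format.
#' @param seed Seed used to produce `x`.
#'
#' @return `path`, invisibly.
#' @export
write_artifact <- function(x, path, seed = NULL) {
  meta <- list(
    package = "stratburden",
    version = as.character(utils::packageVersion("stratburden")),
    seed = seed,
    hash = rlang::hash(x)
  )
  if (grepl("\\.csv$", path)) {
    readr::write_csv(tibble::as_tibble(x), path)
    meta_path <- sub("\\.csv$", ".meta.json", path)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(list(meta = meta, result = x), path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}
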