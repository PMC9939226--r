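#' Percent change from baseline
#'
#' @param baseline Baseline size(s); must be strictly positive.
#' @param followup Follow-up size(s); must be non-negative.
#'
#' @return `100 * (followup - baseline) / baseline`, vectorised.
#' @export
#' @examples
#' percent_change(100, 50) # -50
percent_change <- function(baseline, followup) {
  if (any(baseline <= 0)) {
    abort("Percent change undefined for baseline size <= 0",
          class = "stratburden_undefined_change")
  }
  if (any(followup < 0)) {
    abort("Follow-up sizes must be non-negative",
          class = "stratburden_undefined_change")
  }
  100 * (followup - baseline) / baseline
}

# One row per baseline lesion of every patient who attended the follow-up
# visit: baseline and follow-up sizes on the response axis, and the percent
# change. A lesion without a follow-up row (for an attending patient) is a
# disappearance and contributes size 0; patients with no follow-up rows are
# excluded entirely (dropout, not response).
lesion_change_table <- function(dataset, metric, lesion_ids = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (metric == "volume" && !dataset$metadata$volume_available) {
    abort("Volume analyses unavailable: dataset has no volume measurements",
          class = "stratburden_measurement_unavailable")
  }
  m <- dataset$measurements
  base <- m[m$timepoint == "baseline", ]
  fup <- m[m$timepoint == "week12", ]
  attended <- unique(fup$patient_id)
  base <- base[base$patient_id %in% attended, ]
  if (!is.null(lesion_ids)) {
    keep_key <- paste(base$patient_id, base$lesion_id)
    base <- base[keep_key %in% lesion_ids, ]
  }
  if (nrow(base) == 0) {
    return(tibble::tibble(
      patient_id = character(), arm = character(), lesion_id = character(),
      location = character(), metric = character(),
      baseline_size = numeric(), followup_size = numeric(), change = numeric()
    ))
  }

  base$baseline_size <- response_axis(base, metric)
  fup$followup_size <- response_axis(fup, metric)
  out <- dplyr::left_join(
    base[, c("patient_id", "arm", "lesion_id", "location", "baseline_size")],
    fup[, c("patient_id", "lesion_id", "followup_size")],
    by = c("patient_id", "lesion_id")
  )
  out$followup_size[is.na(out$followup_size)] <- 0

  zero_base <- out$baseline_size <= 0
  if (any(zero_base)) {
    warn(sprintf("%d lesion(s) with zero baseline size excluded (undefined change)",
                 sum(zero_base)))
    out <- out[!zero_base, ]
  }
  out$metric <- metric
  out$change <- percent_change(out$baseline_size, out$followup_size)
  out[, c("patient_id", "arm", "lesion_id", "location", "metric",
          "baseline_size", "followup_size", "change")]
}

#' RECIST-style per-patient tumor-burden change
#'
#' For each patient who attended the follow-up visit, sums target-lesion
#' sizes on the response axis at baseline and follow-up and returns the
#' percent change of the sums. Lesions absent at follow-up (disappeared)
#' contribute 0 to the follow-up burden; patients with no follow-up visit
#' are excluded, not imputed.
#'
#' @param dataset A [trial_dataset()].
#' @param metric `"diameter"` or `"volume"`.
#' @param patient_id Optional single patient to compute; errors if that
#'   patient has no baseline targets.
#' @param apply_targets Apply RECIST target selection (at most 5 lesions,
#'   2 per organ) before summing. On datasets that already contain only
#'   cap-compliant target lesions this is the identity.
#'
#' @return Tibble with one row per evaluable patient: `unit_id`, `arm`,
#'   `location = "all"`, `metric`, `baseline_burden`, `followup_burden`,
#'   `change`.
#' @export
recist_burden_change <- function(dataset, metric = c("diameter", "volume"),
                                 patient_id = NULL, apply_targets = TRUE) {
  metric <- match.arg(metric)
  targets <- NULL
  if (apply_targets) {
    base <- dataset$measurements[dataset$measurements$timepoint == "baseline", ]
    targets <- unlist(lapply(split(base, base$patient_id), function(b) {
      paste(b$patient_id[1], select_targets(b, metric = metric))
    }), use.names = FALSE)
  }
  tab <- lesion_change_table(dataset, metric, lesion_ids = targets)
  if (!is.null(patient_id)) {
    tab <- tab[tab$patient_id %in% patient_id, ]
    if (nrow(tab) == 0) {
      abort(paste0("Patient '", patient_id,
                   "' has no evaluable baseline target lesions"),
            class = "stratburden_integrity_error")
    }
  }
  out <- tab |>
    dplyr::group_by(.data$patient_id, .data$arm) |>
    dplyr::summarise(
      baseline_burden = sum(.data$baseline_size),
      followup_burden = sum(.data$followup_size),
      .groups = "drop"
    )
  tibble::tibble(
    unit_id = out$patient_id, arm = out$arm, location = "all", metric = metric,
    baseline_burden = out$baseline_burden, followup_burden = out$followup_burden,
    change = percent_change(out$baseline_burden, out$followup_burden)
  )
}

#' Per-patient per-location stratified burden change
#'
#' As [recist_burden_change()], but lesion sizes are summed within each
#' anatomical location, giving one record per patient x location where the
#' patient has at least one baseline lesion. Locations with no lesions for a
#' patient yield no record (never an imputed 0).
#'
#' @inheritParams recist_burden_change
#' @param location Optional location filter applied to the result.
#'
#' @return Tibble with `unit_id` (`patient/location`), `patient_id`, `arm`,
#'   `location`, `metric`, burdens and `change`.
#' @export
stratified_burden_change <- function(dataset, metric = c("diameter", "volume"),
                                     patient_id = NULL, location = NULL) {
  metric <- match.arg(metric)
  tab <- lesion_change_table(dataset, metric)
  if (!is.null(patient_id)) tab <- tab[tab$patient_id %in% patient_id, ]
  if (!is.null(location)) tab <- tab[tab$location %in% location, ]
  out <- tab |>
    dplyr::group_by(.data$patient_id, .data$arm, .data$location) |>
    dplyr::summarise(
      baseline_burden = sum(.data$baseline_size),
      followup_burden = sum(.data$followup_size),
      .groups = "drop"
    )
  tibble::tibble(
    unit_id = paste(out$patient_id, out$location, sep = "/"),
    patient_id = out$patient_id, arm = out$arm, location = out$location,
    metric = metric,
    baseline_burden = out$baseline_burden, followup_burden = out$followup_burden,
    change = percent_change(out$baseline_burden, out$followup_burden)
  )
}

#' Lesion-level percent changes (lesions treated as independent)
#'
#' One record per lesion evaluable at both timepoints, i.e. per baseline
#' lesion of every patient who attended the follow-up visit. A lesion
#' measured (or recorded absent) as size 0 at follow-up gets -100%.
#'
#' @inheritParams recist_burden_change
#'
#' @return Tibble with `unit_id` (`patient/lesion`), `patient_id`, `arm`,
#'   `lesion_id`, `location`, `metric`, sizes and `change`.
#' @export
lesion_level_changes <- function(dataset, metric = c("diameter", "volume")) {
  metric <- match.arg(metric)
  tab <- lesion_change_table(dataset, metric)
  tibble::tibble(
    unit_id = paste(tab$patient_id, tab$lesion_id, sep = "/"),
    patient_id = tab$patient_id, arm = tab$arm, lesion_id = tab$lesion_id,
    location = tab$location, metric = metric,
    baseline_size = tab$baseline_size, followup_size = tab$followup_size,
    change = tab$change
  )
}

#' Per-arm, per-location response summaries
#'
#' Per arm and location, the number of evaluable lesion-level records and
#' the unweighted arithmetic mean of their percent changes. These are the
#' (count, mean change) pairs the weighted response model consumes.
#'
#' @param records Lesion-level records from [lesion_level_changes()] (or any
#'   tibble with `arm`, `location`, `change`).
#' @param as_location_sums If `TRUE`, report instead the percent change of
#'   per-location summed sizes (alternative estimator; requires
#'   `baseline_size`/`followup_size` columns).
#'
#' @return Tibble with `arm`, `location`, `n`, `mean_change`.
#' @export
location_summaries <- function(records, as_location_sums = FALSE) {
  if (nrow(records) == 0) {
    return(tibble::tibble(arm = character(), location = character(),
                          n = integer(), mean_change = numeric()))
  }
  if (as_location_sums) {
    records |>
      dplyr::group_by(.data$arm, .data$location) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_change = percent_change(sum(.data$baseline_size),
                                     sum(.data$followup_size)),
        .groups = "drop"
      )
  } else {
    records |>
      dplyr::group_by(.data$arm, .data$location) |>
      dplyr::summarise(n = dplyr::n(), mean_change = mean(.data$change),
                       .groups = "drop")
  }
}

#' Association between baseline size and response
#'
#' Spearman rank correlation (two-sided) between baseline lesion size and
#' percent change from baseline, robust to the heavy right tails typical of
#' lesion size distributions. Degenerate inputs (either variable constant
#' after ranking) return `rho = 0`, `p = 1` by convention.
#'
#' @param baseline_size Numeric vector of baseline sizes.
#' @param change Numeric vector of percent changes, same length.
#'
#' @return List with `rho` and `p`.
#' @export
baseline_size_response_association <- function(baseline_size, change) {
  stopifnot(length(baseline_size) == length(change))
  ok <- complete.cases(baseline_size, change)
  x <- baseline_size[ok]; y <- change[ok]
  if (length(x) < 3 || sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    return(list(rho = 0, p = 1))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Waterfall-plot data
#'
#' Per-unit percent changes sorted in decreasing order, the data behind the
#' standard waterfall visualisation of response heterogeneity.
#'
#' @param records Any response-record tibble with `unit_id`, `arm`, `change`
#'   and (optionally) `location`.
#'
#' @return Tibble `unit_id`, `arm`, `location`, `change`, sorted by
#'   decreasing change.
#' @export
waterfall_data <- function(records) {
  loc <- if ("location" %in% names(records)) records$location else "all"
  out <- tibble::tibble(unit_id = records$unit_id, arm = records$arm,
                        location = loc, change = records$change)
  out[order(-out$change, out$unit_id), ]
}
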