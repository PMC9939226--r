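#' Outlier-excluded re-analysis
#'
#' Flags extreme responses with the k x IQR rule on the distribution of
#' percent changes (both arms pooled by default, so "extreme response"
#' rather than "extreme for its arm"), removes them, and re-runs the
#' inter-arm Wilcoxon rank test. Both p-values are reported so conclusions
#' driven by outliers are visible.
#'
#' @param records Response records at any analysis level (patient or
#'   lesion): a tibble with `arm` and `change`.
#' @param level Label for the analysis level, recorded in the report.
#' @param k Fence multiplier for [iqr_outlier_mask()].
#' @param pooled Detect outliers on the pooled distribution (`TRUE`,
#'   default) or within each arm separately.
#'
#' @return List of class `sensitivity_report` with `analysis`, `level`,
#'   `n_outliers_removed`, `p_before`, `p_after`, `removed` (the flagged
#'   records).
#' @export
remove_outliers_and_retest <- function(records, level = "lesion", k = 1.5,
                                       pooled = TRUE) {
  if (nrow(records) == 0) {
    abort("No records to analyse", class = "stratburden_degenerate_analysis")
  }
  arms <- sort(unique(records$arm))
  if (length(arms) != 2) {
    abort("Outlier re-test needs exactly two arms",
          class = "stratburden_degenerate_analysis")
  }
  if (pooled) {
    mask <- iqr_outlier_mask(records$change, k = k)
  } else {
    mask <- logical(nrow(records))
    for (a in arms) {
      i <- which(records$arm == a)
      mask[i] <- iqr_outlier_mask(records$change[i], k = k)
    }
  }
  kept <- records[!mask, ]
  if (nrow(kept) == 0 || length(unique(kept$arm)) < 2) {
    abort("Outlier removal left no testable records",
          class = "stratburden_degenerate_analysis")
  }
  p_of <- function(r) mann_whitney(r$change[r$arm == arms[1]],
                                   r$change[r$arm == arms[2]])
  structure(
    list(analysis = "outlier_exclusion", level = level,
         n_outliers_removed = sum(mask),
         p_before = p_of(records), p_after = p_of(kept),
         removed = records[mask, ]),
    class = "sensitivity_report"
  )
}

# Shared engine for the two rebalancing schemes: repeatedly subsample,
# without replacement, each arm x location cell down to the smaller arm's
# count for that location, then recompute the weighted-response difference
# and the inter-arm Wilcoxon p on the retained units.
rebalance_records <- function(records, analysis, level, n_resamples, seed) {
  if (nrow(records) == 0) {
    abort("No records to analyse", class = "stratburden_degenerate_analysis")
  }
  arms <- sort(unique(records$arm))
  if (length(arms) != 2) {
    abort("Rebalancing needs exactly two arms",
          class = "stratburden_degenerate_analysis")
  }
  counts <- table(records$location, records$arm)
  both <- rownames(counts)[counts[, arms[1]] > 0 & counts[, arms[2]] > 0]
  missing <- setdiff(rownames(counts), both)
  if (length(missing) > 0) {
    warn(paste0("Location(s) absent from one arm dropped from rebalancing: ",
                paste(missing, collapse = ", ")))
  }
  if (length(both) == 0) {
    abort("No location present in both arms",
          class = "stratburden_degenerate_analysis")
  }
  rec <- records[records$location %in% both, ]
  target_n <- setNames(pmin(counts[both, arms[1]], counts[both, arms[2]]), both)

  one_resample <- function() {
    keep <- unlist(lapply(both, function(loc) {
      unlist(lapply(arms, function(a) {
        i <- which(rec$location == loc & rec$arm == a)
        if (length(i) > target_n[loc]) i[sample.int(length(i), target_n[loc])] else i
      }))
    }))
    sub <- rec[keep, ]
    s <- location_summaries(sub)
    diff <- weighted_response(s[s$arm == arms[1], ]) -
      weighted_response(s[s$arm == arms[2], ])
    p <- mann_whitney(sub$change[sub$arm == arms[1]],
                      sub$change[sub$arm == arms[2]])
    c(diff = diff, p = p, n = nrow(sub))
  }
  run <- function() t(vapply(seq_len(n_resamples), function(b) one_resample(),
                             numeric(3)))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  res <- tibble::as_tibble(as.data.frame(res))

  structure(
    list(analysis = analysis, level = level,
         n_resamples = n_resamples, seed = seed,
         locations = both, per_cell_n = as.integer(target_n),
         resamples = res,
         median_p = median(res$p), p_iqr = unname(quantile(res$p, c(0.25, 0.75))),
         median_diff = median(res$diff)),
    class = "sensitivity_report"
  )
}

#' Lesion-count rebalanced re-analysis
#'
#' Adjusts for the imbalance in the number of independent lesions per
#' location between the arms: within each location, the larger arm is
#' randomly subsampled (without replacement) down to the smaller arm's
#' lesion count, and the weighted-response difference and inter-arm
#' Wilcoxon test are recomputed. Repeated over `n_resamples` draws; the
#' p-value distribution is summarised by its median and IQR.
#'
#' @param records Lesion-level records ([lesion_level_changes()]).
#' @param n_resamples Number of random subsamples (default 1000).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A `sensitivity_report` with the per-resample statistics.
#' @export
rebalance_lesion_counts <- function(records, n_resamples = 1000, seed = NULL) {
  rebalance_records(records, "lesion_count_rebalancing", "lesion",
                    n_resamples, seed)
}

#' Patient-count rebalanced re-analysis
#'
#' As [rebalance_lesion_counts()], but the subsampling unit is the
#' patient x location stratified burden record, balancing the number of
#' patients contributing to each location.
#'
#' @param records Stratified burden records ([stratified_burden_change()]).
#' @inheritParams rebalance_lesion_counts
#'
#' @return A `sensitivity_report` with the per-resample statistics.
#' @export
rebalance_patient_counts <- function(records, n_resamples = 1000, seed = NULL) {
  rebalance_records(records, "patient_count_rebalancing", "patient_location",
                    n_resamples, seed)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> ", x$analysis, " (", x$level, " level)\n", sep = "")
  if (x$analysis == "outlier_exclusion") {
    cat(sprintf("  outliers removed: %d\n  p before: %.4g\n  p after:  %.4g\n",
                x$n_outliers_removed, x$p_before, x$p_after))
  } else {
    cat(sprintf("  %d resamples over locations: %s\n", x$n_resamples,
                paste(x$locations, collapse = ", ")))
    cat(sprintf("  median p = %.4g  [IQR %.4g, %.4g]; median difference = %.2f\n",
                x$median_p, x$p_iqr[1], x$p_iqr[2], x$median_diff))
  }
  invisible(x)
}
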