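#' Count-weighted mean of per-location mean responses
#'
#' The stratified response model: given per-location lesion counts `n_i`
#' and mean percent changes `m_i`, the arm-level response is
#' `sum(n_i * m_i) / sum(n_i)` — each location's mean response weighted by
#' the proportion of lesions at that location.
#'
#' @param summaries Tibble with columns `n` (counts, >= 0, summing > 0) and
#'   `mean_change` (%), e.g. from [location_summaries()].
#'
#' @return The weighted response (%), a single number.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   location = c("breast", "lung", "liver", "lymph_node"),
#'   n = c(11, 5, 6, 6),
#'   mean_change = c(-50.19, -29.96, -8.64, -46.15)
#' )
#' weighted_response(s) # -36.8
weighted_response <- function(summaries) {
  n <- summaries$n
  m <- summaries$mean_change
  if (length(n) == 0 || any(n < 0) || sum(n) == 0) {
    abort("weighted_response() needs non-negative counts with a positive sum",
          class = "stratburden_undefined_model")
  }
  sum(n * m) / sum(n)
}

#' Fit the weighted response model per arm
#'
#' Builds per-arm, per-location summaries from lesion-level records and
#' applies [weighted_response()] to each arm.
#'
#' @param records Lesion-level records ([lesion_level_changes()]).
#'
#' @return List of class `weighted_model_result`: per arm, the summaries
#'   used, the weighted response (%), and the total lesion count; plus the
#'   metric analysed.
#' @export
weighted_model <- function(records) {
  if (nrow(records) == 0) {
    abort("No records to model", class = "stratburden_undefined_model")
  }
  summ <- location_summaries(records)
  arms <- sort(unique(summ$arm))
  per_arm <- lapply(arms, function(a) {
    s <- summ[summ$arm == a, ]
    list(arm = a, summaries = s,
         weighted_response = weighted_response(s),
         total_count = sum(s$n))
  })
  names(per_arm) <- arms
  structure(
    list(arms = per_arm,
         metric = if ("metric" %in% names(records)) records$metric[1] else NA),
    class = "weighted_model_result"
  )
}

#' @export
print.weighted_model_result <- function(x, ...) {
  cat("Count-weighted stratified response model (", x$metric, ")\n", sep = "")
  for (a in x$arms) {
    cat(sprintf("  %s: %.1f%%  (n = %d lesions over %d locations)\n",
                a$arm, a$weighted_response, a$total_count, nrow(a$summaries)))
  }
  invisible(x)
}

#' Inter-arm comparison of the weighted responses
#'
#' Tests the difference between the two arms' weighted responses with a
#' permutation test; the two-sided p-value is
#' `(1 + #\{|diff*| >= |diff|\}) / (1 + n_permutations)`.
#'
#' Two permutation schemes are available. `permute = "lesion"` (default)
#' shuffles arm labels within each location, matching the framework in
#' which the weighted model is defined: lesions treated as independent
#' units, location mixture held fixed. `permute = "patient"` re-randomises
#' whole patients between the arms (lesions inherit their patient's label),
#' which respects within-patient correlation of responses but tests the
#' broader null that the arm label is exchangeable at the patient level,
#' location mixture included. With strong patient-level clustering the
#' lesion-level scheme is anticonservative; see the package vignette.
#'
#' A chi-square variant on the 2 x 2 table of responder counts (lesion
#' change <= `responder_cut`, the RECIST partial-response threshold, vs not)
#' is reported alongside.
#'
#' @param records Lesion-level records with exactly two arms.
#' @param n_permutations Number of label permutations (>= 100 recommended).
#' @param seed Optional integer seed; the result is reproducible given
#'   (`seed`, `n_permutations`).
#' @param permute `"lesion"` (stratified within location) or `"patient"`
#'   (cluster permutation; requires a `patient_id` column).
#' @param responder_cut Percent-change threshold defining a responder for
#'   the chi-square variant (default -30).
#'
#' @return List of class `arm_comparison`: `arms`, `difference`
#'   (first arm minus second, in sorted arm order), `p_permutation`,
#'   `p_chisq` (NA if the responder table is degenerate), `permute`,
#'   `n_permutations`, `seed`.
#' @export
compare_arms_weighted <- function(records, n_permutations = 1000, seed = NULL,
                                  permute = c("lesion", "patient"),
                                  responder_cut = -30) {
  permute <- match.arg(permute)
  arms <- sort(unique(records$arm))
  if (length(arms) != 2) {
    abort("compare_arms_weighted() needs exactly two arms",
          class = "stratburden_undefined_model")
  }
  if (n_permutations < 100) {
    warn("Fewer than 100 permutations: the p-value will be coarse")
  }
  common <- intersect(unique(records$location[records$arm == arms[1]]),
                      unique(records$location[records$arm == arms[2]]))
  if (length(common) == 0) {
    abort("Arms share no lesion location", class = "stratburden_undefined_model")
  }
  dropped <- setdiff(unique(records$location), common)
  if (length(dropped) > 0) {
    inform(paste0("Location(s) present in one arm only, excluded from the ",
                  "stratified test: ", paste(dropped, collapse = ", ")))
  }
  rec <- records[records$location %in% common, ]
  # Canonical row order so the Monte-Carlo p-value does not depend on how
  # the caller happened to sort the records.
  ord <- if ("unit_id" %in% names(rec)) {
    order(rec$location, rec$unit_id)
  } else {
    order(rec$location, rec$change, rec$arm)
  }
  rec <- rec[ord, ]

  # With weights equal to the realized lesion counts, the count-weighted
  # mean of per-location means reduces algebraically to the arm's grand
  # mean of lesion changes; the permutation loop uses that identity.
  x <- rec$change
  is_arm1 <- rec$arm == arms[1]
  n1 <- sum(is_arm1); n2 <- sum(!is_arm1)
  total <- sum(x)
  diff_of <- function(arm1_mask) {
    s1 <- sum(x[arm1_mask])
    s1 / n1 - (total - s1) / n2
  }
  observed <- diff_of(is_arm1)

  if (permute == "patient") {
    if (!"patient_id" %in% names(rec)) {
      abort("permute = \"patient\" needs a patient_id column",
            class = "stratburden_undefined_model")
    }
    pat <- unique(rec[, c("patient_id", "arm")])
    pat_rows <- split(seq_along(x), rec$patient_id)[pat$patient_id]
    pat_arm1 <- pat$arm == arms[1]
    perm_one <- function() {
      new_arm1 <- pat_arm1[sample.int(length(pat_arm1))]
      lab <- logical(length(x))
      for (j in which(new_arm1)) lab[pat_rows[[j]]] <- TRUE
      s1 <- sum(x[lab]); m1 <- sum(lab)
      s1 / m1 - (total - s1) / (length(x) - m1)
    }
  } else {
    loc_idx <- split(seq_along(x), rec$location)
    perm_one <- function() {
      lab <- is_arm1
      for (i in loc_idx) lab[i] <- lab[i][sample.int(length(i))]
      diff_of(lab)
    }
  }
  run_perms <- function() vapply(seq_len(n_permutations),
                                 function(b) perm_one(), numeric(1))
  perm <- if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
  p_perm <- (1 + sum(abs(perm) >= abs(observed) - 1e-12)) / (1 + n_permutations)

  responder <- rec$change <= responder_cut
  tab <- table(factor(rec$arm, levels = arms),
               factor(responder, levels = c(FALSE, TRUE)))
  p_chisq <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    NA_real_
  } else {
    pearson_chi_square(tab)$p
  }

  structure(
    list(arms = arms, difference = observed, p_permutation = p_perm,
         p_chisq = p_chisq, responder_cut = responder_cut,
         permute = permute, n_permutations = n_permutations, seed = seed),
    class = "arm_comparison"
  )
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("Weighted-response difference %s - %s: %.2f percentage points\n",
              x$arms[1], x$arms[2], x$difference))
  cat(sprintf("  stratified permutation p = %.4g (%d permutations)\n",
              x$p_permutation, x$n_permutations))
  cat(sprintf("  responder (change <= %g%%) chi-square p = %.4g\n",
              x$responder_cut, x$p_chisq))
  invisible(x)
}
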