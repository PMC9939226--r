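#' Assemble and validate a per-lesion measurement dataset
#'
#' A trial dataset holds one row per target lesion per timepoint, with the
#' three CT measurements used throughout the package: longest axial diameter
#' (LAD, mm), short axial diameter (SAD, mm) and segmented volume (mm^3).
#' Lymph-node lesions are flagged `nodal` and are measured by SAD on the
#' diameter axis, following RECIST 1.1.
#'
#' Validation enforces the structural invariants every analysis relies on:
#' `lad_mm >= sad_mm >= 0`, `volume_mm3 >= 0`, `nodal` if and only if
#' `location == "lymph_node"`, uniqueness of (patient, lesion, timepoint),
#' and baseline coverage (every lesion seen at follow-up must have a baseline
#' row). Volume may be entirely absent, in which case the dataset is marked
#' volume-unavailable and volume analyses refuse to run.
#'
#' @param measurements A data frame with columns `patient_id`, `arm`,
#'   `lesion_id`, `location` (one of breast, lung, liver, lymph_node, other),
#'   `nodal` (logical), `timepoint` (`"baseline"` or `"week12"`), `lad_mm`,
#'   `sad_mm`, and optionally `volume_mm3`.
#' @param provenance Free-text note on where the measurements came from.
#'
#' @return An object of class `trial_dataset`: a list with `measurements`
#'   (tibble) and `metadata` (arms, timepoints, volume availability,
#'   provenance).
#' @export
#' @examples
#' m <- tibble::tibble(
#'   patient_id = "P1", arm = "VC", lesion_id = "L1", location = "lung",
#'   nodal = FALSE, timepoint = c("baseline", "week12"),
#'   lad_mm = c(20, 10), sad_mm = c(12, 6), volume_mm3 = c(4000, 500)
#' )
#' trial_dataset(m)
trial_dataset <- function(measurements, provenance = "") {
  measurements <- tibble::as_tibble(measurements)
  missing_cols <- setdiff(setdiff(MEASUREMENT_COLS, "volume_mm3"),
                          names(measurements))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "stratburden_schema_error"
    )
  }
  volume_available <- "volume_mm3" %in% names(measurements) &&
    any(!is.na(measurements$volume_mm3))
  if (!"volume_mm3" %in% names(measurements)) {
    measurements$volume_mm3 <- NA_real_
  }
  measurements <- measurements[, MEASUREMENT_COLS]
  validate_measurements(measurements)

  structure(
    list(
      measurements = measurements,
      metadata = list(
        arms = sort(unique(measurements$arm)),
        timepoints = TIMEPOINTS,
        volume_available = volume_available,
        provenance = provenance
      )
    ),
    class = "trial_dataset"
  )
}

validate_measurements <- function(m) {
  bad_loc <- setdiff(unique(m$location), LOCATIONS)
  if (length(bad_loc) > 0) {
    abort(paste0("Unknown location(s): ", paste(bad_loc, collapse = ", ")),
          class = "stratburden_schema_error")
  }
  bad_tp <- setdiff(unique(m$timepoint), TIMEPOINTS)
  if (length(bad_tp) > 0) {
    abort(paste0("Unknown timepoint(s): ", paste(bad_tp, collapse = ", ")),
          class = "stratburden_schema_error")
  }
  if (!is.logical(m$nodal) || anyNA(m$nodal)) {
    abort("`nodal` must be TRUE/FALSE with no missing values",
          class = "stratburden_schema_error")
  }
  if (nrow(m) == 0) {
    abort("Dataset contains no measurements", class = "stratburden_integrity_error")
  }

  neg <- which(m$lad_mm < 0 | m$sad_mm < 0 | m$volume_mm3 < 0)
  if (length(neg) > 0) {
    abort(paste0("Negative measurement(s) at row(s): ",
                 paste(head(neg, 5), collapse = ", ")),
          class = "stratburden_integrity_error")
  }
  axis_bad <- which(!is.na(m$lad_mm) & !is.na(m$sad_mm) & m$lad_mm < m$sad_mm)
  if (length(axis_bad) > 0) {
    abort(paste0("LAD < SAD at row(s): ", paste(head(axis_bad, 5), collapse = ", ")),
          class = "stratburden_integrity_error")
  }
  nodal_bad <- which(m$nodal != (m$location == "lymph_node"))
  if (length(nodal_bad) > 0) {
    abort(paste0("`nodal` flag inconsistent with lymph_node location at row(s): ",
                 paste(head(nodal_bad, 5), collapse = ", ")),
          class = "stratburden_integrity_error")
  }

  key <- paste(m$patient_id, m$lesion_id, m$timepoint, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate (patient, lesion, timepoint) record(s): ",
                 paste(head(gsub("\r", "/", dup), 5), collapse = "; ")),
          class = "stratburden_integrity_error")
  }

  lesion_key <- function(tp) {
    rows <- m$timepoint == tp
    paste(m$patient_id[rows], m$lesion_id[rows], sep = "/")
  }
  orphans <- setdiff(lesion_key("week12"), lesion_key("baseline"))
  if (length(orphans) > 0) {
    abort(paste0("Follow-up lesion(s) without a baseline record: ",
                 paste(head(orphans, 5), collapse = "; ")),
          class = "stratburden_integrity_error")
  }
  invisible(m)
}

#' @export
print.trial_dataset <- function(x, ...) {
  m <- x$measurements
  base <- m[m$timepoint == "baseline", ]
  cat("<trial_dataset>\n")
  cat("  arms:      ", paste(x$metadata$arms, collapse = ", "), "\n", sep = "")
  cat("  patients:  ", length(unique(m$patient_id)), "\n", sep = "")
  cat("  lesions:   ", nrow(base), " at baseline, ",
      sum(m$timepoint == "week12"), " at week 12\n", sep = "")
  cat("  volume:    ", if (x$metadata$volume_available) "available" else
    "unavailable (diameter analyses only)", "\n", sep = "")
  invisible(x)
}

#' Read a lesion-measurement table from CSV
#'
#' Expects one row per lesion per timepoint with columns `patient_id`, `arm`,
#' `lesion_id`, `location`, `nodal`, `timepoint`, `lad_mm`, `sad_mm` and
#' optionally `volume_mm3`. Empty cells are missing values; unparseable
#' numeric cells are reported with their row numbers and the read is
#' rejected. A `schema` mapping allows files with different column names.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(lad_mm = "longest_diameter")`. Unmapped columns use canonical names.
#'
#' @return A validated [trial_dataset()].
#' @export
read_measurements <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "stratburden_schema_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  col_map <- setNames(MEASUREMENT_COLS, MEASUREMENT_COLS)
  if (!is.null(schema)) col_map[names(schema)] <- schema

  for (canon in setdiff(MEASUREMENT_COLS, "volume_mm3")) {
    if (!col_map[[canon]] %in% names(raw)) {
      abort(paste0("Column '", col_map[[canon]], "' (", canon, ") not found in ", path),
            class = "stratburden_schema_error")
    }
  }
  get_col <- function(canon) {
    if (col_map[[canon]] %in% names(raw)) raw[[col_map[[canon]]]] else NULL
  }

  parse_num <- function(canon) {
    x <- get_col(canon)
    if (is.null(x)) return(NULL)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("Unparseable numeric value(s) in '", canon, "' at data row(s): ",
                   paste(head(bad, 10), collapse = ", ")),
            class = "stratburden_schema_error")
    }
    out
  }
  parse_lgl <- function(canon) {
    x <- tolower(trimws(get_col(canon)))
    out <- ifelse(x %in% c("true", "t", "1", "yes"), TRUE,
                  ifelse(x %in% c("false", "f", "0", "no"), FALSE, NA))
    bad <- which(is.na(out))
    if (length(bad) > 0) {
      abort(paste0("Unparseable logical value(s) in '", canon, "' at data row(s): ",
                   paste(head(bad, 10), collapse = ", ")),
            class = "stratburden_schema_error")
    }
    out
  }

  m <- tibble::tibble(
    patient_id = as.character(get_col("patient_id")),
    arm        = as.character(get_col("arm")),
    lesion_id  = as.character(get_col("lesion_id")),
    location   = as.character(get_col("location")),
    nodal      = parse_lgl("nodal"),
    timepoint  = as.character(get_col("timepoint")),
    lad_mm     = parse_num("lad_mm"),
    sad_mm     = parse_num("sad_mm")
  )
  vol <- parse_num("volume_mm3")
  if (!is.null(vol)) m$volume_mm3 <- vol
  trial_dataset(m, provenance = path)
}

#' Size of a lesion on its response axis
#'
#' The response axis is the measurement RECIST tracks for the requested
#' metric: the segmented volume for `metric = "volume"`, and for
#' `metric = "diameter"` the short axial diameter for nodal (lymph-node)
#' lesions and the longest axial diameter otherwise.
#'
#' @param lesions A data frame of lesion measurements (rows from a
#'   [trial_dataset()]).
#' @param metric `"diameter"` or `"volume"`.
#'
#' @return Numeric vector of sizes (mm or mm^3), one per row.
#' @export
response_axis <- function(lesions, metric = c("diameter", "volume")) {
  metric <- match.arg(metric)
  if (metric == "volume") {
    out <- lesions$volume_mm3
    if (anyNA(out)) {
      abort("Volume requested but missing for one or more lesions",
            class = "stratburden_measurement_unavailable")
    }
  } else {
    out <- ifelse(lesions$nodal, lesions$sad_mm, lesions$lad_mm)
    if (anyNA(out)) {
      abort("Diameter (LAD/SAD) missing for one or more lesions",
            class = "stratburden_measurement_unavailable")
    }
  }
  out
}

#' Select RECIST target lesions at baseline
#'
#' Applies RECIST 1.1 target-lesion selection to one patient's baseline
#' lesions: eligible lesions (non-nodal with LAD >= `min_lad_mm`, nodal with
#' SAD >= `min_sad_mm`) are taken in decreasing size on the response axis
#' (ties broken by `lesion_id`), keeping at most `max_per_organ` per location
#' and `max_total` overall. The greedy order maximises the summed selected
#' size under the per-organ cap.
#'
#' @param lesions One patient's baseline lesion rows.
#' @param max_total Maximum number of target lesions (default 5).
#' @param max_per_organ Maximum per location (default 2).
#' @param min_lad_mm Eligibility threshold for non-nodal lesions, mm.
#' @param min_sad_mm Eligibility threshold for nodal lesions, mm.
#' @param metric Response axis used to rank candidates.
#'
#' @return Character vector of selected `lesion_id`s (possibly empty).
#' @export
select_targets <- function(lesions, max_total = 5, max_per_organ = 2,
                           min_lad_mm = 10, min_sad_mm = 15,
                           metric = "diameter") {
  if (nrow(lesions) == 0) return(character(0))
  if (length(unique(lesions$patient_id)) > 1) {
    abort("select_targets() expects lesions from a single patient",
          class = "stratburden_schema_error")
  }
  eligible <- ifelse(lesions$nodal,
                     lesions$sad_mm >= min_sad_mm,
                     lesions$lad_mm >= min_lad_mm)
  cand <- lesions[eligible, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  size <- response_axis(cand, metric)
  ord <- order(-size, cand$lesion_id)
  cand <- cand[ord, ]

  taken <- character(0)
  per_organ <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(taken) >= max_total) break
    loc <- cand$location[i]
    n_loc <- per_organ[loc]
    if (is.na(n_loc)) n_loc <- 0L
    if (n_loc < max_per_organ) {
      taken <- c(taken, cand$lesion_id[i])
      per_organ[loc] <- n_loc + 1L
    }
  }
  taken
}

#' Drop under-represented lesion locations
#'
#' Removes, from all timepoints, lesions whose location has fewer than
#' `min_count` lesions at baseline (both arms pooled). Typical use is to
#' exclude miscellaneous sites too rare to stratify on. Each removal is
#' reported with its counts.
#'
#' @param dataset A [trial_dataset()].
#' @param min_count Minimum pooled baseline lesion count for a location to
#'   be retained (default 4).
#'
#' @return A filtered [trial_dataset()]. Warns if nothing survives.
#' @export
filter_major_locations <- function(dataset, min_count = 4) {
  stopifnot(inherits(dataset, "trial_dataset"), min_count >= 1)
  m <- dataset$measurements
  base <- m[m$timepoint == "baseline", ]
  counts <- table(base$location)
  drop <- names(counts)[counts < min_count]
  if (length(drop) > 0) {
    for (loc in drop) {
      inform(sprintf("Excluding location '%s': %d baseline lesion(s) < min_count = %d",
                     loc, counts[[loc]], min_count))
    }
    m <- m[!m$location %in% drop, ]
  }
  if (nrow(m) == 0) {
    warn("All locations fell below min_count; dataset is empty")
    out <- dataset
    out$measurements <- m
    return(out)
  }
  trial_dataset(m, provenance = dataset$metadata$provenance)
}
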