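test_that("percent_change follows the baseline-relative convention", {
  expect_equal(percent_change(100, 50), -50)
  expect_equal(percent_change(20, 20), 0)
  expect_equal(percent_change(10, 0), -100)
  expect_equal(percent_change(c(10, 40), c(5, 50)), c(-50, 25))
  expect_error(percent_change(0, 5), class = "stratburden_undefined_change")
})

test_that("recist_burden_change sums target sizes and tracks the sums", {
  # two lesions halving: (20->10) + (30->15), 50 -> 25
  ds <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "lung", lad = 20, factor = 0.5),
    two_tp("P1", "L2", "liver", lad = 30, factor = 0.5)
  ))
  expect_equal(recist_burden_change(ds, "diameter")$change, -50)

  # one stable, one disappeared: sums 50 -> 20
  ds2 <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "lung", lad = 20, factor = 1),
    two_tp("P1", "L2", "liver", lad = 30, factor = 0)
  ))
  expect_equal(recist_burden_change(ds2, "diameter")$change, -60)

  # single nodal lesion is tracked by SAD: 16 -> 8
  ds3 <- trial_dataset(dplyr::bind_rows(
    mrow("P1", "L1", "lymph_node", "baseline", lad = 20, sad = 16),
    mrow("P1", "L1", "lymph_node", "week12", lad = 10, sad = 8)
  ))
  expect_equal(recist_burden_change(ds3, "diameter")$change, -50)

  # an unknown patient id errors
  expect_error(recist_burden_change(ds, "diameter", patient_id = "nobody"),
               class = "stratburden_integrity_error")
})

test_that("a lesion absent at an attended follow-up counts as disappearance,
           a patient with no follow-up visit is excluded", {
  m <- dplyr::bind_rows(
    two_tp("P1", "L1", "lung", lad = 20, factor = 0.5),
    mrow("P1", "L2", "liver", "baseline", 30),      # no week12 row, P1 attended
    two_tp("P2", "L1", "lung", lad = 25, factor = 0.8),
    mrow("P3", "L1", "breast", "baseline", 40)      # P3 dropped out
  )
  ds <- trial_dataset(m)
  lesions <- lesion_level_changes(ds, "diameter")
  expect_setequal(lesions$unit_id, c("P1/L1", "P1/L2", "P2/L1"))
  expect_equal(lesions$change[lesions$unit_id == "P1/L2"], -100)
  expect_false(any(lesions$patient_id == "P3"))
  # burden for P1: 50 -> 10
  rb <- recist_burden_change(ds, "diameter")
  expect_equal(rb$change[rb$unit_id == "P1"], -80)
  expect_setequal(rb$unit_id, c("P1", "P2"))
})

test_that("stratified_burden_change gives one record per patient x location", {
  ds <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "liver", lad = 20, factor = 0.5),
    two_tp("P1", "L2", "liver", lad = 30, factor = 0.5),
    two_tp("P1", "L3", "lung", lad = 25, factor = 1)
  ))
  s <- stratified_burden_change(ds, "diameter")
  expect_equal(nrow(s), 2)
  expect_equal(s$change[s$location == "liver"], -50)
  expect_equal(s$change[s$location == "lung"], 0)
  expect_false("breast" %in% s$location)  # absence, not zero

  # compensating changes within a location: sums 40 -> 40
  ds2 <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "breast", lad = 10, factor = 1.4),
    two_tp("P1", "L2", "breast", lad = 30, factor = 26 / 30)
  ))
  expect_equal(stratified_burden_change(ds2, "diameter")$change, 0)
})

test_that("lesion_level_changes treats lesions independently", {
  ds <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "lung", lad = 20, factor = 0.5),
    two_tp("P1", "L2", "liver", lad = 30, factor = 0.5),
    two_tp("P2", "L1", "breast", lad = 40, factor = 0.5)
  ))
  expect_equal(lesion_level_changes(ds, "diameter")$change, rep(-50, 3))

  # measured 0 at follow-up in a retained patient
  ds2 <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "lung", lad = 20, factor = 0)
  ))
  expect_equal(lesion_level_changes(ds2, "diameter")$change, -100)
})

test_that("location_summaries averages lesion-level changes per location", {
  rec <- tibble::tibble(arm = "A", location = c("liver", "liver"),
                        change = c(-10, -30))
  s <- location_summaries(rec)
  expect_equal(s$n, 2)
  expect_equal(s$mean_change, -20)
  expect_equal(nrow(location_summaries(rec[0, ])), 0)
})

test_that("lesion changes built to match the published VC means average back
           to them and reproduce the -36.8% weighted response", {
  vc <- tibble::tibble(
    location = c("breast", "lung", "liver", "lymph_node"),
    n = c(11, 5, 6, 6),
    mean = c(-50.19, -29.96, -8.64, -46.15)
  )
  rec <- dplyr::bind_rows(lapply(seq_len(nrow(vc)), function(i) {
    n <- vc$n[i]
    offsets <- seq_len(n) - (n + 1) / 2  # symmetric, mean zero
    tibble::tibble(arm = "VC", location = vc$location[i],
                   change = vc$mean[i] + offsets)
  }))
  s <- location_summaries(rec)
  expect_equal(s$mean_change[match(vc$location, s$location)], vc$mean)
  expect_equal(round(weighted_response(
    dplyr::left_join(vc, s, by = "location")[, c("n.x", "mean_change")] |>
      dplyr::rename(n = "n.x")), 1), -36.8)
})

test_that("baseline size vs response association is rank-based and calibrated", {
  # all changes identical: degenerate, rho 0, p 1
  flat <- baseline_size_response_association(c(10, 20, 30, 40), rep(-20, 4))
  expect_equal(flat$rho, 0)
  expect_equal(flat$p, 1)

  # strictly monotone relation: rho 1
  mono <- baseline_size_response_association(1:20, (1:20)^2 - 50)
  expect_equal(mono$rho, 1)

  # type-I error under independence ~ 5%
  rejections <- withr::with_seed(99, {
    vapply(1:1000, function(r) {
      a <- baseline_size_response_association(rlnorm(200, 3, 0.5),
                                              rnorm(200, -20, 15))
      a$p < 0.05
    }, logical(1))
  })
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("burden additivity, factor-identity, weighted identity and scale
           invariance hold on generated trials", {
  for (seed in c(11, 12, 13)) {
    ds <- random_dataset(seed)
    for (metric in c("diameter", "volume")) {
      rb <- recist_burden_change(ds, metric)
      sb <- stratified_burden_change(ds, metric)

      # additivity: the "all" burden is the sum of per-location burdens
      by_patient <- split(sb, sb$patient_id)
      for (pid in names(by_patient)) {
        expect_equal(sum(by_patient[[pid]]$baseline_burden),
                     rb$baseline_burden[rb$unit_id == pid])
        expect_equal(sum(by_patient[[pid]]$followup_burden),
                     rb$followup_burden[rb$unit_id == pid])
      }

      # weighted identity: stratified changes weighted by baseline burden
      # recover the RECIST burden change
      for (pid in names(by_patient)) {
        p <- by_patient[[pid]]
        expect_equal(sum(p$baseline_burden * p$change) / sum(p$baseline_burden),
                     rb$change[rb$unit_id == pid], tolerance = 1e-9)
      }

      # scale invariance: multiplying all sizes by a constant changes nothing
      scaled <- ds
      scaled$measurements$lad_mm <- 3 * scaled$measurements$lad_mm
      scaled$measurements$sad_mm <- 3 * scaled$measurements$sad_mm
      scaled$measurements$volume_mm3 <- 3 * scaled$measurements$volume_mm3
      expect_equal(lesion_level_changes(scaled, metric)$change,
                   lesion_level_changes(ds, metric)$change)
    }
  }

  # uniform shrinkage factor: every analysis level agrees at 100(f - 1)
  f <- 0.7
  ds <- trial_dataset(dplyr::bind_rows(
    two_tp("P1", "L1", "lung", lad = 20, factor = f),
    two_tp("P1", "L2", "liver", lad = 30, factor = f),
    two_tp("P2", "L1", "breast", lad = 25, factor = f)
  ))
  expect_equal(recist_burden_change(ds, "diameter")$change, rep(100 * (f - 1), 2))
  expect_equal(stratified_burden_change(ds, "diameter")$change,
               rep(100 * (f - 1), 3))
  expect_equal(lesion_level_changes(ds, "diameter")$change,
               rep(100 * (f - 1), 3))
})

test_that("waterfall data is sorted by decreasing change", {
  rec <- tibble::tibble(unit_id = c("a", "b", "c"), arm = "A",
                        location = "all", change = c(-10, 40, -60))
  w <- waterfall_data(rec)
  expect_equal(w$change, c(40, -10, -60))
})
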