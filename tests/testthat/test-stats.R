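test_that("pearson_chi_square reproduces the published per-location
           proportion comparisons without continuity correction", {
  counts <- aslan_baseline_counts()
  rest <- function(loc) {
    with(counts, rbind(c(VC[location == loc], LC[location == loc]),
                       c(sum(VC) - VC[location == loc],
                         sum(LC) - LC[location == loc])))
  }
  expect_equal(round(pearson_chi_square(rest("breast"))$p, 2), 0.16)
  expect_equal(round(pearson_chi_square(rest("lung"))$p, 2), 0.07)
  expect_equal(round(pearson_chi_square(rest("liver"))$p, 1), 0.6)
  # lymph-node proportions are identical across arms: statistic exactly 0
  ln <- pearson_chi_square(rest("lymph_node"))
  expect_equal(ln$statistic, 0)
  expect_equal(ln$p, 1)
})

test_that("chi-square matches the 2x2 closed form and is permutation-invariant", {
  closed_form <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4) {
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expect_equal(pearson_chi_square(m)$statistic, closed_form(a, b, c, d),
                 tolerance = 1e-12)
  }
  m <- matrix(c(12, 22, 11, 40, 3, 9), 3, byrow = TRUE)
  expect_equal(pearson_chi_square(m[c(2, 3, 1), c(2, 1)])$statistic,
               pearson_chi_square(m)$statistic, tolerance = 1e-12)

  # homogeneous table and degenerate margins
  hom <- pearson_chi_square(matrix(10, 2, 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p, 1)
  expect_error(pearson_chi_square(matrix(c(1, 0, 2, 0), 2)),
               class = "stratburden_degenerate_table")
})

test_that("mann_whitney: exact enumeration at small n, approximation close
           to exact beyond it", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(mann_whitney(c(5, 7, 9), c(5, 7, 9)), 1)

  withr::with_seed(31, {
    # exact branch agrees with the enumeration oracle
    for (r in 1:10) {
      x <- round(rnorm(sample(3:6, 1)), 3)
      y <- round(rnorm(sample(3:6, 1), 0.5), 3)
      if (length(c(x, y)) <= 12 && !any(duplicated(c(x, y)))) {
        expect_equal(mann_whitney(x, y), mw_exact_enum(x, y), tolerance = 1e-12)
      }
    }
    # approximation branch close to the enumerated exact p: typically
    # within 0.01, never further than 0.02 at these sample sizes
    errs <- vapply(1:10, function(r) {
      x <- rnorm(7)
      y <- rnorm(6, 0.8)
      abs(mann_whitney(x, y) - mw_exact_enum(x, y))
    }, numeric(1))
    expect_lt(median(errs), 0.01)
    expect_lt(max(errs), 0.02)
  })
})

test_that("tukey_hsd gives honest simultaneous pairwise comparisons", {
  # identical groups: zero difference, p = 1, CI symmetric about 0
  tk <- tukey_hsd(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(tk$diff, 0)
  expect_equal(tk$p_adj, 1)
  expect_equal(tk$lwr, -tk$upr)

  # k = 2: adjusted p equals the pooled-variance two-sample t-test p
  withr::with_seed(7, {
    for (r in 1:5) {
      x <- rnorm(6 + r)
      y <- rnorm(9, 0.7)
      tk2 <- tukey_hsd(c(x, y), rep(c("g1", "g2"), c(length(x), length(y))))
      tt <- t.test(y, x, var.equal = TRUE)
      expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-9)
    }
  })

  # k = 3, one group shifted by 3 sigma: that pair significant, null pair's CI spans 0
  withr::with_seed(8, {
    vals <- c(rnorm(50), rnorm(50), rnorm(50, 3))
    grp <- rep(c("a", "b", "c"), each = 50)
    tk3 <- tukey_hsd(vals, grp)
    expect_lt(tk3$p_adj[tk3$pair == "c-a"], 0.001)
    null_pair <- tk3[tk3$pair == "b-a", ]
    expect_lt(null_pair$lwr, 0)
    expect_gt(null_pair$upr, 0)
  })

  # simultaneity: adjusted p never below the unadjusted pairwise t p
  withr::with_seed(9, {
    vals <- rnorm(30)
    grp <- rep(c("a", "b", "c"), each = 10)
    tk <- tukey_hsd(vals, grp)
    s2 <- sum((vals - ave(vals, grp))^2) / (30 - 3)  # pooled variance
    for (i in seq_len(nrow(tk))) {
      gs <- strsplit(tk$pair[i], "-")[[1]]
      se <- sqrt(s2 * (1 / 10 + 1 / 10))
      p_t <- 2 * pt(-abs(tk$diff[i] / se), df = 27)
      expect_gte(tk$p_adj[i] + 1e-12, p_t)
    }
  })

  expect_error(tukey_hsd(c(1, 2), c("a", "b")),
               class = "stratburden_insufficient_df")
})

test_that("anova_eta_squared decomposes variance sequentially", {
  # zero total variance: all shares zero
  rec0 <- tibble::tibble(change = rep(-20, 6),
                         location = rep(c("lung", "liver"), 3),
                         patient_id = rep(c("P1", "P2", "P3"), each = 2))
  vd0 <- anova_eta_squared(rec0)
  expect_equal(vd0$eta_location + vd0$eta_patient + vd0$eta_interaction +
                 vd0$residual, 0)

  # two locations with distinct constants, disjoint singleton patients:
  # location explains everything
  rec1 <- tibble::tibble(change = c(-50, 10),
                         location = c("breast", "liver"),
                         patient_id = c("P1", "P2"))
  expect_equal(anova_eta_squared(rec1)$eta_location, 1)

  # balanced crossed design: shares match brute-force sums of squares
  withr::with_seed(21, {
    d <- expand.grid(location = c("breast", "lung", "liver"),
                     patient_id = paste0("P", 1:4),
                     rep = 1:2, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    d$change <- rnorm(nrow(d), -20, 15)
    vd <- anova_eta_squared(d)

    grand <- mean(d$change)
    ss_tot <- sum((d$change - grand)^2)
    loc_mean <- ave(d$change, d$location)
    pat_mean <- ave(d$change, d$patient_id)
    cell_mean <- ave(d$change, d$location, d$patient_id)
    ss_loc <- sum((loc_mean - grand)^2)
    ss_pat <- sum((pat_mean - grand)^2)
    ss_int <- sum((cell_mean - loc_mean - pat_mean + grand)^2)
    ss_res <- sum((d$change - cell_mean)^2)

    expect_equal(vd$eta_location, ss_loc / ss_tot, tolerance = 1e-9)
    expect_equal(vd$eta_patient, ss_pat / ss_tot, tolerance = 1e-9)
    expect_equal(vd$eta_interaction, ss_int / ss_tot, tolerance = 1e-9)
    expect_equal(vd$residual, ss_res / ss_tot, tolerance = 1e-9)
    expect_equal(vd$eta_location + vd$eta_patient + vd$eta_interaction +
                   vd$residual, 1, tolerance = 1e-9)

    # invariance to affine transformation of the response
    d2 <- d
    d2$change <- 3.7 * d$change + 11
    vd2 <- anova_eta_squared(d2)
    expect_equal(vd2$eta_location, vd$eta_location, tolerance = 1e-9)
    expect_equal(vd2$eta_interaction, vd$eta_interaction, tolerance = 1e-9)
  })
})

test_that("levene and jarque_bera behave as ANOVA prerequisites", {
  # identical groups: Levene statistic 0
  lv <- levene(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(lv$statistic, 0)

  # unequal spread detected
  withr::with_seed(4, {
    lv2 <- levene(c(rnorm(60, sd = 1), rnorm(60, sd = 5)),
                  rep(c("a", "b"), each = 60))
    expect_lt(lv2$p, 0.001)
  })

  # JB calibration: keeps normal samples, rejects exponential ones
  withr::with_seed(5, {
    p_norm <- vapply(1:200, function(i) jarque_bera(rnorm(500))$p, numeric(1))
    p_exp <- vapply(1:200, function(i) jarque_bera(rexp(500))$p, numeric(1))
    expect_gte(mean(p_norm > 0.01), 0.95)
    expect_gte(mean(p_exp < 0.01), 0.95)
  })
  expect_equal(jarque_bera(rep(2, 10))$p, 1)
})

test_that("iqr_outlier_mask flags Tukey-fence outliers, monotone in k", {
  x <- c(1:9, 100)
  expect_equal(which(iqr_outlier_mask(x)), 10)
  expect_false(any(iqr_outlier_mask(rep(7, 10))))

  withr::with_seed(6, {
    for (r in 1:20) {
      v <- rnorm(50, sd = sample(1:10, 1))
      flagged <- sapply(c(0.5, 1, 1.5, 2, 3), function(k)
        sum(iqr_outlier_mask(v, k = k)))
      expect_true(all(diff(flagged) <= 0))
    }
  })

  # fuzzed p-values stay in [0, 1]
  withr::with_seed(61, {
    for (r in 1:20) {
      x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), 1)
      expect_gte(mann_whitney(x, y), 0)
      expect_lte(mann_whitney(x, y), 1)
      p <- pearson_chi_square(matrix(sample(1:20, 4), 2))$p
      expect_gte(p, 0); expect_lte(p, 1)
    }
  })
})
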