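test_that("chi-square test matches closed-form Pearson computation", {
  got <- chi_square_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)

  got2 <- chi_square_test(rbind(c(20, 0), c(0, 20)))
  expect_equal(got2$statistic, 40)
  expect_lt(got2$p_value, 1e-9)

  # direct-formula oracle on random tables
  set.seed(51)
  for (r in 1:10) {
    tab <- matrix(rpois(6, 30) + 1, 3, 2)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat_o <- sum((tab - exp_tab)^2 / exp_tab)
    expect_equal(chi_square_test(tab)$statistic, stat_o, tolerance = 1e-10)
  }

  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))), "zero margin")
})

test_that("Kruskal-Wallis H matches hand rank computation and is rank-invariant", {
  got <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 21
  expect_equal(got$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-10)

  # invariance under monotone transforms of the pooled data
  set.seed(52)
  g1 <- rnorm(20)
  g2 <- rnorm(25, 1)
  a <- kruskal_wallis(list(g1, g2))
  b <- kruskal_wallis(list(exp(g1), exp(g2)))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  # null behaviour: permuted copies of one distribution rarely give small p
  set.seed(53)
  small_p <- 0
  for (r in 1:100) {
    pool <- rnorm(60)
    grp <- split(pool, sample(rep(1:3, 20)))
    if (kruskal_wallis(grp)$p_value <= 0.01) small_p <- small_p + 1
  }
  expect_lte(small_p, 5)

  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 5))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("cluster profile table computes medians, IQRs, percentages and tests", {
  pts <- data.frame(
    patient_id = sprintf("p%02d", 1:18),
    age = c(1:9, 1:9 + 20),
    HT = c(rep(1, 5), rep(0, 4), rep(1, 5), rep(0, 4)),
    stringsAsFactors = FALSE)
  labels <- rep(1:2, each = 9)
  prof <- summarize_clusters(pts, labels, continuous = "age", binary = "HT")

  age_row <- prof[prof$characteristic == "age", ]
  expect_equal(age_row$cluster_1, 5)                 # median of 1..9
  expect_equal(median_iqr(1:9), c(q1 = 3, median = 5, q3 = 7))
  expect_equal(age_row$test, "kruskal_wallis")

  ht_row <- prof[prof$characteristic == "HT", ]
  expect_equal(ht_row$cluster_1, ht_row$cluster_2)   # identical prevalence
  expect_gt(ht_row$p_value, 0.9)                     # chi-square p near 1
  expect_equal(ht_row$overall, 100 * 10 / 18)

  # whole-cohort percentage equals the size-weighted cluster combination
  w <- as.numeric(table(labels)) / length(labels)
  expect_equal(ht_row$overall, w[1] * ht_row$cluster_1 + w[2] * ht_row$cluster_2)

  # a 2-sd shift at n = 200 per group is detected
  set.seed(54)
  pts2 <- data.frame(patient_id = sprintf("q%03d", 1:400),
                     lab = c(rnorm(200), rnorm(200, 2)),
                     stringsAsFactors = FALSE)
  prof2 <- summarize_clusters(pts2, rep(1:2, each = 200),
                              continuous = "lab", binary = character())
  expect_lt(prof2$p_value[prof2$characteristic == "lab"], 0.001)

  expect_error(summarize_clusters(pts, c(rep(1, 17), 3), continuous = "age",
                                  binary = "HT"),
               NA)  # labels 1 and 3 are fine: ids need not be contiguous
})

test_that("profile generation is label-permutation equivariant", {
  co <- simulate_cohort(default_cohort_spec(n_patients = 300, seed = 55))
  labels <- ward_cluster(gower_matrix(preprocess_cohort(co$patients, scale = FALSE)), 3)$labels
  prof <- summarize_clusters(co$patients, labels)
  # swap cluster ids 1 and 2: columns swap, values unchanged
  swapped <- ifelse(labels == 1, 2, ifelse(labels == 2, 1, labels))
  prof_s <- summarize_clusters(co$patients, swapped)
  expect_equal(prof$cluster_1, prof_s$cluster_2)
  expect_equal(prof$cluster_2, prof_s$cluster_1)
  expect_equal(prof$p_value, prof_s$p_value)
})

test_that("prescription summaries count at-least-one prevalence and rates", {
  pts <- data.frame(patient_id = sprintf("p%02d", 1:10), stringsAsFactors = FALSE)
  labels <- rep(1:2, each = 5)
  rx <- data.frame(
    patient_id = c("p01", "p01", "p02", "p06", "p07", "p08", "p09"),
    drug_group = c("ACEi_ARB", "ACEi_ARB", "statin", "statin", "statin",
                   "statin", "mystery_pill"),
    stringsAsFactors = FALSE)
  expect_warning(
    prof <- summarize_prescriptions(rx, pts, labels, observation_years = 2),
    "unmapped")

  acei <- prof[prof$characteristic == "ACEi_ARB" & prof$kind == "pct_any", ]
  expect_equal(acei$cluster_1, 20)   # p01 counted once despite 2 rows
  expect_equal(acei$cluster_2, 0)

  statin <- prof[prof$characteristic == "statin" & prof$kind == "pct_any", ]
  expect_equal(statin$overall, 40)   # 4 of 10 patients

  other <- prof[prof$characteristic == "other" & prof$kind == "pct_any", ]
  expect_equal(other$cluster_2, 20)

  rate <- prof[prof$characteristic == "ACEi_ARB" & prof$kind == "rx_per_year", ]
  expect_equal(rate$cluster_1, mean(c(2, 0, 0, 0, 0)) / 2)

  # empty prescriptions: all zero
  prof0 <- summarize_prescriptions(rx[0, ], pts, labels)
  expect_true(all(prof0$overall[prof0$kind == "pct_any"] == 0))
})

test_that("admission summaries respect the one-year window and person-time", {
  pts <- data.frame(
    patient_id = c("a", "b", "c"),
    hf_diagnosis_date = as.Date(c("2015-01-01", "2015-01-01", "2015-01-01")),
    stringsAsFactors = FALSE)
  ev <- data.frame(
    patient_id = c("a", "a", "b"),
    event_type = "hospitalisation",
    event_date = as.Date(c("2015-07-01", "2016-07-01", "2014-06-01")),
    stringsAsFactors = FALSE)
  labels <- c(1, 1, 2)
  expect_warning(
    prof <- summarize_admissions(ev, pts, labels, horizon_years = 2),
    "before HF diagnosis")
  w1 <- prof[prof$kind == "pct_within_1y", ]
  expect_equal(w1$cluster_1, 50)    # a yes (+0.5y), b's event predates diagnosis
  expect_equal(w1$cluster_2, 0)
  wp <- prof[prof$kind == "pct_within_period", ]
  expect_equal(wp$cluster_1, 50)
  rate <- prof[prof$kind == "events_per_year_median", ]
  py <- round(2 * 365.25) / 365.25   # person-years after day rounding
  expect_equal(rate$cluster_1, stats::median(c(2 / py, 0)))

  # no events at all: all zeros
  prof0 <- summarize_admissions(ev[0, ], pts, labels, horizon_years = 2)
  expect_true(all(prof0$overall == 0))
})
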