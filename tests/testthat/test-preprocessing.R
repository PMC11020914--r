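test_that("HF cohort identification matches codes and keywords", {
  rec <- data.frame(
    patient_id = c("a", "b", "c", "d", "e", "f"),
    icd9_code = c("428.0", "", "410.1", "4259", "", "39891"),
    free_text = c("", "insuficiência cardíaca congestiva", "enfarte", "",
                  "INSUFICIENCIA CARDIACA", ""),
    stringsAsFactors = FALSE)
  got <- identify_hf_patients(rec)
  expect_setequal(got, c("a", "b", "d", "e", "f"))
  expect_false("c" %in% got)

  # diacritic-insensitive both ways: accented keyword, unaccented text
  rec2 <- data.frame(patient_id = "x", icd9_code = "",
                     free_text = "insuficiencia cardiaca descompensada",
                     stringsAsFactors = FALSE)
  expect_equal(identify_hf_patients(rec2), "x")

  # dotted and undotted code dialects both match
  rec3 <- data.frame(patient_id = c("p", "q"), icd9_code = c("404.91", "40491"),
                     free_text = "", stringsAsFactors = FALSE)
  expect_setequal(identify_hf_patients(rec3), c("p", "q"))

  expect_error(identify_hf_patients(rec, codes = character(), keywords = character()),
               "at least one")
})

test_that("longitudinal aggregation takes lab means, last age, ever-flags", {
  obs <- data.frame(
    patient_id = c("p1", "p1", "p2"),
    obs_date = as.Date(c("2019-01-01", "2020-06-01", "2020-01-01")),
    age = c(80, 82, 70),
    hemoglobin = c(10, 14, NA),
    HT = c(0, 1, 0),
    stringsAsFactors = FALSE)
  agg <- aggregate_patient_features(obs, labs = "hemoglobin", flags = "HT")
  expect_equal(agg$hemoglobin[agg$patient_id == "p1"], 12)
  expect_equal(agg$age[agg$patient_id == "p1"], 82)   # value at the later visit
  expect_equal(agg$HT[agg$patient_id == "p1"], 1)     # flagged at any visit
  # patient with no lab observations gets a missing cell, not an error
  expect_true(is.na(agg$hemoglobin[agg$patient_id == "p2"]))
  # single observation passes through
  expect_equal(agg$age[agg$patient_id == "p2"], 70)
})

test_that("prevalence and missingness filters use strict thresholds", {
  set.seed(1)
  vals <- cbind(rare = c(1, rep(0, 99)),               # 1% prevalence
                common = rbinom(100, 1, 0.5),
                lab_hi = c(rep(NA, 41), rnorm(59)),    # 41% missing
                lab_at = c(rep(NA, 40), rnorm(60)),    # exactly 40% missing
                lab_ok = rnorm(100))
  fm <- feature_matrix(vals, kinds = c("binary", "binary", rep("continuous", 3)))
  out <- filter_features(fm)
  expect_setequal(out$meta$name, c("common", "lab_at", "lab_ok"))
  expect_setequal(out$audit$name, c("rare", "lab_hi"))
  expect_equal(out$audit$rule, c("prevalence_min", "missing_max"))

  # a binary feature exactly at 2% prevalence is kept
  vals2 <- cbind(at2 = c(1, 1, rep(0, 98)), lab = rnorm(100))
  fm2 <- filter_features(feature_matrix(vals2, c("binary", "continuous")))
  expect_true("at2" %in% fm2$meta$name)

  # no violations: identity
  fm3 <- random_mixed_fm(50)
  expect_equal(filter_features(fm3)$values, fm3$values)

  # all columns dropped is an error
  vals4 <- cbind(rare = c(1, rep(0, 99)))
  expect_error(filter_features(feature_matrix(vals4, "binary")), "all feature columns")
})

test_that("chained imputation recovers exact linear structure and never touches observed cells", {
  # no missing cells: identity
  fm <- random_mixed_fm(30)
  expect_identical(impute_chained(fm)$values, fm$values)

  # y = 2x with one y missing: recovered within 1e-6
  x <- seq(-2, 2, length.out = 21)
  y <- 2 * x
  y[7] <- NA
  fm2 <- feature_matrix(cbind(x = x, y = y), c("continuous", "continuous"))
  imp <- impute_chained(fm2)
  expect_lt(abs(imp$values[7, "y"] - 2 * x[7]), 1e-6)

  # observed cells bit-identical on a random matrix with scattered missingness
  set.seed(8)
  vals <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  mask <- matrix(runif(200) < 0.15, 40, 5)
  mask[, 1] <- FALSE   # keep one fully observed column
  vals_na <- vals
  vals_na[mask] <- NA
  fm3 <- feature_matrix(vals_na, rep("continuous", 5))
  imp3 <- impute_chained(fm3)
  expect_identical(imp3$values[!mask], vals_na[!mask])
  expect_false(anyNA(imp3$values))

  # a fully missing column is an error naming the column
  vals_bad <- cbind(a = rnorm(10), b = rep(NA_real_, 10))
  expect_error(impute_chained(feature_matrix(vals_bad, rep("continuous", 2))),
               "entirely missing")
})

test_that("scaling maps continuous to zero-mean unit-sd and binaries to ±0.5", {
  fm <- feature_matrix(cbind(x = c(1, 2, 3), b = c(0, 1, 1)),
                       c("continuous", "binary"))
  sc <- scale_features(fm)
  expect_equal(sc$values[, "x"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(sc$values[, "b"], c(-0.5, 0.5, 0.5))

  # idempotent on its own output
  sc2 <- scale_features(sc)
  expect_equal(sc2$values, sc$values, tolerance = 1e-8)

  # population-sd convention: post-scaling moments
  fm2 <- scale_features(random_mixed_fm(40, seed = 2))
  for (j in which(fm2$meta$kind == "continuous")) {
    v <- fm2$values[, j]
    expect_lt(abs(mean(v)), 1e-8)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-8)
  }

  expect_error(
    scale_features(feature_matrix(cbind(k = rep(2, 5), x = rnorm(5)),
                                  rep("continuous", 2))),
    "'k' has zero variance")
})

test_that("preprocessing chain is deterministic and a no-op on clean input", {
  co <- simulate_cohort(default_cohort_spec(n_patients = 300, seed = 21))
  fm1 <- preprocess_cohort(co$patients, scale = FALSE)
  fm2 <- preprocess_cohort(co$patients, scale = FALSE)
  expect_identical(fm1$values, fm2$values)
  # re-filtering preprocessed output drops nothing further
  refiltered <- filter_features(fm1)
  expect_equal(ncol(refiltered$values), ncol(fm1$values))
  # dropped-column count equals direct application of the two rules
  raw <- build_feature_matrix(co$patients)
  prev_drop <- sum(raw$meta$kind == "binary" & raw$meta$prevalence < 0.02)
  miss_drop <- sum(raw$meta$missing_frac > 0.40 &
                     !(raw$meta$kind == "binary" & raw$meta$prevalence < 0.02))
  expect_equal(nrow(fm1$audit), prev_drop + miss_drop)
})
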