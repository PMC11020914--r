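## small cohort specs and toy tables used across the suite

one_cluster_spec <- function(n = 500, prev = c(HT = 0.5), labs = list(),
                             rho = 0, baseline_rate = 0.2, horizon = 2,
                             seed = 1L) {
  d <- length(prev)
  R <- matrix(rho, d, d)
  diag(R) <- 1
  cohort_spec(
    n_patients = n, n_clusters = 1,
    comorbidity_names = names(prev),
    prevalence_matrix = matrix(prev, nrow = 1),
    copula_correlation = R,
    lab_specs = labs,
    age_specs = list(mean = 78, sd = 6),
    female_prob = 0.5,
    hazard_multipliers = list(hospitalisation = 1, emergency = 1),
    baseline_rate = baseline_rate, censor_horizon = horizon, seed = seed)
}

two_cluster_spec <- function(n = 1000, hr = 3, baseline_rate = 0.15,
                             horizon = 2.5, seed = 1L) {
  cohort_spec(
    n_patients = n, n_clusters = 2,
    mixing_proportions = c(0.5, 0.5),
    comorbidity_names = c("HT", "CKD"),
    prevalence_matrix = rbind(c(0.9, 0.1), c(0.1, 0.9)),
    copula_correlation = diag(2),
    lab_specs = list(),
    age_specs = list(mean = c(80, 70), sd = c(5, 5)),
    female_prob = c(0.5, 0.5),
    hazard_multipliers = list(hospitalisation = c(hr, 1), emergency = c(1, 1)),
    baseline_rate = baseline_rate, censor_horizon = horizon, seed = seed)
}

## small mixed feature matrix with both kinds, reproducible
random_mixed_fm <- function(n = 20, n_cont = 3, n_bin = 3, seed = 1) {
  set.seed(seed)
  vals <- cbind(
    matrix(rnorm(n * n_cont), n, n_cont,
           dimnames = list(NULL, paste0("x", seq_len(n_cont)))),
    matrix(rbinom(n * n_bin, 1, 0.5), n, n_bin,
           dimnames = list(NULL, paste0("b", seq_len(n_bin)))))
  # guard against constant columns, which are invalid inputs downstream
  for (j in seq_len(ncol(vals))) {
    if (length(unique(vals[, j])) == 1) vals[1, j] <- 1 - vals[1, j]
  }
  feature_matrix(vals, kinds = c(rep("continuous", n_cont), rep("binary", n_bin)))
}

## naive double-loop Gower oracle, written independently of gower_matrix()
gower_oracle <- function(X, kinds, weights = rep(1, ncol(X))) {
  n <- nrow(X)
  m <- ncol(X)
  r <- vapply(seq_len(m), function(j)
    if (kinds[j] == "continuous") max(X[, j]) - min(X[, j]) else NA_real_,
    numeric(1))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (l in seq_len(n)) {
      s <- 0
      for (j in seq_len(m)) {
        f <- if (kinds[j] == "continuous") {
          abs(X[i, j] - X[l, j]) / r[j]
        } else {
          as.numeric(X[i, j] != X[l, j])
        }
        s <- s + weights[j] * f
      }
      D[i, l] <- s / sum(weights)
    }
  }
  D
}

## direct-formula validity index oracles (independent implementations)
ch_oracle <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- unique(labels)
  k <- length(ks)
  grand <- colMeans(X)
  B <- 0
  W <- 0
  for (g in ks) {
    Xg <- X[labels == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((cg - grand)^2)
    W <- W + sum(sweep(Xg, 2, cg)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

db_oracle <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  k <- length(ks)
  cent <- t(sapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE])))
  s <- sapply(seq_len(k), function(i)
    mean(sqrt(rowSums(sweep(X[labels == ks[i], , drop = FALSE], 2, cent[i, ])^2))))
  total <- 0
  for (i in seq_len(k)) {
    best <- 0
    for (j in seq_len(k)) {
      if (i == j) next
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      best <- max(best, (s[i] + s[j]) / d)
    }
    total <- total + best
  }
  total / k
}

sil_oracle <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(g)
      mean(D[i, labels == g])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
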