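make_stats_tbl <- function() {
  tidyr::expand_grid(
    subject = c("S1", "S2"),
    channel = c("F3", "Cz"),
    stage = "N2", night = "n2",
    kind = c("sw", "fast_spindle")
  ) |>
    dplyr::mutate(
      n_events = 10,
      density_per_min = ifelse(.data$channel == "F3", 0.4, 0.6),
      mean_amplitude_uV = 100, mean_duration_s = 1, mean_freq_hz = 1.1
    )
}

test_that("feature tables average event properties over electrodes", {
  tbl <- build_feature_table(make_stats_tbl(), night = "n2", stage = "N2")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$sw_density_per_min, c(0.5, 0.5))
  expect_equal(tbl$fast_spindle_mean_amplitude_uV, c(100, 100))

  # a subject missing one kind is flagged, others averaged as usual
  partial <- make_stats_tbl() |>
    dplyr::filter(!(.data$subject == "S2" & .data$kind == "fast_spindle"))
  expect_warning(tbl2 <- build_feature_table(partial, "n2", "N2"),
                 "missing an event kind")
  expect_equal(attr(tbl2, "flagged"), "S2")
  expect_equal(tbl2$sw_density_per_min, c(0.5, 0.5))

  expect_error(build_feature_table(make_stats_tbl(), night = "n9"),
               "no summaries")
})

test_that("feature correlations behave like Pearson's rho", {
  set.seed(61)
  x <- rnorm(1000)
  tbl <- tibble::tibble(a = x, b = 2 * x + 1, c = -x, d = rnorm(1000))
  rho <- feature_correlation(tbl)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_lt(abs(rho["a", "d"]), 0.1)
  expect_true(all(diag(rho) == 1))
  expect_equal(rho, t(rho))
  expect_warning(feature_correlation(tibble::tibble(a = rnorm(10), z = 1)),
                 "zero-variance")
})

test_that("Box's M is zero on identical groups and detects inflation", {
  set.seed(62)
  a <- matrix(rnorm(400), 100, 4)
  same <- box_m_test(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)
  expect_equal(same$df, 10)

  b4 <- matrix(rnorm(400, sd = 2), 100, 4)
  expect_lt(box_m_test(a, b4)$p_value, 0.01)

  expect_error(box_m_test(a), "at least two")
  expect_error(box_m_test(a, matrix(rnorm(300), 100, 3)), "share")
  sing <- matrix(rnorm(100), 100, 1) %*% t(rep(1, 4)) # rank-1 covariance
  expect_error(box_m_test(a, sing), "singular")
})

test_that("PCA of features: standardized, ordered, decorrelated", {
  set.seed(63)
  x <- rnorm(50)
  two <- tibble::tibble(a = x, b = 3 * x)   # perfectly correlated
  p2 <- pca_features(two)
  expect_equal(p2$explained[1], 1, tolerance = 1e-10)

  iso <- tibble::as_tibble(matrix(rnorm(10000 * 5), ncol = 5,
                                  dimnames = list(NULL, letters[1:5])))
  piso <- pca_features(iso)
  expect_true(all(abs(piso$explained - 0.2) < 0.05))
  expect_equal(sum(piso$explained), 1, tolerance = 1e-9)
  expect_true(all(diff(piso$explained) <= 1e-12))
  cors <- stats::cor(piso$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-10)
  # loadings orthonormal
  expect_equal(crossprod(piso$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_warning(pca_features(tibble::tibble(a = rnorm(20), k = 2)),
                 "constant")
})

test_that("forward stepwise: recovery, null behavior, degeneracy, determinism", {
  set.seed(64)
  hits <- logical(100); null_any <- logical(100)
  for (i in 1:100) {
    X <- matrix(rnorm(18 * 10), 18, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
    m <- stepwise_mlr(X, 3 * X[, 2] + rnorm(18, 0, 0.1))
    hits[i] <- identical(m$included_terms, "PC2") ||
      "PC2" %in% m$included_terms
    m0 <- stepwise_mlr(X, rnorm(18))
    null_any[i] <- length(m0$included_terms) > 0
  }
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(null_any), 0.15)

  X <- matrix(rnorm(18 * 10), 18, 10,
              dimnames = list(NULL, paste0("PC", 1:10)))
  y <- 2 * X[, 1] + rnorm(18, 0, 0.2)
  m1 <- stepwise_mlr(X, y); m2 <- stepwise_mlr(X, y)
  expect_identical(m1$included_terms, m2$included_terms)
  expect_equal(stats::coef(m1$model), stats::coef(m2$model))

  expect_warning(mc <- stepwise_mlr(X, rep(1, 18)), "constant")
  expect_true(mc$degenerate)
  expect_equal(length(mc$included_terms), 0)
  expect_error(stepwise_mlr(X[1:5, ], rnorm(5)), "too few")
})

test_that("tidiers expose model summaries as tibbles", {
  set.seed(65)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("PC", 1:5)))
  m <- stepwise_mlr(X, 2 * X[, 3] + rnorm(30, 0, 0.3))
  td <- generics::tidy(m)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  gl <- generics::glance(m)
  expect_equal(gl$n_terms, length(m$included_terms))
  bm <- box_m_test(matrix(rnorm(200), 50, 4), matrix(rnorm(200), 50, 4))
  expect_equal(nrow(generics::tidy(bm)), 1)
  p <- pca_features(tibble::as_tibble(X))
  expect_equal(nrow(generics::tidy(p)), 25)
  expect_equal(generics::glance(p)$cumulative[5], 1, tolerance = 1e-9)
})

test_that("component matching is permutation- and sign-invariant", {
  set.seed(66)
  tbl <- tibble::as_tibble(matrix(rnorm(40 * 6), ncol = 6,
                                  dimnames = list(NULL, letters[1:6])))
  pa <- pca_features(tbl)
  expect_equal(match_components(pa, pa, "PC2")$component, "PC2")
  expect_equal(match_components(pa, pa, "PC2")$distance, 0)

  perm <- pa
  perm$loadings <- pa$loadings[, c(3, 1, 2, 4, 5, 6)]
  colnames(perm$loadings) <- paste0("PC", 1:6)
  expect_equal(match_components(pa, perm, "PC1")$component, "PC2")

  neg <- pa
  neg$loadings[, "PC2"] <- -neg$loadings[, "PC2"]
  m <- match_components(pa, neg, "PC2")
  expect_equal(m$component, "PC2")
  expect_equal(m$distance, 0, tolerance = 1e-12)
  expect_true(m$flipped)

  other <- pa
  rownames(other$loadings) <- paste0("x", 1:6)
  expect_error(match_components(pa, other, "PC1"), "common")
})

test_that("mixed model: balanced zero-variance fit equals OLS", {
  d <- simulate_event_amplitudes(n_per_group = 4, events_per_cell = 6,
                                 subject_sd = 0, residual_sd = 8,
                                 interaction_uV = 3, seed = 67)
  fit <- fit_event_lmm(d, "amplitude_uV", marginal_means = FALSE)
  ols <- stats::lm(amplitude_uV ~ genotype + night + electrode +
                     sleep_stage + genotype:night,
                   data = dplyr::mutate(d, dplyr::across(
                     c("genotype", "night", "electrode", "sleep_stage"),
                     as.factor)))
  co_l <- lme4::fixef(fit$full)
  co_o <- stats::coef(ols)
  expect_equal(co_l, co_o[names(co_l)], tolerance = 1e-8)
})

test_that("marginal means reproduce raw cell means in a balanced design", {
  d <- simulate_event_amplitudes(n_per_group = 4, events_per_cell = 10,
                                 subject_sd = 4, residual_sd = 6,
                                 interaction_uV = 25, seed = 68)
  fit <- fit_event_lmm(d, "amplitude_uV")
  expect_true("genotype:night" %in% fit$retained)
  raw <- d |>
    dplyr::group_by(.data$genotype, .data$night) |>
    dplyr::summarise(m = mean(.data$amplitude_uV), .groups = "drop")
  merged <- dplyr::left_join(fit$emmeans,
                             dplyr::mutate(raw,
                                           genotype = factor(.data$genotype),
                                           night = factor(.data$night)),
                             by = c("genotype", "night"))
  expect_equal(merged$emmean, merged$m, tolerance = 1e-8)
})

test_that("end-to-end cohort generator carries the planted structure", {
  sim <- simulate_consolidation_cohort(seed = 69)
  expect_equal(nrow(sim$features), 40)
  expect_equal(nrow(sim$behavior), 40)
  cc <- sim$behavior$group == "CC"
  res <- consolidation_pipeline(
    dplyr::filter(sim$features, .data$group == "CC"),
    sim$behavior$improvement_ncs_pct[cc])
  expect_gte(length(res$model$included_terms), 1)
})
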