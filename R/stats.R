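#' Subject-level NREM feature table
#'
#' Reduces per-(subject, channel, stage, night, kind) event summaries to a
#' subject x feature table by averaging each event property over all
#' electrodes, for one night and stage selection. Feature columns are
#' named `<kind>_<property>` (e.g. `sw_density_per_min`,
#' `fast_spindle_mean_amplitude_uV`). Subjects missing an event kind
#' entirely keep `NA` in that kind's columns and are listed in the
#' `flagged` attribute.
#'
#' @param stats Event summaries from [summarize_events()] including a
#'   `subject` column (and optionally `group`, carried through).
#' @param night Night to select (`NULL` = all rows).
#' @param stage Stages to pool (`NULL` = all); electrode averages pool
#'   the selected stages.
#' @return Tibble, one row per subject, with attribute `flagged` naming
#'   subjects that miss at least one event kind.
#' @export
build_feature_table <- function(stats, night = NULL, stage = NULL) {
  tbl <- stats
  if (!is.null(night)) tbl <- tbl[tbl$night %in% night, ]
  if (!is.null(stage)) tbl <- tbl[tbl$stage %in% stage, ]
  if (nrow(tbl) == 0) stop("no summaries for the requested night/stage",
                           call. = FALSE)
  props <- intersect(c("density_per_min", "mean_amplitude_uV",
                       "mean_duration_s", "mean_freq_hz"), names(tbl))
  keys <- intersect(c("subject", "group"), names(tbl))
  long <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "kind")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(props),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(
    long, names_from = "kind",
    values_from = dplyr::all_of(props),
    names_glue = "{kind}_{.value}"
  )
  feat_cols <- setdiff(names(wide), keys)
  flagged <- wide$subject[apply(is.na(wide[feat_cols]), 1, any)]
  if (length(flagged) > 0) {
    warning("subject(s) missing an event kind: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  attr(wide, "flagged") <- flagged
  wide
}

#' Pearson correlation matrix of feature columns
#'
#' @param tbl Feature table; non-numeric columns (e.g. `subject`,
#'   `group`) are ignored.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   columns yield `NA` rows/columns and a warning.
#' @export
feature_correlation <- function(tbl) {
  num <- tbl[vapply(tbl, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 rows", call. = FALSE)
  vars <- vapply(num, stats::var, numeric(1), na.rm = TRUE)
  if (any(vars == 0, na.rm = TRUE)) {
    warning("zero-variance column(s): ",
            paste(names(num)[which(vars == 0)], collapse = ", "),
            call. = FALSE)
  }
  suppressWarnings(stats::cor(as.matrix(num),
                              use = "pairwise.complete.obs"))
}

#' Box's M test for equality of covariance matrices
#'
#' Compares the covariance matrices of two (or more) groups of
#' multivariate observations:
#' `M = (N - g) ln|S_pooled| - sum (n_i - 1) ln|S_i|`, with Box's
#' chi-square approximation `X2 = M (1 - c)` on
#' `df = (g - 1) p (p + 1) / 2` degrees of freedom.
#'
#' @param ... Two or more numeric matrices / data frames (rows =
#'   observations, identical columns).
#' @return Object of class `box_m`: list with `statistic` (M), `chi_sq`,
#'   `df`, `p_value`, `n_features`, `n_obs`, and `degenerate` (TRUE when
#'   some group has `n <= p`, where the chi-square approximation is
#'   unreliable).
#' @export
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(400), 100, 4)
#' b <- matrix(rnorm(400), 100, 4)
#' box_m_test(a, b)
box_m_test <- function(...) {
  groups <- lapply(list(...), function(x) {
    x <- as.data.frame(x)
    as.matrix(x[vapply(x, is.numeric, logical(1))])
  })
  g <- length(groups)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  p <- ncol(groups[[1]])
  if (any(vapply(groups, ncol, 1L) != p)) {
    stop("groups must share the same feature columns", call. = FALSE)
  }
  n_i <- vapply(groups, nrow, 1L)
  N <- sum(n_i)
  S_i <- lapply(groups, stats::cov)
  logdet <- function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0 || !is.finite(d$modulus)) {
      stop("singular group covariance; reduce the feature dimension first",
           call. = FALSE)
    }
    as.numeric(d$modulus)
  }
  S_pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, S_i, n_i)) /
    (N - g)
  M <- (N - g) * logdet(S_pooled) -
    sum(mapply(function(S, n) (n - 1) * logdet(S), S_i, n_i))
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (n_i - 1)) - 1 / (N - g))
  chi_sq <- M * (1 - c1)
  df <- (g - 1) * p * (p + 1) / 2
  structure(
    list(statistic = M, chi_sq = chi_sq, df = df,
         p_value = stats::pchisq(chi_sq, df, lower.tail = FALSE),
         n_features = p, n_obs = n_i, degenerate = any(n_i <= p)),
    class = "box_m"
  )
}

#' @export
print.box_m <- function(x, ...) {
  cat(sprintf("Box's M test: M = %.4g, chi-sq = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$chi_sq, x$df, x$p_value))
  if (x$degenerate) cat("  (warning: some group has n <= p)\n")
  invisible(x)
}

#' Principal components of a feature table
#'
#' Standardizes the feature columns (z-score) and performs PCA — an
#' eigendecomposition of the correlation matrix. Constant columns are
#' dropped with a warning. Scores are exactly decorrelated; loadings are
#' orthonormal.
#'
#' @param tbl Feature table (non-numeric columns ignored, carried in the
#'   result for reference).
#' @return Object of class `nrem_pca`: list with `loadings` (feature x
#'   component), `scores` (subject x component), `explained` (fraction of
#'   variance per component, non-increasing, summing to 1), `sdev`, and
#'   `features`.
#' @export
pca_features <- function(tbl) {
  num <- as.data.frame(tbl[vapply(tbl, is.numeric, logical(1))])
  if (nrow(num) < 2) stop("need at least 2 rows", call. = FALSE)
  vars <- vapply(num, stats::var, numeric(1))
  if (any(vars == 0)) {
    warning("dropping constant column(s): ",
            paste(names(num)[vars == 0], collapse = ", "), call. = FALSE)
    num <- num[vars > 0]
  }
  fit <- stats::prcomp(as.matrix(num), center = TRUE, scale. = TRUE)
  structure(
    list(loadings = fit$rotation, scores = fit$x,
         explained = fit$sdev^2 / sum(fit$sdev^2), sdev = fit$sdev,
         features = colnames(num)),
    class = "nrem_pca"
  )
}

#' @export
print.nrem_pca <- function(x, ...) {
  cat(sprintf("<nrem_pca> %d features, %d components\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("  explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
            collapse = ", "),
      if (length(x$explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' Forward stepwise multilinear regression on principal components
#'
#' Builds a multiple linear regression of a behavioral response on
#' principal-component scores by forward selection: at each step the
#' candidate whose partial F-test p-value is smallest is added if it falls
#' below the entry criterion (p < 0.01 by default); selection stops when
#' no candidate qualifies. There is no removal phase.
#'
#' @param scores Matrix or data frame of candidate predictors (e.g. the
#'   first 10 PC scores).
#' @param response Numeric response (overnight improvement, percent).
#' @param alpha_enter Entry criterion on the partial F-test p-value.
#' @param max_terms Cap on the number of terms (default all candidates).
#' @return Object of class `stepwise_mlr`: list with `included_terms`,
#'   `model` (the final `lm`; intercept-only when nothing enters),
#'   `f_statistic`, `p_value`, `sse`, `r_squared`, `steps` (entry log),
#'   and `degenerate` (TRUE for a constant response).
#' @export
stepwise_mlr <- function(scores, response, alpha_enter = 0.01,
                         max_terms = ncol(scores)) {
  X <- as.data.frame(scores)
  n <- nrow(X)
  if (n != length(response)) stop("length mismatch", call. = FALSE)
  if (n <= ncol(X) + 2) {
    stop("too few observations for the candidate set", call. = FALSE)
  }
  if (stats::var(response) == 0) {
    warning("constant response; no terms selected", call. = FALSE)
    dat0 <- cbind(.y = response, X)
    return(structure(
      list(included_terms = character(0),
           model = stats::lm(.y ~ 1, data = dat0),
           f_statistic = NA_real_, p_value = NA_real_,
           sse = 0, r_squared = NA_real_,
           steps = tibble::tibble(term = character(), p_enter = numeric()),
           degenerate = TRUE),
      class = "stepwise_mlr"))
  }
  dat <- cbind(.y = response, X)
  included <- character(0)
  steps <- list()
  repeat {
    remaining <- setdiff(colnames(X), included)
    if (length(remaining) == 0 || length(included) >= max_terms) break
    base_form <- stats::reformulate(if (length(included)) included else "1",
                                    response = ".y")
    base_fit <- stats::lm(base_form, data = dat)
    pvals <- vapply(remaining, function(term) {
      fit <- stats::update(base_fit,
                           stats::reformulate(c(included, term), ".y"),
                           data = dat)
      stats::anova(base_fit, fit)$`Pr(>F)`[2]
    }, numeric(1))
    best <- names(which.min(pvals))
    if (pvals[best] < alpha_enter) {
      included <- c(included, best)
      steps[[length(steps) + 1L]] <- tibble::tibble(term = best,
                                                    p_enter = pvals[best])
    } else break
  }
  final <- stats::lm(
    stats::reformulate(if (length(included)) included else "1", ".y"),
    data = dat)
  fs <- summary(final)$fstatistic
  structure(
    list(included_terms = included, model = final,
         f_statistic = if (!is.null(fs)) unname(fs[1]) else NA_real_,
         p_value = if (!is.null(fs)) {
           unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
         } else NA_real_,
         sse = sum(stats::residuals(final)^2),
         r_squared = summary(final)$r.squared,
         steps = dplyr::bind_rows(steps), degenerate = FALSE),
    class = "stepwise_mlr"
  )
}

#' @export
print.stepwise_mlr <- function(x, ...) {
  if (length(x$included_terms) == 0) {
    cat("<stepwise_mlr> no terms passed the entry criterion\n")
  } else {
    cat("<stepwise_mlr> terms:",
        paste(x$included_terms, collapse = " + "),
        sprintf("(F = %.3g, p = %.3g, R2 = %.3f)\n",
                x$f_statistic, x$p_value, x$r_squared))
  }
  invisible(x)
}

#' Match a principal component across groups
#'
#' Finds, among the components of one PCA, the component whose loading
#' vector lies at the shortest Euclidean distance from a target component
#' of another PCA, evaluating each candidate under both signs (component
#' signs are arbitrary).
#'
#' @param pca_a,pca_b `nrem_pca` objects sharing feature columns.
#' @param target Component of `pca_a` to match (index or name).
#' @return List with `component` (name in `pca_b`), `index`, `distance`,
#'   and `flipped` (TRUE when the negated loading matched).
#' @export
match_components <- function(pca_a, pca_b, target) {
  common <- intersect(rownames(pca_a$loadings), rownames(pca_b$loadings))
  if (length(common) == 0) stop("no common features", call. = FALSE)
  va <- pca_a$loadings[common, target]
  d2 <- apply(pca_b$loadings[common, , drop = FALSE], 2, function(vb) {
    min(sum((vb - va)^2), sum((vb + va)^2))
  })
  flips <- apply(pca_b$loadings[common, , drop = FALSE], 2, function(vb) {
    sum((vb + va)^2) < sum((vb - va)^2)
  })
  idx <- which.min(d2)
  list(component = names(d2)[idx], index = unname(idx),
       distance = sqrt(d2[[idx]]), flipped = unname(flips[idx]))
}
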