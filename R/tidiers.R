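#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Box's M test
#' @param x A `box_m` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `chi_sq`, `df`, `p_value`.
#' @exportS3Method generics::tidy
tidy.box_m <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, chi_sq = x$chi_sq, df = x$df,
                 p_value = x$p_value)
}

#' @rdname tidy.box_m
#' @exportS3Method generics::glance
glance.box_m <- function(x, ...) {
  tibble::tibble(n_features = x$n_features,
                 n_obs = sum(x$n_obs), degenerate = x$degenerate)
}

#' Tidy a stepwise regression model
#' @param x A `stepwise_mlr` object.
#' @param ... Unused.
#' @return Coefficient table (term, estimate, std.error, statistic,
#'   p.value) of the final model.
#' @exportS3Method generics::tidy
tidy.stepwise_mlr <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3],
                 p.value = cf[, 4])
}

#' @rdname tidy.stepwise_mlr
#' @exportS3Method generics::glance
glance.stepwise_mlr <- function(x, ...) {
  tibble::tibble(n_terms = length(x$included_terms),
                 f_statistic = x$f_statistic, p_value = x$p_value,
                 r_squared = x$r_squared, sse = x$sse,
                 degenerate = x$degenerate)
}

#' Tidy a PCA of NREM features
#' @param x An `nrem_pca` object.
#' @param ... Unused.
#' @return Long tibble of loadings (`feature`, `component`, `loading`).
#' @exportS3Method generics::tidy
tidy.nrem_pca <- function(x, ...) {
  ld <- x$loadings
  tibble::tibble(
    feature = rep(rownames(ld), ncol(ld)),
    component = rep(colnames(ld), each = nrow(ld)),
    loading = as.vector(ld)
  )
}

#' @rdname tidy.nrem_pca
#' @exportS3Method generics::glance
glance.nrem_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' Tidy a fitted NREM mixed model
#' @param x An `nrem_lmm` object.
#' @param ... Unused.
#' @return Fixed-effect table of the final (post-elimination) model with
#'   Satterthwaite tests when available.
#' @exportS3Method generics::tidy
tidy.nrem_lmm <- function(x, ...) {
  cf <- stats::coef(summary(x$final))
  out <- tibble::as_tibble(cf, rownames = "term")
  names(out) <- sub("^Estimate$", "estimate", names(out))
  names(out) <- sub("^Std\\. Error$", "std.error", names(out))
  names(out) <- sub("^Pr\\(>\\|t\\|\\)$", "p.value", names(out))
  out
}

#' @rdname tidy.nrem_lmm
#' @exportS3Method generics::glance
glance.nrem_lmm <- function(x, ...) {
  tibble::tibble(
    retained = paste(x$retained, collapse = " + "),
    interaction_retained = "genotype:night" %in% x$retained,
    n_messages = length(x$messages)
  )
}
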