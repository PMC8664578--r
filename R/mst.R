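#' Score one MST trial
#'
#' Scans a trial's keystream left to right for complete, error-free,
#' non-overlapping occurrences of the 4-1-3-2-4 sequence. After a
#' completed sequence the scan resumes at the next keypress, so the
#' terminal 4 is not reused as the initial 4 of the next sequence
#' ("4132441324" contains exactly two). A wrong keypress resets the match;
#' the wrong key itself may begin a new match if it is a 4.
#'
#' @param t_ms Keypress times in ms (non-decreasing).
#' @param key Integer keypresses in 1..4.
#' @return A one-row tibble with `ncs` (number of correct sequences) and
#'   `et_ms` (execution time: the mean of the four inter-press gaps within
#'   each correct sequence, averaged over sequences; `NA` when `ncs` is 0).
#' @export
#' @examples
#' score_mst_trial(seq(250, 2500, by = 250),
#'                 c(4, 1, 3, 2, 4, 4, 1, 3, 2, 4))
score_mst_trial <- function(t_ms, key) {
  stopifnot(length(t_ms) == length(key))
  if (length(t_ms) > 1 && any(diff(t_ms) < 0)) {
    stop("keypress timestamps must be non-decreasing", call. = FALSE)
  }
  target <- c(4L, 1L, 3L, 2L, 4L)
  pos <- 1L
  start <- 1L
  ncs <- 0L
  seq_et <- numeric(0)
  for (j in seq_along(key)) {
    if (key[j] == target[pos]) {
      if (pos == 1L) start <- j
      pos <- pos + 1L
      if (pos == 6L) {
        ncs <- ncs + 1L
        seq_et <- c(seq_et, mean(diff(t_ms[start:j])))
        pos <- 1L
      }
    } else if (key[j] == target[1L]) {
      start <- j
      pos <- 2L
    } else {
      pos <- 1L
    }
  }
  tibble::tibble(ncs = ncs,
                 et_ms = if (ncs > 0) mean(seq_et) else NA_real_)
}

#' Score a full keystroke log
#'
#' Applies [score_mst_trial()] to every (subject, session, trial) of a
#' keystroke log.
#'
#' @param logs Tibble with columns `subject`, `session`, `trial`, `t_ms`,
#'   `key` (and optionally `group`, carried through).
#' @return Tibble with one row per trial: identifiers plus `ncs`, `et_ms`.
#' @export
score_mst_logs <- function(logs) {
  keys <- intersect(c("subject", "group", "session", "trial"), names(logs))
  logs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ score_mst_trial(.x$t_ms, .x$key)) |>
    dplyr::ungroup()
}

#' Overnight improvement per subject
#'
#' Training performance is the mean of the last three training trials,
#' test performance the mean of the first three test trials; overnight
#' improvement is the percentage change from training to test for each
#' outcome (for execution time, negative means faster).
#'
#' @param scores Trial scores from [score_mst_logs()].
#' @return Tibble with one row per subject: `training_ncs`, `test_ncs`,
#'   `improvement_ncs_pct`, `training_et_ms`, `test_et_ms`,
#'   `improvement_et_pct`. Improvements are `NA` (flagged) when the
#'   training mean is zero.
#' @export
mst_improvement <- function(scores) {
  keys <- intersect(c("subject", "group"), names(scores))
  pct <- function(test, train) {
    ifelse(is.na(train) | train == 0, NA_real_, 100 * (test - train) / train)
  }
  scores |>
    dplyr::arrange(.data$trial) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      training_ncs = mean(utils::tail(.data$ncs[.data$session == "training"], 3)),
      test_ncs = mean(utils::head(.data$ncs[.data$session == "test"], 3)),
      training_et_ms = mean(utils::tail(.data$et_ms[.data$session == "training"], 3)),
      test_et_ms = mean(utils::head(.data$et_ms[.data$session == "test"], 3)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      improvement_ncs_pct = pct(.data$test_ncs, .data$training_ncs),
      improvement_et_pct = pct(.data$test_et_ms, .data$training_et_ms)
    )
}

#' Compare overnight improvement across groups
#'
#' Runs the three group-level comparisons used for behavioral outcomes: a
#' Welch two-sample two-sided t-test on the means, Levene's robust test
#' for equality of variances (centered on the group means), and an F-based
#' two-sample variance-ratio comparison.
#'
#' @param data Data frame with one row per subject.
#' @param value Name of the outcome column (string).
#' @param group Name of the two-level group column (string).
#' @return Tibble with columns `test`, `statistic`, `p_value`, `estimate`
#'   (mean difference, variance-of-|deviation| ratio, and variance ratio
#'   respectively).
#' @export
mst_group_tests <- function(data, value, group = "group") {
  x <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  ok <- !is.na(x)
  x <- x[ok]; g <- droplevels(g[ok])
  xs <- split(x, g)
  if (any(lengths(xs) < 2)) stop("need >= 2 subjects per group", call. = FALSE)
  if (all(vapply(xs, stats::var, 1) == 0)) {
    warning("zero variance in both groups; tests are degenerate",
            call. = FALSE)
  }
  tt <- stats::t.test(x ~ g, var.equal = FALSE)
  lv <- levene_test(x, g)
  vt <- stats::var.test(xs[[1]], xs[[2]])
  tibble::tibble(
    test = c("welch_t", "levene", "variance_ratio"),
    statistic = c(unname(tt$statistic), lv$statistic, unname(vt$statistic)),
    p_value = c(tt$p.value, lv$p_value, vt$p.value),
    estimate = c(mean(xs[[1]]) - mean(xs[[2]]),
                 lv$estimate,
                 unname(vt$estimate))
  )
}

#' Levene's test for equality of variances (mean-centered)
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group mean — Levene's original (mean-centered) robust variance test.
#'
#' @param x Numeric values.
#' @param g Grouping factor.
#' @return List with `statistic` (F), `df`, `p_value` and `estimate` (the
#'   ratio of group means of absolute deviations, first over second level).
#' @export
levene_test <- function(x, g) {
  g <- factor(g)
  d <- abs(x - stats::ave(x, g))
  fit <- stats::anova(stats::lm(d ~ g))
  means <- tapply(d, g, mean)
  list(statistic = fit$`F value`[1],
       df = fit$Df,
       p_value = fit$`Pr(>F)`[1],
       estimate = unname(means[1] / means[2]))
}
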