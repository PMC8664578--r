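#' Linear mixed model for NREM event properties
#'
#' Fits the full model
#' `y ~ genotype + night + electrode + sleep_stage + genotype:night +
#' (1 | subject)` by REML with Satterthwaite denominator degrees of
#' freedom, applies backward elimination of non-significant fixed terms
#' (hierarchy-respecting: the interaction is eligible before its main
#' effects, and at each round every eligible term with p at or above the
#' threshold is removed — in the balanced designs this model serves the
#' round-wise rule coincides with one-at-a-time elimination), and
#' computes estimated marginal means for the genotype x night cells of
#' the final model with 95% confidence intervals, balanced over the
#' remaining factors.
#'
#' @param data Data frame with the response plus factors `genotype`,
#'   `night`, `electrode`, `sleep_stage` (any subset of the nuisance
#'   factors may be absent) and `subject`.
#' @param response Name of the response column (string), e.g. per-event
#'   slow-wave amplitude.
#' @param alpha_drop Elimination threshold for fixed effects (default
#'   0.05).
#' @param marginal_means Compute the genotype x night marginal means
#'   (default TRUE; skip for large simulation sweeps).
#' @return Object of class `nrem_lmm`: list with `full` (the full
#'   `lmerModLmerTest` fit), `final` (post-elimination model; may be an
#'   `lm` if the random effect were ever dropped — random effects are not
#'   eliminated here), `elimination` (the step table for fixed effects),
#'   `retained` (character vector of retained fixed terms), `emmeans`
#'   (tibble of genotype x night marginal means, or NULL when neither
#'   factor survives) and `messages` (convergence diagnostics, if any).
#' @export
fit_event_lmm <- function(data, response, alpha_drop = 0.05,
                          marginal_means = TRUE) {
  stopifnot(response %in% names(data), "subject" %in% names(data))
  fixed <- intersect(c("genotype", "night", "electrode", "sleep_stage"),
                     names(data))
  if (!all(c("genotype", "night") %in% fixed)) {
    stop("`genotype` and `night` columns are required", call. = FALSE)
  }
  data <- dplyr::mutate(
    data,
    dplyr::across(dplyr::all_of(c(fixed, "subject")), as.factor))
  if (nlevels(data$subject) < 2 || nlevels(data$night) < 2) {
    stop("need at least 2 subjects and 2 nights", call. = FALSE)
  }
  msgs <- character(0)
  fit_terms <- function(terms) {
    rhs <- paste(c(if (length(terms)) terms else "1", "(1 | subject)"),
                 collapse = " + ")
    form <- stats::as.formula(paste(response, "~", rhs))
    withCallingHandlers(
      do.call(lmerTest::lmer,
              list(formula = form, data = data, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  terms_now <- c(fixed, "genotype:night")
  full <- fit_terms(terms_now)
  fit <- full
  elim <- list()
  repeat {
    if (length(terms_now) == 0) break
    a <- stats::anova(fit, ddf = "Satterthwaite")
    inter <- grep(":", terms_now, value = TRUE)
    protected <- unique(unlist(strsplit(inter, ":")))
    eligible <- setdiff(terms_now, protected)
    p <- a[eligible, "Pr(>F)"]
    drop_terms <- eligible[!is.na(p) & p >= alpha_drop]
    for (tm in eligible) {
      elim[[length(elim) + 1L]] <- tibble::tibble(
        term = tm, f_value = a[tm, "F value"], p_value = a[tm, "Pr(>F)"],
        dropped = tm %in% drop_terms)
    }
    if (length(drop_terms) == 0) break
    terms_now <- setdiff(terms_now, drop_terms)
    fit <- fit_terms(terms_now)
  }
  retained <- terms_now
  emm <- NULL
  keep_gn <- intersect(c("genotype", "night"), unlist(strsplit(retained, ":")))
  if (marginal_means && length(keep_gn) > 0) {
    spec <- stats::as.formula(paste("~", paste(keep_gn, collapse = " * ")))
    emm <- suppressMessages(tibble::as_tibble(as.data.frame(
      emmeans::emmeans(fit, spec, lmer.df = "asymptotic"))))
  }
  structure(
    list(full = full, final = fit, elimination = dplyr::bind_rows(elim),
         retained = retained, emmeans = emm, messages = msgs),
    class = "nrem_lmm"
  )
}

#' @export
print.nrem_lmm <- function(x, ...) {
  cat("<nrem_lmm> retained fixed terms:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$emmeans)) {
    cat("marginal means:\n")
    print(x$emmeans)
  }
  if (length(x$messages)) {
    cat("fit messages:", paste(unique(x$messages), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Simulate per-event amplitudes for the mixed-model design
#'
#' Generates event-level observations for a two-genotype, two-night,
#' multi-electrode design with a subject random intercept and an optional
#' genotype x night interaction planted as an additive shift for one
#' genotype on night 2 — the structure against which the mixed-model
#' pipeline is validated.
#'
#' @param n_per_group Subjects per genotype group (default 10, i.e. a
#'   20-subject cohort).
#' @param electrodes Electrode labels (default the 9-channel montage).
#' @param events_per_cell Events per subject x night x electrode cell.
#' @param baseline_uV Grand-mean amplitude.
#' @param interaction_uV Shift added for `interaction_group` on night 2.
#' @param interaction_group Genotype receiving the night-2 shift.
#' @param subject_sd,residual_sd Random-intercept and residual SDs (uV).
#' @param stages Sleep-stage labels assigned cyclically to events.
#' @param seed Integer seed.
#' @return Tibble with `subject`, `genotype`, `night`, `electrode`,
#'   `sleep_stage`, `amplitude_uV`.
#' @export
simulate_event_amplitudes <- function(n_per_group = 10,
                                      electrodes = c("F3", "Fz", "F4", "C3",
                                                     "Cz", "C4", "Pz", "O1",
                                                     "O2"),
                                      events_per_cell = 200,
                                      baseline_uV = 75,
                                      interaction_uV = 5,
                                      interaction_group = "CC",
                                      subject_sd = 5, residual_sd = 10,
                                      stages = c("N2", "N3"),
                                      seed = 1L) {
  set.seed(as.integer(seed))
  genotypes <- c("CC", "AA")
  subj <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(2 * n_per_group)),
    genotype = rep(genotypes, each = n_per_group),
    u = stats::rnorm(2 * n_per_group, 0, subject_sd)
  )
  grid <- tidyr::expand_grid(
    subj, night = c("night1", "night2"), electrode = electrodes,
    event = seq_len(events_per_cell)
  )
  grid$sleep_stage <- stages[(grid$event - 1L) %% length(stages) + 1L]
  grid$amplitude_uV <- baseline_uV + grid$u +
    ifelse(grid$genotype == interaction_group & grid$night == "night2",
           interaction_uV, 0) +
    stats::rnorm(nrow(grid), 0, residual_sd)
  dplyr::select(grid, "subject", "genotype", "night", "electrode",
                "sleep_stage", "amplitude_uV")
}
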