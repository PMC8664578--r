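#' Configuration for synthetic motor-sequence-task keystroke logs
#'
#' Parameters of the simulated finger-tapping cohort: every subject types
#' the 4-1-3-2-4 sequence for 30 s per trial, 12 trials in the evening
#' (training) and 12 the next morning (test). Overnight consolidation is
#' planted as an additive gain in correct sequences per trial at test,
#' with a per-group multiplier on the between-subject gain SD so that one
#' group can be given more variable consolidation than the other.
#'
#' @param n_per_group Subjects per group.
#' @param groups Group labels (default the two rs1344706 genotype groups
#'   CC and AA).
#' @param trials_per_session Trials per session (default 12; at least 3,
#'   since session summaries average three trials).
#' @param trial_len_s Trial length in seconds (default 30).
#' @param base_ncs True correct sequences per trial at training.
#' @param session_gain Mean additive gain in correct sequences at test.
#' @param gain_sd Between-subject SD of the gain (correct sequences).
#' @param group_sd_multiplier Numeric vector (recycled over `groups`)
#'   multiplying `gain_sd` per group.
#' @param keypress_noise_ms SD of Gaussian jitter on every inter-press
#'   interval, ms.
#' @param error_rate Probability that a keypress is replaced by a wrong
#'   key (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `mst_sim_config`.
#' @export
mst_sim_config <- function(n_per_group = 20, groups = c("CC", "AA"),
                           trials_per_session = 12, trial_len_s = 30,
                           base_ncs = 20, session_gain = 4, gain_sd = 1.5,
                           group_sd_multiplier = 1,
                           keypress_noise_ms = 10, error_rate = 0.05,
                           seed = 1L) {
  if (trials_per_session < 3) {
    stop("session summaries need at least 3 trials", call. = FALSE)
  }
  stopifnot(gain_sd >= 0, keypress_noise_ms >= 0,
            error_rate >= 0, error_rate < 1, base_ncs > 0)
  structure(
    list(n_per_group = n_per_group, groups = groups,
         trials_per_session = trials_per_session, trial_len_s = trial_len_s,
         base_ncs = base_ncs, session_gain = session_gain,
         gain_sd = gain_sd,
         group_sd_multiplier = rep_len(group_sd_multiplier, length(groups)),
         keypress_noise_ms = keypress_noise_ms, error_rate = error_rate,
         seed = as.integer(seed)),
    class = "mst_sim_config"
  )
}

#' Generate synthetic MST keystroke logs
#'
#' Simulates timestamped keypresses for every subject, trial and session.
#' Each subject types at a constant nominal inter-press interval chosen so
#' that the trial holds the target number of correct sequences
#' (`trial_len_s * 1000 / (5 * target_ncs)` ms), with optional Gaussian
#' timing jitter and random wrong keypresses.
#'
#' @param config An [mst_sim_config()].
#' @return List with `logs` (tibble: `subject`, `group`, `session`,
#'   `trial`, `t_ms`, `key`) and `truth` (tibble: per-subject target NCS
#'   per session and true overnight improvement in percent).
#' @export
generate_mst_logs <- function(config) {
  stopifnot(inherits(config, "mst_sim_config"))
  set.seed(config$seed)
  seqkeys <- c(4L, 1L, 3L, 2L, 4L)
  log_rows <- list(); truth_rows <- list()
  sid <- 0L
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    sdm <- config$group_sd_multiplier[gi]
    for (i in seq_len(config$n_per_group)) {
      sid <- sid + 1L
      subject <- sprintf("S%03d", sid)
      gain <- config$session_gain +
        if (config$gain_sd * sdm > 0) {
          stats::rnorm(1, 0, config$gain_sd * sdm)
        } else 0
      targets <- c(training = config$base_ncs,
                   test = config$base_ncs + gain)
      for (session in c("training", "test")) {
        ncs_t <- targets[[session]]
        ipi <- config$trial_len_s * 1000 / (5 * ncs_t)
        for (trial in seq_len(config$trials_per_session)) {
          n_keys_max <- ceiling(config$trial_len_s * 1000 / ipi) + 10L
          gaps <- rep(ipi, n_keys_max)
          if (config$keypress_noise_ms > 0) {
            gaps <- gaps + stats::rnorm(n_keys_max, 0,
                                        config$keypress_noise_ms)
            gaps <- pmax(gaps, 1)
          }
          t_ms <- cumsum(gaps)
          keep <- t_ms <= config$trial_len_s * 1000
          t_ms <- t_ms[keep]
          keys <- rep_len(seqkeys, length(t_ms))
          if (config$error_rate > 0 && length(keys) > 0) {
            err <- stats::runif(length(keys)) < config$error_rate
            keys[err] <- vapply(keys[err], function(k) {
              sample(setdiff(1:4, k), 1)
            }, integer(1))
          }
          log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
            subject = subject, group = g, session = session,
            trial = trial, t_ms = t_ms, key = keys
          )
        }
      }
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        subject = subject, group = g,
        train_ncs = targets[["training"]], test_ncs = targets[["test"]],
        true_improvement_pct = 100 * gain / config$base_ncs
      )
    }
  }
  list(logs = dplyr::bind_rows(log_rows),
       truth = dplyr::bind_rows(truth_rows))
}
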