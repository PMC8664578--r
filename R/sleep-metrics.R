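#' Sleep architecture from a hypnogram
#'
#' Standard sleep continuity and architecture variables from a 30-s-epoch
#' hypnogram between lights-out and get-up: time in bed (TIB), total sleep
#' time (TST, minutes in N1/N2/N3/REM), sleep onset latency (SOL, lights
#' out to the first sleep epoch), wake after sleep onset (WASO), sleep
#' efficiency (100 TST / TIB) and each stage as a percentage of TST.
#'
#' @param hyp A [hypnogram()].
#' @param lights_out_epoch,got_up_epoch 0-based epoch indices bounding the
#'   time in bed (half-open: `[lights_out, got_up)`); default the whole
#'   hypnogram.
#' @return One-row tibble: `tib_min`, `tst_min`, `sol_min`, `waso_min`,
#'   `sleep_efficiency_pct`, `pct_N1` .. `pct_REM`, and `sol_defined`
#'   (FALSE when no sleep epoch exists, in which case SOL/WASO are `NA`).
#' @export
#' @examples
#' psg_architecture(hypnogram(c("W", "W", rep("N2", 14))))
psg_architecture <- function(hyp, lights_out_epoch = 0,
                             got_up_epoch = nrow(hyp)) {
  if (!(lights_out_epoch < got_up_epoch && got_up_epoch <= nrow(hyp))) {
    stop("need lights_out < got_up within the hypnogram", call. = FALSE)
  }
  st <- as.character(hyp$stage[(lights_out_epoch + 1):got_up_epoch])
  sleep_stages <- c("N1", "N2", "N3", "REM")
  asleep <- st %in% sleep_stages
  epw <- 0.5                              # minutes per 30-s epoch
  tib <- length(st) * epw
  tst <- sum(asleep) * epw
  if (any(asleep)) {
    first_sleep <- which(asleep)[1]
    sol <- (first_sleep - 1) * epw
    waso <- sum(st[first_sleep:length(st)] == "W") * epw
    sol_defined <- TRUE
  } else {
    sol <- NA_real_; waso <- NA_real_; sol_defined <- FALSE
  }
  pct <- vapply(sleep_stages, function(s) {
    if (tst > 0) 100 * sum(st == s) * epw / tst else NA_real_
  }, numeric(1))
  tibble::tibble(
    tib_min = tib, tst_min = tst, sol_min = sol, waso_min = waso,
    sleep_efficiency_pct = 100 * tst / tib,
    pct_N1 = pct[["N1"]], pct_N2 = pct[["N2"]], pct_N3 = pct[["N3"]],
    pct_REM = pct[["REM"]], sol_defined = sol_defined
  )
}

#' Actigraphy sleep variables for one or more nights
#'
#' Epoch-by-epoch (1-min) wake/sleep categorization by an activity-count
#' threshold within each night's in-bed window, yielding TIB, TST, sleep
#' efficiency, SOL and the fragmentation index (FI = mobile time percent
#' plus the percentage of immobile bouts lasting at most 1 min). Nights
#' whose window is entirely missing are flagged invalid.
#'
#' @param activity Tibble with per-minute `counts` and logical `missing`
#'   (see [generate_actigraphy()]); row i is minute i - 1.
#' @param lights_out_min,got_up_min Vectors (one element per night) of
#'   0-based minute indices bounding each night, half-open.
#' @param sleep_threshold Counts below this score a minute as sleep
#'   (default 20).
#' @param mobile_threshold Counts at or above this score a minute as
#'   mobile for the fragmentation index (default 4).
#' @return Tibble with one row per night (`night`, `tib_min`, `tst_min`,
#'   `sleep_efficiency_pct`, `sol_min`, `fragmentation_index`, `valid`).
#' @export
actigraphy_sleep <- function(activity, lights_out_min, got_up_min,
                             sleep_threshold = 20, mobile_threshold = 4) {
  stopifnot(length(lights_out_min) == length(got_up_min),
            all(lights_out_min < got_up_min))
  rows <- lapply(seq_along(lights_out_min), function(k) {
    idx <- (lights_out_min[k] + 1):got_up_min[k]
    cnt <- activity$counts[idx]
    mis <- activity$missing[idx]
    if (all(mis)) {
      return(tibble::tibble(night = k, tib_min = length(idx),
                            tst_min = NA_real_,
                            sleep_efficiency_pct = NA_real_,
                            sol_min = NA_real_,
                            fragmentation_index = NA_real_, valid = FALSE))
    }
    cnt <- cnt[!mis]
    asleep <- cnt < sleep_threshold
    tib <- length(cnt)
    tst <- sum(asleep)
    sol <- if (any(asleep)) which(asleep)[1] - 1 else NA_real_
    mobile <- cnt >= mobile_threshold
    mobile_pct <- 100 * mean(mobile)
    r <- rle(!mobile)
    ib <- r$lengths[r$values]              # immobile bout lengths, minutes
    short_pct <- if (length(ib) > 0) 100 * mean(ib <= 1) else 0
    tibble::tibble(night = k, tib_min = tib, tst_min = tst,
                   sleep_efficiency_pct = 100 * tst / tib, sol_min = sol,
                   fragmentation_index = mobile_pct + short_pct,
                   valid = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Average actigraphy nights
#'
#' Averages per-night actigraphy summaries over the valid nights, as done
#' when reducing a multi-night wear period to per-participant variables.
#'
#' @param nights Output of [actigraphy_sleep()].
#' @return One-row tibble of means over valid nights plus `n_nights`.
#' @export
average_actigraphy_nights <- function(nights) {
  ok <- nights[nights$valid, ]
  dplyr::summarise(
    ok,
    tib_min = mean(.data$tib_min), tst_min = mean(.data$tst_min),
    sleep_efficiency_pct = mean(.data$sleep_efficiency_pct),
    sol_min = mean(.data$sol_min),
    fragmentation_index = mean(.data$fragmentation_index),
    n_nights = dplyr::n()
  )
}

#' Non-parametric circadian rhythm analysis
#'
#' Computes inter-daily stability (IS), intra-daily variability (IV) and
#' the activity amplitude from 1-min actigraphy with missing-data flags.
#' The series is first aggregated to hourly means (an hour is valid when
#' at least half of its minutes are non-missing; a day is valid when at
#' least `min_valid_hours` of its hours are). Over the valid hourly
#' epochs:
#' \deqn{IS = \frac{n \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2}}
#' with p = 24 hour-of-day bins, and IV is the ratio of the mean squared
#' successive difference to the variance, with pairs spanning a missing
#' hour dropped. The amplitude is M10 - L5: the mean of the 10 most
#' active minus the 5 least active consecutive hours of the average 24-h
#' profile (circular windows). A summary with fewer than 7 valid days is
#' marked invalid.
#'
#' @param activity Tibble with per-minute `counts` and `missing`.
#' @param min_valid_hours Hours a day must retain to count (default 20).
#' @return One-row tibble: `is`, `iv`, `amplitude`, `days_used`, `valid`.
#' @export
npcra <- function(activity, min_valid_hours = 20) {
  n_min <- nrow(activity)
  n_hours <- n_min %/% 60
  if (n_hours < 24) stop("need at least one full day of data", call. = FALSE)
  cnt <- ifelse(activity$missing, NA_real_, activity$counts)
  cnt <- cnt[seq_len(n_hours * 60)]       # whole hours only
  hh <- factor(rep(seq_len(n_hours), each = 60), levels = seq_len(n_hours))
  hr_mean <- as.numeric(tapply(cnt, hh, function(v) {
    if (mean(!is.na(v)) >= 0.5) mean(v, na.rm = TRUE) else NA_real_
  }))
  day_of <- (seq_len(n_hours) - 1) %/% 24
  n_days <- n_hours %/% 24
  day_valid <- vapply(seq_len(n_days) - 1, function(d) {
    sum(!is.na(hr_mean[day_of == d])) >= min_valid_hours
  }, logical(1))
  days_used <- sum(day_valid)
  x <- hr_mean
  x[day_of >= n_days | !day_valid[day_of + 1]] <- NA  # drop invalid days
  hod <- (seq_len(n_hours) - 1) %% 24                  # hour of day, 0-23
  ok <- !is.na(x)
  n <- sum(ok)
  xbar <- mean(x[ok])
  ss_tot <- sum((x[ok] - xbar)^2)
  profile <- tapply(x[ok], factor(hod[ok], levels = 0:23), mean)
  is_val <- if (ss_tot > 0) {
    n * sum((profile - xbar)^2) / (24 * ss_tot)
  } else NA_real_
  d <- diff(x)
  d <- d[!is.na(d)]                                    # drops gap-spanning pairs
  iv_val <- if (ss_tot == 0) {
    0
  } else if (length(d) > 0) {
    (sum(d^2) / length(d)) / (ss_tot / (n - 1))
  } else NA_real_
  prof24 <- as.numeric(profile[as.character(0:23)])
  amp <- npcra_amplitude(prof24)
  tibble::tibble(is = is_val, iv = iv_val, amplitude = amp,
                 days_used = days_used, valid = days_used >= 7)
}

# M10 - L5 over circular windows of the 24-h mean profile
npcra_amplitude <- function(prof24) {
  if (anyNA(prof24)) return(NA_real_)
  circ_mean <- function(w) {
    vapply(0:23, function(s) mean(prof24[(s + 0:(w - 1)) %% 24 + 1]),
           numeric(1))
  }
  max(circ_mean(10)) - min(circ_mean(5))
}

#' Generate synthetic actigraphy
#'
#' Simulates per-minute activity counts from a 24-h template profile with
#' optional multiplicative log-normal noise, plus missing spans
#' (flagged, never zero-filled), emulating an actiwatch worn over several
#' days. The default template is quiescent overnight (23:00-07:00) with a
#' smooth daytime hump peaking mid-afternoon.
#'
#' @param days Number of days (>= 1).
#' @param profile Numeric vector of length 1440: expected counts per
#'   minute of day. Default as described.
#' @param noise_sd Log-normal sigma of multiplicative noise (0 = exact
#'   template).
#' @param missing_spans List of `c(start_min, end_min)` 0-based half-open
#'   minute ranges to flag missing.
#' @param seed Integer seed.
#' @return Tibble with `minute` (0-based), `counts`, `missing`.
#' @export
generate_actigraphy <- function(days, profile = default_activity_profile(),
                                noise_sd = 0, missing_spans = list(),
                                seed = 1L) {
  stopifnot(days >= 1, length(profile) == 1440)
  set.seed(as.integer(seed))
  n <- days * 1440L
  base <- rep(profile, days)
  counts <- if (noise_sd > 0) {
    base * stats::rlnorm(n, -noise_sd^2 / 2, noise_sd)
  } else base
  missing <- rep(FALSE, n)
  for (sp in missing_spans) {
    idx <- (sp[1] + 1):min(sp[2], n)
    missing[idx] <- TRUE
  }
  counts[missing] <- NA_real_
  tibble::tibble(minute = seq_len(n) - 1L, counts = counts,
                 missing = missing)
}

#' Default 24-h activity template
#' @return Numeric vector of 1440 expected counts per minute of day.
#' @export
default_activity_profile <- function() {
  m <- 0:1439
  h <- m / 60
  day <- h >= 7 & h < 23
  out <- numeric(1440)
  out[day] <- 250 * sin(pi * (h[day] - 7) / 16)^2 + 20
  out[!day] <- 2
  out
}
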