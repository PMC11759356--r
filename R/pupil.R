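#' Simulate pupil-area traces
#'
#' Generates eye-tracking traces as recorded during fMRI acquisitions:
#' pupil area in pixel units sampled at `fs` Hz, with completely white and
#' completely black screen reference segments at both ends of each trial
#' (constricting and dilating the pupil respectively), a group-specific
#' baseline area during the task, dilation at run start (exponentially
#' decaying) and during the stimulation window (Gaussian bump with equal
#' default amplitude across groups, matching the observation that both
#' groups dilate to similar peak levels), smooth noise, and optional
#' blink dropouts. Defaults emulate the reference study: FM-like baseline
#' 1920 and HC-like baseline 1540 pixel units (about 25% larger in FM),
#' 500 Hz sampling.
#'
#' @param group_params Named list per group; each entry may override
#'   `baseline`, `white_frac`, `black_frac`, `start_dilation`,
#'   `start_tau`, `stim_dilation`, `stim_sigma`, `noise_sd`,
#'   `blink_rate` (blinks/s), `blink_duration` (s).
#' @param n_trials Named integer vector of trials per group.
#' @param n_participants Named integer vector; trials are assigned to
#'   participants round-robin.
#' @param seed Integer seed; traces are fully deterministic under it.
#' @param fs Sampling rate, Hz.
#' @param task_duration Task (fMRI run) duration, seconds.
#' @param ref_duration Duration of each reference segment, seconds.
#' @param stimulus_onset,inform_time Event times within the task, seconds
#'   (clipped into short tasks).
#' @return Tibble: `group`, `participant`, `trial`, `time` (s from trial
#'   start), `screen_state` (`white`/`black`/`task`), `area`.
#' @export
simulate_pupil <- function(group_params = list(FM = list(baseline = 1920),
                                               HC = list(baseline = 1540)),
                           n_trials = c(FM = 125, HC = 45),
                           n_participants = c(FM = 26, HC = 10),
                           seed = 0, fs = 500, task_duration = 270,
                           ref_duration = 2, stimulus_onset = 120,
                           inform_time = 60) {
  abort_if(any(n_trials < 1), "n_trials must be >= 1 per group")
  defaults <- list(baseline = 1600, white_frac = 0.65, black_frac = 1.3,
                   start_dilation = 150, start_tau = 10,
                   stim_dilation = 150, stim_sigma = 8, noise_sd = 30,
                   blink_rate = 0.05, blink_duration = 0.15)
  seg <- function(state, dur) {
    n <- round(dur * fs)
    rep(state, n)
  }
  out <- list()
  idx <- 0L
  for (g in names(group_params)) {
    pars <- modifyList(defaults, group_params[[g]])
    npart <- n_participants[[g]] %||% max(1, ceiling(n_trials[[g]] / 5))
    stim_center <- if (task_duration >= stimulus_onset + 30)
      stimulus_onset + 15 else task_duration * 0.5
    states <- c(seg("white", ref_duration), seg("black", ref_duration),
                seg("task", task_duration),
                seg("white", ref_duration), seg("black", ref_duration))
    n <- length(states)
    tt <- (seq_len(n) - 1) / fs
    task_i <- which(states == "task")
    task_t <- tt[task_i] - tt[task_i[1]]
    for (tr in seq_len(n_trials[[g]])) {
      idx <- idx + 1L
      area <- with_seed(child_seed(seed, idx), {
        a <- numeric(n)
        a[states == "white"] <- pars$baseline * pars$white_frac
        a[states == "black"] <- pars$baseline * pars$black_frac
        task_area <- pars$baseline +
          pars$start_dilation * exp(-task_t / pars$start_tau) +
          pars$stim_dilation *
            exp(-(task_t - stim_center)^2 / (2 * pars$stim_sigma^2))
        a[task_i] <- task_area
        # smooth noise: low-pass filtered white noise
        noise <- stats::filter(rnorm(n, sd = pars$noise_sd),
                               rep(1 / 25, 25), sides = 2)
        noise[is.na(noise)] <- 0
        a <- a + as.numeric(noise) * 5
        # blink dropouts
        if (pars$blink_rate > 0) {
          n_blinks <- stats::rpois(1, pars$blink_rate * n / fs)
          if (n_blinks > 0) {
            starts <- sort(runif(n_blinks, 0, max(tt) - pars$blink_duration))
            for (b in starts) {
              a[tt >= b & tt < b + pars$blink_duration] <-
                runif(1, 0, 0.1) * pars$baseline
            }
          }
        }
        a
      })
      out[[idx]] <- tibble::tibble(
        group = g,
        participant = sprintf("%s%02d", g, ((tr - 1) %% npart) + 1),
        trial = tr, time = tt, screen_state = states, area = area
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Repair blink dropouts in a pupil trace
#'
#' Samples whose area falls below `threshold` times the local (running)
#' median are marked missing; gaps no longer than `max_gap` seconds are
#' linearly interpolated, longer gaps stay missing. Trials with more than
#' 50% missing samples are flagged unusable.
#'
#' @param trace Tibble for a single trial with columns `time`, `area`.
#' @param threshold Fraction of the local median below which a sample is
#'   treated as a dropout.
#' @param max_gap Longest interpolatable gap, seconds.
#' @param median_window Running-median window, seconds.
#' @return The trace with repaired `area`, plus attributes `usable`
#'   (logical) and `missing_fraction`.
#' @export
repair_blinks <- function(trace, threshold = 0.5, max_gap = 0.3,
                          median_window = 1) {
  abort_if(!all(c("time", "area") %in% names(trace)),
           "trace needs columns time, area")
  a <- trace$area
  n <- length(a)
  fs <- if (n > 1) 1 / stats::median(diff(trace$time)) else 1
  k <- max(3, round(median_window * fs))
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, if (n %% 2 == 0) n - 1 else n)
  local_med <- as.numeric(stats::runmed(a, k))
  # reference: local median, floored by the whole-trace median so that
  # dropouts longer than the median window are still caught
  ref <- pmax(local_med, stats::median(a))
  bad <- a < threshold * ref | a <= 0
  missing_fraction <- mean(bad)
  usable <- missing_fraction <= 0.5
  a[bad] <- NA_real_
  if (usable && any(bad) && any(!bad)) {
    # interpolate short gaps only
    r <- rle(is.na(a))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    filled <- approx(trace$time[!is.na(a)], a[!is.na(a)],
                     xout = trace$time, rule = 2)$y
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] / fs <= max_gap) {
        a[starts[i]:ends[i]] <- filled[starts[i]:ends[i]]
      }
    }
  }
  out <- trace
  out$area <- a
  attr(out, "usable") <- usable
  attr(out, "missing_fraction") <- missing_fraction
  out
}

#' Group mean pupil area and percent difference
#'
#' Per-trial mean area over the chosen period (missing samples excluded),
#' averaged within group. The percent difference between two group means
#' is `100 * (a - b) / b`; with the reference values 1920 (FM-like) and
#' 1540 (HC-like) pixel units this gives 24.7%, i.e. approximately 25%
#' larger pupil area.
#'
#' @param traces Tibble from [simulate_pupil()] (or same columns), blink
#'   dropouts repaired or marked `NA` beforehand as appropriate.
#' @param period Screen state(s) to average over (default `"task"`).
#' @return Tibble: `group`, `mean_area`, `n_trials`, `n_participants`;
#'   attribute `percent_difference` (first group vs second) when exactly
#'   two groups are present.
#' @export
group_mean_area <- function(traces, period = "task") {
  d <- traces[traces$screen_state %in% period & !is.na(traces$area), ]
  abort_if(nrow(d) == 0, "no usable samples in the requested period")
  per_trial <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$participant, .data$trial),
    area = mean(.data$area), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$group),
    mean_area = mean(.data$area),
    n_trials = dplyr::n(),
    n_participants = dplyr::n_distinct(.data$participant),
    .groups = "drop"
  )
  if (nrow(out) == 2) {
    attr(out, "percent_difference") <-
      pupil_percent_difference(out$mean_area[1], out$mean_area[2])
  }
  out
}

#' Percent difference between two pupil areas
#'
#' @param a,b Mean areas; result is `100 * (a - b) / b`.
#' @return Numeric scalar.
#' @export
pupil_percent_difference <- function(a, b) {
  abort_if(b <= 0, "reference area must be positive")
  100 * (a - b) / b
}

#' Average pupil traces on a common clock
#'
#' Resamples every trial to a common paradigm-locked grid by linear
#' interpolation, then reports the pointwise mean and standard error per
#' group.
#'
#' @param traces Tibble with `group`, `trial`, `time`, `area`.
#' @param grid Numeric vector of output times; default: the time grid of
#'   the first trial, thinned to at most 2000 points.
#' @return Tibble: `group`, `time`, `n`, `mean`, `sem`.
#' @export
average_trace <- function(traces, grid = NULL) {
  if (is.null(grid)) {
    t1 <- traces[traces$trial == traces$trial[1] &
                   traces$group == traces$group[1], ]
    grid <- t1$time
    if (length(grid) > 2000) grid <- grid[seq(1, length(grid), length.out = 2000)]
  }
  groups <- dplyr::group_by(traces, .data$group, .data$trial,
                            .data$participant)
  parts <- dplyr::group_split(groups)
  keys <- dplyr::group_keys(groups)
  resampled <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    d <- parts[[i]]
    rng <- range(d$time)
    abort_if(min(grid) < rng[1] - 1e-9 || max(grid) > rng[2] + 1e-9,
             "trial timing incompatible with the requested grid")
    ok <- !is.na(d$area)
    resampled[[i]] <- tibble::tibble(
      group = keys$group[i], trial = keys$trial[i], time = grid,
      area = approx(d$time[ok], d$area[ok], xout = grid, rule = 2)$y
    )
  }
  all <- dplyr::bind_rows(resampled)
  dplyr::summarise(
    dplyr::group_by(all, .data$group, .data$time),
    n = dplyr::n(), mean = mean(.data$area),
    sem = if (dplyr::n() > 1) sd(.data$area) / sqrt(dplyr::n()) else 0,
    .groups = "drop"
  )
}
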