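#' Quantify the pre-stimulus initial rise
#'
#' The initial rise is the increase in BOLD signal over roughly the first
#' 40 seconds of a run, before any stimulus. It is measured as the mean
#' over a plateau window minus the value at the first retained volume;
#' the plateau window default ends at 60 s, before the inform cue, so the
#' rise is not conflated with the cue response. `starting_point` is the
#' first retained value of the mean-centered course (the axis convention
#' of the published scatter plots: a negative starting point corresponds
#' to a positive rise). Both conventions are reported to avoid sign
#' ambiguity; the rise is invariant to adding a constant to the course.
#'
#' @param tc Numeric time course in % signal change (initial volumes
#'   already masked where applicable).
#' @param TR Seconds per volume.
#' @param rise_window Two numbers, seconds; the window over which the rise
#'   develops (its start locates the first retained volume).
#' @param plateau_window Two numbers, seconds.
#' @param n_masked Number of initially masked (replaced) volumes; the
#'   starting value is read at the first retained volume.
#' @return Tibble with `initial_rise`, `starting_point`.
#' @export
initial_rise <- function(tc, TR, rise_window = c(0, 40),
                         plateau_window = c(40, 60), n_masked = 0) {
  v <- initial_rise_values(tc, TR, rise_window, plateau_window, n_masked)
  tibble::tibble(initial_rise = v[1], starting_point = v[2])
}

initial_rise_values <- function(tc, TR, rise_window = c(0, 40),
                                plateau_window = c(40, 60), n_masked = 0) {
  n <- length(tc)
  tt <- (seq_len(n) - 1) * TR
  abort_if(plateau_window[2] > tt[n] + TR,
           "plateau window extends beyond the run")
  start_idx <- n_masked + 1
  abort_if(start_idx > n, "all volumes masked")
  abort_if(tt[start_idx] >= rise_window[2],
           "rise window contains only masked data")
  plate <- tc[tt >= plateau_window[1] & tt < plateau_window[2]]
  abort_if(length(plate) == 0, "plateau window contains no volumes")
  c(mean(plate) - tc[start_idx], tc[start_idx] - mean(tc))
}

#' Responses to stimulation onset and offset
#'
#' For Pain runs: the response to an event is the maximum over the 15 s
#' following it minus the mean over the 10 s preceding it (windows chosen
#' from standard hemodynamic latency; configurable). No-Pain runs have no
#' stimulation events; they are flagged undefined.
#'
#' @param tc Numeric time course, % signal change.
#' @param paradigm A `bold_paradigm`.
#' @param post_window Seconds after the event searched for the peak.
#' @param baseline_window Seconds before the event averaged as baseline.
#' @return Tibble with `onset_response`, `offset_response`, `flag`.
#' @export
event_responses <- function(tc, paradigm, post_window = 15,
                            baseline_window = 10) {
  stopifnot(inherits(paradigm, "bold_paradigm"))
  if (paradigm$condition != "Pain") {
    return(tibble::tibble(onset_response = NA_real_,
                          offset_response = NA_real_,
                          flag = "no stimulation in No-Pain runs"))
  }
  v <- event_response_values(tc, paradigm, post_window, baseline_window)
  tibble::tibble(onset_response = v[1], offset_response = v[2], flag = "")
}

event_response_values <- function(tc, paradigm, post_window = 15,
                                  baseline_window = 10) {
  tt <- (seq_along(tc) - 1) * paradigm$TR
  one <- function(event) {
    post <- tc[tt >= event & tt <= event + post_window]
    base <- tc[tt >= event - baseline_window & tt < event]
    abort_if(length(post) == 0 || length(base) == 0,
             "event windows contain no volumes")
    max(post) - mean(base)
  }
  onset <- paradigm$stimulus_onset
  c(one(onset), one(onset + paradigm$stim_duration))
}

#' Align the baselines of two time courses
#'
#' Shifts the second course vertically so the two starting values
#' coincide, as used when overlaying group-average responses that begin
#' at different baseline states.
#'
#' @param tc_a,tc_b Numeric time courses of equal length.
#' @return List: `a`, `b` (shifted), `shift` (amount added to `tc_b`).
#' @export
align_baselines <- function(tc_a, tc_b) {
  abort_if(length(tc_a) != length(tc_b), "time courses differ in length")
  shift <- tc_a[1] - tc_b[1]
  list(a = tc_a, b = tc_b + shift, shift = shift)
}

#' Extract time-course features for every analysis unit
#'
#' Applies [initial_rise()] and (for Pain runs) [event_responses()] within
#' every participant/group/condition/run/region cell of a tidy time-course
#' table, yielding the feature table consumed by the group-level
#' statistics.
#'
#' @param data Tidy tibble with `region`, `t`, `bold` and unit columns.
#' @param paradigm A `bold_paradigm` (provides TR and event timing).
#' @param n_masked Initially masked volumes (3 for brain, 2 for
#'   brainstem/cord acquisitions).
#' @param ... Passed to [initial_rise()].
#' @return Tibble: unit columns, `region`, `initial_rise`,
#'   `starting_point`, `onset_response`, `offset_response`, `flag`.
#' @export
timecourse_features <- function(data, paradigm, n_masked = 0, ...) {
  keys <- intersect(c("participant", "group", "condition", "run", "region"),
                    names(data))
  d <- dplyr::arrange(data,
                      dplyr::across(dplyr::all_of(c(keys, "t"))))
  gid <- do.call(paste, c(lapply(keys, function(k) d[[k]]), sep = "\r"))
  idx <- split(seq_len(nrow(d)), factor(gid, levels = unique(gid)))
  n_g <- length(idx)
  ir_v <- sp_v <- on_v <- off_v <- numeric(n_g)
  flag_v <- character(n_g)
  first_row <- integer(n_g)
  for (i in seq_len(n_g)) {
    rows <- idx[[i]]
    first_row[i] <- rows[1]
    b <- d$bold[rows]
    ir <- initial_rise_values(b, TR = paradigm$TR, n_masked = n_masked, ...)
    ir_v[i] <- ir[1]
    sp_v[i] <- ir[2]
    unit_cond <- if ("condition" %in% keys) d$condition[rows[1]]
                 else paradigm$condition
    if (unit_cond == "Pain") {
      er <- event_response_values(b, paradigm)
      on_v[i] <- er[1]
      off_v[i] <- er[2]
      flag_v[i] <- ""
    } else {
      on_v[i] <- NA_real_
      off_v[i] <- NA_real_
      flag_v[i] <- "no stimulation in No-Pain runs"
    }
  }
  out <- tibble::as_tibble(d[first_row, keys, drop = FALSE])
  out$initial_rise <- ir_v
  out$starting_point <- sp_v
  out$onset_response <- on_v
  out$offset_response <- off_v
  out$flag <- flag_v
  out
}
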