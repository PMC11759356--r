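#' Define a threat/safety stimulation paradigm
#'
#' Encodes the run design used throughout: a run of fixed duration during
#' which the participant is informed at `inform_time` whether a noxious
#' stimulus will follow; in `Pain` runs a block of brief heat contacts
#' starts at `stimulus_onset` (defaults: 10 contacts of 1.5 s with onsets
#' every 3 s, i.e. a 30 s block); `NoPain` runs carry no stimulation.
#' Default timing: 4.5-minute runs, inform cue at 1 minute, stimulation at
#' 2 minutes. The brain acquisition uses TR = 2 s (135 volumes/run); the
#' brainstem/cord acquisition uses TR = 6.75 s (40 volumes/run).
#'
#' @param condition `"Pain"` or `"NoPain"`.
#' @param TR Repetition time, seconds per volume.
#' @param run_duration Run length in seconds (default 270 = 4.5 min).
#' @param inform_time Time of the stimulus-type cue, seconds.
#' @param stimulus_onset Start of the stimulation block, seconds.
#' @param n_contacts Number of heat contacts.
#' @param contact_duration Duration of each contact, seconds.
#' @param onset_interval Interval between contact onsets, seconds.
#'
#' @return A `bold_paradigm`: list with the arguments plus `n_volumes`,
#'   `time` (volume onset times, seconds, 0-based index times TR),
#'   `stimulus` (0/1 indicator per volume), `stim_duration` (seconds; 0 for
#'   NoPain).
#' @export
#' @examples
#' p <- make_paradigm("Pain", TR = 2)
#' p$n_volumes      # 135
#' sum(p$stimulus)  # volumes within the 30-s stimulation block
make_paradigm <- function(condition = c("Pain", "NoPain"), TR = 2,
                          run_duration = 270, inform_time = 60,
                          stimulus_onset = 120, n_contacts = 10,
                          contact_duration = 1.5, onset_interval = 3) {
  condition <- match.arg(condition)
  abort_if(TR <= 0 || run_duration <= 0, "TR and run_duration must be positive")
  n_volumes <- run_duration / TR
  abort_if(abs(n_volumes - round(n_volumes)) > 1e-9,
           sprintf("run_duration / TR = %.4f is not an integer volume count",
                   n_volumes))
  n_volumes <- as.integer(round(n_volumes))
  stim_duration <- n_contacts * onset_interval
  if (condition == "Pain") {
    abort_if(stimulus_onset + stim_duration > run_duration,
             "stimulation block extends beyond the run")
  } else {
    stim_duration <- 0
  }
  time <- (seq_len(n_volumes) - 1) * TR
  stimulus <- if (condition == "Pain") {
    as.integer(time >= stimulus_onset & time < stimulus_onset + n_contacts * onset_interval)
  } else {
    integer(n_volumes)
  }
  structure(
    list(condition = condition, TR = TR, run_duration = run_duration,
         inform_time = inform_time, stimulus_onset = stimulus_onset,
         n_contacts = n_contacts, contact_duration = contact_duration,
         onset_interval = onset_interval, n_volumes = n_volumes,
         time = time, stimulus = stimulus, stim_duration = stim_duration),
    class = "bold_paradigm"
  )
}

#' @export
print.bold_paradigm <- function(x, ...) {
  cat(sprintf("<bold_paradigm> %s: %g s run, TR %g s, %d volumes%s\n",
              x$condition, x$run_duration, x$TR, x$n_volumes,
              if (x$condition == "Pain")
                sprintf(", %g s stimulation from %g s", x$stim_duration,
                        x$stimulus_onset) else ""))
  invisible(x)
}

# Gamma-shaped hemodynamic kernel sampled on the volume grid; peak ~5 s.
hemodynamic_kernel <- function(TR, peak = 5, length_s = 30) {
  t <- seq(0, length_s, by = TR)
  shape <- 6
  rate <- (shape - 1) / peak  # gamma mode (shape-1)/rate sits at `peak`
  h <- stats::dgamma(t, shape = shape, rate = rate)
  if (sum(h) > 0) h <- h / max(h)
  h
}

# Convolve an impulse/indicator vector with the hemodynamic kernel,
# truncated to the run length.
convolve_hrf <- function(x, TR, peak = 5) {
  h <- hemodynamic_kernel(TR, peak = peak)
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out[seq_len(n)]
}
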