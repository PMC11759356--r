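# Shared fixtures: small, fully identified networks so closed-loop tests
# are well posed, plus quiet fitting helpers.

tiny_cycle_net <- function() {
  network_model(
    regions = c("A", "B", "C"),
    edges = list(c("A", "B"), c("B", "C"), c("C", "A")),
    latents = list(c("L0", "A"), c("L1", "B")),
    name = "tiny_cycle"
  )
}

two_region_cycle <- function(db = 0.5) {
  net <- network_model(
    regions = c("A", "B"),
    edges = list(c("A", "B"), c("B", "A")),
    latents = list(c("L", "A")),
    name = "two_cycle"
  )
  list(net = net,
       DB = setNames(c(db, db, 0.8), connection_labels(net)))
}

quiet_fit <- function(...) suppressWarnings(fit_sapm(...))

# short Pain paradigm for fast fits
short_paradigm <- function(TR = 2, run_duration = 120) {
  make_paradigm("Pain", TR = TR, run_duration = run_duration,
                inform_time = 30, stimulus_onset = 60, n_contacts = 5,
                onset_interval = 3)
}
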