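test_that("paradigm arithmetic reproduces the acquisition geometry", {
  brain <- make_paradigm("Pain", TR = 2)
  expect_equal(brain$n_volumes, 135)
  cord <- make_paradigm("Pain", TR = 6.75)
  expect_equal(cord$n_volumes, 40)
  # stimulation block: 10 onsets every 3 s = 30 s, inside the run
  expect_equal(brain$stim_duration, 30)
  expect_equal(sum(brain$stimulus) * brain$TR, 30)
  expect_equal(sum(cord$stimulus), 5)  # coarse volumes whose onset falls in the block
  expect_true(all(brain$time[brain$stimulus == 1] >= 120))
  expect_true(all(brain$time[brain$stimulus == 1] < 150))
  nopain <- make_paradigm("NoPain", TR = 2)
  expect_equal(sum(nopain$stimulus), 0)
  expect_equal(nopain$stim_duration, 0)
  expect_length(brain$stimulus, brain$n_volumes)
})

test_that("paradigm construction rejects inconsistent timing", {
  expect_error(make_paradigm("Pain", TR = 2, run_duration = 271),
               "not an integer")
  expect_error(make_paradigm("Pain", TR = 2, run_duration = 140,
                             stimulus_onset = 120),
               "beyond the run")
  # the same block is fine in a NoPain run (no stimulation applied)
  expect_silent(make_paradigm("NoPain", TR = 2, run_duration = 140,
                              stimulus_onset = 120))
})

test_that("latent generation is seeded, event-locked and zeroable", {
  net <- tiny_cycle_net()
  p <- make_paradigm("Pain", TR = 2)
  cfg <- sim_config(net, seed = 4)
  U1 <- generate_latents(p, cfg, seed = 11)
  U2 <- generate_latents(p, cfg, seed = 11)
  expect_identical(U1, U2)
  U3 <- generate_latents(p, cfg, seed = 12)
  expect_false(identical(U1, U3))
  expect_equal(dim(U1), c(2, 135))

  # zero amplitudes produce identically zero latents
  cfg0 <- sim_config(net, event_amplitude = 0, fluctuation_amplitude = 0,
                     initial_rise = list(amplitude = 0))
  expect_true(all(generate_latents(p, cfg0, seed = 1) == 0))

  # a local maximum within 15 s after stimulation onset (hemodynamic lag)
  cfg_ev <- sim_config(net, fluctuation_amplitude = 0,
                       initial_rise = list(amplitude = 0))
  U <- generate_latents(p, cfg_ev, seed = 3)
  win <- which(p$time >= 120 & p$time <= 135)
  for (k in 1:2) {
    i_max <- win[which.max(U[k, win])]
    expect_gt(U[k, i_max], U[k, i_max - 1])
    expect_gt(U[k, i_max], max(U[k, (i_max + 3):(i_max + 6)]))
  }
})

test_that("with all DB zero, BOLD appears only at latent targets, proportional to the latent", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  labels <- connection_labels(net)
  cfg <- sim_config(net, true_DB = setNames(rep(0, 5), labels), noise_sd = 0,
                    n_participants = c(HC = 1), n_runs = 1)
  tc <- simulate_bold(cfg, p)
  U <- generate_latents(p, cfg, seed = boldnet:::child_seed(cfg$seed, 1))
  # C receives no latent: identically zero
  expect_equal(max(abs(tc$bold[tc$region == "C"])), 0)
  # A's course equals its D-weighted latent (D = 1/2: edge C->A plus L0)
  expect_equal(tc$bold[tc$region == "A"], 0.5 * U["L0", ], tolerance = 1e-12)
})

test_that("noise-free simulation satisfies the forward model equations exactly", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, noise_sd = 0, n_participants = c(HC = 1), n_runs = 1)
  tc <- simulate_bold(cfg, p)
  U <- generate_latents(p, cfg, seed = boldnet:::child_seed(cfg$seed, 1))
  mats <- build_matrices(net, cfg$true_D, cfg$true_B)
  fwd <- solve_forward(mats, U)
  Y <- boldnet:::tc_matrix(tc, net)
  expect_equal(unname(Y), unname(fwd$S_input), tolerance = 1e-12)
})

test_that("the generative model is linear in the latents", {
  net <- tiny_cycle_net()
  cfg <- sim_config(net)
  mats <- build_matrices(net, cfg$true_D, cfg$true_B)
  U <- matrix(rnorm(2 * 30), 2, 30)
  f1 <- solve_forward(mats, U)
  f2 <- solve_forward(mats, 3 * U)
  expect_equal(f2$S_input, 3 * f1$S_input, tolerance = 1e-12)
  expect_equal(f2$S_output, 3 * f1$S_output, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, n_participants = c(FM = 2, HC = 1), n_runs = 2,
                    seed = 9)
  tc1 <- simulate_bold(cfg, p)
  tc2 <- simulate_bold(cfg, p)
  expect_identical(tc1$bold, tc2$bold)
  cfg2 <- sim_config(net, n_participants = c(FM = 2, HC = 1), n_runs = 2,
                     seed = 10)
  expect_false(identical(simulate_bold(cfg2, p)$bold, tc1$bold))
})

test_that("a non-dissipative network is rejected", {
  two <- two_region_cycle(db = 1.1)  # spectral radius 1.1 > 1
  cfg <- sim_config(two$net, true_DB = two$DB)
  expect_error(simulate_bold(cfg, short_paradigm()), "spectral radius")
})

test_that("sim_config validates the D weighting structure", {
  net <- tiny_cycle_net()
  expect_error(sim_config(net, noise_sd = -1), "noise_sd")
  badD <- uniform_D(net)
  badD[1] <- badD[1] * 2
  expect_error(sim_config(net, true_D = badD), "sum to 1")
  # uniform D sums to 1 per region by construction
  D <- uniform_D(net)
  tg <- boldnet:::connection_targets(net)
  expect_true(all(abs(tapply(D, tg, sum) - 1) < 1e-12))
})

test_that("voxel simulation has the configured sub-region geometry", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, n_participants = c(HC = 1), n_runs = 1, seed = 2)
  tc <- simulate_bold(cfg, p)
  sub <- make_subregion_timecourses(tc, n_subregions = 5, divergence = 0.4,
                                    seed = 1)
  vox <- simulate_voxels(sub[, c("region", "subregion", "t", "bold")],
                         voxels_per_subregion = 10, within_sd = 0.1, seed = 3)
  m <- voxel_matrix(vox, "A")
  expect_equal(nrow(m), 50)  # 5 sub-regions x 10 voxels
  expect_equal(ncol(m), p$n_volumes)
  # within_sd = 0: all voxels in a sub-region identical
  vox0 <- simulate_voxels(sub[, c("region", "subregion", "t", "bold")],
                          voxels_per_subregion = 3, within_sd = 0, seed = 3)
  m0 <- voxel_matrix(vox0, "A")
  lab <- vox0[vox0$region == "A" & vox0$t == 0, ]
  for (s in 1:5) {
    rows <- m0[lab$subregion_true == s, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
  }
  expect_error(simulate_voxels(sub, voxels_per_subregion = 0), ">= 1")
})

test_that("pupil traces carry references at both ends and honour the seed", {
  traces <- simulate_pupil(n_trials = c(FM = 2, HC = 2),
                           n_participants = c(FM = 2, HC = 2),
                           seed = 5, fs = 50, task_duration = 20)
  t1 <- traces[traces$group == "FM" & traces$trial == 1, ]
  states <- rle(t1$screen_state)$values
  expect_equal(states, c("white", "black", "task", "white", "black"))
  traces2 <- simulate_pupil(n_trials = c(FM = 2, HC = 2),
                            n_participants = c(FM = 2, HC = 2),
                            seed = 5, fs = 50, task_duration = 20)
  expect_identical(traces$area, traces2$area)
  # zero blink rate: no dropout samples
  nb <- simulate_pupil(group_params = list(HC = list(baseline = 1540,
                                                     blink_rate = 0)),
                       n_trials = c(HC = 3), n_participants = c(HC = 2),
                       seed = 1, fs = 50, task_duration = 20)
  expect_gt(min(nb$area), 0.4 * 1540)
})
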