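test_that("build_matrices lays parameters on the topology", {
  # no edges: all-zero region matrices, latent blocks carry D / DB
  net0 <- network_model("A", latents = list(c("L", "A")))
  m0 <- build_matrices(net0, uniform_D(net0), setNames(0.7, "L->A"))
  expect_true(all(m0$M_input == 0) && all(m0$M_output == 0))
  expect_equal(m0$Lat_D["A", "L"], 1)
  expect_equal(m0$Lat_DB["A", "L"], 0.7)

  # single edge placement: M_output[target, source] = D * B
  net1 <- network_model(c("A", "B"), list(c("A", "B")),
                        list(c("L", "A")))
  D <- uniform_D(net1)
  B <- setNames(c(0.5, 1), connection_labels(net1))
  m1 <- build_matrices(net1, D, B)
  expect_equal(m1$M_output["B", "A"], 0.5)   # D = 1 (B's only input)
  expect_equal(m1$M_input["B", "A"], 1)
  expect_equal(diag(m1$M_output), c(A = 0, B = 0))
  expect_error(build_matrices(net1, D[1], B), "named over")
})

test_that("forward solve matches symbolic solutions for 2-region systems", {
  U <- matrix(rnorm(40), 1, 40)
  # chain L -> A -> B with edge gain g: S_out(B) = g * S_out(A)
  chain <- network_model(c("A", "B"), list(c("A", "B")), list(c("L", "A")))
  g <- 0.6
  B <- setNames(c(g, 0.9), connection_labels(chain))
  mats <- build_matrices(chain, uniform_D(chain), B)
  fwd <- solve_forward(mats, U)
  expect_equal(fwd$S_output["B", ], g * fwd$S_output["A", ],
               tolerance = 1e-12)
  expect_equal(fwd$S_output["A", ], 0.9 * U[1, ], tolerance = 1e-12)
  # S_input(B) = D * S_out(A) = S_out(A)
  expect_equal(fwd$S_input["B", ], fwd$S_output["A", ], tolerance = 1e-12)

  # cycle with DB 0.5 both ways: S_out(A) = drive / (1 - 0.25)
  two <- two_region_cycle(db = 0.5)
  D2 <- uniform_D(two$net)
  mats2 <- build_matrices(two$net, D2, two$DB / D2)
  fwd2 <- solve_forward(mats2, U)
  drive <- 0.8 * U[1, ]  # latent DB at A
  expect_equal(fwd2$S_output["A", ], drive / (1 - 0.25), tolerance = 1e-12)
  expect_equal(fwd2$S_output["B", ], 0.5 * drive / (1 - 0.25),
               tolerance = 1e-12)

  # all edge DB zero: output equals the latent drive at target regions only
  DB0 <- setNames(c(0, 0, 0.8), connection_labels(two$net))
  fwd0 <- solve_forward(build_matrices(two$net, D2, DB0 / D2), U)
  expect_equal(fwd0$S_output["A", ], 0.8 * U[1, ], tolerance = 1e-12)
  expect_equal(max(abs(fwd0$S_output["B", ])), 0)
})

test_that("forward solve refuses non-dissipative weightings, naming the radius", {
  two <- two_region_cycle(db = 1.2)
  D2 <- uniform_D(two$net)
  mats <- build_matrices(two$net, D2, two$DB / D2)
  expect_error(solve_forward(mats, matrix(0, 1, 5)), "spectral radius 1.2")
})

test_that("noise-free closed loop recovers every identified DB within 1e-3", {
  net <- brain_network()
  p <- make_paradigm("Pain", TR = 2)
  cfg <- sim_config(net, noise_sd = 0, n_participants = c(HC = 1), n_runs = 1,
                    initial_rise = list(amplitude = 0), seed = 6)
  tc <- simulate_bold(cfg, p)
  fit <- quiet_fit(tc, net, fit_config(n_restarts = 3, tol = 1e-10))
  truth <- attr(tc, "truth")
  td <- tidy(fit)
  expect_lt(max(abs(td$DB - truth$DB)[td$identified]), 1e-3)
  expect_true(all(fit_quality(fit)$R2 > 0.999))
  expect_equal(sum(td$identified), 9)
})

test_that("a single latent-fed region yields the observed course as latent, R2 = 1", {
  net <- network_model("A", latents = list(c("L", "A")))
  y <- as.numeric(scale(cumsum(rnorm(60)), scale = FALSE))
  Y <- matrix(y, 1, 60, dimnames = list("A", NULL))
  fit <- quiet_fit(Y, net, fit_config(n_restarts = 2))
  # S_input(A) = D * u = u, so the latent estimate is the observed course
  expect_equal(as.numeric(fit$latents["L", ]), y, tolerance = 1e-8)
  expect_equal(fit$R2$R2, 1, tolerance = 1e-10)
})

test_that("structured data is better explained than white noise", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, noise_sd = 0.3, n_participants = c(HC = 1),
                    n_runs = 1, seed = 1)
  tc <- simulate_bold(cfg, p)
  fit_s <- quiet_fit(tc, net, fit_config(n_restarts = 3))
  Y <- withr::with_seed(99, matrix(rnorm(3 * p$n_volumes), 3, p$n_volumes,
                                   dimnames = list(net$regions, NULL)))
  fit_n <- quiet_fit(Y, net, fit_config(n_restarts = 3))
  expect_gt(mean(fit_quality(fit_s)$R2), mean(fit_quality(fit_n)$R2))
})

test_that("fits are deterministic and their objective trace is non-increasing", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, noise_sd = 0.2, n_participants = c(HC = 1),
                    n_runs = 1, seed = 3)
  tc <- simulate_bold(cfg, p)
  f1 <- quiet_fit(tc, net, fit_config(n_restarts = 2, seed = 11))
  f2 <- quiet_fit(tc, net, fit_config(n_restarts = 2, seed = 11))
  expect_identical(tidy(f1)$DB, tidy(f2)$DB)
  expect_identical(f1$latents, f2$latents)
  expect_true(all(diff(f1$objective_trace) <= 1e-10))
})

test_that("fitted parameters respect the weighting invariants", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, noise_sd = 0.25, n_participants = c(HC = 1),
                    n_runs = 1, seed = 8)
  fit <- quiet_fit(simulate_bold(cfg, p), net, fit_config(n_restarts = 2))
  td <- tidy(fit)
  expect_true(all(td$D >= 0))
  tg <- td$to
  expect_true(all(abs(tapply(td$D, tg, sum) - 1) < 1e-12))
  expect_equal(td$DB, td$D * td$B, tolerance = 1e-12)
  expect_true(all(fit_quality(fit)$R2 <= 1 + 1e-12))
  # doubling the latents doubles the prediction (forward linearity)
  mats <- build_matrices(net, setNames(td$D, td$connection),
                         setNames(td$B, td$connection))
  f1 <- solve_forward(mats, fit$latents)
  f2 <- solve_forward(mats, 2 * fit$latents)
  expect_equal(f2$S_input, 2 * f1$S_input, tolerance = 1e-12)
})

test_that("fit_quality matches a brute-force variance decomposition", {
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, noise_sd = 0.3, n_participants = c(HC = 1),
                    n_runs = 1, seed = 4)
  tc <- simulate_bold(cfg, p)
  fit <- quiet_fit(tc, net, fit_config(n_restarts = 2))
  Y <- boldnet:::tc_matrix(tc, net)
  Y <- Y - rowMeans(Y)
  for (i in seq_along(net$regions)) {
    r2_brute <- 1 - sum((Y[i, ] - fit$S_input[i, ])^2) / sum(Y[i, ]^2)
    expect_equal(fit$R2$R2[i], r2_brute, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  net <- tiny_cycle_net()
  Y <- matrix(rnorm(3 * 30), 3, 30, dimnames = list(net$regions, NULL))
  Y[2, 5] <- NA
  expect_error(quiet_fit(Y, net), "non-finite")
  d <- tibble::tibble(participant = rep(c("a", "b"), each = 3),
                      region = "A", t = rep(0:2, 2), bold = rnorm(6))
  expect_error(fit_sapm(d, net), "multiple participant")
  expect_error(fit_sapm(tibble::tibble(region = "A", t = 0:9,
                                       bold = rnorm(10)), net),
               "missing time courses")
  nolat <- network_model(c("A", "B"), list(c("A", "B"), c("B", "A")))
  expect_error(fit_sapm(matrix(0, 2, 10,
                               dimnames = list(c("A", "B"), NULL)), nolat),
               "latent")
})

test_that("identifiability analysis flags sinks and exact trade-offs", {
  # chain into a sink: edge B value cannot reach any observable
  chain <- network_model(c("A", "B"), list(c("A", "B")), list(c("L", "A")))
  ids <- connection_identifiability(chain)
  expect_equal(ids$status[ids$connection == "A->B"], "sink")
  # fully recurrent: everything identified
  expect_true(all(connection_identifiability(tiny_cycle_net())$identified))
  # collinear outputs (two parallel single-input chains into one target)
  par_net <- network_model(
    c("A", "B", "C", "D"),
    list(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D"), c("D", "A")),
    list(c("L", "A"))
  )
  ids2 <- connection_identifiability(par_net)
  expect_true(all(c("B->D", "C->D") %in%
                    ids2$connection[ids2$status == "degenerate"]))
})
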