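test_that("Bonferroni thresholds reproduce the published family corrections", {
  expect_equal(fwe_threshold(0.05, 1), 0.05)
  # the published network-wide corrections: 32 and 52 tested connections
  expect_equal(fwe_threshold(0.05, 32), 0.0015625)
  expect_equal(fwe_threshold(0.05, 52), 0.00096, tolerance = 2e-3)
  expect_equal(round(fwe_threshold(0.05, 52), 5), 0.00096)
  # doubling the family halves the per-connection threshold exactly
  for (m in c(3, 10, 26)) {
    expect_equal(fwe_threshold(0.05, 2 * m), fwe_threshold(0.05, m) / 2)
  }
  expect_error(fwe_threshold(0, 10), "alpha")
  expect_error(fwe_threshold(1.2, 10), "alpha")
  expect_error(fwe_threshold(0.05, 0), "n_connections")
})

test_that("null generation is reproducible and matched to its dimensions", {
  net <- tiny_cycle_net()
  n1 <- generate_null(net, n_time = 30, reps = 2,
                      cfg = fit_config(n_restarts = 1), seed = 7)
  n2 <- generate_null(net, n_time = 30, reps = 2,
                      cfg = fit_config(n_restarts = 1), seed = 7)
  expect_identical(n1$samples$DB, n2$samples$DB)
  expect_equal(nrow(n1$samples), 2 * n_connections(net))
  expect_error(generate_null(net, 30, reps = 0), "reps")

  group <- tibble::tibble(connection = rep("A->B", 3), DB = c(0.1, 0.2, 0.3))
  expect_error(connection_ttest(group, n1, n_time = 40), "does not match")
  bad <- tibble::tibble(connection = rep("X->Y", 3), DB = c(0.1, 0.2, 0.3))
  expect_error(connection_ttest(bad, n1), "lacks samples")
})

test_that("group values identical to the null sample give T = 0, p = 1", {
  net <- network_model("A", latents = list(c("L", "A")))
  null <- structure(
    list(samples = tibble::tibble(rep = 1:4, connection = "L->A",
                                  DB = c(-1, 0, 1, 2)),
         network = "m", connections = "L->A", n_time = 10, reps = 4,
         seed = 0),
    class = "null_distribution")
  group <- tibble::tibble(connection = rep("L->A", 4), DB = c(-1, 0, 1, 2))
  st <- connection_ttest(group, null)
  expect_equal(st$T, 0, tolerance = 1e-12)
  expect_equal(st$p, 1, tolerance = 1e-12)
  expect_false(st$significant)
})

test_that("connection T-tests match a hand-computed Welch oracle", {
  set.seed(31)
  x <- rnorm(12, 0.4, 0.3)
  y <- rnorm(200, 0.05, 0.25)
  null <- structure(
    list(samples = tibble::tibble(rep = seq_along(y), connection = "c1",
                                  DB = y),
         network = "m", connections = "c1", n_time = 10,
         reps = length(y), seed = 0),
    class = "null_distribution")
  st <- connection_ttest(tibble::tibble(connection = "c1", DB = x), null,
                         alpha = 0.05)
  # Welch statistic and Welch-Satterthwaite df from first principles
  se2x <- var(x) / length(x); se2y <- var(y) / length(y)
  T_o <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_o <- (se2x + se2y)^2 /
    (se2x^2 / (length(x) - 1) + se2y^2 / (length(y) - 1))
  p_o <- 2 * pt(-abs(T_o), df_o)
  expect_equal(st$T, T_o, tolerance = 1e-10)
  expect_equal(st$df, df_o, tolerance = 1e-10)
  expect_equal(st$p, p_o, tolerance = 1e-10)
  expect_equal(st$mean, mean(x))
  expect_equal(st$sem, sd(x) / sqrt(length(x)))
})

test_that("a strong simulated connection is detected at the corrected threshold", {
  net <- brain_network()
  p <- make_paradigm("Pain", TR = 2)
  # the null-mean uncertainty scales as null_sd/sqrt(reps); the published
  # analysis used 10,000 replicates, and detection of strong connections
  # needs the null mean pinned well below the group sem
  null <- generate_null(net, p$n_volumes, reps = 400,
                        cfg = fit_config(n_restarts = 1), seed = 3)
  truth <- default_true_DB(net)
  truth["AC->PC"] <- 0.5
  hits <- 0
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(net, true_DB = truth, noise_sd = 0.2,
                      n_participants = c(FM = 15), seed = 100 + r)
    tc <- simulate_bold(cfg, p)
    pdb <- suppressWarnings(
      fit_sapm_groups(tc, net, fit_config(n_restarts = 2, seed = r)))
    st <- connection_ttest(pdb[, c("connection", "DB")], null, alpha = 0.05)
    if (st$significant[st$connection == "AC->PC"]) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("zero-variance comparisons are flagged undefined", {
  null <- structure(
    list(samples = tibble::tibble(rep = 1:3, connection = "c1",
                                  DB = rep(0.2, 3)),
         network = "m", connections = "c1", n_time = 10, reps = 3, seed = 0),
    class = "null_distribution")
  st <- connection_ttest(tibble::tibble(connection = "c1",
                                        DB = rep(0.2, 4)), null)
  expect_true(is.na(st$T))
  expect_equal(st$flag, "zero-variance")
  # non-identified connections (all-NA group DB) are flagged, not tested
  st2 <- connection_ttest(tibble::tibble(connection = "c1",
                                         DB = rep(NA_real_, 4)), null)
  expect_equal(st2$flag, "non-identified")
  expect_false(st2$significant)
})

test_that("p-values are valid and the FWE flag matches the threshold rule", {
  net <- tiny_cycle_net()
  null <- generate_null(net, 30, reps = 60,
                        cfg = fit_config(n_restarts = 1), seed = 2)
  pdb <- dplyr::bind_rows(lapply(1:5, function(j) {
    Y <- withr::with_seed(200 + j,
                          matrix(rnorm(3 * 30), 3, 30,
                                 dimnames = list(net$regions, NULL)))
    f <- suppressWarnings(fit_sapm(Y, net, fit_config(n_restarts = 1)))
    tibble::tibble(connection = tidy(f)$connection, DB = tidy(f)$DB)
  }))
  st <- connection_ttest(pdb, null, alpha = 0.05)
  expect_true(all(st$p >= 0 & st$p <= 1, na.rm = TRUE))
  expect_equal(st$significant, !is.na(st$p) & st$p < st$fwe_threshold[1])
})
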