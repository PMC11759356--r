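test_that("initial-volume masking replaces points and preserves length", {
  expect_equal(mask_initial_volumes(c(1, 2, 3, 4, 5), 3), c(4, 4, 4, 4, 5))
  expect_equal(mask_initial_volumes(c(7, 9), 0), c(7, 9))
  expect_error(mask_initial_volumes(c(1, 2), 2), "smaller than")
  # idempotent
  for (i in 1:5) {
    x <- rnorm(20)
    once <- mask_initial_volumes(x, 3)
    expect_identical(mask_initial_volumes(once, 3), once)
    expect_length(once, 20)
  }
  # data-frame form applies per unit
  d <- tidyr::expand_grid(participant = c("a", "b"), region = c("R1", "R2"),
                          t = 0:4)
  d$bold <- seq_len(nrow(d))
  md <- mask_initial_volumes(d, 2)
  one <- md[md$participant == "a" & md$region == "R1", ]
  expect_equal(one$bold, c(3, 3, 3, 4, 5))
})

test_that("percent signal change centers on the run mean", {
  expect_equal(to_percent_signal_change(rep(5, 10)), rep(0, 10))
  expect_equal(to_percent_signal_change(c(90, 110)), c(-10, 10))
  x <- runif(50, 50, 150)
  expect_equal(mean(to_percent_signal_change(x)), 0, tolerance = 1e-12)
  expect_error(to_percent_signal_change(c(-2, 2)), "positive")
})

test_that("k-means clustering recovers separable sub-regions deterministically", {
  Tn <- 60
  centers <- matrix(rnorm(5 * Tn), 5, Tn)
  vox <- centers[rep(1:5, each = 8), ]  # perfectly separable
  rownames(vox) <- sprintf("v%02d", 1:40)
  truth <- rep(1:5, each = 8)
  ca <- cluster_region(vox, k = 5, seed = 0)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(ca$labels, truth))), 5)
  expect_equal(sort(ca$sizes), rep(8, 5))
  ca2 <- cluster_region(vox, k = 5, seed = 0)
  expect_identical(ca$labels, ca2$labels)
  expect_error(cluster_region(vox[1:3, ], k = 5), "fewer voxels")
})

test_that("clustering agrees with ground truth on noisy synthetic voxels", {
  skip_if_not_installed("mclust")
  net <- tiny_cycle_net()
  p <- short_paradigm()
  cfg <- sim_config(net, n_participants = c(HC = 1), n_runs = 1, seed = 1)
  tc <- simulate_bold(cfg, p)
  sub <- make_subregion_timecourses(tc, n_subregions = 5, divergence = 0.5,
                                    seed = 2)
  vox <- simulate_voxels(sub[, c("region", "subregion", "t", "bold")],
                         voxels_per_subregion = 10, within_sd = 0.1, seed = 3)
  m <- voxel_matrix(vox, "A")
  truth <- vox[vox$region == "A" & vox$t == 0, ]$subregion_true
  ca <- cluster_region(m, k = 5, seed = 0)
  ari <- mclust::adjustedRandIndex(ca$labels, truth)
  expect_gt(ari, 0.9)
})

test_that("clustering is invariant to voxel order up to label permutation", {
  skip_if_not_installed("mclust")
  Tn <- 40
  centers <- matrix(rnorm(5 * Tn, sd = 2), 5, Tn)
  vox <- centers[rep(1:5, each = 6), ] + matrix(rnorm(30 * Tn, sd = 0.1),
                                                30, Tn)
  rownames(vox) <- sprintf("v%02d", 1:30)
  perm <- sample(30)
  ca1 <- cluster_region(vox, k = 5, seed = 0)
  ca2 <- cluster_region(vox[perm, ], k = 5, seed = 0)
  expect_equal(mclust::adjustedRandIndex(ca1$labels[perm], ca2$labels), 1)
})

test_that("unbalanced partitions trigger the volume-balance warning", {
  Tn <- 30
  base <- rnorm(Tn)
  vox <- rbind(matrix(rep(base, 20), 20, Tn, byrow = TRUE) +
                 matrix(rnorm(20 * Tn, sd = 0.01), 20, Tn),
               matrix(rnorm(4 * Tn, sd = 3), 4, Tn))
  rownames(vox) <- sprintf("v%02d", 1:24)
  expect_warning(cluster_region(vox, k = 5, seed = 0), "unbalanced")
})

test_that("sub-region extraction averages voxels then converts to percent change", {
  Tn <- 20
  vox <- matrix(runif(5 * Tn, 90, 110), 5, Tn)
  rownames(vox) <- paste0("v", 1:5)
  # one voxel per sub-region: course equals that voxel, percent-changed
  out <- extract_subregion_timecourses(vox, setNames(1:5, rownames(vox)))
  for (s in 1:5) {
    expect_equal(out$bold[out$subregion == s],
                 to_percent_signal_change(vox[s, ]))
  }
  # averaging reduces noise variance ~ 1/n_voxels
  base <- 100 + sin(seq_len(200) / 10)
  n_vox <- 16
  noisy <- matrix(rep(base, n_vox), n_vox, byrow = TRUE) +
    matrix(rnorm(n_vox * 200, sd = 1), n_vox)
  rownames(noisy) <- paste0("v", seq_len(n_vox))
  one <- extract_subregion_timecourses(noisy[1, , drop = FALSE],
                                       setNames(1, "v1"))
  all16 <- extract_subregion_timecourses(noisy, setNames(rep(1, n_vox),
                                                         rownames(noisy)))
  resid_var <- function(b) var(b - to_percent_signal_change(base))
  ratio <- resid_var(all16$bold) / resid_var(one$bold)
  expect_lt(ratio, 3 / n_vox)  # ~1/16 with sampling slack
})

test_that("run averaging returns pointwise mean and sem", {
  d <- tibble::tibble(
    participant = "p1", group = "FM", condition = "Pain",
    run = rep(1:2, each = 2), region = "A", t = rep(0:1, 2),
    bold = c(0, 2, 2, 0)
  )
  avg <- average_runs(d)
  expect_equal(avg$mean, c(1, 1))
  expect_equal(avg$sem, c(1, 1))  # sd(c(0,2))/sqrt(2) = 1
  single <- average_runs(d[d$run == 1, ])
  expect_equal(single$mean, c(0, 2))
  expect_equal(single$sem, c(0, 0))
  # n identical runs: sem 0
  dd <- dplyr::bind_rows(lapply(1:4, function(r) {
    tibble::tibble(participant = "p", run = r, region = "A", t = 0:3,
                   bold = c(1, 2, 3, 4))
  }))
  expect_equal(average_runs(dd)$sem, rep(0, 4))
  bad <- dplyr::bind_rows(d, tibble::tibble(
    participant = "p2", group = "FM", condition = "Pain", run = 1,
    region = "A", t = 0:2, bold = 1:3))
  expect_error(average_runs(bad), "mismatched")
})

test_that("extraction and averaging commute with raw intensity scaling", {
  Tn <- 30
  vox <- matrix(runif(10 * Tn, 90, 110), 10, Tn)
  rownames(vox) <- paste0("v", 1:10)
  labels <- setNames(rep(1:2, each = 5), rownames(vox))
  a <- extract_subregion_timecourses(vox, labels)
  b <- extract_subregion_timecourses(vox * 7.5, labels)
  expect_equal(a$bold, b$bold, tolerance = 1e-12)
})
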