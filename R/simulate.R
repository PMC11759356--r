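#' Simulation configuration for synthetic BOLD studies
#'
#' Bundles the generative ground truth used by [simulate_bold()]: the
#' network, per-connection true D and B weightings (as their product DB,
#' the reported connectivity statistic), latent waveform shape parameters,
#' the pre-stimulus initial-rise component, observation noise, and study
#' size. Defaults emulate the study conditions of the threat/safety heat
#' paradigm: two groups (a fibromyalgia-like `FM` group and a healthy
#' control-like `HC` group), an initial rise about twice as large in the
#' FM-like group, and published group-average DB values as the default
#' truth for the bundled networks.
#'
#' D values are nonnegative input weightings that sum to 1 over each
#' region's incoming connections; by default every incoming connection of
#' a region receives an equal share (the same normalization the fitting
#' engine uses, making closed-loop recovery well posed).
#'
#' @param network A `bold_network`.
#' @param true_DB Named vector of DB values over `connection_labels(network)`.
#'   `NULL` uses published group-average values for the bundled networks and
#'   a deterministic fallback pattern otherwise.
#' @param true_D Named vector of D values; `NULL` for the uniform split.
#' @param event_amplitude Amplitude of the event-locked latent components
#'   (arbitrary units prior to standardization).
#' @param fluctuation_amplitude Amplitude of the smooth stochastic latent
#'   component ensuring latents are linearly independent.
#' @param hrf_peak Hemodynamic kernel peak latency, seconds.
#' @param initial_rise List with `amplitude` (% signal change, baseline
#'   group), `tau` (saturation time constant, seconds; the default reaches
#'   ~95% of the plateau by 40 s), `group_multiplier` (amplitude multiplier
#'   for `groups`), `groups` (character, which groups get the multiplier).
#' @param noise_sd Gaussian observation noise sd, % signal change.
#' @param n_participants Named integer vector, participants per group.
#' @param n_runs Runs per participant and condition.
#' @param seed Integer seed; fully determines all generator output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(network,
                       true_DB = NULL,
                       true_D = NULL,
                       event_amplitude = 1,
                       fluctuation_amplitude = 0.4,
                       hrf_peak = 5,
                       initial_rise = list(),
                       noise_sd = 0.2,
                       n_participants = c(FM = 20, HC = 17),
                       n_runs = 5,
                       seed = 0) {
  stopifnot(inherits(network, "bold_network"))
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  rise <- modifyList(
    list(amplitude = 0.5, tau = 40 / 3, group_multiplier = 2, groups = "FM"),
    initial_rise
  )
  labels <- connection_labels(network)
  if (is.null(true_DB)) true_DB <- default_true_DB(network)
  abort_if(!all(labels %in% names(true_DB)),
           "true_DB must be named over all connection labels")
  true_DB <- true_DB[labels]
  if (is.null(true_D)) true_D <- uniform_D(network)
  true_D <- true_D[labels]
  abort_if(any(true_D < 0), "true_D entries must be nonnegative")
  # per-region D must sum to 1 over the region's inputs
  tgt <- connection_targets(network)
  sums <- tapply(true_D, tgt, sum)
  abort_if(any(abs(sums - 1) > 1e-8),
           "true_D must sum to 1 over each region's incoming connections")
  structure(
    list(network = network, true_DB = true_DB, true_D = true_D,
         true_B = ifelse(true_D > 0, true_DB / true_D, 0),
         event_amplitude = event_amplitude,
         fluctuation_amplitude = fluctuation_amplitude,
         hrf_peak = hrf_peak, initial_rise = rise, noise_sd = noise_sd,
         n_participants = n_participants, n_runs = n_runs, seed = seed),
    class = "sim_config"
  )
}

# Target region of every connection (edges then latent edges).
connection_targets <- function(net) {
  c(net$edges$to, net$latents$target)
}

#' Default ground-truth DB values
#'
#' For the bundled brain and brainstem/cord networks these are the
#' published group-average DB values (FM group, Pain condition) for the
#' connections that appear in the group-connectivity tables, with modest
#' positive values for the few anatomy-completion edges and excitatory
#' latent drives. For other networks a deterministic sign-alternating
#' pattern is used.
#'
#' @param net A `bold_network`.
#' @return Named numeric vector over `connection_labels(net)`.
#' @export
default_true_DB <- function(net) {
  published <- c(
    # brain network, FM Pain group averages
    "AC->PC" = 0.402, "IC->AC" = 0.679, "AC->IC" = 0.275,
    "Thal->AC" = 0.276, "Amyg->Thal" = 0.311, "Thal->PC" = 0.326,
    "PC->AC" = 0.133, "AC->FOrb" = -0.253, "PBN->Thal" = 0.094,
    "Hypo->PAG" = 0.036, "Thal->Hypo" = 0.245, "Amyg->Hippo" = 0.098,
    "AC->Amyg" = 0.071, "Thal->Hippo" = 0.165, "IC->HG" = 0.340,
    # anatomy-completion edges
    "Hypo->VTA" = 0.2, "VTA->NAcc" = 0.3,
    # latent drives
    "Lat0->FOrb" = 0.6, "Lat1->IC" = 0.6, "Lat2->LC" = 0.8
  )
  published_bs <- c(
    # brainstem/cord network, FM Pain group averages
    "LC->Thal" = 0.478, "LC->PBN" = 0.612, "NRM->C6RD" = -0.266,
    "Hypo->NTS" = 0.054, "PBN->Thal" = 0.275, "Hypo->Thal" = 0.197,
    "Thal->Hypo" = 0.25, "Hypo->PAG" = 0.2, "PAG->NRM" = 0.3,
    "PAG->NGc" = 0.3, "NGc->C6RD" = 0.2, "DRt->C6RD" = 0.2,
    "C6RD->DRt" = 0.2, "Lat2->LC" = 0.8
  )
  # the brain table also names LC->PBN (-0.050), Hypo->Thal (0.340),
  # LC->Thal (0.347); use the brain values in the brain network
  brain_extra <- c("LC->PBN" = -0.050, "Hypo->Thal" = 0.340,
                   "LC->Thal" = 0.347)
  labels <- connection_labels(net)
  lookup <- if (identical(net$name, "brainstem_cord")) published_bs
            else c(published, brain_extra)
  out <- lookup[labels]
  names(out) <- labels
  missing <- is.na(out)
  if (any(missing)) {
    idx <- which(missing)
    n_lat <- nrow(net$latents)
    is_latent <- labels %in% paste(net$latents$name, net$latents$target,
                                   sep = "->")
    out[missing & is_latent] <- 0.7
    still <- is.na(out)
    out[still] <- ifelse(seq_along(labels)[still] %% 3 == 0, -0.25, 0.4)
  }
  out
}

#' Generate latent input time courses
#'
#' Each latent is a deterministic function of the seed: event-locked
#' components at the inform cue and (for Pain runs) at stimulation onset
#' and offset, convolved with a smooth gamma-shaped hemodynamic kernel,
#' plus a smooth stochastic fluctuation. This transient part is centered
#' and standardized to unit variance. A saturating initial-rise component
#' `amplitude * (1 - exp(-t/tau))` (centered, not re-standardized so its
#' configured amplitude is preserved) is then added, scaled by
#' `rise_multiplier`.
#'
#' @param paradigm A `bold_paradigm`.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param rise_multiplier Multiplier on the initial-rise amplitude (the
#'   group multiplier for FM-like participants).
#' @return Matrix, latents by time, rownames = latent names.
#' @export
generate_latents <- function(paradigm, config, seed = config$seed,
                             rise_multiplier = 1) {
  stopifnot(inherits(paradigm, "bold_paradigm"))
  net <- config$network
  K <- nrow(net$latents)
  n <- paradigm$n_volumes
  tt <- paradigm$time
  U <- matrix(0, K, n, dimnames = list(net$latents$name, NULL))
  impulse_at <- function(t0) {
    v <- numeric(n)
    i <- which.min(abs(tt - t0))
    v[i] <- 1
    v
  }
  rise_shape <- 1 - exp(-tt / config$initial_rise$tau)
  for (k in seq_len(K)) {
    u <- with_seed(child_seed(seed, k), {
      transient <- numeric(n)
      if (config$event_amplitude > 0) {
        w <- runif(3, 0.5, 1.5) * config$event_amplitude
        ev <- w[1] * impulse_at(paradigm$inform_time)
        if (paradigm$condition == "Pain") {
          ev <- ev + w[2] * impulse_at(paradigm$stimulus_onset) +
            w[3] * impulse_at(paradigm$stimulus_onset + paradigm$stim_duration)
        }
        transient <- transient + convolve_hrf(ev, paradigm$TR, config$hrf_peak)
      }
      if (config$fluctuation_amplitude > 0) {
        fl <- convolve_hrf(rnorm(n), paradigm$TR, config$hrf_peak)
        transient <- transient + config$fluctuation_amplitude * fl / max(sd(fl), 1e-12)
      }
      transient
    })
    u <- u - mean(u)
    s <- sd(u)
    if (s > 0) u <- u / s
    amp <- config$initial_rise$amplitude * rise_multiplier
    if (amp != 0) {
      u <- u + amp * (rise_shape - mean(rise_shape))
    }
    U[k, ] <- u
  }
  U
}

#' Simulate network-propagated BOLD time series
#'
#' Generates regional BOLD observations from the forward signaling model:
#' the noise-free signal is the model's region input signal
#' `S_input = M_input S_output + D_latent U` where `S_output` solves the
#' latent-driven fixed point (see [solve_forward()]); observations add
#' i.i.d. Gaussian noise. Participants in groups named in
#' `config$initial_rise$groups` receive the initial-rise group multiplier
#' (default 2 for the FM-like group).
#'
#' @param config A `sim_config`.
#' @param paradigm A `bold_paradigm`; default Pain run at TR 2 s.
#' @param seed Integer; defaults to `config$seed`.
#' @return A tibble with columns `participant`, `group`, `condition`,
#'   `run`, `region`, `t` (0-based volume index), `time` (s), `bold`
#'   (% signal change). Attributes: `truth` (tibble of connections with
#'   true D, B, DB), `config`, `paradigm`.
#' @export
simulate_bold <- function(config, paradigm = make_paradigm("Pain", TR = 2),
                          seed = config$seed) {
  net <- config$network
  mats <- build_matrices(net, D = config$true_D, B = config$true_B)
  rho <- spectral_radius(mats$M_output)
  abort_if(rho >= 1,
           sprintf("non-dissipative network: spectral radius %.3f >= 1", rho))
  G <- forward_gain(mats)
  groups <- names(config$n_participants)
  abort_if(is.null(groups), "n_participants must be a named vector")
  out <- list()
  unit <- 0L
  for (g in groups) {
    mult <- if (g %in% config$initial_rise$groups)
      config$initial_rise$group_multiplier else 1
    for (i in seq_len(config$n_participants[[g]])) {
      pid <- sprintf("%s%02d", g, i)
      for (r in seq_len(config$n_runs)) {
        unit <- unit + 1L
        sub_seed <- child_seed(seed, unit)
        U <- generate_latents(paradigm, config, seed = sub_seed,
                              rise_multiplier = mult)
        signal <- G %*% U
        y <- signal
        if (config$noise_sd > 0) {
          y <- y + with_seed(child_seed(sub_seed, 1e6), {
            matrix(rnorm(length(signal), sd = config$noise_sd),
                   nrow(signal), ncol(signal))
          })
        }
        out[[unit]] <- tibble::tibble(
          participant = pid, group = g, condition = paradigm$condition,
          run = r,
          region = rep(net$regions, each = paradigm$n_volumes),
          t = rep(seq_len(paradigm$n_volumes) - 1L, times = length(net$regions)),
          time = rep(paradigm$time, times = length(net$regions)),
          bold = as.vector(t(y))
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- tibble::tibble(
    connection = connection_labels(net),
    D = unname(config$true_D), B = unname(config$true_B),
    DB = unname(config$true_DB)
  )
  attr(res, "config") <- config
  attr(res, "paradigm") <- paradigm
  res
}

#' Derive per-sub-region time courses from regional courses
#'
#' Gives each of `n_subregions` sub-regions per region the regional course
#' plus an independent smooth divergence component, emulating functional
#' heterogeneity within anatomical regions.
#'
#' @param tc Tibble from [simulate_bold()] (or same columns).
#' @param n_subregions Sub-regions per region (default 5).
#' @param divergence SD of the smooth sub-region-specific component.
#' @param seed Integer seed.
#' @return Tibble like `tc` with an added `subregion` column.
#' @export
make_subregion_timecourses <- function(tc, n_subregions = 5, divergence = 0.3,
                                       seed = 0) {
  TRsec <- if (nrow(tc) > 1) diff(sort(unique(tc$time)))[1] else 1
  groups <- dplyr::group_by(tc, .data$participant, .data$group,
                            .data$condition, .data$run, .data$region)
  keys <- dplyr::group_keys(groups)
  split_tc <- dplyr::group_split(groups)
  out <- vector("list", length(split_tc) * n_subregions)
  idx <- 0L
  for (gi in seq_along(split_tc)) {
    d <- split_tc[[gi]]
    n <- nrow(d)
    for (j in seq_len(n_subregions)) {
      idx <- idx + 1L
      extra <- if (divergence > 0) {
        with_seed(child_seed(seed, gi * 97 + j), {
          fl <- convolve_hrf(rnorm(n), TRsec)
          divergence * fl / max(sd(fl), 1e-12)
        })
      } else numeric(n)
      dd <- d
      dd$subregion <- j
      dd$bold <- d$bold + extra
      out[[idx]] <- dd
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate voxel-level data with known sub-region structure
#'
#' Each sub-region contributes `voxels_per_subregion` voxels whose time
#' courses equal the sub-region course plus independent Gaussian noise;
#' the generating sub-region label is recorded as ground truth, and voxels
#' receive arbitrary-unit spatial coordinates clustered by sub-region.
#'
#' @param subregion_tc Tibble with columns `region`, `subregion`, `t`,
#'   `bold` for a single participant/run (e.g. one group of
#'   [make_subregion_timecourses()] output).
#' @param voxels_per_subregion Voxels per sub-region (>= 1).
#' @param within_sd Within-sub-region voxel noise sd.
#' @param seed Integer seed.
#' @return Tibble with columns `region`, `voxel`, `subregion_true`,
#'   `x`, `y`, `z`, `t`, `value`.
#' @export
simulate_voxels <- function(subregion_tc, voxels_per_subregion = 10,
                            within_sd = 0.1, seed = 0) {
  abort_if(voxels_per_subregion < 1, "voxels_per_subregion must be >= 1")
  groups <- dplyr::group_by(subregion_tc, .data$region, .data$subregion)
  split_tc <- dplyr::group_split(groups)
  out <- vector("list", length(split_tc) * voxels_per_subregion)
  idx <- 0L
  for (gi in seq_along(split_tc)) {
    d <- dplyr::arrange(split_tc[[gi]], .data$t)
    n <- nrow(d)
    sub <- d$subregion[1]
    for (v in seq_len(voxels_per_subregion)) {
      idx <- idx + 1L
      noise_xyz <- with_seed(child_seed(seed, idx), {
        list(noise = rnorm(n, sd = within_sd), xyz = runif(3, -0.5, 0.5))
      })
      out[[idx]] <- tibble::tibble(
        region = d$region[1],
        voxel = sprintf("%s_s%d_v%02d", d$region[1], sub, v),
        subregion_true = sub,
        x = 3 * sub + noise_xyz$xyz[1], y = noise_xyz$xyz[2],
        z = noise_xyz$xyz[3],
        t = d$t, value = d$bold + noise_xyz$noise
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Pivot one region's voxels to a voxel-by-time matrix
#'
#' @param voxels Tibble from [simulate_voxels()].
#' @param region Region to extract.
#' @return Numeric matrix, voxels by time, rownames = voxel ids.
#' @export
voxel_matrix <- function(voxels, region) {
  d <- voxels[voxels$region == region, c("voxel", "t", "value")]
  abort_if(nrow(d) == 0, paste0("no voxels for region ", region))
  w <- tidyr::pivot_wider(d, names_from = "t", values_from = "value")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$voxel
  m
}
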