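#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()], a
#' small synthetic study sized for interactive use. Blocks: `simulate`
#' (study generation), `subregions` (sub-region structure and search),
#' `fit`, `null` (null-simulation significance), `features`, `stats`,
#' `pupil`. Unknown keys anywhere are rejected so configuration typos
#' fail fast.
#'
#' @param seed Integer master seed.
#' @return Nested list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    network = "brain",
    simulate = list(TR = 2, run_duration = 270, condition = "Pain",
                    n_FM = 4, n_HC = 4, n_runs = 2, noise_sd = 0.2),
    subregions = list(n_subregions = 3, divergence = 0.3, search = TRUE,
                      n_starts = 2),
    fit = list(n_restarts = 2, max_iterations = 300, tol = 1e-6),
    null_sim = list(reps = 60),
    features = list(n_masked = 3),
    stats = list(covariate_effect = 6, covariate_sd = 8),
    pupil = list(enabled = TRUE, n_FM = 8, n_HC = 6, task_duration = 60,
                 fs = 50)
  )
}

pipeline_schema <- list(
  ".top" = c("seed", "network", "simulate", "subregions", "fit",
             "null_sim", "features", "stats", "pupil"),
  simulate = c("TR", "run_duration", "condition", "n_FM", "n_HC", "n_runs",
               "noise_sd"),
  subregions = c("n_subregions", "divergence", "search", "n_starts"),
  fit = c("n_restarts", "max_iterations", "tol"),
  null_sim = c("reps"),
  features = c("n_masked"),
  stats = c("covariate_effect", "covariate_sd"),
  pupil = c("enabled", "n_FM", "n_HC", "task_duration", "fs")
)

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_schema$.top)
  abort_if(length(unknown) > 0,
           paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  for (blk in setdiff(pipeline_schema$.top, c("seed", "network"))) {
    bad <- setdiff(names(cfg[[blk]]), pipeline_schema[[blk]])
    abort_if(length(bad) > 0,
             paste0("unknown key(s) in config block '", blk, "': ",
                    paste(bad, collapse = ", ")))
  }
  merged <- modifyList(default_pipeline_config(), cfg)
  abort_if(!is.numeric(merged$seed), "config seed must be numeric")
  merged
}

# FNV-1a hash of the serialized configuration, for provenance logging.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Executes the analysis chain end to end on generated data: simulate
#' regional BOLD -> derive sub-region courses -> greedy sub-region search
#' on the group-average courses -> freeze the selection -> fit the
#' network model per participant/condition -> null simulations and
#' connection significance -> time-course features -> group ANCOVA ->
#' pupil summary. All outputs are TSV/JSON files under `out_dir`, plus a
#' log recording the seed, configuration hash and stage defaults; rerun
#' with the same configuration and seed reproduces them bit-identically.
#'
#' @param config Path to a YAML/JSON configuration, or a configuration
#'   list (see [default_pipeline_config()]); partial configurations are
#'   completed with the defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results
#'   (`connectivity`, `participant_db`, `features`, `ancova`, `pupil`,
#'   `selection`, `recovery`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("boldnet_run_")) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  log_lines <- c(sprintf("seed: %d", cfg$seed),
                 sprintf("config_hash: %s", config_hash(cfg)))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage %s: %s", name,
                                      conditionMessage(e))), logf)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  net <- stage("network", {
    if (cfg$network == "brain") brain_network()
    else if (cfg$network == "brainstem_cord") brainstem_cord_network()
    else load_network(cfg$network)
  })
  save_network(net, file.path(out_dir, "network.json"))
  say("network: %s (%d regions, %d connections)", net$name,
      length(net$regions), n_connections(net))

  sim <- cfg$simulate
  paradigm <- make_paradigm(sim$condition, TR = sim$TR,
                            run_duration = sim$run_duration)
  scfg <- sim_config(net, noise_sd = sim$noise_sd,
                     n_participants = c(FM = sim$n_FM, HC = sim$n_HC),
                     n_runs = sim$n_runs, seed = cfg$seed)
  tc <- stage("simulate", simulate_bold(scfg, paradigm))
  truth <- attr(tc, "truth")
  say("simulate: %d participants x %d runs, %d volumes, noise %.2f",
      sim$n_FM + sim$n_HC, sim$n_runs, paradigm$n_volumes, sim$noise_sd)

  fcfg <- fit_config(n_restarts = cfg$fit$n_restarts,
                     max_iterations = cfg$fit$max_iterations,
                     tol = cfg$fit$tol, seed = cfg$seed)

  sub <- cfg$subregions
  selection <- stage("subregions", {
    if (isTRUE(sub$search)) {
      subtc <- make_subregion_timecourses(tc, n_subregions = sub$n_subregions,
                                          divergence = sub$divergence,
                                          seed = child_seed(cfg$seed, 11))
      avg <- dplyr::summarise(
        dplyr::group_by(subtc, .data$region, .data$subregion, .data$t),
        bold = mean(.data$bold), .groups = "drop")
      comb <- search_subregions(avg, net,
                                cfg = fit_config(n_restarts = 1, seed = cfg$seed),
                                seed = child_seed(cfg$seed, 13),
                                n_starts = sub$n_starts)
      freeze_combination(comb)
    } else {
      freeze_combination(setNames(rep(1L, length(net$regions)), net$regions))
    }
  })
  save_selection(selection, file.path(out_dir, "selection.json"))
  say("subregions: frozen selection %s", selection$fingerprint)

  pdb <- stage("fit", fit_sapm_groups(tc, net, fcfg))
  write_tsv_file(pdb, file.path(out_dir, "participant_DB.tsv"))
  say("fit: %d participant/condition fits, mean R2 %.3f",
      length(unique(paste(pdb$participant, pdb$condition))),
      mean(pdb$mean_R2))

  stats_out <- stage("null", {
    null <- generate_null(net, paradigm$n_volumes, reps = cfg$null_sim$reps,
                          cfg = fit_config(n_restarts = 1, seed = cfg$seed),
                          seed = child_seed(cfg$seed, 17))
    res <- lapply(split(pdb, paste(pdb$group, pdb$condition)), function(d) {
      st <- connection_ttest(d[, c("connection", "DB")], null)
      st$group <- d$group[1]; st$condition <- d$condition[1]
      st
    })
    dplyr::bind_rows(res)
  })
  write_tsv_file(stats_out, file.path(out_dir, "connectivity_stats.tsv"))
  say("null: %d reps; %d significant connection/group cells",
      cfg$null_sim$reps, sum(stats_out$significant, na.rm = TRUE))

  feats <- stage("features", {
    masked <- mask_initial_volumes(tc, cfg$features$n_masked)
    timecourse_features(masked, paradigm, n_masked = cfg$features$n_masked)
  })
  write_tsv_file(feats, file.path(out_dir, "features.tsv"))
  say("features: %d rows", nrow(feats))

  anc <- stage("stats", {
    rise <- dplyr::summarise(
      dplyr::group_by(feats, .data$participant, .data$group),
      initial_rise = mean(.data$initial_rise), .groups = "drop")
    rise$score <- with_seed(child_seed(cfg$seed, 23), {
      40 + cfg$stats$covariate_effect * (rise$group == "FM") +
        rnorm(nrow(rise), sd = cfg$stats$covariate_sd)
    })
    ancova(rise, "initial_rise", "group", "score",
           n_family = n_connections(net))
  })
  write_tsv_file(anc, file.path(out_dir, "ancova.tsv"))
  say("stats: ANCOVA p_group %.3g", anc$p_group)

  pup <- NULL
  if (isTRUE(cfg$pupil$enabled)) {
    pup <- stage("pupil", {
      traces <- simulate_pupil(
        n_trials = c(FM = cfg$pupil$n_FM, HC = cfg$pupil$n_HC),
        n_participants = c(FM = max(2, cfg$pupil$n_FM %/% 2),
                           HC = max(2, cfg$pupil$n_HC %/% 2)),
        seed = child_seed(cfg$seed, 29),
        fs = cfg$pupil$fs, task_duration = cfg$pupil$task_duration)
      group_mean_area(traces)
    })
    write_tsv_file(pup, file.path(out_dir, "pupil_summary.tsv"))
    say("pupil: FM/HC difference %.1f%%",
        attr(pup, "percent_difference") %||% NA)
  }

  recovery <- stage("recovery", {
    est <- dplyr::summarise(dplyr::group_by(pdb, .data$connection),
                            DB_fitted = mean(.data$DB), .groups = "drop")
    dplyr::left_join(truth, est, by = "connection")
  })
  write_tsv_file(recovery, file.path(out_dir, "recovery.tsv"))
  say("recovery: median |DB error| %.3f (identified connections)",
      median(abs(recovery$DB - recovery$DB_fitted), na.rm = TRUE))

  writeLines(log_lines, logf)
  invisible(list(connectivity = stats_out, participant_db = pdb,
                 features = feats, ancova = anc, pupil = pup,
                 selection = selection, recovery = recovery,
                 out_dir = out_dir))
}

write_tsv_file <- function(d, path) {
  write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
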