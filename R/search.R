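#' Search for the sub-region combination that best fits the network
#'
#' Greedy coordinate descent over the discrete space of sub-region
#' choices (one of `k` per region): starting from a seeded random
#' combination, regions are swept in canonical network order; for each
#' region every sub-region choice is tried with the others held fixed and
#' the best is kept (ties keep the incumbent); sweeps repeat until a full
#' sweep yields no improvement. Each candidate combination is evaluated
#' by a full model re-fit, so the error trajectory is non-increasing by
#' construction. `n_starts` seeded random starts are run and the best
#' final combination is returned.
#'
#' @param data Tidy tibble with columns `region`, `subregion`, `t`,
#'   `bold` (one analysis unit; typically a group-average course per
#'   sub-region).
#' @param net A `bold_network`.
#' @param cfg A [fit_config()] used for the candidate fits (a light
#'   configuration, e.g. 1-2 restarts, keeps the search affordable).
#' @param seed Integer seed for the random starting combinations.
#' @param n_starts Number of random starts (default 10).
#' @return An object of class `subregion_combination`: `combination`
#'   (named integer vector region -> sub-region), `fit_error`,
#'   `trajectory` (tibble `start`, `iteration`, `error`), `n_sweeps`.
#' @export
search_subregions <- function(data, net, cfg = fit_config(n_restarts = 2),
                              seed = 0, n_starts = 10) {
  abort_if(!all(c("region", "subregion", "t", "bold") %in% names(data)),
           "data needs columns region, subregion, t, bold")
  regions <- net$regions
  subs <- sort(unique(data$subregion))
  k <- length(subs)
  # course lookup: [[region]][[subregion]] -> numeric vector
  courses <- list()
  for (r in regions) {
    dr <- data[data$region == r, ]
    abort_if(nrow(dr) == 0, paste0("missing sub-region courses for region ", r))
    courses[[r]] <- lapply(subs, function(s) {
      ds <- dr[dr$subregion == s, ]
      abort_if(nrow(ds) == 0,
               paste0("missing sub-region ", s, " for region ", r))
      ds$bold[order(ds$t)]
    })
  }
  Tn <- length(courses[[1]][[1]])
  assemble <- function(comb) {
    m <- t(vapply(seq_along(regions),
                  function(i) courses[[regions[i]]][[comb[i]]],
                  numeric(Tn)))
    rownames(m) <- regions
    m
  }
  eval_comb <- function(comb) {
    fit_sapm(assemble(comb), net, cfg)$fit_error
  }

  best <- NULL
  traj_all <- list()
  for (s in seq_len(n_starts)) {
    comb <- with_seed(child_seed(seed, s), sample(k, length(regions),
                                                  replace = TRUE))
    err <- eval_comb(comb)
    traj <- tibble::tibble(start = s, iteration = 0L, error = err)
    sweeps <- 0L
    repeat {
      improved <- FALSE
      sweeps <- sweeps + 1L
      for (i in seq_along(regions)) {
        for (cand in seq_len(k)) {
          if (cand == comb[i]) next
          trial <- comb
          trial[i] <- cand
          e <- eval_comb(trial)
          if (e < err) {  # strict: ties keep the incumbent
            err <- e
            comb <- trial
            improved <- TRUE
          }
        }
        traj <- dplyr::bind_rows(
          traj, tibble::tibble(start = s, iteration = nrow(traj), error = err))
      }
      if (!improved) break
    }
    traj_all[[s]] <- traj
    if (is.null(best) || err < best$err) {
      best <- list(comb = comb, err = err, sweeps = sweeps)
    }
  }
  combination <- setNames(as.integer(subs[best$comb]), regions)
  structure(
    list(combination = combination, fit_error = best$err,
         trajectory = dplyr::bind_rows(traj_all), n_sweeps = best$sweeps,
         network = net$name, k = k),
    class = "subregion_combination"
  )
}

#' @export
print.subregion_combination <- function(x, ...) {
  cat(sprintf("<subregion_combination> %s: fit error %.4g\n  %s\n",
              x$network, x$fit_error,
              paste(names(x$combination), x$combination, sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Freeze a sub-region selection for all downstream analyses
#'
#' Once the best-fitting combination is identified, the same set of
#' sub-regions is used for all subsequent analyses for consistency
#' (including across network models sharing regions). The frozen
#' selection carries a fingerprint; downstream code can refuse data whose
#' selection differs via [check_selection()].
#'
#' @param comb A `subregion_combination` (or named integer vector).
#' @return An object of class `subregion_selection`.
#' @export
freeze_combination <- function(comb) {
  combination <- if (inherits(comb, "subregion_combination"))
    comb$combination else comb
  abort_if(is.null(names(combination)),
           "combination must be a named region -> sub-region vector")
  structure(
    list(combination = combination,
         fingerprint = selection_fingerprint(combination)),
    class = "subregion_selection"
  )
}

selection_fingerprint <- function(combination) {
  paste(names(combination), combination, sep = ":", collapse = "|")
}

#' Compare a selection against a frozen one
#'
#' @param selection A `subregion_selection`.
#' @param other A `subregion_selection` or named combination vector
#'   covering the shared regions.
#' @param override Allow mismatches (returns `FALSE` instead of erroring).
#' @return `TRUE` if the selections agree on all shared regions.
#' @export
check_selection <- function(selection, other, override = FALSE) {
  stopifnot(inherits(selection, "subregion_selection"))
  comb2 <- if (inherits(other, "subregion_selection"))
    other$combination else other
  shared <- intersect(names(selection$combination), names(comb2))
  ok <- all(selection$combination[shared] == comb2[shared])
  if (!ok && !override) {
    bad <- shared[selection$combination[shared] != comb2[shared]]
    stop("sub-region selection mismatch for region(s): ",
         paste(bad, collapse = ", "),
         " (use override = TRUE to proceed anyway)", call. = FALSE)
  }
  ok
}

#' Save / load a frozen sub-region selection (JSON)
#'
#' @param selection A `subregion_selection`.
#' @param path File path.
#' @return `load_selection()` returns a `subregion_selection` identical to
#'   the one saved.
#' @export
save_selection <- function(selection, path) {
  stopifnot(inherits(selection, "subregion_selection"))
  jsonlite::write_json(
    list(combination = as.list(selection$combination),
         fingerprint = selection$fingerprint),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_selection
#' @export
load_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- freeze_combination(unlist(x$combination))
  abort_if(!identical(sel$fingerprint, x$fingerprint),
           "selection file fingerprint does not match its contents")
  sel
}
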