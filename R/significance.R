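#' Generate a null distribution of connectivity values
#'
#' For each replicate, regional time courses are drawn as i.i.d. standard
#' normal values with dimensions matching the real analysis (same network,
#' same time length), the network model is fitted, and the DB value of
#' every connection is recorded. Group-average DB values are then tested
#' against this empirical null. The published analysis used 10,000
#' replicates; the default here is a desk-scale 1,000 with the full size
#' available by configuration.
#'
#' @param net A `bold_network`.
#' @param n_time Time-series length (volumes) of the matching analysis.
#' @param reps Number of null replicates (>= 1).
#' @param cfg [fit_config()] used for the null fits (should match the
#'   real-data fits).
#' @param seed Integer seed; the null is bit-reproducible under it.
#' @return Object of class `null_distribution`: `samples` (tibble `rep`,
#'   `connection`, `DB`), `network`, `n_time`, `reps`, `seed`.
#' @export
generate_null <- function(net, n_time, reps = 1000,
                          cfg = fit_config(n_restarts = 2), seed = 0) {
  abort_if(reps < 1, "reps must be >= 1")
  labels <- connection_labels(net)
  R <- length(net$regions)
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    Y <- with_seed(child_seed(seed, i),
                   matrix(rnorm(R * n_time), R, n_time,
                          dimnames = list(net$regions, NULL)))
    f <- suppressWarnings(fit_sapm(Y, net, cfg))
    out[[i]] <- tibble::tibble(rep = i, connection = labels,
                               DB = f$connections$DB)
  }
  structure(list(samples = dplyr::bind_rows(out), network = net$name,
                 connections = labels, n_time = n_time, reps = reps,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: %d reps x %d connections (T = %d)\n",
              x$network, x$reps, length(x$connections), x$n_time))
  invisible(x)
}

#' Test group connectivity values against the null
#'
#' Welch two-sample T-test of the participants' DB values per connection
#' against the null-fit DB samples, two-tailed p from the t distribution
#' with Welch-Satterthwaite degrees of freedom. Connections are flagged
#' significant at the Bonferroni family-wise threshold
#' `alpha / n_connections`.
#'
#' @param group_db Tibble with columns `connection`, `DB` (one row per
#'   participant and connection), e.g. from [fit_sapm_groups()].
#' @param null A `null_distribution` whose connections match `group_db`.
#' @param alpha Family-wise error level (default 0.05).
#' @param n_time Optional time length of the analysis that produced
#'   `group_db`; when supplied it must equal the null's.
#' @return Tibble: `connection`, `n`, `mean`, `sem`, `T`, `df`, `p`,
#'   `fwe_threshold`, `significant`, `flag`.
#' @export
connection_ttest <- function(group_db, null, alpha = 0.05, n_time = NULL) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.null(n_time)) {
    abort_if(n_time != null$n_time,
             sprintf("analysis time length (%d) does not match the null's (%d)",
                     n_time, null$n_time))
  }
  conns <- unique(group_db$connection)
  abort_if(!all(conns %in% null$connections),
           "null distribution lacks samples for some tested connections")
  m <- length(conns)
  thr <- fwe_threshold(alpha, m)
  out <- lapply(conns, function(cn) {
    x <- group_db$DB[group_db$connection == cn]
    y <- null$samples$DB[null$samples$connection == cn]
    if (all(is.na(x))) {
      return(tibble::tibble(
        connection = cn, n = length(x), mean = NA_real_, sem = NA_real_,
        T = NA_real_, df = NA_real_, p = NA_real_, fwe_threshold = thr,
        significant = FALSE, flag = "non-identified"))
    }
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    abort_if(length(x) < 2, "need >= 2 participants per connection")
    flag <- ""
    if (var(x) == 0 && var(y) == 0) {
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
      flag <- "zero-variance"
    } else {
      tt <- t.test(x, y)
    }
    tibble::tibble(
      connection = cn, n = length(x), mean = mean(x),
      sem = sd(x) / sqrt(length(x)),
      T = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, fwe_threshold = thr,
      significant = !is.na(tt$p.value) && tt$p.value < thr,
      flag = flag
    )
  })
  dplyr::bind_rows(out)
}

#' Bonferroni family-wise error threshold
#'
#' The per-connection uncorrected alpha corresponding to a family-wise
#' error level over `n_connections` tests: `alpha / n_connections`.
#' At alpha = 0.05 this gives 0.0015625 for 32 connections and
#' 0.00096154 for 52 connections.
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_connections Number of tested connections (>= 1).
#' @return Per-connection threshold.
#' @export
fwe_threshold <- function(alpha, n_connections) {
  abort_if(!is.numeric(alpha) || alpha <= 0 || alpha >= 1,
           "alpha must lie in (0, 1)")
  abort_if(n_connections < 1, "n_connections must be >= 1")
  alpha / n_connections
}

#' Empirical family-wise error rate under the null
#'
#' Validates the whole calibration chain: for each replicate family, a
#' group of participants' DB values is generated by fitting the model to
#' pure-noise data, every connection is tested against a shared null
#' distribution, and the family counts as a false positive if any
#' connection passes the Bonferroni-corrected threshold. Returns the
#' fraction of families with at least one corrected rejection, which
#' should be close to (and not exceed by much) the nominal alpha.
#'
#' @param net A `bold_network` (small networks keep this affordable).
#' @param n_time Time length of the simulated courses.
#' @param n_per_group Participants per simulated group.
#' @param reps Number of simulated families (>= 50).
#' @param alpha Nominal family-wise error level.
#' @param cfg [fit_config()] for all fits.
#' @param null_reps Replicates for the shared null distribution.
#' @param seed Integer seed.
#' @return List: `fwe` (empirical rate), `reps`, `alpha`, `rejections`
#'   (per-family rejection counts).
#' @export
type1_calibration <- function(net, n_time = 40, n_per_group = 8, reps = 200,
                              alpha = 0.05, cfg = fit_config(n_restarts = 1),
                              null_reps = 400, seed = 0) {
  abort_if(reps < 50, "reps must be >= 50")
  null <- generate_null(net, n_time, reps = null_reps, cfg = cfg,
                        seed = child_seed(seed, 999983))
  R <- length(net$regions)
  labels <- connection_labels(net)
  rejections <- integer(reps)
  for (i in seq_len(reps)) {
    dbs <- vector("list", n_per_group)
    for (j in seq_len(n_per_group)) {
      Y <- with_seed(child_seed(seed, i * 1000 + j),
                     matrix(rnorm(R * n_time), R, n_time,
                            dimnames = list(net$regions, NULL)))
      f <- suppressWarnings(fit_sapm(Y, net, cfg))
      dbs[[j]] <- tibble::tibble(connection = labels, DB = f$connections$DB)
    }
    stats <- connection_ttest(dplyr::bind_rows(dbs), null, alpha = alpha)
    rejections[i] <- sum(stats$significant, na.rm = TRUE)
  }
  list(fwe = mean(rejections > 0), reps = reps, alpha = alpha,
       rejections = rejections)
}
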