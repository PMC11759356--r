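#' Mask initial volumes with variable T1-weighting
#'
#' The first `n_replace` points of each time course are replaced with the
#' value at the first subsequent time point rather than removed, so that
#' information about time elapsed since the start of the run is preserved.
#' Defaults in the acquisition this emulates: 3 points for brain data,
#' 2 points for brainstem/spinal cord data. The operation is idempotent.
#'
#' @param x Numeric vector, or a tidy tibble with a `bold` column (applied
#'   within every combination of the non-time columns).
#' @param n_replace Number of initial points to replace (0 = identity).
#' @return Same shape as `x`.
#' @export
#' @examples
#' mask_initial_volumes(c(1, 2, 3, 4, 5), 3)  # 4 4 4 4 5
mask_initial_volumes <- function(x, n_replace) {
  abort_if(n_replace < 0, "n_replace must be >= 0")
  if (is.numeric(x)) {
    abort_if(n_replace >= length(x),
             "n_replace must be smaller than the series length")
    if (n_replace > 0) x[seq_len(n_replace)] <- x[n_replace + 1]
    return(x)
  }
  abort_if(!is.data.frame(x) || !"bold" %in% names(x),
           "x must be numeric or a data frame with a `bold` column")
  keys <- setdiff(names(x), c("t", "time", "bold"))
  ord <- if ("t" %in% names(x)) "t" else "time"
  grouped <- dplyr::group_by(x, dplyr::across(dplyr::all_of(keys)))
  dplyr::ungroup(dplyr::mutate(
    grouped,
    bold = mask_initial_volumes(.data$bold[order(.data[[ord]])],
                                n_replace)[rank(.data[[ord]])]
  ))
}

#' Convert raw intensities to percent signal change
#'
#' `100 * (x - mean(x)) / mean(x)`; the output has mean zero. The baseline
#' is the within-run mean, which yields mean-zero plotted responses.
#'
#' @param x Numeric vector of raw (positive) intensities.
#' @return Numeric vector, % signal change.
#' @export
to_percent_signal_change <- function(x) {
  m <- mean(x)
  abort_if(!is.finite(m) || m <= 0,
           "run mean must be positive to define percent signal change")
  100 * (x - m) / m
}

#' Partition a region's voxels into sub-regions by k-means
#'
#' Clusters standardized voxel time courses (each voxel centered and
#' scaled) into `k` sub-regions. Clustering operates on time courses, not
#' spatial coordinates: the downstream use of the sub-regions is
#' time-course fitting. "Approximately equal volume" is monitored rather
#' than enforced -- a balance warning is emitted when the largest
#' sub-region exceeds 3x the smallest.
#'
#' @param vox Voxel-by-time numeric matrix (rownames = voxel ids).
#' @param k Number of sub-regions (default 5).
#' @param seed Seed making the assignment deterministic (default 0).
#' @param n_restarts k-means restarts (default 10).
#' @return A list of class `cluster_assignment`: `labels` (named integer
#'   vector, voxel to sub-region 1..k), `sizes`, `centers` (k x time),
#'   `balance_warning` (logical).
#' @export
cluster_region <- function(vox, k = 5, seed = 0, n_restarts = 10) {
  abort_if(!is.matrix(vox), "vox must be a voxel-by-time matrix")
  abort_if(nrow(vox) < k,
           sprintf("fewer voxels (%d) than sub-regions (k = %d)", nrow(vox), k))
  Z <- t(scale(t(vox)))
  Z[!is.finite(Z)] <- 0  # constant voxels carry no time-course information
  km <- with_seed(seed, kmeans(Z, centers = k, nstart = n_restarts,
                               iter.max = 100))
  labels <- km$cluster
  names(labels) <- rownames(vox)
  sizes <- tabulate(labels, nbins = k)
  balance <- max(sizes) / max(min(sizes), 1) > 3
  if (balance) {
    warning(sprintf("unbalanced sub-regions: sizes %s",
                    paste(sizes, collapse = "/")), call. = FALSE)
  }
  structure(list(labels = labels, sizes = sizes, centers = km$centers,
                 k = k, balance_warning = balance),
            class = "cluster_assignment")
}

#' Extract sub-region time courses from voxel data
#'
#' Each sub-region's course is the mean over its voxels, converted to
#' percent signal change.
#'
#' @param vox Voxel-by-time matrix of raw intensities.
#' @param assignment A `cluster_assignment` (or integer label vector over
#'   the rows of `vox`).
#' @return Tibble with columns `subregion`, `t` (0-based), `bold`.
#' @export
extract_subregion_timecourses <- function(vox, assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  abort_if(length(labels) != nrow(vox),
           "assignment length must match the number of voxels")
  ks <- sort(unique(labels))
  out <- lapply(ks, function(kk) {
    rows <- which(labels == kk)
    abort_if(length(rows) == 0, paste0("empty sub-region ", kk))
    m <- colMeans(vox[rows, , drop = FALSE])
    tibble::tibble(subregion = kk, t = seq_along(m) - 1L,
                   bold = to_percent_signal_change(m))
  })
  dplyr::bind_rows(out)
}

#' Average time courses across runs/participants
#'
#' Pointwise mean and standard error of the mean at each time point,
#' within the grouping given by `by` (e.g. condition and group, matching
#' group-average response plots).
#'
#' @param data Tidy time-course tibble with `region`, `t`, `bold` plus
#'   unit columns (`participant`, `run`, ...).
#' @param by Character vector of columns to stratify by (besides `region`
#'   and `t`).
#' @return Tibble with `region`, `t`, the `by` columns, `n`, `mean`, `sem`.
#' @export
average_runs <- function(data, by = c("group", "condition")) {
  by <- intersect(by, names(data))
  lens <- dplyr::count(data,
                       dplyr::across(dplyr::all_of(
                         intersect(c("participant", "group", "condition",
                                     "run", "region"), names(data)))))
  abort_if(length(unique(lens$n)) > 1,
           "time courses have mismatched lengths; cannot average")
  grouped <- dplyr::group_by(data,
                             dplyr::across(dplyr::all_of(c(by, "region", "t"))))
  dplyr::ungroup(dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean = mean(.data$bold),
    sem = if (dplyr::n() > 1) sd(.data$bold) / sqrt(dplyr::n()) else 0,
    .groups = "drop"
  ))
}
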