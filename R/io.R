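#' Write / read regional time courses (TSV + JSON sidecar)
#'
#' One analysis unit (participant/run) per file: a tab-separated table
#' with a 0-based `t` volume-index column (seconds = `t * TR`) and one
#' column per region or sub-region, plus a JSON sidecar `<path>.json`
#' carrying the unit metadata (`participant`, `group`, `run`,
#' `condition`, `TR`). Round-trips losslessly to machine precision.
#'
#' @param data Tidy tibble with `region`, `t`, `bold` for one unit.
#' @param path TSV output path (sidecar written to `<path>.json`).
#' @param meta Named list of metadata; fields missing from `meta` are
#'   taken from constant columns of `data` when present.
#' @return `read_timecourses()` returns the tidy tibble with metadata
#'   columns restored and `TR`/`time` attached.
#' @export
write_timecourses <- function(data, path, meta = list()) {
  for (f in c("participant", "group", "run", "condition")) {
    if (is.null(meta[[f]]) && f %in% names(data)) {
      u <- unique(data[[f]])
      abort_if(length(u) > 1,
               paste0("data contains multiple ", f, "s; write one unit per file"))
      meta[[f]] <- u
    }
  }
  if (is.null(meta$TR) && "time" %in% names(data)) {
    tu <- sort(unique(data$time))
    if (length(tu) > 1) meta$TR <- diff(tu)[1]
  }
  for (f in c("participant", "group", "run", "condition", "TR")) {
    abort_if(is.null(meta[[f]]), paste0("metadata field '", f, "' is required"))
  }
  wide <- tidyr::pivot_wider(data[, c("region", "t", "bold")],
                             names_from = "region", values_from = "bold")
  wide <- dplyr::arrange(wide, .data$t)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  side <- paste0(path, ".json")
  abort_if(!file.exists(side),
           paste0("missing metadata sidecar: ", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("participant", "group", "run", "condition", "TR")) {
    abort_if(is.null(meta[[f]]),
             paste0("metadata sidecar missing field '", f, "'"))
  }
  wide <- read.delim(path, check.names = FALSE)
  bad <- which(is.na(as.matrix(wide)), arr.ind = TRUE)
  abort_if(nrow(bad) > 0,
           paste0("NaN/missing cells at (row, column): ",
                  paste(sprintf("(%d, %s)", bad[, 1],
                                colnames(wide)[bad[, 2]]), collapse = ", ")))
  long <- tidyr::pivot_longer(wide, -"t", names_to = "region",
                              values_to = "bold")
  tibble::tibble(
    participant = meta$participant, group = meta$group,
    condition = meta$condition, run = meta$run,
    region = long$region, t = long$t, time = long$t * meta$TR,
    bold = long$bold
  )
}

#' Extract region-mean time courses from a 4D NIfTI volume
#'
#' Convenience ingestion path: given a 4D BOLD volume and a 3D integer
#' label image on the same grid, returns the mean time course over the
#' voxels of each nonzero label code. Voxels are traversed in the image's
#' native (column-major x, y, z) order.
#'
#' @param bold_path Path to the 4D NIfTI.
#' @param label_path Path to the 3D integer label NIfTI.
#' @param region_names Optional named map label-code -> region name.
#' @return Tibble: `region` (label code or mapped name), `t`, `bold`.
#' @export
read_nifti_timecourses <- function(bold_path, label_path,
                                   region_names = NULL) {
  abort_if(!requireNamespace("RNifti", quietly = TRUE),
           "the RNifti package is required for NIfTI ingestion")
  vol <- RNifti::readNifti(bold_path)
  lab <- RNifti::readNifti(label_path)
  abort_if(length(dim(vol)) != 4, "bold volume must be 4D")
  abort_if(!all(dim(vol)[1:3] == dim(lab)[1:3]),
           "label image grid does not match the bold volume")
  n_t <- dim(vol)[4]
  vmat <- matrix(as.numeric(vol), ncol = n_t)  # voxels x time, column-major
  codes <- sort(unique(as.integer(lab)))
  codes <- codes[codes != 0]
  out <- lapply(codes, function(cd) {
    sel <- as.integer(lab) == cd
    nm <- if (!is.null(region_names) && as.character(cd) %in% names(region_names))
      region_names[[as.character(cd)]] else as.character(cd)
    tibble::tibble(region = nm, t = seq_len(n_t) - 1L,
                   bold = colMeans(vmat[sel, , drop = FALSE]))
  })
  dplyr::bind_rows(out)
}
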