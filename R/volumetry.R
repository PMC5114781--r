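#' Apply intensity thresholds within the ROI
#'
#' Voxels inside the ROI with intensity in the closed interval
#' `[lower, upper]` are kept as parenchyma; the remainder are split into a
#' below-lower and an above-upper mask.  Voxels exactly at a threshold are
#' kept.  No morphological clean-up is applied: removed voxels may be
#' scattered, exactly as the raw threshold dictates.
#'
#' @param volume An [image_volume()].
#' @param roi An `roi_mask` on the same grid.
#' @param thresholds A `threshold_pair`, or any list/vector with elements
#'   `lower` and `upper`.
#' @return An object of class `segmentation_result`: logical masks
#'   `kept_mask`, `below_mask`, `above_mask`; counts `kept_n`, `below_n`,
#'   `above_n`, `roi_n`; volumes `kept_ml`, `removed_ml`, `roi_ml`;
#'   `removed_fraction`; and the `thresholds` used.
#' @export
apply_thresholds <- function(volume, roi, thresholds) {
  stopifnot_aligned(volume, roi)
  lower <- thresholds[["lower"]]; upper <- thresholds[["upper"]]
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    err("unithresh_config_error",
        "need finite lower < upper, got (%s, %s)", lower, upper)
  x <- volume$data; m <- roi$data
  kept  <- m & x >= lower & x <= upper
  below <- m & x < lower
  above <- m & x > upper
  vox <- voxel_volume_ml(volume)
  kept_n <- sum(kept); below_n <- sum(below); above_n <- sum(above)
  roi_n <- sum(m)
  structure(list(kept_mask = kept, below_mask = below, above_mask = above,
                 thresholds = thresholds,
                 kept_n = kept_n, below_n = below_n, above_n = above_n,
                 roi_n = roi_n,
                 kept_ml = kept_n * vox,
                 removed_ml = (below_n + above_n) * vox,
                 roi_ml = roi_n * vox,
                 removed_fraction = (below_n + above_n) / roi_n,
                 voxel_ml = vox),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result> kept %.1f ml of %.1f ml ROI ",
                     "(removed %.1f ml, %.1f%%)\n"),
              x$kept_ml, x$roi_ml, x$removed_ml, 100 * x$removed_fraction))
  invisible(x)
}

#' Flatten a segmentation result into a one-row record
#'
#' Produces the flat per-kidney row that the results table is built from:
#' labels, thresholds, peak provenance (how many maxima were detected and
#' which was used), voxel counts, volumes, software version and a UTC
#' timestamp.  The default `run_id` is derived from the labels so that
#' re-running the same kidney overwrites rather than duplicates.
#'
#' @param result A `segmentation_result`.
#' @param subject,kidney,observer Label strings.
#' @param run_id Idempotency key; defaults to `subject_kidney_observer`.
#' @return A one-row `data.frame`.
#' @export
summarize_result <- function(result, subject = "NA", kidney = "NA",
                             observer = "NA", run_id = NULL) {
  th <- result$thresholds
  if (is.null(run_id))
    run_id <- paste(subject, kidney, observer, sep = "_")
  data.frame(
    subject = as.character(subject), kidney = as.character(kidney),
    observer = as.character(observer), run_id = as.character(run_id),
    lower = th[["lower"]], upper = th[["upper"]],
    selected_peak = if (!is.null(th$selected_ordinal)) th$selected_ordinal else NA_integer_,
    n_peaks = if (!is.null(th$n_peaks)) th$n_peaks else NA_integer_,
    kept_n = result$kept_n, below_n = result$below_n,
    above_n = result$above_n, roi_n = result$roi_n,
    kept_ml = result$kept_ml, removed_ml = result$removed_ml,
    roi_ml = result$roi_ml, removed_fraction = result$removed_fraction,
    version = as.character(utils::packageVersion("unithresh")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stringsAsFactors = FALSE)
}

results_key <- function(df) {
  paste(df$subject, df$kidney, df$observer, df$run_id, sep = "\r")
}

#' Append result records to the persistent results table
#'
#' The results table is a single CSV file, one row per kidney run, with the
#' column schema of [summarize_result()].  Appending is idempotent per the
#' `(subject, kidney, observer, run_id)` key: records whose key is already
#' present are skipped.  An existing file with a different column set is an
#' error rather than silently merged.
#'
#' @param records A `data.frame` of records (rows from
#'   [summarize_result()]), or a list of such one-row frames.
#' @param destination CSV file path; created if absent.
#' @return The number of rows appended, invisibly.
#' @export
export_results <- function(records, destination) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (file.exists(destination)) {
    old <- utils::read.csv(destination, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (!identical(names(old), names(records)))
      err("unithresh_export_error",
          "schema mismatch with existing results table %s", destination)
    new <- records[!(results_key(records) %in% results_key(old)), ,
                   drop = FALSE]
    if (nrow(new))
      utils::write.table(new, destination, sep = ",", append = TRUE,
                         col.names = FALSE, row.names = FALSE, qmethod = "double")
    invisible(nrow(new))
  } else {
    utils::write.csv(records, destination, row.names = FALSE)
    invisible(nrow(records))
  }
}

#' Read the results table back
#'
#' @param destination CSV file written by [export_results()].
#' @return A `data.frame` with numeric columns restored.
#' @export
read_results <- function(destination) {
  if (!file.exists(destination))
    err("unithresh_io_error", "no results table at %s", destination)
  utils::read.csv(destination, stringsAsFactors = FALSE)
}
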