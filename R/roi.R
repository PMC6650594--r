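# Per-scan measurements: structure volumes from label maps, mean scalar
# (FA/MD) per ROI, and assembly into the long-format scan panel.

#' Volumes of labelled structures
#'
#' @param labels a [label_map()].
#' @param which_labels optional integer vector of labels to report; labels
#'   absent from the map are reported with volume 0. Default: all nonzero
#'   labels present.
#' @return Named numeric vector, volume in mm^3 per label.
#' @export
label_volumes <- function(labels, which_labels = NULL) {
  stopifnot(inherits(labels, "label_map"))
  vv <- voxel_volume(labels)
  present <- sort(unique(as.vector(labels$data)))
  present <- present[present != 0L]
  if (is.null(which_labels)) which_labels <- present
  counts <- vapply(which_labels,
                   function(l) sum(labels$data == l), numeric(1L))
  stats::setNames(counts * vv, as.character(which_labels))
}

#' Mean scalar value per ROI
#'
#' @param scalar_map an [image_volume()] (e.g. an FA or MD map).
#' @param rois a [label_map()] on the identical grid.
#' @return Named numeric vector, mean scalar per nonzero label. Empty ROIs
#'   are omitted with a warning-level log message.
#' @export
roi_mean_scalar <- function(scalar_map, rois) {
  stopifnot(inherits(scalar_map, "image_volume"), inherits(rois, "label_map"))
  if (!same_grid(scalar_map, rois)) stop_mri("scalar map and ROI grid mismatch")
  labs <- sort(unique(as.vector(rois$data)))
  labs <- labs[labs != 0L]
  vals <- vapply(labs, function(l)
    mean(scalar_map$data[rois$data == l]), numeric(1L))
  stats::setNames(vals, as.character(labs))
}

#' Assemble per-scan measurements into a scan panel
#'
#' @param measurements list of per-scan entries, each
#'   `list(session_id =, metric =, values = <named numeric by label>)`.
#' @param metadata data frame with columns session_id, scanner_id, vendor
#'   and optionally is_rescan, covering every session.
#' @return A `scan_panel` data frame with columns scanner_id, vendor,
#'   session_id, is_rescan, label, metric, value; unique on
#'   (scanner, session, label, metric).
#' @export
assemble_panel <- function(measurements, metadata) {
  stopifnot(is.data.frame(metadata),
            all(c("session_id", "scanner_id", "vendor") %in% names(metadata)))
  if (!"is_rescan" %in% names(metadata)) metadata$is_rescan <- FALSE
  rows <- lapply(measurements, function(m) {
    meta <- metadata[metadata$session_id == m$session_id, , drop = FALSE]
    if (nrow(meta) == 0L)
      stop_mri("no metadata for session %s", m$session_id)
    data.frame(scanner_id = meta$scanner_id[1L], vendor = meta$vendor[1L],
               session_id = m$session_id, is_rescan = meta$is_rescan[1L],
               label = names(m$values), metric = m$metric,
               value = as.numeric(m$values), row.names = NULL)
  })
  panel <- do.call(rbind, rows)
  key <- with(panel, paste(scanner_id, session_id, label, metric, sep = "\r"))
  if (anyDuplicated(key))
    stop_mri("duplicate (scanner, session, label, metric) rows in panel")
  if (any(!is.finite(panel$value))) stop_mri("non-finite panel values")
  class(panel) <- c("scan_panel", "data.frame")
  panel
}

#' Read / write a scan panel as CSV
#'
#' @param panel a `scan_panel` data frame.
#' @param path CSV path (UTF-8, comma-separated, header row).
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   panel.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(label = "character"))
  need <- c("scanner_id", "vendor", "session_id", "is_rescan", "label",
            "metric", "value")
  if (!all(need %in% names(panel)))
    stop_mri("panel is missing columns: %s",
             paste(setdiff(need, names(panel)), collapse = ", "))
  class(panel) <- c("scan_panel", "data.frame")
  panel
}
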