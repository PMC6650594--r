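# Coefficient-of-variation reproducibility engine: inter-scanner,
# intra-scanner and intra-vendor CVs per label, the across-label summaries,
# and the inter : mean-intra ratio summaries.

#' Coefficient of variation
#'
#' `100 * sd(values) / mean(values)` with the sample standard deviation
#' (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_mri("insufficient replicates (n = %d < 2)",
                                    length(values))
  m <- mean(values)
  if (m == 0) stop_mri("zero mean: CV undefined")
  100 * stats::sd(values) / m
}

#' Coefficient of variation from summary statistics
#'
#' Applies `100 * sd / mean` to an already-summarised (mean, SD) pair, e.g.
#' a row of a published summary table.
#'
#' @param mean,sd summary statistics; `mean != 0`, `sd >= 0`.
#' @return CV in percent (full precision; rounding is the report layer's
#'   job).
#' @export
cv_from_summary <- function(mean, sd) {
  stopifnot(length(mean) == length(sd))
  if (any(mean == 0)) stop_mri("zero mean: CV undefined")
  if (any(sd < 0)) stop_mri("negative SD")
  100 * sd / mean
}

# Half-even rounding to 1 decimal, the report-layer convention.
round1 <- function(x) round(x, 1L)

#' Build the reproducibility table from a scan panel
#'
#' For every (label, metric): the inter-scanner row pools every scan across
#' all scanners (rescans included); per-scanner intra rows use that
#' scanner's scans (scanners with fewer than 2 scans contribute no intra
#' row); per-vendor rows pool scans across a vendor's scanners. Derived
#' columns: `mean_intra_cv_pct` is the unweighted mean of the per-scanner
#' intra CVs and `ratio_inter_to_mean_intra` is the full-precision ratio of
#' the inter CV to it.
#'
#' @param panel a `scan_panel` data frame (see [assemble_panel()]).
#' @return A `repro_table` list of data frames: `inter` (label, metric,
#'   mean, sd, cv_pct, mean_intra_cv_pct, ratio_inter_to_mean_intra),
#'   `intra` (scanner_id, label, metric, n, mean, sd, cv_pct), `vendor`
#'   (vendor, label, metric, n, mean, sd, cv_pct).
#' @export
build_repro_table <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("scanner_id", "vendor", "label", "metric", "value")
                %in% names(panel)))
  groups <- unique(panel[, c("label", "metric")])
  inter_rows <- list(); intra_rows <- list(); vendor_rows <- list()
  for (i in seq_len(nrow(groups))) {
    lab <- groups$label[i]; met <- groups$metric[i]
    sub <- panel[panel$label == lab & panel$metric == met, , drop = FALSE]
    if (nrow(sub) < 2L) {
      msg("label %s (%s) present on a single scan: excluded", lab, met)
      next
    }
    inter_cv <- cv(sub$value)
    per_scanner <- lapply(split(sub, sub$scanner_id), function(d) {
      if (nrow(d) < 2L) return(NULL)
      data.frame(scanner_id = d$scanner_id[1L], label = lab, metric = met,
                 n = nrow(d), mean = mean(d$value), sd = stats::sd(d$value),
                 cv_pct = cv(d$value), row.names = NULL)
    })
    per_scanner <- do.call(rbind, per_scanner)
    intra_rows[[length(intra_rows) + 1L]] <- per_scanner
    per_vendor <- lapply(split(sub, sub$vendor), function(d) {
      if (nrow(d) < 2L) return(NULL)
      data.frame(vendor = d$vendor[1L], label = lab, metric = met,
                 n = nrow(d), mean = mean(d$value), sd = stats::sd(d$value),
                 cv_pct = cv(d$value), row.names = NULL)
    })
    vendor_rows[[length(vendor_rows) + 1L]] <- do.call(rbind, per_vendor)
    mean_intra <- if (is.null(per_scanner)) NA_real_
                  else mean(per_scanner$cv_pct)
    inter_rows[[length(inter_rows) + 1L]] <- data.frame(
      label = lab, metric = met, n = nrow(sub), mean = mean(sub$value),
      sd = stats::sd(sub$value), cv_pct = inter_cv,
      mean_intra_cv_pct = mean_intra,
      ratio_inter_to_mean_intra =
        if (is.na(mean_intra) || mean_intra == 0) NA_real_
        else inter_cv / mean_intra,
      row.names = NULL)
  }
  structure(list(inter = do.call(rbind, inter_rows),
                 intra = do.call(rbind, intra_rows),
                 vendor = do.call(rbind, vendor_rows)),
            class = "repro_table")
}

#' Across-label summaries of a reproducibility table
#'
#' Unweighted mean and sample SD of the selected CV column across labels.
#' Scopes: `"inter"` summarises per-label inter-scanner CVs;
#' `"mean-intra"` first averages each scanner's per-label CVs across labels,
#' then averages those per-scanner means across scanners (the
#' "mean intra-scanner" headline); `"per-scanner"` returns one row per
#' scanner (mean/SD of its per-label CVs); `"vendor"` one row per vendor.
#'
#' @param table a `repro_table` from [build_repro_table()].
#' @param scope one of "inter", "mean-intra", "per-scanner", "vendor".
#' @param metric optional metric filter.
#' @return Data frame with columns scope, group, metric, n_labels,
#'   mean_cv_pct, sd_cv_pct. A single contributing value yields `NA` SD.
#' @export
summarize_across_labels <- function(table,
                                    scope = c("inter", "mean-intra",
                                              "per-scanner", "vendor"),
                                    metric = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "repro_table"))
  pick <- function(df) {
    if (is.null(df) || nrow(df) == 0L) stop_mri("empty scope: %s", scope)
    if (!is.null(metric)) df <- df[df$metric %in% metric, , drop = FALSE]
    if (nrow(df) == 0L) stop_mri("no rows for metric %s", metric)
    df
  }
  summ <- function(v) c(mean = mean(v),
                        sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  if (scope == "inter") {
    df <- pick(table$inter)
    out <- do.call(rbind, lapply(split(df, df$metric), function(d) {
      s <- summ(d$cv_pct)
      data.frame(scope = scope, group = "all", metric = d$metric[1L],
                 n_labels = nrow(d), mean_cv_pct = s[["mean"]],
                 sd_cv_pct = s[["sd"]], row.names = NULL)
    }))
    return(out)
  }
  df <- pick(table$intra)
  if (scope == "per-scanner") {
    out <- do.call(rbind, lapply(
      split(df, list(df$scanner_id, df$metric), drop = TRUE), function(d) {
        s <- summ(d$cv_pct)
        data.frame(scope = scope, group = d$scanner_id[1L],
                   metric = d$metric[1L], n_labels = nrow(d),
                   mean_cv_pct = s[["mean"]], sd_cv_pct = s[["sd"]],
                   row.names = NULL)
      }))
    rownames(out) <- NULL
    return(out)
  }
  if (scope == "mean-intra") {
    out <- do.call(rbind, lapply(split(df, df$metric), function(d) {
      per_scanner_means <- vapply(split(d$cv_pct, d$scanner_id), mean,
                                  numeric(1L))
      s <- summ(per_scanner_means)
      data.frame(scope = scope, group = "all", metric = d$metric[1L],
                 n_labels = length(unique(d$label)),
                 mean_cv_pct = s[["mean"]], sd_cv_pct = s[["sd"]],
                 row.names = NULL)
    }))
    return(out)
  }
  dfv <- pick(table$vendor)
  out <- do.call(rbind, lapply(
    split(dfv, list(dfv$vendor, dfv$metric), drop = TRUE), function(d) {
      s <- summ(d$cv_pct)
      data.frame(scope = scope, group = d$vendor[1L], metric = d$metric[1L],
                 n_labels = nrow(d), mean_cv_pct = s[["mean"]],
                 sd_cv_pct = s[["sd"]], row.names = NULL)
    }))
  rownames(out) <- NULL
  out
}

#' Summary of inter : mean-intra CV ratios
#'
#' @param table a `repro_table`, or a data frame with columns `label` and
#'   `ratio_inter_to_mean_intra` (e.g. a published per-label table).
#' @param metric optional metric filter.
#' @return A list: `mean_ratio`, `min_ratio`, `min_label`, `max_ratio`,
#'   `max_label`, `n`.
#' @export
ratio_summary <- function(table, metric = NULL) {
  df <- if (inherits(table, "repro_table")) table$inter else table
  stopifnot(is.data.frame(df),
            all(c("label", "ratio_inter_to_mean_intra") %in% names(df)))
  if (!is.null(metric)) df <- df[df$metric %in% metric, , drop = FALSE]
  df <- df[is.finite(df$ratio_inter_to_mean_intra), , drop = FALSE]
  if (nrow(df) == 0L) stop_mri("no defined ratios")
  r <- df$ratio_inter_to_mean_intra
  list(mean_ratio = mean(r),
       min_ratio = min(r), min_label = df$label[which.min(r)],
       max_ratio = max(r), max_label = df$label[which.max(r)],
       n = nrow(df))
}

#' Write report CSVs for a reproducibility table
#'
#' Emits `table_labels.csv` (per label: inter mean/SD/CV, mean-intra CV,
#' ratio), `table_intra.csv` (per scanner and label) and `summary.csv`
#' (across-label summaries per scope), all carrying a `metric` column and
#' CVs rounded to 1 decimal (half-even); full precision stays internal.
#'
#' @param table a `repro_table`.
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_repro_report <- function(table, out_dir) {
  stopifnot(inherits(table, "repro_table"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lab <- table$inter
  lab$cv_pct <- round1(lab$cv_pct)
  lab$mean_intra_cv_pct <- round1(lab$mean_intra_cv_pct)
  lab$ratio_inter_to_mean_intra <- round1(lab$ratio_inter_to_mean_intra)
  p1 <- file.path(out_dir, "table_labels.csv")
  utils::write.csv(lab, p1, row.names = FALSE)
  intra <- table$intra
  intra$cv_pct <- round1(intra$cv_pct)
  p2 <- file.path(out_dir, "table_intra.csv")
  utils::write.csv(intra, p2, row.names = FALSE)
  scopes <- c("inter", "mean-intra", "per-scanner")
  if (!is.null(table$vendor) && nrow(table$vendor) > 0L)
    scopes <- c(scopes, "vendor")
  summ <- do.call(rbind, lapply(scopes, function(s)
    summarize_across_labels(table, s)))
  summ$mean_cv_pct <- round1(summ$mean_cv_pct)
  summ$sd_cv_pct <- round1(summ$sd_cv_pct)
  p3 <- file.path(out_dir, "summary.csv")
  utils::write.csv(summ, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
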