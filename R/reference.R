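# Bundled reference tables: per-scanner and per-label summary statistics
# (mean, SD, CV, inter:intra ratio) published by a seven-scanner,
# five-site 3T quality-assurance study of ACR-phantom SNR/uniformity,
# brain-parcellation volumes (38 labels) and white-matter FA/MD (17 ROIs)
# in a traveling human phantom. They serve as worked-example inputs: the
# package's CV machinery must reproduce the printed CV columns and
# headline summaries from the printed means and SDs. FA values are in
# display units of 1e-1, MD in 1e-4 mm^2/s; display scaling is never used
# in computation.

#' Load a bundled reference summary table
#'
#' @param which one of "acr" (per-scanner SNR/IU summary), "overview"
#'   (across-label CV overview), "volume", "fa", "md" (per-label inter and
#'   mean-intra summaries).
#' @return A data frame.
#' @export
reference_table <- function(which = c("acr", "overview", "volume", "fa",
                                      "md")) {
  which <- match.arg(which)
  fn <- c(acr = "acr_summary.csv", overview = "cv_overview.csv",
          volume = "volume_labels.csv", fa = "fa_labels.csv",
          md = "md_labels.csv")[[which]]
  path <- system.file("extdata", "reference", fn, package = "mrirepro")
  if (path == "") stop_mri("bundled reference table %s not found", fn)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference per-label table in reproducibility layout
#'
#' Reshapes a per-label reference table ("volume", "fa" or "md") to the
#' column layout of `repro_table$inter` so that [ratio_summary()] and the
#' across-label summaries apply unchanged. The label column combines
#' structure and side.
#'
#' @param which "volume", "fa" or "md".
#' @param recompute_cv recompute the CV columns from the printed means and
#'   SDs via [cv_from_summary()] instead of taking the printed CV column.
#' @return A data frame with columns label, metric, mean, sd, cv_pct,
#'   mean_intra_cv_pct, ratio_inter_to_mean_intra.
#' @export
reference_label_table <- function(which = c("volume", "fa", "md"),
                                  recompute_cv = FALSE) {
  which <- match.arg(which)
  df <- reference_table(which)
  cv_col <- if (recompute_cv) cv_from_summary(df$inter_mean, df$inter_sd)
            else df$inter_cv_pct
  intra_col <- if (recompute_cv) cv_from_summary(df$intra_mean, df$intra_sd)
               else df$intra_cv_pct
  data.frame(label = paste(df$label, df$side),
             metric = c(volume = "volume_mm3", fa = "FA", md = "MD")[[which]],
             mean = df$inter_mean, sd = df$inter_sd, cv_pct = cv_col,
             mean_intra_cv_pct = intra_col,
             ratio_inter_to_mean_intra = df$ratio,
             row.names = NULL)
}
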