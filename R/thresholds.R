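#' Decision thresholds for the screening triage pipeline
#'
#' Bundles every cutoff used by hit calling, curve classification and cyst
#' segmentation into one list so sensitivity analyses are a single-argument
#' change. Defaults are the values used throughout the mouse, 3D-cyst and
#' human-panel screens.
#'
#' @param delta_auc_primary ΔAUC cutoff (AUC units) below which a compound is
#'   differential in the primary mouse screen.
#' @param delta_auc_validation ΔAUC cutoff for the validation mouse screen.
#' @param delta_auc_human ΔAUC cutoff for ADPKD vs NHK isolate pairs.
#' @param delta_zero_max upper bound on the difference of absolute fitted
#'   baseline ("zero") activities, percent, for a human differential call.
#' @param cyst_auc AUC cutoff below which a 3D-cyst CTG curve is active.
#' @param min_pairs,min_adpkd,min_nhk aggregation rule for the human panel: a
#'   compound is flagged when at least `min_pairs` isolate pairs are
#'   differential and those pairs span at least `min_adpkd` distinct ADPKD and
#'   `min_nhk` distinct NHK isolates.
#' @param inactive_band percent-activity magnitude below which a curve is
#'   considered inactive (curve class 4).
#' @param high_efficacy percent-efficacy magnitude separating the high- from
#'   partial-efficacy subclasses (x.1 vs x.2).
#' @param r2_min minimal coefficient of determination for a high-quality curve
#'   (classes -1.x / -2.x).
#' @param p_similar p-value threshold of the paired Wilcoxon test separating
#'   "similar" from "different" isolate pairs.
#' @param p_enrich adjusted p-value threshold for target enrichment.
#' @param area_min minimal accepted cyst region area, µm².
#' @param sbr_min minimal accepted region signal-to-background ratio.
#'
#' @return A named list of class `pkd_thresholds`.
#' @export
pkd_thresholds <- function(delta_auc_primary = -10,
                           delta_auc_validation = -20,
                           delta_auc_human = -60,
                           delta_zero_max = 10,
                           cyst_auc = -100,
                           min_pairs = 6,
                           min_adpkd = 2,
                           min_nhk = 3,
                           inactive_band = 25,
                           high_efficacy = 80,
                           r2_min = 0.9,
                           p_similar = 0.05,
                           p_enrich = 0.05,
                           area_min = 3500,
                           sbr_min = 0.4) {
  out <- list(
    delta_auc_primary = delta_auc_primary,
    delta_auc_validation = delta_auc_validation,
    delta_auc_human = delta_auc_human,
    delta_zero_max = delta_zero_max,
    cyst_auc = cyst_auc,
    min_pairs = min_pairs,
    min_adpkd = min_adpkd,
    min_nhk = min_nhk,
    inactive_band = inactive_band,
    high_efficacy = high_efficacy,
    r2_min = r2_min,
    p_similar = p_similar,
    p_enrich = p_enrich,
    area_min = area_min,
    sbr_min = sbr_min
  )
  class(out) <- "pkd_thresholds"
  out
}

#' @export
print.pkd_thresholds <- function(x, ...) {
  cat("pkdscreen decision thresholds\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
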