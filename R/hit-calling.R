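## Phase-specific decision rules turning compound profiles into hit lists.

# high-quality inhibitory curve classes (-1.x and -2.x)
is_high_quality <- function(curve_class) {
  !is.na(curve_class) & curve_class > -3 & curve_class < 0
}

#' Differential hit calling for paired Pkd1-null / wild-type profiles
#'
#' A compound is differential when its curve in the null line is high
#' quality (class -1.x or -2.x) and the AUC difference
#' `delta_auc = auc_null - auc_wt` falls below the phase cutoff (-10 for the
#' primary screen, -20 for validation). Both profile tables must be aligned
#' on compound and channel; the wt AUC is subtracted unconditionally, even
#' for inactive (class 4) wt curves.
#'
#' @param profiles_null,profiles_wt profile data.frames from
#'   [fit_profiles()] for the null and wild-type line of one cell pair.
#' @param phase `"primary"` or `"validation"`.
#' @param pair_id label of the cell pair carried into the output.
#' @param thresholds a [pkd_thresholds()].
#' @return data.frame with one row per compound and channel: compound_id,
#'   pair_id, channel, phase, class_null, class_wt, auc_null, auc_wt,
#'   delta_auc, is_hit.
#' @export
call_differential_mouse <- function(profiles_null, profiles_wt,
                                    phase = c("primary", "validation"),
                                    pair_id = NA_character_,
                                    thresholds = pkd_thresholds()) {
  phase <- match.arg(phase)
  cutoff <- if (phase == "primary") thresholds$delta_auc_primary
            else thresholds$delta_auc_validation
  key_n <- paste(profiles_null$compound_id, profiles_null$channel)
  key_w <- paste(profiles_wt$compound_id, profiles_wt$channel)
  m <- match(key_n, key_w)
  if (anyNA(m))
    warning(sum(is.na(m)), " compound/channel profiles lack a wild-type ",
            "counterpart; calls set inconclusive")
  auc_wt <- profiles_wt$auc[m]
  class_wt <- profiles_wt$curve_class[m]
  delta <- profiles_null$auc - auc_wt
  out <- data.frame(
    compound_id = profiles_null$compound_id,
    pair_id = pair_id,
    channel = profiles_null$channel,
    phase = phase,
    class_null = profiles_null$curve_class,
    class_wt = class_wt,
    auc_null = profiles_null$auc,
    auc_wt = auc_wt,
    delta_auc = delta,
    is_hit = is_high_quality(profiles_null$curve_class) &
      !is.na(delta) & delta < cutoff,
    stringsAsFactors = FALSE
  )
  out$is_hit[is.na(auc_wt)] <- NA
  out
}

#' Activity calling for the 3D cyst assay (CTG-3D readout)
#'
#' A compound is active when its CTG-3D curve class is non-4 (-1.x, -2.x,
#' -3 or 5) and its AUC is below the cutoff (default -100).
#'
#' @param profiles_3d profile data.frame restricted to the CTG-3D channel.
#' @param thresholds a [pkd_thresholds()].
#' @return data.frame: compound_id, curve_class, auc, is_active.
#' @export
call_cyst_active <- function(profiles_3d, thresholds = pkd_thresholds()) {
  data.frame(
    compound_id = profiles_3d$compound_id,
    curve_class = profiles_3d$curve_class,
    auc = profiles_3d$auc,
    is_active = profiles_3d$curve_class != 4 &
      profiles_3d$auc < thresholds$cyst_auc,
    stringsAsFactors = FALSE
  )
}

#' Differential calling for one ADPKD vs NHK isolate pair
#'
#' A compound shows a differential response when the ADPKD curve is high
#' quality (class -1.x/-2.x), `delta_auc = auc_ADPKD - auc_NHK < -60`, and
#' the difference of the absolute fitted baseline activities
#' `| |zero_ADPKD| - |zero_NHK| |` is below 10 percent, guarding against
#' pairs whose baselines disagree.
#'
#' @param profiles_adpkd,profiles_nhk profile data.frames for one ADPKD and
#'   one NHK isolate.
#' @param pair_id label (e.g. "K251xK347").
#' @param thresholds a [pkd_thresholds()].
#' @return data.frame per compound and channel with delta_auc,
#'   delta_abs_zero and is_hit.
#' @export
call_differential_human_pair <- function(profiles_adpkd, profiles_nhk,
                                         pair_id = NA_character_,
                                         thresholds = pkd_thresholds()) {
  key_a <- paste(profiles_adpkd$compound_id, profiles_adpkd$channel)
  key_n <- paste(profiles_nhk$compound_id, profiles_nhk$channel)
  m <- match(key_a, key_n)
  delta <- profiles_adpkd$auc - profiles_nhk$auc[m]
  dzero <- abs(abs(profiles_adpkd$zero) - abs(profiles_nhk$zero[m]))
  out <- data.frame(
    compound_id = profiles_adpkd$compound_id,
    pair_id = pair_id,
    channel = profiles_adpkd$channel,
    phase = "human",
    class_adpkd = profiles_adpkd$curve_class,
    delta_auc = delta,
    delta_abs_zero = dzero,
    is_hit = is_high_quality(profiles_adpkd$curve_class) &
      !is.na(delta) & delta < thresholds$delta_auc_human &
      !is.na(dzero) & dzero < thresholds$delta_zero_max,
    stringsAsFactors = FALSE
  )
  out$is_hit[is.na(m)] <- NA
  out
}

#' Aggregate human-pair calls into panel-level hits
#'
#' A pair counts as differential for a compound when it is a hit in either
#' viability channel. A compound is flagged when at least `min_pairs` pairs
#' are differential and those pairs span at least `min_adpkd` distinct
#' ADPKD and `min_nhk` distinct NHK isolates (defaults 6 / 2 / 3).
#'
#' @param calls data.frame of [call_differential_human_pair()] results over
#'   all isolate pairs; `pair_id` must be "ADPKD-isolate" and "NHK-isolate"
#'   joined by `"x"`.
#' @param thresholds a [pkd_thresholds()].
#' @return data.frame per compound: n_pairs, n_adpkd, n_nhk, flagged.
#' @export
aggregate_human_hits <- function(calls, thresholds = pkd_thresholds()) {
  parts <- strsplit(calls$pair_id, "x", fixed = TRUE)
  calls$adpkd_iso <- vapply(parts, `[`, "", 1)
  calls$nhk_iso <- vapply(parts, `[`, "", 2)
  hit <- calls[!is.na(calls$is_hit) & calls$is_hit, ]
  # a pair is counted once per compound regardless of channel
  hit_pairs <- unique(hit[c("compound_id", "pair_id", "adpkd_iso", "nhk_iso")])
  all_cpds <- unique(calls$compound_id)
  sp <- split(hit_pairs, factor(hit_pairs$compound_id, levels = all_cpds))
  out <- do.call(rbind, lapply(names(sp), function(cpd) {
    d <- sp[[cpd]]
    data.frame(compound_id = cpd,
               n_pairs = nrow(d),
               n_adpkd = length(unique(d$adpkd_iso)),
               n_nhk = length(unique(d$nhk_iso)),
               stringsAsFactors = FALSE)
  }))
  out$flagged <- out$n_pairs >= thresholds$min_pairs &
    out$n_adpkd >= thresholds$min_adpkd &
    out$n_nhk >= thresholds$min_nhk
  rownames(out) <- NULL
  out
}

#' Categorize mouse hits by cell pair and readout
#'
#' Partitions validated differential compounds into embryonic-only,
#' postnatal-only or both (pair axis) crossed with GF-AFC-only, CTG-only or
#' both (readout axis), and reports fractions.
#'
#' @param calls data.frame of [call_differential_mouse()] results covering
#'   both cell pairs and channels.
#' @return data.frame per hit compound: pair_category, channel_category;
#'   attribute `"fractions"` holds the pair-axis proportions.
#' @export
categorize_hits <- function(calls) {
  hits <- calls[!is.na(calls$is_hit) & calls$is_hit, ]
  if (nrow(hits) == 0) {
    out <- data.frame(compound_id = character(), pair_category = character(),
                      channel_category = character(), stringsAsFactors = FALSE)
    attr(out, "fractions") <- numeric(0)
    return(out)
  }
  sp <- split(hits, hits$compound_id)
  out <- do.call(rbind, lapply(names(sp), function(cpd) {
    d <- sp[[cpd]]
    pairs <- unique(d$pair_id)
    chans <- unique(d$channel)
    pc <- if (length(pairs) > 1) "both" else paste0(pairs, "_only")
    cc <- if (length(chans) > 1) "both" else chans
    data.frame(compound_id = cpd, pair_category = pc, channel_category = cc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "fractions") <- table(out$pair_category) / nrow(out)
  out
}
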