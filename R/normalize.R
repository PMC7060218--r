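#' Percent activity relative to intra-plate controls
#'
#' Affine rescaling anchored on the plate's own controls: the neutral
#' (DMSO) center maps to 0% and the positive (full-kill) center to -100%,
#' so viability loss is negative.
#'
#' @param signal raw signal(s), arbitrary units.
#' @param neutral_center central value of the neutral-control wells.
#' @param positive_center central value of the positive-control wells.
#' @return Percent activity, same length as `signal`.
#' @export
percent_activity <- function(signal, neutral_center, positive_center) {
  if (!is.finite(neutral_center) || !is.finite(positive_center) ||
      neutral_center == positive_center)
    stop("degenerate controls: neutral and positive centers must differ")
  100 * (signal - neutral_center) / (neutral_center - positive_center)
}

#' Normalize a well table plate-wise
#'
#' Computes, per plate and channel, the median of the neutral and positive
#' control wells and converts every signal to percent activity with
#' [percent_activity()]. Plates whose control centers coincide are flagged:
#' their activities are set to `NA`.
#'
#' With `recenter_baseline = TRUE` a second pass re-anchors each plate and
#' channel on the median activity of its bottom-dose compound wells. On an
#' 11-point titration the lowest dose (~1 nM) sits far below any realistic
#' AC50, so those ~100+ wells act as a large internal negative control that
#' estimates the plate's residual offset far more precisely than the
#' control column alone; the offset is subtracted from every well of the
#' plate/channel. Use it for deep titrations only - on the 8-point cyst
#' series the bottom dose (0.78 µM) is not baseline for potent compounds.
#'
#' @param wells well-record data.frame (see [simulate_monolayer_screen()]).
#' @param recenter_baseline re-anchor plates on bottom-dose compound wells
#'   (see Details).
#' @return The input with an added `activity` column (percent).
#' @export
normalize_wells <- function(wells, recenter_baseline = FALSE) {
  key <- paste(wells$plate_id, wells$channel, sep = "\r")
  neu <- tapply(wells$signal[wells$role == "neutral"],
                key[wells$role == "neutral"], stats::median)
  pos <- tapply(wells$signal[wells$role == "positive"],
                key[wells$role == "positive"], stats::median)
  nc <- neu[key]; pc <- pos[key]
  bad <- !is.finite(nc) | !is.finite(pc) | nc == pc
  act <- rep(NA_real_, nrow(wells))
  act[!bad] <- 100 * (wells$signal[!bad] - nc[!bad]) / (nc[!bad] - pc[!bad])
  if (any(bad)) {
    flagged <- unique(wells$plate_id[bad])
    warning("degenerate or missing controls on plate(s): ",
            paste(flagged, collapse = ", "), "; activities set missing")
  }
  wells$activity <- as.numeric(act)
  if (recenter_baseline) {
    is_cpd <- wells$role == "compound" & !is.na(wells$conc_um)
    bottom <- is_cpd & wells$conc_um == min(wells$conc_um[is_cpd])
    off <- tapply(wells$activity[bottom], key[bottom], stats::median,
                  na.rm = TRUE)
    adj <- off[key]
    adj[is.na(adj)] <- 0
    wells$activity <- wells$activity - as.numeric(adj)
  }
  wells
}

#' Plate quality control: Z' factor and signal-to-background
#'
#' For each plate and channel computes the Z' factor,
#' `1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, and the
#' signal-to-background ratio `mean_neg / mean_pos` (neutral control as
#' signal). Zero separation of the control means yields `Z' = -Inf` and a
#' flag.
#'
#' @param wells well-record data.frame.
#' @return data.frame with one row per plate and channel: plate_id, channel,
#'   n_neg, n_pos, zprime, s_to_b, flagged.
#' @export
plate_qc <- function(wells) {
  ctrl <- wells[wells$role %in% c("neutral", "positive"), ]
  sp <- split(ctrl, list(ctrl$plate_id, ctrl$channel), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    neg <- d$signal[d$role == "neutral"]   # neutral = high-signal group
    pos <- d$signal[d$role == "positive"]
    if (length(neg) < 2 || length(pos) < 2)
      stop("plate ", d$plate_id[1], "/", d$channel[1],
           ": need >= 2 wells per control group")
    sep <- abs(mean(neg) - mean(pos))
    z <- if (sep == 0) -Inf else 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / sep
    data.frame(plate_id = d$plate_id[1], channel = d$channel[1],
               n_neg = length(neg), n_pos = length(pos),
               zprime = z,
               s_to_b = mean(neg) / mean(pos),
               flagged = !is.finite(z),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble per-compound titrations from normalized wells
#'
#' Collects one titration per compound, cell line and channel: ascending
#' concentrations with replicate activities kept separate and a
#' median-aggregated activity alongside. Missing dose points stay absent
#' (gaps), they are not imputed.
#'
#' @param wells normalized well-record data.frame (column `activity`).
#' @return data.frame with columns compound_id, cell_line, channel, conc_um,
#'   activity (median across replicates), n_rep; attribute `"replicates"`
#'   holds the long per-replicate table.
#' @export
assemble_titrations <- function(wells) {
  if (!"activity" %in% names(wells))
    stop("wells are not normalized; run normalize_wells() first")
  cpd <- wells[wells$role == "compound" & !is.na(wells$compound_id), ]
  if (nrow(cpd) == 0) {
    out <- data.frame(compound_id = character(), cell_line = character(),
                      channel = character(), conc_um = numeric(),
                      activity = numeric(), n_rep = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "replicates") <- cpd
    return(out)
  }
  key <- interaction(cpd$compound_id, cpd$cell_line, cpd$channel, cpd$conc_um,
                     drop = TRUE, lex.order = TRUE)
  agg <- data.frame(
    compound_id = tapply(cpd$compound_id, key, `[`, 1),
    cell_line = tapply(cpd$cell_line, key, `[`, 1),
    channel = tapply(cpd$channel, key, `[`, 1),
    conc_um = as.numeric(tapply(cpd$conc_um, key, `[`, 1)),
    activity = as.numeric(tapply(cpd$activity, key, stats::median, na.rm = TRUE)),
    n_rep = as.integer(tapply(cpd$activity, key, length)),
    stringsAsFactors = FALSE
  )
  agg <- agg[order(agg$compound_id, agg$cell_line, agg$channel, agg$conc_um), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- cpd[c("compound_id", "cell_line", "channel",
                                   "conc_um", "replicate", "activity")]
  agg
}
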