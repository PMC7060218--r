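## Synthetic bright-field z-stack rendering and cyst quantification.
##
## Wells are imaged as 30-plane bright-field stacks; analysis picks the
## sharpest plane per well, segments high-contrast regions, and keeps those
## above the area (3500 µm²) and region signal-to-background (0.4) cutoffs.

#' Render a synthetic bright-field cyst image stack
#'
#' Draws each ground-truth object onto a constant-background stack: solid
#' cell aggregates as filled bright discs, swelled cysts (lumen = TRUE) as a
#' bright annulus around a dim fluid-filled lumen. Every object is sharpest
#' at its assigned focus plane and increasingly Gaussian-blurred away from
#' it, emulating confocal defocus.
#'
#' @param objects data.frame with columns `x_um`, `y_um`, `radius_um`,
#'   `lumen` (logical), `contrast` (relative to background) and
#'   `focus_plane` (1-based). Empty data.frame gives a pure-background
#'   stack. Overlapping objects are permitted; negative radii are an error.
#' @param pixel_size µm per pixel.
#' @param n_planes number of z sections (default 30).
#' @param dim_px image size, pixels (rows, cols).
#' @param background background intensity (normalized units in (0, 1)).
#' @param z_spacing µm between sections (metadata only).
#' @param blur_per_plane Gaussian sigma (pixels) added per plane of defocus.
#' @param well_id label carried on the stack.
#' @return Object of class `cyst_stack`: list(planes = 3-D array
#'   rows x cols x z, pixel_size, z_spacing, well_id).
#' @export
render_cyst_image <- function(objects, pixel_size = 2, n_planes = 30,
                              dim_px = c(256, 256), background = 0.2,
                              z_spacing = 25, blur_per_plane = 1.2,
                              well_id = "well") {
  stopifnot(pixel_size > 0, n_planes >= 1)
  if (nrow(objects) > 0 && any(objects$radius_um < 0))
    stop("negative object radius")
  if (!"contrast" %in% names(objects) && nrow(objects) > 0)
    objects$contrast <- 0.8
  if (!"focus_plane" %in% names(objects) && nrow(objects) > 0)
    objects$focus_plane <- ceiling(n_planes / 2)
  planes <- array(background, dim = c(dim_px[1], dim_px[2], n_planes))
  for (k in seq_len(nrow(objects))) {
    ob <- objects[k, ]
    r_px <- ob$radius_um / pixel_size
    cx <- ob$x_um / pixel_size
    cy <- ob$y_um / pixel_size
    for (z in seq_len(n_planes)) {
      sigma <- blur_per_plane * abs(z - ob$focus_plane)
      half <- ceiling(r_px + 3 * sigma + 2)
      rows <- max(1, round(cx - half)):min(dim_px[1], round(cx + half))
      cols <- max(1, round(cy - half)):min(dim_px[2], round(cy + half))
      if (length(rows) == 0 || length(cols) == 0) next
      rr <- outer(rows - cx, cols - cy, function(i, j) sqrt(i^2 + j^2))
      delta <- matrix(0, length(rows), length(cols))
      if (isTRUE(ob$lumen)) {
        ring <- rr <= r_px & rr > 0.7 * r_px
        lum <- rr <= 0.7 * r_px
        delta[ring] <- background * ob$contrast
        delta[lum] <- -0.4 * background
      } else {
        delta[rr <= r_px] <- background * ob$contrast
      }
      if (sigma > 0.05)
        delta <- as.matrix(EBImage::gblur(delta, sigma = sigma))
      planes[rows, cols, z] <- planes[rows, cols, z] + delta
    }
  }
  out <- list(planes = planes, pixel_size = pixel_size,
              z_spacing = z_spacing, well_id = well_id)
  class(out) <- "cyst_stack"
  out
}

#' @export
print.cyst_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("cyst_stack %s: %d x %d px, %d planes, %.3g um/px\n",
              x$well_id, d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' Select the most-focused plane of a z-stack
#'
#' Sharpness surrogate: high-frequency texture energy, the mean squared
#' response of a 4-neighbor Laplacian. The plane maximizing it is returned;
#' exact ties break to the lowest index. A uniform stack returns plane 1
#' with a warning.
#'
#' @param stack a `cyst_stack` (or plain 3-D array).
#' @return 1-based plane index.
#' @export
select_focus_plane <- function(stack) {
  planes <- if (inherits(stack, "cyst_stack")) stack$planes else stack
  stopifnot(length(dim(planes)) == 3, dim(planes)[3] >= 1)
  nr <- dim(planes)[1]; nc <- dim(planes)[2]
  score <- vapply(seq_len(dim(planes)[3]), function(z) {
    p <- planes[, , z]
    if (nr < 3 || nc < 3) return(stats::var(as.numeric(p)))
    lap <- 4 * p[2:(nr - 1), 2:(nc - 1)] -
      p[1:(nr - 2), 2:(nc - 1)] - p[3:nr, 2:(nc - 1)] -
      p[2:(nr - 1), 1:(nc - 2)] - p[2:(nr - 1), 3:nc]
    mean(lap^2)
  }, numeric(1))
  if (max(score) < 1e-12)
    warning("uniform stack: no texture, returning plane 1")
  which.max(score)
}

#' Segment cyst regions in one image plane
#'
#' Contrast-based detection: pixels deviating from the background (plane
#' median) by more than `detect_frac` relative contrast form the candidate
#' mask; connected components are hole-filled (a dim lumen belongs to its
#' cyst) and kept iff area >= `area_min` µm² and region
#' signal-to-background ratio >= `sbr_min`. The SBR is the region mean of
#' `|intensity - background| / background`: bright-field structures deviate
#' in both directions (bright cyst wall, dim lumen), so the unsigned
#' deviation measures contrast where a signed mean would cancel over a
#' swelled cyst.
#'
#' @param plane 2-D intensity matrix.
#' @param pixel_size µm per pixel.
#' @param thresholds a [pkd_thresholds()] (area_min, sbr_min).
#' @param detect_frac pixel-level relative-contrast detection threshold;
#'   kept below `sbr_min` so low-contrast regions are detected and then
#'   rejected by the region rule rather than silently missed.
#' @return data.frame of accepted regions: area_um2, sbr, x_px, y_px
#'   (centroid), n_px.
#' @export
segment_cysts <- function(plane, pixel_size, thresholds = pkd_thresholds(),
                          detect_frac = 0.2) {
  bg <- stats::median(plane)
  empty <- data.frame(area_um2 = numeric(), sbr = numeric(),
                      x_px = numeric(), y_px = numeric(), n_px = integer())
  if (bg <= 0) return(empty)
  mask <- abs(plane - bg) / bg > detect_frac
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask * 1)))
  lab <- as.matrix(EBImage::imageData(lab))
  ids <- setdiff(unique(as.integer(lab)), 0L)
  rows <- lapply(ids, function(id) {
    sel <- lab == id
    n_px <- sum(sel)
    area <- n_px * pixel_size^2
    sbr <- mean(abs(plane[sel] - bg)) / bg
    idx <- which(sel, arr.ind = TRUE)
    data.frame(area_um2 = area, sbr = sbr,
               x_px = mean(idx[, 1]), y_px = mean(idx[, 2]), n_px = n_px)
  })
  out <- do.call(rbind, rows)
  out <- out[out$area_um2 >= thresholds$area_min &
               out$sbr >= thresholds$sbr_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the cyst content of one well
#'
#' @param regions accepted regions from [segment_cysts()] on the selected
#'   focus plane.
#' @return list(n_cysts, total_area_um2); (0, 0) for an empty well.
#' @export
summarize_well <- function(regions) {
  list(n_cysts = nrow(regions),
       total_area_um2 = if (nrow(regions)) sum(regions$area_um2) else 0)
}

#' Full imaging analysis of one well stack
#'
#' Convenience wrapper: focus-plane selection, segmentation on that plane,
#' well summary.
#'
#' @param stack a `cyst_stack`.
#' @param thresholds a [pkd_thresholds()].
#' @param ... passed to [segment_cysts()].
#' @return list(focus_plane, regions, n_cysts, total_area_um2).
#' @export
analyze_cyst_stack <- function(stack, thresholds = pkd_thresholds(), ...) {
  fp <- select_focus_plane(stack)
  regions <- segment_cysts(stack$planes[, , fp], stack$pixel_size,
                           thresholds = thresholds, ...)
  c(list(focus_plane = fp, regions = regions), summarize_well(regions))
}

#' Imaging-based cyst-size dose-response titrations
#'
#' Normalizes per-well total cyst area to the neutral-control (DMSO) median
#' - DMSO maps to 0%, complete cyst loss to -100% - and assembles
#' per-compound titrations on the `cyst-area` channel, ready for
#' [fit_profiles()].
#'
#' @param summaries per-well data.frame with columns role, compound_id,
#'   conc_um, total_area_um2 (e.g. the `cysts` table of
#'   [simulate_cyst_plate()] or collected [analyze_cyst_stack()] output).
#' @param cell_line label for the output titrations.
#' @return Titration data.frame (compound_id, cell_line, channel, conc_um,
#'   activity, n_rep) like [assemble_titrations()].
#' @export
cyst_dose_response <- function(summaries, cell_line = "PN24-3D") {
  dmso <- summaries$total_area_um2[summaries$role == "neutral"]
  if (length(dmso) == 0) stop("no neutral (DMSO) reference wells")
  ref <- stats::median(dmso)
  if (ref <= 0) stop("DMSO reference cyst area is zero")
  cpd <- summaries[summaries$role == "compound" & !is.na(summaries$compound_id), ]
  cpd$activity <- 100 * (cpd$total_area_um2 / ref - 1)
  key <- interaction(cpd$compound_id, cpd$conc_um, drop = TRUE,
                     lex.order = TRUE)
  out <- data.frame(
    compound_id = tapply(cpd$compound_id, key, `[`, 1),
    cell_line = cell_line,
    channel = "cyst-area",
    conc_um = as.numeric(tapply(cpd$conc_um, key, `[`, 1)),
    activity = as.numeric(tapply(cpd$activity, key, stats::median)),
    n_rep = as.integer(tapply(cpd$activity, key, length)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$compound_id, out$conc_um), ]
  rownames(out) <- NULL
  out
}

#' Write / read a cyst stack as multi-page TIFF
#'
#' Intensities are stored as 32-bit float; pixel size and z spacing are not
#' serialized and must be supplied on read.
#'
#' @param stack a `cyst_stack`.
#' @param path TIFF file path.
#' @param pixel_size,z_spacing,well_id metadata for the reconstructed stack.
#' @return `read_cyst_stack` returns a `cyst_stack`.
#' @export
write_cyst_stack <- function(stack, path) {
  pls <- lapply(seq_len(dim(stack$planes)[3]),
                function(z) stack$planes[, , z])
  tiff::writeTIFF(pls, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_cyst_stack
#' @export
read_cyst_stack <- function(path, pixel_size, z_spacing = 25,
                            well_id = basename(path)) {
  pls <- tiff::readTIFF(path, all = TRUE)
  planes <- array(unlist(pls), dim = c(dim(pls[[1]])[1], dim(pls[[1]])[2],
                                       length(pls)))
  out <- list(planes = planes, pixel_size = pixel_size,
              z_spacing = z_spacing, well_id = well_id)
  class(out) <- "cyst_stack"
  out
}
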