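## Four-parameter Hill fitting for qHTS concentration-response curves.
##
## The model is a(c) = zero + (inf - zero) / (1 + (ac50/c)^h): `zero` is the
## low-concentration asymptote (baseline activity), `inf` the
## high-concentration asymptote, both in percent activity; ac50 in µM; h a
## positive slope. For fixed (ac50, h) the model is linear in (zero, inf),
## which the multi-start exploits: a coarse grid over (log ac50, h) with an
## analytic linear solve picks starting points for bounded quasi-Newton
## refinement.

#' Hill model response
#'
#' @param conc concentrations, µM.
#' @param zero low-concentration asymptote, percent.
#' @param inf high-concentration asymptote, percent.
#' @param ac50 midpoint concentration, µM.
#' @param hill slope, > 0.
#' @return Percent activity at `conc`.
#' @export
hill_response <- function(conc, zero, inf, ac50, hill) {
  zero + (inf - zero) / (1 + (ac50 / conc)^hill)
}

# parameter bounds shared by grid and refinement
.hill_bounds <- function(conc) {
  list(zero = c(-30, 30), inf = c(-130, 30),
       la = log10(range(conc)) + c(-1, 1), h = c(0.3, 8))
}

# cache of grid precomputations keyed by the concentration vector
.grid_cache <- new.env(parent = emptyenv())

.hill_grid <- function(conc) {
  key <- paste(signif(conc, 8), collapse = ",")
  g <- .grid_cache[[key]]
  if (!is.null(g)) return(g)
  la <- seq(log10(min(conc) / 3), log10(max(conc) * 3), length.out = 15)
  h <- c(0.5, 1, 2, 4)
  par <- expand.grid(la = la, h = h, KEEP.OUT.ATTRS = FALSE)
  Fm <- t(vapply(seq_len(nrow(par)),
                 function(i) 1 / (1 + (10^par$la[i] / conc)^par$h[i]),
                 numeric(length(conc))))
  U <- 1 - Fm
  g <- list(par = par, Fm = Fm, U = U,
            Suu = rowSums(U^2), Suv = rowSums(U * Fm), Svv = rowSums(Fm^2))
  .grid_cache[[key]] <- g
  g
}

.clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

#' Fit the Hill equation to a titration
#'
#' Bounded least squares with multi-start: candidate (AC50, slope) pairs on
#' a log-spaced grid are scored by an analytic linear fit of the two
#' asymptotes, and the best candidates are refined by L-BFGS-B inside the
#' parameter box zero in [-30, 30], inf in [-130, 30], slope in [0.3, 8] and
#' AC50 within a tenfold extension of the tested range.
#'
#' @param conc ascending concentrations, µM (>= 4 points).
#' @param activity percent activities (replicate-aggregated), same length.
#' @param n_starts number of grid candidates refined by optimization.
#' @return Object of class `hill_fit`: zero, inf, ac50, hill, r2, rss,
#'   converged, plus the data.
#' @export
fit_hill <- function(conc, activity, n_starts = 3) {
  stopifnot(length(conc) == length(activity), all(diff(conc) > 0),
            all(conc > 0))
  if (length(conc) < 4) stop("Hill fit requires at least 4 dose points")
  keep <- is.finite(activity)
  conc_f <- conc[keep]; a <- activity[keep]
  if (length(a) < 4) stop("Hill fit requires at least 4 finite activities")

  b <- .hill_bounds(conc_f)
  g <- .hill_grid(conc_f)
  Sua <- as.numeric(g$U %*% a)
  Sva <- as.numeric(g$Fm %*% a)
  det <- g$Suu * g$Svv - g$Suv^2
  ok <- det > 1e-9
  zero <- ifelse(ok, (g$Svv * Sua - g$Suv * Sva) / det, mean(a))
  infv <- ifelse(ok, (g$Suu * Sva - g$Suv * Sua) / det, mean(a))
  zero <- .clamp(zero, b$zero)
  infv <- .clamp(infv, b$inf)
  aa <- sum(a^2)
  rss <- aa - 2 * zero * Sua - 2 * infv * Sva +
    zero^2 * g$Suu + 2 * zero * infv * g$Suv + infv^2 * g$Svv

  obj <- function(p) {
    r <- a - hill_response(conc_f, p[1], p[2], 10^p[3], p[4])
    sum(r * r)
  }
  lower <- c(b$zero[1], b$inf[1], b$la[1], b$h[1])
  upper <- c(b$zero[2], b$inf[2], b$la[2], b$h[2])
  starts <- order(rss)[seq_len(min(n_starts, length(rss)))]
  best <- NULL
  for (i in starts) {
    p0 <- c(zero[i], infv[i], g$par$la[i], g$par$h[i])
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    # fall back to the best grid candidate
    i <- starts[1]
    best <- list(par = c(zero[i], infv[i], g$par$la[i], g$par$h[i]),
                 value = rss[i], convergence = 1L)
  }
  p <- best$par
  tss <- sum((a - mean(a))^2)
  r2 <- if (tss < 1e-12) as.numeric(best$value < 1e-8) else 1 - best$value / tss
  # L-BFGS-B reports an abnormal line-search exit when started at (or next
  # to) an exact minimum; that is convergence, not failure
  conv <- best$convergence == 0 ||
    (!is.null(best$message) && grepl("ABNORMAL", best$message))
  out <- list(zero = p[1], inf = p[2], ac50 = 10^p[3], hill = p[4],
              r2 = r2, rss = best$value,
              converged = conv,
              conc = conc_f, activity = a)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: zero %.1f%%, inf %.1f%%, AC50 %.3g uM, slope %.2f (r2 %.3f%s)\n",
    x$zero, x$inf, x$ac50, x$hill, x$r2,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(zero = object$zero, inf = object$inf, ac50 = object$ac50,
    hill = object$hill)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$conc else newdata
  hill_response(conc, object$zero, object$inf, object$ac50, object$hill)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$activity - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$conc, x$activity, log = "x", xlab = "concentration (uM)",
                 ylab = "activity (%)", ...)
  cc <- 10^seq(log10(min(x$conc)), log10(max(x$conc)), length.out = 100)
  graphics::lines(cc, predict(x, cc))
  invisible(x)
}

#' Efficacy of a Hill fit
#'
#' The fitted span `inf - zero` in percent; negative values are viability
#' loss.
#' @param fit a `hill_fit`.
#' @return Numeric efficacy.
#' @export
hill_efficacy <- function(fit) fit$inf - fit$zero

#' Assign a signed curve class to a fitted titration
#'
#' Classes follow the qHTS taxonomy for decreasing (inhibitory) responses:
#' -1.1/-1.2 complete curves with both asymptotes inside the tested range
#' and good fit (split at 80% efficacy magnitude), -2.1/-2.2 incomplete
#' curves with a single observed asymptote, -3 activity only at the highest
#' tested concentration, 4 inactive (efficacy magnitude below the
#' inactivity band), 5 active but poorly fit.
#'
#' @param fit a `hill_fit`.
#' @param conc,activity the titration the fit was computed from (defaults to
#'   the data stored in the fit).
#' @param thresholds a [pkd_thresholds()].
#' @return Numeric class code in {-1.1, -1.2, -2.1, -2.2, -3, 4, 5}.
#' @export
classify_curve <- function(fit, conc = fit$conc, activity = fit$activity,
                           thresholds = pkd_thresholds()) {
  band <- thresholds$inactive_band
  hi <- thresholds$high_efficacy
  m <- length(activity)
  # single-point activity: the top dose responds while the rest of the
  # titration is genuinely flat (within half the inactivity band), which
  # separates -3 curves from shallow incomplete sigmoids
  top_only <- m >= 3 && abs(activity[m]) >= band &&
    all(abs(activity[-m]) < band / 2)
  if (fit$converged) {
    eff <- hill_efficacy(fit)
    if (abs(eff) < band) return(4)
    if (top_only) return(-3)
    if (fit$r2 >= thresholds$r2_min) {
      f_lo <- 1 / (1 + (fit$ac50 / min(conc))^fit$hill)
      f_hi <- 1 / (1 + (fit$ac50 / max(conc))^fit$hill)
      sub <- if (abs(eff) >= hi) 0.1 else 0.2
      if (f_lo <= 0.1 && f_hi >= 0.9) return(-(1 + sub))
      return(-(2 + sub))
    }
    return(5)
  }
  # data-driven fallback when the optimizer failed
  if (all(abs(activity) < band)) return(4)
  if (top_only) return(-3)
  5
}

#' Area under the concentration-response curve
#'
#' Trapezoidal integral of the fitted percent activity evaluated at the
#' tested concentrations with unit spacing per dilution step, so curves
#' screened over different ranges stay comparable. A fully inhibitory curve
#' (-100% everywhere) over an 11-point titration gives -1000. Non-converged
#' fits fall back to the empirical activities.
#'
#' @param fit a `hill_fit` (or `NULL` to integrate the raw activities).
#' @param conc,activity titration data (defaults taken from the fit).
#' @return AUC in percent x dilution-step units.
#' @export
compute_auc <- function(fit = NULL, conc = fit$conc, activity = fit$activity) {
  if (length(conc) < 2) stop("AUC undefined for fewer than 2 dose points")
  v <- if (!is.null(fit) && fit$converged) predict(fit, conc) else activity
  sum((v[-1] + v[-length(v)]) / 2)
}

#' Fit, classify and summarize every titration of a screen
#'
#' Batch driver producing the compound-profile table that all hit calling
#' consumes: one row per compound, cell line and channel with the fitted
#' Hill parameters, curve class and AUC. For class-4 curves whose
#' activities all lie within the inactivity band the AUC is reported as 0.
#'
#' @param titrations data.frame from [assemble_titrations()].
#' @param thresholds a [pkd_thresholds()].
#' @return data.frame with columns compound_id, cell_line, channel, n_points,
#'   zero, inf, ac50_um, hill, r2, converged, curve_class, auc.
#' @export
fit_profiles <- function(titrations, thresholds = pkd_thresholds()) {
  key <- interaction(titrations$compound_id, titrations$cell_line,
                     titrations$channel, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(titrations)), key)
  rows <- lapply(idx, function(i) {
    d <- titrations[i, ]
    d <- d[order(d$conc_um), ]
    fit <- fit_hill(d$conc_um, d$activity)
    cls <- classify_curve(fit, thresholds = thresholds)
    auc <- compute_auc(fit)
    if (cls == 4 && all(abs(d$activity) < thresholds$inactive_band,
                        na.rm = TRUE))
      auc <- 0
    data.frame(compound_id = d$compound_id[1], cell_line = d$cell_line[1],
               channel = d$channel[1], n_points = nrow(d),
               zero = fit$zero, inf = fit$inf, ac50_um = fit$ac50,
               hill = fit$hill, r2 = fit$r2, converged = fit$converged,
               curve_class = cls, auc = auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
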