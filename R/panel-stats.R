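## Pairwise compound-response similarity across the human isolate panel.

#' Paired Wilcoxon signed-rank test on compound AUC vectors
#'
#' Two-sided test of whether two isolates respond differently to the same
#' compound set. Pairs with a missing value are dropped, zero differences
#' are discarded (classic Wilcoxon convention), ties in the absolute
#' differences get mid-ranks. The exact null distribution is used up to
#' n = 25 remaining pairs when no ties are present, the normal approximation
#' with continuity correction otherwise.
#'
#' @param x,y AUC vectors aligned on the same compounds.
#' @param exact_max largest n for which the exact distribution is used.
#' @return Two-sided p-value; 1 when every difference is zero.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (length(x[keep]) < 5)
    warning("fewer than 5 complete compound pairs; p-value unstable")
  has_ties <- anyDuplicated(abs(d)) > 0
  exact <- !has_ties && n <= exact_max
  suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value
  )
}

#' Pairwise similarity matrix of isolate compound responses
#'
#' Builds the symmetric matrix of paired Wilcoxon p-values over all isolate
#' pairs for one viability channel, plus the categorical map used for the
#' heat map: pairs with p above the threshold are "similar", below it
#' "different".
#'
#' @param profiles profile data.frame from [fit_profiles()] over all
#'   isolates (cell_line = isolate).
#' @param channel viability channel to analyze ("CTG" or "GF-AFC").
#' @param thresholds a [pkd_thresholds()].
#' @param min_common isolates sharing fewer compounds than this with the
#'   panel are excluded (with a message).
#' @return Object of class `panel_matrix`: list with `isolates`, `pvalues`
#'   (symmetric, unit diagonal), `category` ("similar"/"different") and
#'   `channel`.
#' @export
similarity_matrix <- function(profiles, channel = "CTG",
                              thresholds = pkd_thresholds(),
                              min_common = 5) {
  d <- profiles[profiles$channel == channel, ]
  isolates <- unique(d$cell_line)
  cpds <- Reduce(intersect, split(d$compound_id, d$cell_line))
  if (length(cpds) < min_common)
    stop("fewer than ", min_common, " compounds shared across isolates")
  auc <- vapply(isolates, function(iso) {
    di <- d[d$cell_line == iso, ]
    di$auc[match(cpds, di$compound_id)]
  }, numeric(length(cpds)))
  n_ok <- colSums(is.finite(auc))
  drop <- n_ok < min_common
  if (any(drop)) {
    message("excluding isolates with < ", min_common, " usable compounds: ",
            paste(isolates[drop], collapse = ", "))
    isolates <- isolates[!drop]
    auc <- auc[, !drop, drop = FALSE]
  }
  k <- length(isolates)
  pm <- matrix(1, k, k, dimnames = list(isolates, isolates))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- wilcoxon_signed_rank(auc[, i], auc[, j])
      pm[i, j] <- pm[j, i] <- p
    }
  }
  out <- list(isolates = isolates, pvalues = pm,
              category = ifelse(pm < thresholds$p_similar,
                                "different", "similar"),
              channel = channel)
  class(out) <- "panel_matrix"
  out
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat("Panel similarity matrix (", x$channel, " readout), ",
      length(x$isolates), " isolates\n", sep = "")
  print(round(x$pvalues, 4))
  invisible(x)
}

#' Two-color heat map of a panel similarity matrix
#'
#' Similar pairs (p above threshold) in yellow, different pairs in pink,
#' mirroring the panel-comparison display convention.
#'
#' @param x a `panel_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.panel_matrix <- function(x, ...) {
  k <- length(x$isolates)
  z <- matrix(as.numeric(x$category == "similar"), k, k)
  graphics::image(seq_len(k), seq_len(k), z[, k:1],
                  col = c("#f8b4c8", "#f5e663"), zlim = c(0, 1),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("Compound-response similarity,", x$channel), ...)
  graphics::axis(1, at = seq_len(k), labels = x$isolates, las = 2, tick = FALSE)
  graphics::axis(2, at = seq_len(k), labels = rev(x$isolates), las = 1,
                 tick = FALSE)
  invisible(x)
}

#' Write a panel matrix as CSV
#' @param x a `panel_matrix`.
#' @param path output file.
#' @export
write_panel_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x$pvalues), path, row.names = TRUE)
  invisible(path)
}
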