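## Primary-target enrichment of hit compounds vs the screened collection.

#' Fisher's exact over-representation test for one target gene
#'
#' One-sided test on the 2x2 table crossing hit membership with annotation
#' to `gene`. Compounds without any annotation are excluded from the
#' universe.
#'
#' @param gene gene symbol.
#' @param hits character vector of hit compound ids.
#' @param screened character vector of all screened compound ids (superset
#'   of `hits`).
#' @param annotations data.frame with columns `compound_id`, `gene` (one row
#'   per compound-gene link).
#' @return List: gene, counts (hits_with_gene, hits_total,
#'   screened_with_gene, screened_total), odds_ratio, p.
#' @export
fisher_gene <- function(gene, hits, screened, annotations) {
  ann <- annotations[!is.na(annotations$gene), ]
  annotated <- unique(ann$compound_id)
  screened <- intersect(screened, annotated)
  hits <- intersect(hits, screened)
  if (length(screened) == 0) stop("no annotated screened compounds")
  with_gene <- unique(ann$compound_id[ann$gene == gene])
  a <- length(intersect(hits, with_gene))
  b <- length(hits) - a
  c <- length(intersect(setdiff(screened, hits), with_gene))
  d <- length(screened) - length(hits) - c
  ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                           alternative = "greater")
  list(gene = gene,
       hits_with_gene = a, hits_total = length(hits),
       screened_with_gene = a + c, screened_total = length(screened),
       odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction (order-preserving,
#' monotone).
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Target enrichment table for a hit list
#'
#' Runs [fisher_gene()] for every gene annotated to at least one screened
#' compound, adjusts with Benjamini-Hochberg and ranks by adjusted p.
#' Genes with fewer than `min_count` hit compounds are marked
#' `displayed = FALSE` (suppressed from display output) but retained in the
#' table. Significance is declared at adjusted p below the threshold.
#'
#' @param hits,screened compound id vectors, `hits` a subset of `screened`.
#' @param annotations compound-gene annotation data.frame.
#' @param min_count minimal hit-compound count for display.
#' @param thresholds a [pkd_thresholds()].
#' @param sig_greater treat adjusted p greater than the threshold as
#'   significant instead (non-standard literal convention; default off).
#' @return data.frame ranked by p_adj: gene, hits_with_gene, hits_total,
#'   screened_with_gene, screened_total, odds_ratio, p, p_adj, significant,
#'   displayed.
#' @export
enrich_targets <- function(hits, screened, annotations, min_count = 2,
                           thresholds = pkd_thresholds(),
                           sig_greater = FALSE) {
  stopifnot(all(hits %in% screened))
  ann <- annotations[!is.na(annotations$gene) &
                       annotations$compound_id %in% screened, ]
  if (length(hits) == 0 || nrow(ann) == 0) {
    return(data.frame(gene = character(), hits_with_gene = integer(),
                      hits_total = integer(), screened_with_gene = integer(),
                      screened_total = integer(), odds_ratio = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), displayed = logical(),
                      stringsAsFactors = FALSE))
  }
  genes <- sort(unique(ann$gene))
  rows <- lapply(genes, fisher_gene, hits = hits, screened = screened,
                 annotations = ann)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- if (sig_greater) out$p_adj > thresholds$p_enrich
                     else out$p_adj < thresholds$p_enrich
  out$displayed <- out$hits_with_gene >= min_count
  out <- out[order(out$p_adj, out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Build the annotation table of a synthetic truth table
#'
#' @param truth a [make_truth_table()] result.
#' @return data.frame compound_id, gene, moa, indication (one row per
#'   compound-gene link; unannotated compounds are absent).
#' @export
truth_annotations <- function(truth) {
  cmp <- truth$compounds
  ann <- cmp[!is.na(cmp$target_gene),
             c("compound_id", "target_gene", "category")]
  data.frame(compound_id = ann$compound_id, gene = ann$target_gene,
             moa = paste0(ann$target_gene, " modulation"),
             indication = ifelse(grepl("differential|pan", ann$category),
                                 "antineoplastic", "other"),
             stringsAsFactors = FALSE)
}
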