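## End-to-end pipeline: simulate -> normalize -> fit -> call -> panel ->
## enrich (-> cyst assay), with versioned CSV outputs and a machine-readable
## summary.

.pipeline_stages <- c("simulate", "normalize", "fit", "call", "cyst",
                      "panel", "enrich")

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent); `NULL` disables file
#'   output.
#' @param stages subset of `simulate, normalize, fit, call, cyst, panel,
#'   enrich`, executed in canonical order. Later stages require earlier
#'   ones.
#' @param n_compounds compounds in the simulated campaign.
#' @param noise_cv measurement noise CV.
#' @param n_replicates replicate plates for the monolayer screen.
#' @param phase mouse hit-calling phase (`"primary"` or `"validation"`).
#' @param n_panel_compounds compounds carried onto the human panel (capped
#'   at the mouse hit-list size when hits exist).
#' @param n_panel_selective,n_panel_pan planted ADPKD-selective and
#'   pan-active compounds on the panel.
#' @param seed master seed; every stage derives from it.
#' @param thresholds a [pkd_thresholds()].
#' @return List of class `pkd_config`.
#' @export
pkd_config <- function(out_dir = NULL,
                       stages = .pipeline_stages,
                       n_compounds = 200,
                       noise_cv = 0.1,
                       n_replicates = 1,
                       phase = "validation",
                       n_panel_compounds = 60,
                       n_panel_selective = 10,
                       n_panel_pan = 15,
                       seed = 1L,
                       thresholds = pkd_thresholds()) {
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  out <- list(out_dir = out_dir,
              stages = .pipeline_stages[.pipeline_stages %in% stages],
              n_compounds = n_compounds, noise_cv = noise_cv,
              n_replicates = n_replicates, phase = phase,
              n_panel_compounds = n_panel_compounds,
              n_panel_selective = n_panel_selective,
              n_panel_pan = n_panel_pan,
              seed = as.integer(seed), thresholds = thresholds)
  class(out) <- "pkd_config"
  out
}

.emit <- function(cfg, name, df) {
  if (!is.null(cfg$out_dir))
    utils::write.csv(df, file.path(cfg$out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  invisible(df)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the screening triage pipeline
#'
#' Executes the configured stages on a synthetic campaign with planted
#' ground truth and writes per-stage CSVs plus a JSON summary to
#' `config$out_dir`. Reruns with the same configuration are reproducible.
#'
#' @param config a [pkd_config()].
#' @return Invisibly, a list with every stage result plus `summary`.
#' @export
run_pipeline <- function(config = pkd_config()) {
  stopifnot(inherits(config, "pkd_config"))
  if (!is.null(config$out_dir) &&
      !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  th <- config$thresholds
  res <- list(config = config)
  stages <- config$stages

  truth <- make_truth_table(config$n_compounds, seed = config$seed)
  res$truth <- truth

  if ("simulate" %in% stages) {
    res$wells <- .stage("simulate", {
      cfg <- screen_config(n_compounds = config$n_compounds,
                           noise_cv = config$noise_cv,
                           n_replicates = config$n_replicates,
                           seed = config$seed)
      simulate_monolayer_screen(cfg, truth)
    })
  }

  if ("normalize" %in% stages) {
    res$wells <- .stage("normalize",
                        normalize_wells(res$wells, recenter_baseline = TRUE))
    res$qc <- .stage("normalize", plate_qc(res$wells))
    .emit(config, "plate_qc", res$qc)
  }

  if ("fit" %in% stages) {
    res$titrations <- .stage("fit", assemble_titrations(res$wells))
    res$profiles <- .stage("fit", fit_profiles(res$titrations, th))
    .emit(config, "profiles", res$profiles)
  }

  if ("call" %in% stages) {
    res$mouse_calls <- .stage("call", {
      lines <- mouse_cell_lines()
      do.call(rbind, lapply(unique(lines$pair_id), function(pid) {
        nl <- lines$cell_line[lines$pair_id == pid & lines$genotype == "null"]
        wl <- lines$cell_line[lines$pair_id == pid & lines$genotype == "wt"]
        call_differential_mouse(
          res$profiles[res$profiles$cell_line == nl, ],
          res$profiles[res$profiles$cell_line == wl, ],
          phase = config$phase, pair_id = pid, thresholds = th)
      }))
    })
    res$mouse_hits <- sort(unique(
      res$mouse_calls$compound_id[res$mouse_calls$is_hit %in% TRUE]))
    res$hit_categories <- categorize_hits(res$mouse_calls)
    .emit(config, "mouse_calls", res$mouse_calls)
    .emit(config, "hit_categories", res$hit_categories)
  }

  if ("cyst" %in% stages) {
    res$cyst <- .stage("cyst", {
      cfg <- screen_config(n_compounds = config$n_compounds,
                           plate_format = 384,
                           titration = cyst_titration(),
                           noise_cv = config$noise_cv,
                           seed = config$seed)
      sim <- simulate_cyst_plate(cfg, truth)
      wells <- normalize_wells(sim$wells)
      prof3d <- fit_profiles(assemble_titrations(wells), th)
      calls <- call_cyst_active(prof3d, th)
      area_titr <- cyst_dose_response(sim$cysts)
      area_prof <- fit_profiles(area_titr, th)
      # swelling-only phenotype: imaging channel active (same rule as the
      # viability call), viability channel inactive
      area_calls <- call_cyst_active(area_prof, th)
      swell <- merge(
        data.frame(compound_id = calls$compound_id,
                   viability_class = calls$curve_class),
        data.frame(compound_id = area_calls$compound_id,
                   area_class = area_calls$curve_class,
                   area_active = area_calls$is_active),
        by = "compound_id")
      swell$swelling_reduced <- swell$area_active &
        swell$viability_class == 4
      list(profiles = prof3d, calls = calls, area_profiles = area_prof,
           swelling = swell)
    })
    .emit(config, "cyst_calls", res$cyst$calls)
  }

  if ("panel" %in% stages) {
    res$panel <- .stage("panel", {
      cpds <- if (!is.null(res$mouse_hits) && length(res$mouse_hits) >= 10)
        utils::head(res$mouse_hits, config$n_panel_compounds)
      else truth$compounds$compound_id[seq_len(config$n_panel_compounds)]
      ptruth <- make_panel_truth(
        cpds, n_selective = min(config$n_panel_selective, length(cpds)),
        n_pan = min(config$n_panel_pan,
                    length(cpds) - config$n_panel_selective),
        seed = config$seed)
      cfg <- screen_config(n_compounds = length(cpds),
                           noise_cv = config$noise_cv,
                           seed = config$seed)
      wells <- normalize_wells(simulate_panel_screen(cfg, ptruth),
                               recenter_baseline = TRUE)
      prof <- fit_profiles(assemble_titrations(wells), th)
      iso <- ptruth$isolates
      pairs <- expand.grid(a = iso$isolate[iso$group == "ADPKD"],
                           n = iso$isolate[iso$group == "NHK"],
                           stringsAsFactors = FALSE)
      calls <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        call_differential_human_pair(
          prof[prof$cell_line == pairs$a[i], ],
          prof[prof$cell_line == pairs$n[i], ],
          pair_id = paste0(pairs$a[i], "x", pairs$n[i]), thresholds = th)
      }))
      hits <- aggregate_human_hits(calls, th)
      sims <- lapply(c("CTG", "GF-AFC"), function(ch)
        similarity_matrix(prof, channel = ch, thresholds = th))
      names(sims) <- c("CTG", "GF-AFC")
      list(truth = ptruth, profiles = prof, calls = calls, hits = hits,
           similarity = sims)
    })
    .emit(config, "panel_hits", res$panel$hits)
    if (!is.null(config$out_dir)) {
      for (ch in names(res$panel$similarity)) {
        write_panel_matrix(res$panel$similarity[[ch]],
                           file.path(config$out_dir,
                                     paste0("panel_similarity_", ch, ".csv")))
        grDevices::png(file.path(config$out_dir,
                                 paste0("panel_similarity_", ch, ".png")),
                       width = 600, height = 600)
        plot(res$panel$similarity[[ch]])
        grDevices::dev.off()
      }
    }
  }

  if ("enrich" %in% stages) {
    res$enrichment <- .stage("enrich", {
      ann <- truth_annotations(truth)
      enrich_targets(res$mouse_hits, truth$compounds$compound_id, ann,
                     thresholds = th)
    })
    .emit(config, "enrichment", res$enrichment)
  }

  res$summary <- .pipeline_summary(res)
  if (!is.null(config$out_dir))
    jsonlite::write_json(res$summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(res)
}

.pipeline_summary <- function(res) {
  s <- list(seed = res$config$seed,
            n_compounds = res$config$n_compounds,
            noise_cv = res$config$noise_cv)
  if (!is.null(res$qc))
    s$median_zprime <- stats::median(res$qc$zprime)
  if (!is.null(res$mouse_hits)) {
    s$n_mouse_hits <- length(res$mouse_hits)
    s$pair_fractions <- as.list(attr(res$hit_categories, "fractions"))
  }
  if (!is.null(res$cyst)) {
    s$n_cyst_active <- sum(res$cyst$calls$is_active)
    s$n_swelling_only <- sum(res$cyst$swelling$swelling_reduced)
  }
  if (!is.null(res$panel))
    s$n_panel_flagged <- sum(res$panel$hits$flagged)
  if (!is.null(res$enrichment))
    s$enriched_genes <- res$enrichment$gene[res$enrichment$significant &
                                              res$enrichment$displayed]
  s
}
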