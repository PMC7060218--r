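## ---- internal helpers -----------------------------------------------------

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# fractional viability suppression at concentration conc (µM); in [-1, 0]
hill_suppression <- function(conc, ac50, efficacy, hill) {
  ifelse(conc <= 0 | efficacy == 0, 0,
         (efficacy / 100) / (1 + (ac50 / conc)^hill))
}

# multiplicative log-normal noise factors with mean 1 and CV = cv
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
         "1536" = c(32L, 48L),
         "384"  = c(16L, 24L),
         stop("unsupported plate format: ", plate_format))
}

## ---- configuration --------------------------------------------------------

#' Titration series used by the screening campaigns
#'
#' `mouse_titration()` is the 11-point 1:3 dilution series topping out at
#' 57 µM used for monolayer viability screens (mouse validation and human
#' panel); `cyst_titration()` is the 8-point 1:2 series from 100 µM used in
#' the 384-well 3D cyst assay.
#'
#' @param n number of concentration points.
#' @param top top concentration, µM.
#' @param fold dilution factor between adjacent points.
#' @return Numeric vector of concentrations in µM, ascending.
#' @export
mouse_titration <- function(n = 11, top = 57, fold = 3) {
  sort(top / fold^(seq_len(n) - 1))
}

#' @rdname mouse_titration
#' @export
cyst_titration <- function(n = 8, top = 100, fold = 2) {
  sort(top / fold^(seq_len(n) - 1))
}

#' Screen configuration
#'
#' @param n_compounds number of test compounds.
#' @param plate_format 1536 (monolayer) or 384 (3D cyst).
#' @param titration ascending concentration series, µM.
#' @param n_replicates replicate plates per condition.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (0 = noiseless).
#' @param seed integer seed controlling all randomness of the simulators.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(n_compounds = 500,
                          plate_format = 1536,
                          titration = mouse_titration(),
                          n_replicates = 1,
                          noise_cv = 0,
                          seed = 1L) {
  stopifnot(n_compounds >= 1, noise_cv >= 0,
            all(diff(titration) > 0), length(titration) >= 2)
  out <- list(n_compounds = as.integer(n_compounds),
              plate_format = as.integer(plate_format),
              titration = as.numeric(titration),
              n_replicates = as.integer(n_replicates),
              noise_cv = noise_cv,
              seed = as.integer(seed))
  class(out) <- "screen_config"
  out
}

#' Mouse cell-line panel: two Pkd1-null / wild-type pairs
#'
#' The embryonic pair is collecting-duct derived (MEK-null vs MEK-wt); the
#' postnatal pair is proximal-tubule derived (PN24, null, vs PH2,
#' heterozygous control).
#'
#' @return data.frame with columns `cell_line`, `pair_id`, `genotype`.
#' @export
mouse_cell_lines <- function() {
  data.frame(
    cell_line = c("MEK-null", "MEK-wt", "PN24", "PH2"),
    pair_id   = c("embryonic", "embryonic", "postnatal", "postnatal"),
    genotype  = c("null", "wt", "null", "wt"),
    stringsAsFactors = FALSE
  )
}

#' Human kidney isolate panel: 5 ADPKD and 6 NHK primary cultures
#'
#' @return data.frame with columns `isolate`, `group`.
#' @export
panel_isolates <- function() {
  data.frame(
    isolate = c("K251", "K287", "K315", "K417", "K429",
                "K347", "K370", "K381", "K388", "K412", "K419"),
    group   = c(rep("ADPKD", 5), rep("NHK", 6)),
    stringsAsFactors = FALSE
  )
}

## ---- truth tables ---------------------------------------------------------

# gene pools used to annotate synthetic compounds; the "hit" pool mimics the
# target classes recurrently found among differential compounds
.hit_genes <- c("XPO1", "TUBB1", "HDAC1", "TOP1", "SPHK1", "HMGCR",
                "HSP90AA1", "CDK9")
.bg_genes <- paste0("GENE", sprintf("%02d", 1:40))

#' Generate a planted truth table for a mouse monolayer screen
#'
#' Assigns every compound a category (differential in the embryonic pair,
#' the postnatal pair, both pairs, pan-active, inactive, or active on cyst
#' swelling only), per-cell-line Hill parameters consistent with that
#' category, and a primary-target gene annotation. Differential compounds
#' carry an efficacy gap of at least `margin` percent between the null and
#' wild-type line of the affected pair, and draw their target genes from a
#' small recurrent pool so that target enrichment has planted signal.
#'
#' @param n_compounds number of compounds.
#' @param fractions named numeric vector of category proportions; must sum
#'   to at most 1 (remainder is inactive).
#' @param cell_lines data.frame as returned by [mouse_cell_lines()].
#' @param margin minimal efficacy gap (percent) planted between null and wt
#'   lines for differential categories.
#' @param seed integer seed.
#' @return List of class `pkd_truth` with elements `compounds` (compound_id,
#'   category, target_gene, swell_ac50_um, swell_reduction), `params`
#'   (compound_id, cell_line, ac50_um, efficacy, hill) and `margin`.
#' @export
make_truth_table <- function(n_compounds = 500,
                             fractions = c(differential_embryonic = 0.08,
                                           differential_postnatal = 0.06,
                                           differential_both = 0.06,
                                           pan_active = 0.15,
                                           cyst_swelling_only = 0.03),
                             cell_lines = mouse_cell_lines(),
                             margin = 60,
                             seed = 1L) {
  stopifnot(sum(fractions) <= 1, margin <= 65)
  with_seed(seed, {
    cats <- c(names(fractions), "inactive")
    n_per <- c(floor(fractions * n_compounds),
               n_compounds - sum(floor(fractions * n_compounds)))
    category <- rep(cats, times = n_per)
    compound_id <- sprintf("CPD%04d", seq_len(n_compounds))

    is_diff <- grepl("^differential", category)
    target_gene <- character(n_compounds)
    target_gene[is_diff] <- sample(.hit_genes, sum(is_diff), replace = TRUE)
    target_gene[!is_diff] <- sample(.bg_genes, sum(!is_diff), replace = TRUE)
    target_gene[stats::runif(n_compounds) < 0.05] <- NA_character_

    swell <- category == "cyst_swelling_only"
    # inside the observable window of the 8-point cyst titration (0.78-100)
    swell_ac50 <- ifelse(swell, 10^stats::runif(n_compounds, log10(2), log10(20)), NA)
    swell_red <- ifelse(swell, stats::runif(n_compounds, 0.7, 0.95), NA)

    compounds <- data.frame(compound_id, category, target_gene,
                            swell_ac50_um = swell_ac50,
                            swell_reduction = swell_red,
                            stringsAsFactors = FALSE)

    # per cell line Hill parameters; active efficacy in [-100, -80] keeps the
    # null/wt gap >= margin given wt efficacy in [-15, 0]
    params <- expand.grid(compound_id = compound_id,
                          cell_line = cell_lines$cell_line,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    params <- merge(params, cell_lines, by = "cell_line", sort = FALSE)
    params <- merge(params, compounds[c("compound_id", "category")],
                    by = "compound_id", sort = FALSE)

    n_par <- nrow(params)
    params$ac50_um <- 10^stats::runif(n_par, log10(0.1), log10(10))
    params$hill <- stats::runif(n_par, 0.8, 2.5)
    params$efficacy <- 0

    active <- with(params,
      (category == "pan_active") |
      (category == "differential_both" & genotype == "null") |
      (category == "differential_embryonic" & genotype == "null" & pair_id == "embryonic") |
      (category == "differential_postnatal" & genotype == "null" & pair_id == "postnatal"))
    weak_wt <- grepl("^differential", params$category) & params$genotype == "wt"

    params$efficacy[active] <- stats::runif(sum(active), -100, -80)
    params$efficacy[weak_wt] <- stats::runif(sum(weak_wt), -15, 0)

    # pan-active compounds suppress both genotypes equally: copy the null
    # parameters onto the wt line so no spurious differential arises
    pan <- params$category == "pan_active"
    key <- paste(params$compound_id, params$pair_id)
    for (fld in c("ac50_um", "hill", "efficacy")) {
      src <- params[[fld]][pan & params$genotype == "null"]
      names(src) <- key[pan & params$genotype == "null"]
      params[[fld]][pan & params$genotype == "wt"] <-
        src[key[pan & params$genotype == "wt"]]
    }

    out <- list(compounds = compounds,
                params = params[c("compound_id", "cell_line", "pair_id",
                                  "genotype", "ac50_um", "hill", "efficacy")],
                margin = margin)
    class(out) <- "pkd_truth"
    out
  })
}

#' @export
print.pkd_truth <- function(x, ...) {
  cat("pkdscreen planted truth table:", nrow(x$compounds), "compounds\n")
  print(table(x$compounds$category))
  invisible(x)
}

#' True differential compounds of a planted truth table
#'
#' @param truth a `pkd_truth` object.
#' @param pair optionally restrict to one cell pair (`"embryonic"` or
#'   `"postnatal"`).
#' @return Character vector of compound ids.
#' @export
truth_differential <- function(truth, pair = NULL) {
  cat_sel <- c("differential_embryonic", "differential_postnatal",
               "differential_both")
  if (!is.null(pair)) {
    cat_sel <- c("differential_both",
                 paste0("differential_", match.arg(pair, c("embryonic", "postnatal"))))
  }
  truth$compounds$compound_id[truth$compounds$category %in% cat_sel]
}

## ---- monolayer simulator --------------------------------------------------

# channel baselines (arbitrary units) and the residual signal fraction of the
# digitonin-killed positive control
.channel_baseline <- c("GF-AFC" = 2500, "CTG" = 5e5, "CTG-3D" = 8e5)
.kill_floor_frac <- 0.05

# lay n_cpd x n_conc compound wells plus two control columns onto plates of
# the given format; returns data.frame of well coordinates
.layout_wells <- function(n_cpd, concs, plate_format, plate_prefix) {
  dims <- plate_dims(plate_format)
  n_rows <- dims[1]; n_cols <- dims[2]
  cap <- n_rows * (n_cols - 2L)          # columns 0-1 reserved for controls
  grid <- expand.grid(conc_idx = seq_along(concs), cpd = seq_len(n_cpd),
                      KEEP.OUT.ATTRS = FALSE)
  idx <- seq_len(nrow(grid)) - 1L
  plate <- idx %/% cap
  within <- idx %% cap
  cmp <- data.frame(
    plate_id = paste0(plate_prefix, "_p", plate + 1L),
    row = as.integer(within %% n_rows),
    col = as.integer(2L + within %/% n_rows),
    role = "compound",
    cpd = grid$cpd,
    conc_idx = grid$conc_idx,
    stringsAsFactors = FALSE
  )
  plates <- unique(cmp$plate_id)
  ctrl <- expand.grid(plate_id = plates, row = seq_len(n_rows) - 1L,
                      col = 0:1, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctrl$role <- ifelse(ctrl$col == 0L, "positive", "neutral")
  ctrl$cpd <- NA_integer_
  ctrl$conc_idx <- NA_integer_
  rbind(cmp, ctrl[names(cmp)])
}

# core well-signal generator shared by all simulators: params gives one row
# per compound with ac50_um, hill, efficacy for a single cell line
.simulate_wells <- function(params, concs, plate_format, plate_prefix,
                            channels, noise_cv) {
  n_cpd <- nrow(params)
  lay <- .layout_wells(n_cpd, concs, plate_format, plate_prefix)
  is_cpd <- lay$role == "compound"
  conc <- ifelse(is_cpd, concs[lay$conc_idx], NA_real_)
  cpd_id <- ifelse(is_cpd, params$compound_id[lay$cpd], NA_character_)

  sup <- numeric(nrow(lay))
  sup[is_cpd] <- hill_suppression(conc[is_cpd],
                                  params$ac50_um[lay$cpd[is_cpd]],
                                  params$efficacy[lay$cpd[is_cpd]],
                                  params$hill[lay$cpd[is_cpd]])
  viab <- 1 + sup                        # fraction of neutral-control signal
  viab[lay$role == "positive"] <- 0

  out <- do.call(rbind, lapply(channels, function(ch) {
    base <- .channel_baseline[[ch]]
    floorv <- .kill_floor_frac * base
    true_sig <- floorv + (base - floorv) * viab
    data.frame(plate_id = lay$plate_id, row = lay$row, col = lay$col,
               role = lay$role, compound_id = cpd_id, conc_um = conc,
               channel = ch,
               signal = true_sig * lnorm_noise(length(true_sig), noise_cv),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a monolayer qHTS viability screen
#'
#' Generates raw well-level signals for every compound of the truth table at
#' all titration points, in both viability channels (GF-AFC fluorescence and
#' CTG luminescence), for each cell line, on 1,536-well plates whose first
#' two columns carry the digitonin positive and DMSO neutral controls.
#' Signals follow `floor + (neutral - floor) * (1 + s(c))` where `s(c)` is
#' the planted Hill-shaped suppression, multiplied by log-normal noise with
#' CV `noise_cv`. Replicates are realized as separate plates.
#'
#' @param config a [screen_config()].
#' @param truth a [make_truth_table()] result; its compound count must match
#'   `config$n_compounds`.
#' @param cell_lines data.frame as [mouse_cell_lines()].
#' @return data.frame of well records with columns plate_id, row, col, role,
#'   compound_id, conc_um, channel, cell_line, replicate, signal.
#' @export
simulate_monolayer_screen <- function(config, truth,
                                      cell_lines = mouse_cell_lines()) {
  stopifnot(inherits(config, "screen_config"), inherits(truth, "pkd_truth"))
  if (nrow(truth$compounds) != config$n_compounds)
    stop("truth table has ", nrow(truth$compounds),
         " compounds but config demands ", config$n_compounds)
  with_seed(config$seed, {
    out <- do.call(rbind, lapply(cell_lines$cell_line, function(cl) {
      p <- truth$params[truth$params$cell_line == cl, ]
      p <- p[match(truth$compounds$compound_id, p$compound_id), ]
      do.call(rbind, lapply(seq_len(config$n_replicates), function(rep_i) {
        w <- .simulate_wells(p, config$titration, config$plate_format,
                             plate_prefix = paste0(cl, "_r", rep_i),
                             channels = c("GF-AFC", "CTG"),
                             noise_cv = config$noise_cv)
        w$cell_line <- cl
        w$replicate <- rep_i
        w
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

## ---- 3D cyst plate simulator ----------------------------------------------

#' Simulate a 384-well 3D cyst assay plate set
#'
#' Produces CTG-3D viability well records plus per-well cyst ground truth
#' (number of structures, number with a swelled lumen, total cross-section
#' area). Viability-active compounds (per the PN24 planted parameters)
#' suppress both the CTG-3D signal and cyst counts; `cyst_swelling_only`
#' compounds reduce the swelled-cyst count and area while leaving CTG-3D at
#' the DMSO level. The positive control emulates a leptomycin-B full kill.
#'
#' @param config a [screen_config()] with `plate_format = 384`; a titration
#'   length other than 8 triggers a warning, not an error.
#' @param truth a [make_truth_table()] result.
#' @param cell_line cell line whose planted parameters drive viability
#'   (default PN24, the cyst-forming line).
#' @return List with `wells` (CTG-3D records) and `cysts` (per-well ground
#'   truth: plate_id, row, col, role, compound_id, conc_um, n_cysts,
#'   n_swelled, total_area_um2).
#' @export
simulate_cyst_plate <- function(config, truth, cell_line = "PN24") {
  stopifnot(inherits(config, "screen_config"), inherits(truth, "pkd_truth"))
  if (config$plate_format != 384)
    stop("3D cyst assay uses 384-well plates")
  if (length(config$titration) != 8)
    warning("cyst assay titration has ", length(config$titration),
            " points; the standard layout uses 8")
  base_count <- 30          # structures per well at DMSO
  swell_frac <- 0.5         # fraction with a visible lumen at DMSO
  mean_area <- 9000         # µm² per structure

  with_seed(config$seed + 1L, {
    p <- truth$params[truth$params$cell_line == cell_line, ]
    p <- p[match(truth$compounds$compound_id, p$compound_id), ]
    out <- lapply(seq_len(config$n_replicates), function(rep_i) {
      w <- .simulate_wells(p, config$titration, 384,
                           plate_prefix = paste0("cyst_r", rep_i),
                           channels = "CTG-3D", noise_cv = config$noise_cv)
      w$cell_line <- cell_line
      w$replicate <- rep_i

      # ground truth cyst content mirrors viability; swelling-only compounds
      # act on the swelled fraction without touching viability
      idx <- match(w$compound_id, truth$compounds$compound_id)
      viab <- 1 + ifelse(w$role == "compound",
                         hill_suppression(w$conc_um, p$ac50_um[idx],
                                          p$efficacy[idx], p$hill[idx]), 0)
      viab[w$role == "positive"] <- 0
      sw_red <- rep(0, nrow(w))
      has_sw <- !is.na(idx) & !is.na(truth$compounds$swell_ac50_um[idx])
      sw_red[has_sw] <- truth$compounds$swell_reduction[idx[has_sw]] /
        (1 + (truth$compounds$swell_ac50_um[idx[has_sw]] / w$conc_um[has_sw])^2)

      noise <- lnorm_noise(nrow(w), config$noise_cv)
      n_cysts <- round(base_count * viab * noise)
      n_swelled <- round(base_count * swell_frac * viab * (1 - sw_red) * noise)
      n_swelled <- pmin(n_swelled, n_cysts)
      # swelled cysts are much larger than solid aggregates, so they
      # dominate the total cross-section area
      area <- mean_area * (n_cysts + 2 * n_swelled)
      cysts <- data.frame(w[c("plate_id", "row", "col", "role",
                              "compound_id", "conc_um", "replicate")],
                          n_cysts = n_cysts, n_swelled = n_swelled,
                          total_area_um2 = area, stringsAsFactors = FALSE)
      list(wells = w, cysts = cysts)
    })
    list(wells = do.call(rbind, lapply(out, `[[`, "wells")),
         cysts = do.call(rbind, lapply(out, `[[`, "cysts")))
  })
}

## ---- human panel simulator ------------------------------------------------

#' Planted truth for the human ADPKD/NHK panel screen
#'
#' ADPKD-selective compounds are active in a configured subset of ADPKD
#' isolates only; pan-active compounds hit every isolate; the rest are
#' inactive everywhere.
#'
#' @param compound_ids character vector of compounds screened on the panel.
#' @param isolates data.frame as [panel_isolates()].
#' @param n_selective,n_pan numbers of ADPKD-selective and pan-active
#'   compounds planted (taken from the head of `compound_ids`).
#' @param n_active_adpkd how many ADPKD isolates each selective compound
#'   hits.
#' @param sensitivity named per-isolate AC50 multipliers emulating
#'   inter-patient variability (default all 1).
#' @param seed integer seed.
#' @return List of class `pkd_panel_truth` with `compounds` (compound_id,
#'   category, active_isolates), `params` (compound_id, isolate, ac50_um,
#'   hill, efficacy) and `isolates`.
#' @export
make_panel_truth <- function(compound_ids,
                             isolates = panel_isolates(),
                             n_selective = 20,
                             n_pan = 30,
                             n_active_adpkd = 3,
                             sensitivity = NULL,
                             seed = 1L) {
  stopifnot(n_selective + n_pan <= length(compound_ids))
  if (nrow(isolates) != 11)
    message("panel has ", nrow(isolates), " isolates (standard design uses 11)")
  adpkd <- isolates$isolate[isolates$group == "ADPKD"]
  if (is.null(sensitivity)) {
    sensitivity <- stats::setNames(rep(1, nrow(isolates)), isolates$isolate)
  }
  with_seed(seed, {
    category <- rep("inactive", length(compound_ids))
    category[seq_len(n_selective)] <- "adpkd_selective"
    if (n_pan > 0) category[n_selective + seq_len(n_pan)] <- "pan_active"
    active_iso <- lapply(seq_along(compound_ids), function(i) {
      switch(category[i],
             adpkd_selective = sample(adpkd, n_active_adpkd),
             pan_active = isolates$isolate,
             character(0))
    })
    params <- expand.grid(compound_id = compound_ids,
                          isolate = isolates$isolate,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_par <- nrow(params)
    ci <- match(params$compound_id, compound_ids)
    base_ac50 <- 10^stats::runif(length(compound_ids), log10(0.1), log10(10))
    base_hill <- stats::runif(length(compound_ids), 0.8, 2.5)
    base_eff <- stats::runif(length(compound_ids), -100, -80)
    params$ac50_um <- base_ac50[ci] * sensitivity[params$isolate]
    params$hill <- base_hill[ci]
    params$efficacy <- ifelse(
      mapply(function(i, iso) iso %in% active_iso[[i]], ci, params$isolate),
      base_eff[ci], 0)
    out <- list(compounds = data.frame(compound_id = compound_ids,
                                       category = category,
                                       stringsAsFactors = FALSE),
                active_isolates = active_iso,
                params = params, isolates = isolates)
    class(out) <- "pkd_panel_truth"
    out
  })
}

#' Simulate the 11-isolate human panel screen
#'
#' One monolayer screen (both viability channels, 1,536-well layout) per
#' isolate, using the per-isolate planted parameters of a
#' [make_panel_truth()] object.
#'
#' @param config a [screen_config()].
#' @param truth a `pkd_panel_truth`.
#' @return data.frame of well records; `cell_line` carries the isolate label.
#' @export
simulate_panel_screen <- function(config, truth) {
  stopifnot(inherits(config, "screen_config"),
            inherits(truth, "pkd_panel_truth"))
  with_seed(config$seed + 2L, {
    out <- do.call(rbind, lapply(truth$isolates$isolate, function(iso) {
      p <- truth$params[truth$params$isolate == iso, ]
      p <- p[match(truth$compounds$compound_id, p$compound_id), ]
      do.call(rbind, lapply(seq_len(config$n_replicates), function(rep_i) {
        w <- .simulate_wells(p, config$titration, config$plate_format,
                             plate_prefix = paste0(iso, "_r", rep_i),
                             channels = c("GF-AFC", "CTG"),
                             noise_cv = config$noise_cv)
        w$cell_line <- iso
        w$replicate <- rep_i
        w
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

## ---- well table IO --------------------------------------------------------

#' Read or write a well table CSV
#'
#' The dialect has one row per well and channel with columns plate_id, row,
#' col, role, compound_id, conc_um, channel, cell_line, replicate, signal
#' (and, after normalization, activity).
#'
#' @param wells data.frame of well records.
#' @param path file path.
#' @return `read_well_table` returns the data.frame.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
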