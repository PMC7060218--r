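test_that("zero-noise signals hit the control anchors exactly", {
  ac50 <- mouse_titration()[7]   # a tested concentration point
  params <- data.frame(compound_id = rep(c("A", "B"), each = 4),
                       cell_line = rep(mouse_cell_lines()$cell_line, 2),
                       ac50_um = ac50, hill = 1,
                       efficacy = rep(c(0, -100), each = 4))
  truth <- manual_truth(params, category = c("inactive", "pan_active"))
  cfg <- screen_config(n_compounds = 2, titration = mouse_titration(),
                       noise_cv = 0, seed = 1)
  w <- simulate_monolayer_screen(cfg, truth)
  ctg <- w[w$channel == "CTG", ]
  neu <- ctg$signal[ctg$role == "neutral"][1]
  pos <- ctg$signal[ctg$role == "positive"][1]
  # inactive compound: every well at the neutral baseline
  a <- ctg[!is.na(ctg$compound_id) & ctg$compound_id == "A" &
             ctg$cell_line == "PN24", ]
  expect_equal(a$signal, rep(neu, nrow(a)))
  # full-efficacy compound at c = AC50: halfway between neutral and positive
  b <- ctg[!is.na(ctg$compound_id) & ctg$compound_id == "B" &
             ctg$cell_line == "PN24" & abs(ctg$conc_um - ac50) < 1e-9, ]
  expect_equal(nrow(b), 1)
  expect_equal(b$signal, (neu + pos) / 2, tolerance = 1e-12)
})

test_that("simulators are deterministic under a fixed seed", {
  truth <- make_truth_table(20, seed = 7)
  cfg <- screen_config(n_compounds = 20, noise_cv = 0.1, seed = 7)
  expect_identical(simulate_monolayer_screen(cfg, truth),
                   simulate_monolayer_screen(cfg, truth))
  expect_identical(make_truth_table(20, seed = 7), truth)
  cfg384 <- screen_config(n_compounds = 20, plate_format = 384,
                          titration = cyst_titration(), noise_cv = 0.1,
                          seed = 7)
  expect_identical(simulate_cyst_plate(cfg384, truth),
                   simulate_cyst_plate(cfg384, truth))
})

test_that("different seeds change noise but not the planted truth", {
  ids <- sprintf("C%02d", 1:12)
  pt <- make_panel_truth(ids, n_selective = 3, n_pan = 3, seed = 1)
  cfg1 <- screen_config(n_compounds = 12, noise_cv = 0.1, seed = 1)
  cfg2 <- screen_config(n_compounds = 12, noise_cv = 0.1, seed = 2)
  w1 <- simulate_panel_screen(cfg1, pt)
  w2 <- simulate_panel_screen(cfg2, pt)
  expect_false(identical(w1$signal, w2$signal))
  expect_identical(w1[setdiff(names(w1), "signal")],
                   w2[setdiff(names(w2), "signal")])
})

test_that("truth table respects category construction and the efficacy gap", {
  truth <- make_truth_table(300, seed = 3)
  expect_false(anyDuplicated(truth$compounds$compound_id) > 0)
  expect_true(all(truth$params$efficacy <= 0 & truth$params$efficacy >= -100))
  diff_ids <- truth_differential(truth)
  for (cpd in sample(diff_ids, 10)) {
    p <- truth$params[truth$params$compound_id == cpd, ]
    cat_ <- truth$compounds$category[truth$compounds$compound_id == cpd]
    pairs <- switch(cat_, differential_embryonic = "embryonic",
                    differential_postnatal = "postnatal",
                    c("embryonic", "postnatal"))
    for (pid in pairs) {
      gap <- p$efficacy[p$pair_id == pid & p$genotype == "wt"] -
        p$efficacy[p$pair_id == pid & p$genotype == "null"]
      expect_gte(gap, truth$margin)
    }
  }
})

test_that("truth/config compound mismatch is a configuration error", {
  truth <- make_truth_table(10, seed = 1)
  cfg <- screen_config(n_compounds = 11, noise_cv = 0, seed = 1)
  expect_error(simulate_monolayer_screen(cfg, truth), "truth table")
})

test_that("cyst plate controls and categories behave by construction", {
  truth <- make_truth_table(60, seed = 5)
  cfg <- screen_config(n_compounds = 60, plate_format = 384,
                       titration = cyst_titration(), noise_cv = 0, seed = 5)
  sim <- simulate_cyst_plate(cfg, truth)
  pos <- sim$cysts[sim$cysts$role == "positive", ]
  expect_true(all(pos$n_cysts == 0))
  pos_w <- sim$wells[sim$wells$role == "positive", ]
  neu_w <- sim$wells[sim$wells$role == "neutral", ]
  expect_lt(max(pos_w$signal), min(neu_w$signal))

  sw <- truth$compounds[truth$compounds$category == "cyst_swelling_only", ]
  top <- max(cfg$titration)
  dmso_swelled <- stats::median(sim$cysts$n_swelled[sim$cysts$role == "neutral"])
  for (cpd in sw$compound_id) {
    wi <- sim$wells$compound_id %in% cpd & sim$wells$conc_um == top
    expect_equal(sim$wells$signal[wi], neu_w$signal[1])  # viability untouched
    ci <- sim$cysts$compound_id %in% cpd & sim$cysts$conc_um == top
    expect_lte(sim$cysts$n_swelled[ci], 0.5 * dmso_swelled)
  }

  # planted actives give monotone non-increasing true viability in dose
  act <- truth$compounds$compound_id[truth$compounds$category == "pan_active"][1]
  v <- sim$wells[sim$wells$compound_id %in% act, ]
  v <- v[order(v$conc_um), ]
  expect_true(all(diff(v$signal) <= 1e-9))
})

test_that("an 8-point titration is expected for the cyst assay", {
  truth <- make_truth_table(5, seed = 1)
  cfg <- screen_config(n_compounds = 5, plate_format = 384,
                       titration = cyst_titration(n = 6), noise_cv = 0,
                       seed = 1)
  expect_warning(simulate_cyst_plate(cfg, truth), "8")
})

test_that("panel screen plants selectivity only in configured ADPKD isolates", {
  ids <- sprintf("C%02d", 1:20)
  pt <- make_panel_truth(ids, n_selective = 5, n_pan = 0, seed = 3)
  sel <- pt$compounds$compound_id[pt$compounds$category == "adpkd_selective"]
  for (i in seq_along(ids)) {
    p <- pt$params[pt$params$compound_id == ids[i], ]
    active <- p$isolate[p$efficacy < 0]
    expect_setequal(active, pt$active_isolates[[i]])
    if (ids[i] %in% sel) {
      expect_length(active, 3)
      expect_true(all(active %in%
                        panel_isolates()$isolate[panel_isolates()$group == "ADPKD"]))
    } else {
      expect_length(active, 0)
    }
  }
})

test_that("rendered disks have the analytic area and stack depth", {
  obs <- data.frame(x_um = 128, y_um = 128, radius_um = 40, lumen = FALSE,
                    contrast = 0.8, focus_plane = 15)
  st <- render_cyst_image(obs, pixel_size = 1, n_planes = 30,
                          dim_px = c(256, 256))
  expect_equal(dim(st$planes)[3], 30)
  sharp <- st$planes[, , 15]
  npix <- sum(sharp > 0.2 * 1.05)
  expect_equal(npix * 1, pi * 40^2, tolerance = 0.05)

  empty <- render_cyst_image(obs[0, ], pixel_size = 1, n_planes = 4,
                             dim_px = c(64, 64), background = 0.2)
  expect_true(all(empty$planes == 0.2))
  expect_error(render_cyst_image(transform(obs, radius_um = -1),
                                 pixel_size = 1), "negative")
})

test_that("planted-hit sensitivity is non-increasing in the noise level", {
  sens <- vapply(c(0, 0.15, 0.4), function(cv) {
    r <- run_mouse_screen(100, noise_cv = cv, seed = 17)
    mean(truth_differential(r$truth) %in% r$hits)
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_equal(sens[1], 1)
})
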