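disk <- function(x, y, r, lumen = FALSE, contrast = 0.8, focus = 1) {
  data.frame(x_um = x, y_um = y, radius_um = r, lumen = lumen,
             contrast = contrast, focus_plane = focus)
}

test_that("focus-plane selection picks the sharp plane with low-index ties", {
  st1 <- render_cyst_image(disk(64, 64, 40), pixel_size = 2, n_planes = 1,
                           dim_px = c(128, 128))
  expect_equal(select_focus_plane(st1), 1)

  st <- render_cyst_image(disk(64, 64, 40, focus = 4), pixel_size = 2,
                          n_planes = 7, dim_px = c(128, 128))
  expect_equal(select_focus_plane(st), 4)

  # duplicated sharp plane: identical scores, lowest index wins
  two <- st$planes[, , c(4, 4)]
  expect_equal(select_focus_plane(two), 1)

  expect_warning(fp <- select_focus_plane(array(0.2, c(32, 32, 3))),
                 "uniform")
  expect_equal(fp, 1)
})

test_that("segmentation applies the area and SBR rules", {
  th <- pkd_thresholds()
  # radius 40 um: area ~5027 >= 3500, high contrast -> one region
  st <- render_cyst_image(disk(100, 100, 40), pixel_size = 2, n_planes = 1,
                          dim_px = c(200, 200))
  reg <- segment_cysts(st$planes[, , 1], 2)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$area_um2, pi * 40^2, tolerance = 0.05)
  expect_gte(reg$sbr, 0.4)

  # radius 30 um: area ~2827 below the cutoff
  st <- render_cyst_image(disk(100, 100, 30), pixel_size = 2, n_planes = 1,
                          dim_px = c(200, 200))
  expect_equal(nrow(segment_cysts(st$planes[, , 1], 2)), 0)

  # large but low-contrast region (sbr 0.2) is rejected by the SBR rule
  st <- render_cyst_image(disk(100, 100, 60, contrast = 0.25), pixel_size = 2,
                          n_planes = 1, dim_px = c(200, 200))
  expect_equal(nrow(segment_cysts(st$planes[, , 1], 2)), 0)

  # swelled cyst (annulus + dim lumen) is accepted, hole-filled
  st <- render_cyst_image(disk(100, 100, 50, lumen = TRUE), pixel_size = 2,
                          n_planes = 1, dim_px = c(200, 200))
  reg <- segment_cysts(st$planes[, , 1], 2)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$area_um2, pi * 50^2, tolerance = 0.06)
})

test_that("measured disk area converges to the analytic value with resolution", {
  errs <- vapply(c(4, 2, 1), function(px) {
    st <- render_cyst_image(disk(150, 150, 40), pixel_size = px, n_planes = 1,
                            dim_px = c(round(300 / px), round(300 / px)))
    reg <- segment_cysts(st$planes[, , 1], px)
    abs(reg$area_um2 - pi * 40^2) / (pi * 40^2)
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(errs[3] <= errs[1] + 1e-9)
})

test_that("well summaries count and add up accepted regions", {
  obs <- rbind(disk(80, 80, 40), disk(200, 200, 45), disk(320, 100, 50))
  st <- render_cyst_image(obs, pixel_size = 2, n_planes = 1,
                          dim_px = c(220, 220))
  s <- analyze_cyst_stack(st)
  expect_equal(s$n_cysts, 3)
  expect_equal(s$total_area_um2, sum(s$regions$area_um2))

  empty <- render_cyst_image(obs[0, ], pixel_size = 2, n_planes = 2,
                             dim_px = c(64, 64))
  s0 <- suppressWarnings(analyze_cyst_stack(empty))
  expect_equal(s0$n_cysts, 0)
  expect_equal(s0$total_area_um2, 0)
})

test_that("cyst stacks round-trip through multi-page TIFF", {
  st <- render_cyst_image(disk(64, 64, 30), pixel_size = 2, n_planes = 5,
                          dim_px = c(64, 64))
  path <- tempfile(fileext = ".tif")
  write_cyst_stack(st, path)
  back <- read_cyst_stack(path, pixel_size = 2)
  expect_equal(dim(back$planes), dim(st$planes))
  expect_equal(back$planes, st$planes, tolerance = 1e-6)
})

test_that("imaging dose-response normalizes to the DMSO reference", {
  # all wells identical to DMSO: flat 0% curve
  wells <- data.frame(role = c(rep("neutral", 4), rep("compound", 8)),
                      compound_id = c(rep(NA, 4), rep("A", 8)),
                      conc_um = c(rep(NA, 4), cyst_titration()),
                      total_area_um2 = 4e5)
  dr <- cyst_dose_response(wells)
  expect_equal(dr$activity, rep(0, 8))
  expect_equal(dr$channel, rep("cyst-area", 8))
  expect_error(cyst_dose_response(wells[wells$role == "compound", ]), "DMSO")

  # monotone planted suppression stays monotone after normalization
  wells2 <- wells
  wells2$total_area_um2[wells2$role == "compound"] <-
    4e5 * (1 - 0.9 / (1 + (10 / cyst_titration())^2))
  dr2 <- cyst_dose_response(wells2)
  expect_true(all(diff(dr2$activity) < 0))
})

test_that("swelling-only compounds are active on cyst area but not viability", {
  truth <- make_truth_table(60, seed = 5)
  cfg <- screen_config(n_compounds = 60, plate_format = 384,
                       titration = cyst_titration(), noise_cv = 0, seed = 5)
  sim <- simulate_cyst_plate(cfg, truth)
  viab <- fit_profiles(assemble_titrations(normalize_wells(sim$wells)))
  area <- fit_profiles(cyst_dose_response(sim$cysts))
  sw <- truth$compounds$compound_id[truth$compounds$category ==
                                      "cyst_swelling_only"]
  expect_true(length(sw) >= 1)
  for (cpd in sw) {
    expect_equal(viab$curve_class[viab$compound_id == cpd], 4)
    expect_true(area$curve_class[area$compound_id == cpd] != 4)
  }
})
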