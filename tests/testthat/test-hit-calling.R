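prof_row <- function(compound_id, cell_line, channel = "CTG", zero = 0,
                     curve_class, auc) {
  data.frame(compound_id = compound_id, cell_line = cell_line,
             channel = channel, n_points = 11, zero = zero, inf = -80,
             ac50_um = 1, hill = 1, r2 = 0.99, converged = TRUE,
             curve_class = curve_class, auc = auc, stringsAsFactors = FALSE)
}

test_that("mouse differential rule applies the phase-specific cutoff", {
  nullp <- prof_row("A", "PN24", curve_class = -1.1, auc = -300)
  wtp <- prof_row("A", "PH2", curve_class = 4, auc = -20)
  call <- call_differential_mouse(nullp, wtp, phase = "primary")
  expect_equal(call$delta_auc, -280)
  expect_true(call$is_hit)

  # identical profiles: delta 0, never a hit
  same <- call_differential_mouse(nullp, transform(nullp, cell_line = "PH2"),
                                  phase = "primary")
  expect_equal(same$delta_auc, 0)
  expect_false(same$is_hit)

  # delta -15 passes the primary (-10) but not the validation (-20) cutoff
  wt15 <- prof_row("A", "PH2", curve_class = 4, auc = -285)
  expect_true(call_differential_mouse(nullp, wt15, phase = "primary")$is_hit)
  expect_false(call_differential_mouse(nullp, wt15, phase = "validation")$is_hit)

  # a hit requires a high-quality curve in the null line
  null4 <- prof_row("A", "PN24", curve_class = 4, auc = -300)
  expect_false(call_differential_mouse(null4, wtp, phase = "primary")$is_hit)
})

test_that("missing wild-type profiles yield inconclusive calls", {
  nullp <- prof_row(c("A", "B"), "PN24", curve_class = -1.1, auc = -300)
  wtp <- prof_row("A", "PH2", curve_class = 4, auc = 0)
  expect_warning(call <- call_differential_mouse(nullp, wtp, "primary"),
                 "wild-type")
  expect_true(is.na(call$is_hit[call$compound_id == "B"]))
})

test_that("cyst activity matches the truth-table oracle on all class/AUC combos", {
  grid <- expand.grid(curve_class = c(-1.1, -1.2, -2.1, -2.2, -3, 4, 5),
                      auc = c(-400, -150, -100, -50, 0))
  prof <- prof_row(sprintf("C%02d", seq_len(nrow(grid))), "PN24-3D",
                   channel = "CTG-3D", curve_class = grid$curve_class,
                   auc = grid$auc)
  calls <- call_cyst_active(prof)
  oracle <- grid$curve_class != 4 & grid$auc < -100
  expect_equal(calls$is_active, oracle)
})

test_that("human pair rule requires delta AUC, baseline match and curve quality", {
  mk <- function(class_a, auc_a, zero_a, auc_n, zero_n) {
    a <- prof_row("A", "K251", curve_class = class_a, auc = auc_a,
                  zero = zero_a)
    n <- prof_row("A", "K347", curve_class = 4, auc = auc_n, zero = zero_n)
    call_differential_human_pair(a, n, pair_id = "K251xK347")
  }
  expect_true(mk(-1.2, -100, 0, -20, 5)$is_hit)    # dAUC -80, dzero 5
  expect_false(mk(-1.2, -100, 0, -20, 15)$is_hit)  # baseline mismatch
  expect_false(mk(-1.2, -70, 0, -20, 0)$is_hit)    # dAUC -50 above cutoff
  expect_false(mk(4, -100, 0, -20, 0)$is_hit)      # low-quality ADPKD curve
})

test_that("panel aggregation needs 6 pairs spanning 2 ADPKD and 3 NHK isolates", {
  mk_calls <- function(pairs) {
    data.frame(compound_id = "A", pair_id = pairs, channel = "CTG",
               phase = "human", class_adpkd = -1.1, delta_auc = -100,
               delta_abs_zero = 0, is_hit = TRUE, stringsAsFactors = FALSE)
  }
  # 2 ADPKD x 3 NHK = 6 pairs: flagged
  p6 <- as.vector(outer(c("K251", "K287"), c("K347", "K370", "K381"),
                        paste, sep = "x"))
  expect_true(aggregate_human_hits(mk_calls(p6))$flagged)
  # 6 pairs but a single ADPKD isolate: not flagged
  p1a <- paste0("K251", "x", c("K347", "K370", "K381", "K388", "K412", "K419"))
  expect_false(aggregate_human_hits(mk_calls(p1a))$flagged)
  # only 5 pairs despite good spread: not flagged
  p5 <- as.vector(outer(c("K251", "K287", "K315"),
                        c("K347", "K370"), paste, sep = "x"))[1:5]
  expect_false(aggregate_human_hits(mk_calls(p5))$flagged)
  # the same pair hit in both channels counts once
  both <- rbind(mk_calls(p1a), transform(mk_calls(p1a), channel = "GF-AFC"))
  expect_equal(aggregate_human_hits(both)$n_pairs, 6)
})

test_that("panel aggregation agrees with brute-force enumeration", {
  th <- pkd_thresholds()
  adpkd <- paste0("A", 1:5)
  nhk <- paste0("N", 1:6)
  all_pairs <- as.vector(outer(adpkd, nhk, paste, sep = "x"))
  set.seed(31)
  for (i in 1:200) {
    sub <- sample(all_pairs, sample(0:12, 1))
    if (length(sub) == 0) next
    calls <- data.frame(compound_id = "X", pair_id = sub, channel = "CTG",
                        phase = "human", class_adpkd = -1.1,
                        delta_auc = -100, delta_abs_zero = 0, is_hit = TRUE,
                        stringsAsFactors = FALSE)
    got <- aggregate_human_hits(calls, th)$flagged
    parts <- strsplit(sub, "x")
    want <- length(sub) >= 6 &&
      length(unique(vapply(parts, `[`, "", 1))) >= 2 &&
      length(unique(vapply(parts, `[`, "", 2))) >= 3
    expect_identical(got, want)
  }
})

test_that("hit categorization partitions hits by pair and readout", {
  calls <- rbind(
    data.frame(compound_id = "E", pair_id = "embryonic", channel = "GF-AFC",
               is_hit = TRUE),
    data.frame(compound_id = "B", pair_id = c("embryonic", "postnatal",
                                              "embryonic", "postnatal"),
               channel = rep(c("GF-AFC", "CTG"), each = 2), is_hit = TRUE),
    data.frame(compound_id = "X", pair_id = "postnatal", channel = "CTG",
               is_hit = FALSE))
  cats <- categorize_hits(calls)
  expect_setequal(cats$compound_id, c("E", "B"))
  expect_equal(cats$pair_category[cats$compound_id == "E"], "embryonic_only")
  expect_equal(cats$channel_category[cats$compound_id == "E"], "GF-AFC")
  expect_equal(cats$pair_category[cats$compound_id == "B"], "both")
  expect_equal(cats$channel_category[cats$compound_id == "B"], "both")
  expect_equal(sum(attr(cats, "fractions")), 1)
})
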