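# Independent oracles used to cross-check the package implementations.

# exact two-sided signed-rank p by full enumeration of the 2^n sign vectors
oracle_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}

# one-sided (over-representation) hypergeometric tail by direct summation
oracle_hyper_p <- function(a, hits_total, with_gene_total, screened_total) {
  kmax <- min(hits_total, with_gene_total)
  ks <- a:kmax
  sum(choose(with_gene_total, ks) *
        choose(screened_total - with_gene_total, hits_total - ks)) /
    choose(screened_total, hits_total)
}

# Benjamini-Hochberg step-up computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# dense brute-force grid search minimizing Hill RSS
oracle_hill_grid <- function(conc, activity) {
  zg <- seq(-20, 20, by = 5)
  ig <- seq(-120, 10, by = 5)
  lg <- seq(log10(min(conc) / 3), log10(max(conc) * 3), length.out = 40)
  hg <- c(0.5, 0.75, 1, 1.5, 2, 3, 4.5)
  best <- list(rss = Inf)
  for (h in hg) for (la in lg) {
    f <- 1 / (1 + (10^la / conc)^h)
    for (z in zg) for (iv in ig) {
      rss <- sum((activity - (z + (iv - z) * f))^2)
      if (rss < best$rss)
        best <- list(rss = rss, zero = z, inf = iv, ac50 = 10^la, hill = h)
    }
  }
  best
}

# build a hand-specified truth table (single category per compound)
manual_truth <- function(params, category, target_gene = NA_character_,
                         margin = 60) {
  cpds <- unique(params$compound_id)
  compounds <- data.frame(compound_id = cpds,
                          category = category,
                          target_gene = target_gene,
                          swell_ac50_um = NA_real_,
                          swell_reduction = NA_real_,
                          stringsAsFactors = FALSE)
  lines <- mouse_cell_lines()
  params <- merge(params, lines, by = "cell_line", sort = FALSE)
  out <- list(compounds = compounds,
              params = params[c("compound_id", "cell_line", "pair_id",
                                "genotype", "ac50_um", "hill", "efficacy")],
              margin = margin)
  class(out) <- "pkd_truth"
  out
}

# run the standard mouse differential calling on a profile table
mouse_calls <- function(profiles, phase = "validation",
                        thresholds = pkd_thresholds()) {
  lines <- mouse_cell_lines()
  do.call(rbind, lapply(unique(lines$pair_id), function(pid) {
    nl <- lines$cell_line[lines$pair_id == pid & lines$genotype == "null"]
    wl <- lines$cell_line[lines$pair_id == pid & lines$genotype == "wt"]
    call_differential_mouse(profiles[profiles$cell_line == nl, ],
                            profiles[profiles$cell_line == wl, ],
                            phase = phase, pair_id = pid,
                            thresholds = thresholds)
  }))
}

# full monolayer pipeline: simulate -> normalize -> fit -> call
run_mouse_screen <- function(n_compounds, noise_cv, seed, n_replicates = 1,
                             phase = "validation") {
  truth <- make_truth_table(n_compounds, seed = seed)
  cfg <- screen_config(n_compounds = n_compounds, noise_cv = noise_cv,
                       n_replicates = n_replicates, seed = seed)
  wells <- normalize_wells(simulate_monolayer_screen(cfg, truth),
                           recenter_baseline = TRUE)
  profiles <- fit_profiles(assemble_titrations(wells))
  calls <- mouse_calls(profiles, phase = phase)
  hits <- unique(calls$compound_id[calls$is_hit %in% TRUE])
  list(truth = truth, wells = wells, profiles = profiles, calls = calls,
       hits = hits)
}
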