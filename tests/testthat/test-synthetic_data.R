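test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123, n_genes = 6L)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a, b)
  expect_identical(simulate_iclip(a, cfg), simulate_iclip(b, cfg))
  expect_identical(simulate_timecourse(a, cfg), simulate_timecourse(b, cfg))
  expect_identical(simulate_deg_table(a, cfg), simulate_deg_table(b, cfg))
})

test_that("config validation catches degenerate worlds", {
  expect_error(sim_config(n_genes = 0L), "empty simulation")
  expect_error(sim_config(di_fraction = 1.5), "proportions")
  expect_error(sim_config(timepoints = "MEF"), "timepoints")
  cfg <- sim_config(seed = 1, n_genes = 4L, signal_to_background = 0.5)
  g <- generate_genome(cfg)
  expect_error(simulate_iclip(g, cfg), "signal_to_background")
})

test_that("detained-intron truth follows di_fraction", {
  g0 <- generate_genome(sim_config(seed = 2, n_genes = 6L,
                                   di_fraction = 0))
  expect_equal(nrow(g0$truth$detained_introns), 0L)
  cfg <- sim_config(seed = 2, n_genes = 10L, di_fraction = 0.5)
  g <- generate_genome(cfg)
  ff <- suppressWarnings(flatten_features(g$annotation))
  n_intron <- sum(ff$kind == "intron")
  n_di <- nrow(g$truth$detained_introns)
  # binomial sampling around n_intron / 2
  expect_gt(n_di, qbinom(0.0005, n_intron, 0.5))
  expect_lt(n_di, qbinom(0.9995, n_intron, 0.5))
  # truth references existing annotation features
  expect_true(all(g$truth$detained_introns$feature_id %in% ff$feature_id))
})

test_that("planted motifs are written into the evaluated windows", {
  cfg <- sim_config(seed = 31, n_genes = 8L, n_planted_sites = 12L)
  g <- generate_genome(cfg)
  ps <- g$truth$planted_sites
  for (i in seq_len(nrow(ps))) {
    km <- site_kmer_weights(g$annotation, ps[i, , drop = FALSE], k = 5L)
    expect_true(g$truth$motif %in% names(km))
  }
})

test_that("iCLIP counts match their configured Poisson rates", {
  cfg <- sim_config(seed = 6, n_genes = 10L, n_planted_sites = 15L,
                    signal_to_background = 50, background_rate = 0.2)
  g <- generate_genome(cfg)
  clip <- simulate_iclip(g, cfg)
  ps <- g$truth$planted_sites
  key_p <- paste(ps$chrom, ps$strand, ps$pos)
  key_s <- paste(clip$signal$chrom, clip$signal$strand, clip$signal$pos)
  planted_counts <- clip$signal$count[match(key_p, key_s)]
  planted_counts[is.na(planted_counts)] <- 0
  # planted mean ~ 10 = 50 x 0.2; z-test against the configured rate
  mu <- cfg$signal_to_background * cfg$background_rate
  z <- (mean(planted_counts) - mu) / sqrt(mu / nrow(ps))
  expect_lt(abs(z), 4)
  # control has no excess at planted positions
  key_c <- paste(clip$control$chrom, clip$control$strand, clip$control$pos)
  ctrl_counts <- clip$control$count[match(key_p, key_c)]
  ctrl_counts[is.na(ctrl_counts)] <- 0
  zc <- (mean(ctrl_counts) - cfg$background_rate) /
    sqrt(cfg$background_rate / nrow(ps))
  expect_lt(abs(zc), 4)
  # background counts chi-square GOF against Poisson(0.2) occupancy
  regions <- cotranscribed_regions(g$annotation)
  total_len <- sum(regions$end - regions$start)
  p_occ <- 1 - exp(-cfg$background_rate)
  n_occ <- nrow(clip$control)
  z_occ <- (n_occ - total_len * p_occ) /
    sqrt(total_len * p_occ * (1 - p_occ))
  expect_lt(abs(z_occ), 4)
})

test_that("time-course events follow their true PSI trajectories", {
  cfg <- sim_config(seed = 9, n_genes = 8L, n_events = 60L,
                    event_depth = 500)
  g <- generate_genome(cfg)
  tc <- simulate_timecourse(g, cfg)
  truth <- tc$truth$true_psi
  for (tp in c("MEF", "iPSC")) {
    inc <- tc$events[[paste0("inc_", tp, "_r1")]] +
      tc$events[[paste0("inc_", tp, "_r2")]]
    exc <- tc$events[[paste0("exc_", tp, "_r1")]] +
      tc$events[[paste0("exc_", tp, "_r2")]]
    emp <- inc / (inc + exc)
    expect_gt(mean(abs(emp - truth[[tp]]) < 0.05), 0.95)
  }
  # zero-depth events give inc = exc = 0
  cfg0 <- sim_config(seed = 9, n_genes = 4L, n_events = 10L,
                     event_depth = 0)
  tc0 <- simulate_timecourse(generate_genome(cfg0), cfg0)
  inc_cols <- grep("^inc_", names(tc0$events))
  exc_cols <- grep("^exc_", names(tc0$events))
  expect_true(all(tc0$events[, c(inc_cols, exc_cols)] == 0))
})

test_that("planted cluster shapes drive the mean trajectories", {
  cfg <- sim_config(seed = 13, n_genes = 12L)
  g <- generate_genome(cfg)
  tc <- simulate_timecourse(g, cfg)
  truth <- tc$truth$feature_truth
  traj <- feature_trajectories(tc$features, cfg$timepoints)
  # "late rise" (shape 1): mean log2FC at the last contrast near 3 and
  # larger than at the first
  ids <- truth$feature_id[truth$shape_id == 1L]
  m <- colMeans(traj[ids, , drop = FALSE])
  expect_gt(m[length(m)], m[1])
  expect_equal(unname(m[length(m)]), 3, tolerance = 0.25)
  # flat features stay near zero
  flat <- truth$feature_id[truth$shape_id == 0L]
  expect_lt(max(abs(colMeans(traj[flat, , drop = FALSE]))), 0.1)
})

test_that("deg table construction honours planted effects and flags", {
  cfg <- sim_config(seed = 21, n_genes = 20L)
  g <- generate_genome(cfg)
  dt <- simulate_deg_table(g, cfg)
  pass <- dt$deg$fdr < 0.05 & abs(dt$deg$log2fc) >= 1
  expect_identical(unname(pass), dt$truth$is_deg)
  # bound flag consistency with planted sites
  bound_truth <- unique(g$truth$planted_sites$gene_id)
  expect_setequal(dt$deg$gene_id[dt$deg$bound], bound_truth)
  # zero planted effect -> zero genes pass
  cfg0 <- sim_config(seed = 21, n_genes = 20L, deg_fraction = 0)
  dt0 <- simulate_deg_table(g, cfg0)
  expect_equal(sum(dt0$deg$fdr < 0.05 & abs(dt0$deg$log2fc) >= 1), 0L)
})
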