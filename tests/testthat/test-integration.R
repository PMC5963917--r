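test_that("call_sarfs applies the feature/window rule", {
  feats <- data.frame(feature_id = c("j1", "j2", "i1"),
                      chrom = "c", strand = "+",
                      start = c(1000L, 5000L, 8000L),
                      end = c(1400L, 5400L, 8600L),
                      stringsAsFactors = FALSE)
  sites <- binding_site_set(data.frame(
    chrom = "c", strand = "+",
    pos = c(1549L, 5651L, 8300L),  # 150 nt past j1 end; 251 past j2; inside i1
    count = 3L, fdr = 0.01))
  out <- call_sarfs(feats, sites, window_nt = 200L)
  expect_equal(out$sarf, c(TRUE, FALSE, TRUE))
  expect_equal(out$support_sites[3], "8300")
})

test_that("call_sarfs equals the brute-force all-pairs scan (property)", {
  set.seed(99)
  for (i in 1:25) {
    fx <- random_sarf_fixture()
    got <- call_sarfs(fx$features, fx$sites, window_nt = 200L)$sarf
    want <- brute_force_sarfs(fx$features, fx$sites, window_nt = 200L)
    expect_identical(got, want)
  }
})

test_that("trajectory_filter applies autocorrelation and fold-change rules", {
  traj <- rbind(zero = rep(0, 5),
                rise = c(0.2, 0.6, 1.2, 2.0, 3.0),
                alt = c(1, -1, 1, -1, 1),
                big = c(1, 4, 9, 9, 9))
  tf <- trajectory_filter(traj)
  expect_equal(rownames(tf$kept), "rise")
  st <- tf$stats
  # lag-1 Pearson by hand for the rising trajectory
  x <- c(0.2, 0.6, 1.2, 2.0); y <- c(0.6, 1.2, 2.0, 3.0)
  expect_equal(st$autocorr[st$feature_id == "rise"], cor(x, y))
  expect_equal(st$autocorr[st$feature_id == "alt"], -1)
  expect_false(st$kept[st$feature_id == "zero"])  # max|FC| = 0 < 0.5
  expect_false(st$kept[st$feature_id == "big"])   # max|FC| = 9 > 8.5
  expect_error(trajectory_filter(traj[, 1:2]), ">= 3")
})

test_that("cluster_trajectories is deterministic and recovers groups", {
  set.seed(5)
  a <- matrix(rnorm(150, mean = 3), ncol = 5)
  b <- matrix(rnorm(150, mean = -3), ncol = 5)
  x <- rbind(a, b)
  rownames(x) <- sprintf("f%02d", 1:60)
  cl <- cluster_trajectories(x, k = 2L, seed = 3L)
  truth <- rep(1:2, each = 30)
  expect_equal(adjusted_rand_index(cl$cluster, truth), 1)
  cl2 <- cluster_trajectories(x, k = 2L, seed = 3L)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_trajectories(x, k = 100L), "fewer")
})

test_that("sarf_cluster_summary ranks clusters by SARF count", {
  cluster <- c(rep(1L, 10), rep(2L, 45), rep(3L, 45))
  sarf <- c(rep(TRUE, 10), rep(FALSE, 90))
  s <- sarf_cluster_summary(cluster, sarf, top_n = 1L)
  expect_equal(s$sarf_fraction, 1.0)
  expect_equal(s$feature_fraction, 0.10)
  expect_equal(s$enrichment, 10)
  expect_error(sarf_cluster_summary(cluster, rep(FALSE, 100)), "zero SARFs")
})

test_that("di_binding_fractions counts hand-built fixtures exactly", {
  feats <- data.frame(
    feature_id = c("e1", "e2", "i1", "i2", "i3", "i4"),
    gene_id = "g", kind = c("exonic_part", "exonic_part", rep("intron", 4)),
    chrom = "c", strand = "+",
    start = c(0L, 200L, 100L, 300L, 500L, 700L),
    end = c(100L, 300L, 200L, 400L, 600L, 800L),
    status = c("regulated", "unregulated", "regulated", "regulated",
               "unregulated", "regulated"),
    sarf = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  di <- data.frame(chrom = "c", strand = "+",
                   start = c(100L, 300L, 500L, 700L),
                   end = c(200L, 400L, 600L, 800L))
  sites <- binding_site_set(data.frame(
    chrom = "c", strand = "+", pos = c(150L, 550L), count = 2L, fdr = 0.01))
  out <- di_binding_fractions(feats, di, sites)
  # both SARF introns are DIs
  expect_equal(out$intronic_sarf_di$fraction, 1.0)
  # regulated DIs: i1 (site), i2, i4 -> 1/3 bound
  expect_equal(out$regulated_di_bound$fraction, 1 / 3)
  expect_equal(out$regulated_di_bound$den, 3L)
  # non-regulated DI: i3 with site -> 1/1
  expect_equal(out$nonregulated_di_bound$fraction, 1.0)
  # DI SARFs flanking a regulated exonic part: i1 touches e1 (regulated)
  # at 100; i2 touches only e2 (unregulated) -> 1/2
  expect_equal(out$di_sarf_flanking_regulated_exon$fraction, 0.5)
  # empty denominator reported as NA, not 0
  out2 <- di_binding_fractions(feats[feats$kind == "exonic_part", ],
                               di, sites)
  expect_true(is.na(out2$intronic_sarf_di$fraction))
})

test_that("deg_overlap_stats applies thresholds and the hypergeometric", {
  deg <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    log2fc = c(rep(2, 5), rep(-1, 3), rep(0.5, 10), 1, -2),
    fdr = c(rep(0.01, 8), rep(0.5, 10), 0.05, 0.02),
    bound = c(rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 5), rep(FALSE, 7)),
    stringsAsFactors = FALSE)
  out <- deg_overlap_stats(deg)
  # DEGs: g1-5 (up), g6-8 (down), g20 (down); g19 excluded: fdr == 0.05
  expect_equal(out$n_deg, 9L)
  expect_equal(out$n_up, 5L)
  expect_equal(out$n_down, 4L)
  expect_equal(out$n_up + out$n_down, out$n_deg)
  expect_equal(out$bound_fraction$fraction, 5 / 9)
  expect_equal(out$bound_fraction_up$fraction, 1.0)
  expect_equal(out$bound_fraction_down$fraction, 0.0)
  # |log2fc| = 1 exactly is included
  expect_true("g06" %in% deg$gene_id[deg$fdr < 0.05 & abs(deg$log2fc) >= 1])
  # exact hypergeometric oracle: 5 DEGs all bound, 10 of 20 bound
  deg2 <- data.frame(gene_id = sprintf("h%02d", 1:20),
                     log2fc = c(rep(2, 5), rep(0, 15)),
                     fdr = c(rep(0.01, 5), rep(0.9, 15)),
                     bound = c(rep(TRUE, 5), rep(TRUE, 5), rep(FALSE, 10)))
  out2 <- deg_overlap_stats(deg2)
  expect_equal(out2$bound_enrichment_p, choose(10, 5) / choose(20, 5),
               tolerance = 1e-12)
})

test_that("adjusted_rand_index behaves at the extremes", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(8)
  a <- sample(1:4, 400, replace = TRUE)
  b <- sample(1:4, 400, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
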