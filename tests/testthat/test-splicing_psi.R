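test_that("psi_point gives the posterior mean under a uniform prior", {
  expect_equal(psi_point(5, 5)$psi, 0.5)
  expect_equal(psi_point(5, 5)$psi_raw, 0.5)
  r <- psi_point(0, 7)
  expect_equal(r$psi_raw, 0)
  expect_equal(r$psi, 1 / 9)
  r2 <- psi_point(30, 10)
  expect_equal(r2$psi_raw, 0.75)
  expect_equal(r2$psi, 31 / 42)
  r3 <- psi_point(0, 0)
  expect_false(r3$defined)
  expect_true(is.na(r3$psi))
})

test_that("delta_psi_bayes matches the Beta-function and integration oracles", {
  r <- delta_psi_bayes(8, 2, 2, 8)
  oracle <- beta(9, 3) * beta(3, 9) / beta(11, 11)
  expect_equal(r$bayes_factor, oracle, tolerance = 1e-9)
  expect_equal(r$delta_psi, 0.5)
  # independent numerical-integration oracle
  marg <- function(i, e) integrate(function(p) dbinom(i, i + e, p),
                                   0, 1, rel.tol = 1e-10)$value
  num_oracle <- marg(8, 2) * marg(2, 8) /
    integrate(function(p) dbinom(8, 10, p) * dbinom(2, 10, p),
              0, 1, rel.tol = 1e-10)$value
  expect_equal(r$bayes_factor, num_oracle, tolerance = 1e-6)
  r2 <- delta_psi_bayes(5, 5, 5, 5)
  expect_equal(r2$bayes_factor, beta(6, 6)^2 / beta(11, 11),
               tolerance = 1e-9)
  expect_equal(r2$delta_psi, 0)
  expect_error(delta_psi_bayes(0, 0, 5, 5), "untestable")
})

test_that("Bayes factor is symmetric and consistent under equality", {
  ab <- delta_psi_bayes(7, 3, 4, 9)
  ba <- delta_psi_bayes(4, 9, 7, 3)
  expect_equal(ab$bayes_factor, ba$bayes_factor)
  expect_equal(ab$delta_psi, -ba$delta_psi)
  # BF shrinks with growing equal counts (consistency at p = 0.5)
  bfs <- vapply(c(10, 100, 1000), function(n)
    delta_psi_bayes(n / 2, n / 2, n / 2, n / 2)$bayes_factor, numeric(1))
  expect_true(all(diff(bfs) < 0))
  expect_lt(bfs[3], 0.1)
})

test_that("event filters match the stated rules with inclusive bounds", {
  fx <- list(
    # a_inc a_exc b_inc b_exc dpsi  bf    pass reason
    list(1, 9, 1, 9, 0.20, 5.0, TRUE, ""),             # all at boundary
    list(0, 9, 5, 9, 0.50, 9.0, FALSE, "num-inc"),
    list(5, 0, 5, 5, 0.30, 9.0, FALSE, "num-exc"),
    list(4, 4, 4, 4, 0.25, 8.0, FALSE, "num-sum-inc-exc"),
    list(8, 2, 2, 8, 0.19, 8.0, FALSE, "delta-psi"),
    list(8, 2, 2, 8, 0.45, 4.99, FALSE, "bayes-factor"),
    list(9, 1, 1, 9, -0.62, 40, TRUE, ""),             # negative dpsi ok
    list(0, 0, 0, 10, 0.0, 0.0, FALSE, "num-inc"))
  for (f in fx) {
    r <- apply_event_filters(f[[1]], f[[2]], f[[3]], f[[4]], f[[5]], f[[6]])
    expect_equal(r$pass, f[[7]])
    if (!f[[7]]) expect_true(f[[8]] %in% r$reasons)
  }
})

test_that("compare_events sums replicates and flags untestable events", {
  ev <- data.frame(event_id = c("e1", "e2"), type = "SE", gene_id = "g",
                   chrom = "c", strand = "+", coord_start = 10L,
                   coord_end = 50L,
                   inc_a_r1 = c(6L, 0L), inc_a_r2 = c(6L, 0L),
                   exc_a_r1 = c(1L, 0L), exc_a_r2 = c(1L, 0L),
                   inc_b_r1 = c(1L, 3L), inc_b_r2 = c(1L, 2L),
                   exc_b_r1 = c(6L, 4L), exc_b_r2 = c(6L, 5L),
                   stringsAsFactors = FALSE)
  res <- compare_events(ev, c("a_r1", "a_r2"), c("b_r1", "b_r2"))
  cmp <- delta_psi_bayes(12, 2, 2, 12)
  expect_equal(res$bayes_factor[1], cmp$bayes_factor)
  expect_equal(res$delta_psi[1], cmp$delta_psi)
  expect_true(res$untestable[2])
  expect_false(res$pass[2])
})

test_that("event_binding_association computes fractions and SE metagene", {
  ann <- tiny_annotation()
  # g1 has a site; g2 does not
  sites <- binding_site_set(data.frame(chrom = "chrT", strand = "+",
                                       pos = 320L, count = 3L, fdr = 0.01))
  ev <- data.frame(
    event_id = c("se1", "se2"), type = "SE",
    gene_id = c("g1", "g2"), chrom = "chrT", strand = c("+", "-"),
    coord_start = c(300L, 1000L), coord_end = c(400L, 1100L),
    pass = TRUE, delta_psi = c(0.4, -0.3), stringsAsFactors = FALSE)
  res <- event_binding_association(ev, sites, ann)
  expect_equal(res$bound_fraction, 0.5)
  expect_equal(res$type_tally$n_up, 1)
  expect_equal(res$type_tally$n_down, 1)
  # site at offset 20 inside a 100 nt exon -> fraction 0.2
  m <- res$se_metagene
  expect_equal(m$region, "exon")
  expect_equal(m$rel_coord, 0.2)
  # site exactly at the exon start -> 0 at the 3' splice site
  sites2 <- binding_site_set(data.frame(chrom = "chrT", strand = "+",
                                        pos = 300L, count = 3L, fdr = 0.01))
  m2 <- event_binding_association(ev, sites2, ann)$se_metagene
  expect_equal(m2$rel_coord, 0)
  # minus strand: 50 nt downstream of the 5'SS (transcript orientation)
  sites3 <- binding_site_set(data.frame(chrom = "chrT", strand = "-",
                                        pos = 950L, count = 3L, fdr = 0.01))
  m3 <- event_binding_association(ev, sites3, ann)$se_metagene
  expect_equal(m3$region, "downstream")
  expect_equal(m3$rel_coord, 50)
})

test_that("filter pass-set is monotone in the thresholds (property)", {
  set.seed(1)
  base <- event_filter_defaults()
  for (i in 1:25) {
    cnt <- as.list(sample(0:30, 4, replace = TRUE))
    if (cnt[[1]] + cnt[[2]] == 0 || cnt[[3]] + cnt[[4]] == 0) next
    cmp <- delta_psi_bayes(cnt[[1]], cnt[[2]], cnt[[3]], cnt[[4]])
    r1 <- apply_event_filters(cnt[[1]], cnt[[2]], cnt[[3]], cnt[[4]],
                              cmp$delta_psi, cmp$bayes_factor, base)
    harder <- utils::modifyList(base, list(min_sum = 15L,
                                           min_delta_psi = 0.3,
                                           min_bayes_factor = 10))
    r2 <- apply_event_filters(cnt[[1]], cnt[[2]], cnt[[3]], cnt[[4]],
                              cmp$delta_psi, cmp$bayes_factor, harder)
    expect_true(!r2$pass || r1$pass) # raising thresholds never adds events
  }
})
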