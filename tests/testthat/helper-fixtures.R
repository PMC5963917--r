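# Shared fixtures and independent oracles used across the suite.

# A tiny hand-made annotation: one coding gene on '+', one noncoding on
# '-', plus an intergenic tail.  All coordinates chosen for hand checks.
tiny_annotation <- function() {
  chr <- paste(rep("ACGT", 500), collapse = "") # 2000 nt
  g1 <- gene("g1", "chrT", "+", list(
    transcript("g1.t1", rbind(c(100L, 200L), c(300L, 400L), c(500L, 600L)),
               tsl = 1L, cds = c(150L, 550L))))
  g2 <- gene("g2", "chrT", "-", list(
    transcript("g2.t1", rbind(c(800L, 900L), c(1000L, 1100L)), tsl = 1L)),
    biotype = "noncoding")
  genome_annotation(c(chrT = chr), list(g1, g2))
}

# Brute-force SARF oracle: all-pairs interval scan.
brute_force_sarfs <- function(features, sites, window_nt) {
  vapply(seq_len(nrow(features)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(sites))) {
      if (sites$chrom[j] != features$chrom[i] ||
          sites$strand[j] != features$strand[i]) next
      p <- sites$pos[j]
      s <- features$start[i]; e <- features$end[i]
      if ((p >= s && p < e) || abs(p - s) <= window_nt ||
          abs(p - (e - 1)) <= window_nt) { hit <- TRUE; break }
    }
    hit
  }, logical(1))
}

# Stirling numbers of the second kind, small n, for the exact occupancy
# oracle of the permutation-FDR null.
stirling2 <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  if (k > n) return(0)
  s <- 0
  for (j in 0:k) s <- s + (-1)^(k - j) * choose(k, j) * j^n
  s / factorial(k)
}

# Exact distribution of the number of occupied positions when N events
# land uniformly on L positions: P(X = j) = C(L, j) * j! * S(N, j) / L^N.
occupancy_moments <- function(L, N) {
  j <- 1:min(L, N)
  p <- choose(L, j) * factorial(j) * vapply(j, stirling2, 0, n = N) / L^N
  list(mean = sum(j * p), var = sum(j^2 * p) - sum(j * p)^2)
}

# Random flat-feature / site fixture for brute-force comparisons.
random_sarf_fixture <- function(n_feat = 20L, n_sites = 15L) {
  features <- data.frame(
    feature_id = sprintf("F%02d", seq_len(n_feat)),
    chrom = sample(c("c1", "c2"), n_feat, replace = TRUE),
    start = sample(0:5000, n_feat),
    strand = sample(c("+", "-"), n_feat, replace = TRUE),
    stringsAsFactors = FALSE)
  features$end <- features$start + sample(50:500, n_feat, replace = TRUE)
  sites <- data.frame(
    chrom = sample(c("c1", "c2"), n_sites, replace = TRUE),
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    pos = sample(0:6000, n_sites),
    count = sample(2:10, n_sites, replace = TRUE),
    fdr = 0.001, stringsAsFactors = FALSE)
  list(features = features, sites = binding_site_set(sites))
}
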