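# Integrative layer: binding-associated regulated features (SARFs),
# trajectory filtering and k-means clustering, detained-intron overlap
# fractions and DEG binding/NMD overlap statistics.

#' Call binding-associated regulated features (SARFs)
#'
#' A regulated flat feature is flagged as a SARF when at least one binding
#' site lies inside the feature interval or within `window_nt` of either
#' junction anchor (the feature's two edge coordinates), on the feature's
#' strand.
#'
#' @param features data.frame of regulated flat features with columns
#'   `feature_id`, `chrom`, `start`, `end`, `strand`.
#' @param sites a [binding_site_set()] (typically control-filtered, see
#'   [filter_vs_control()]).
#' @param window_nt window around each anchor (default 200).
#' @return the features data.frame with added `sarf` (logical) and
#'   `support_sites` (semicolon-joined site positions) columns, plus the
#'   window in attribute `window_nt`.
#' @export
call_sarfs <- function(features, sites, window_nt = 200L) {
  stopifnot(window_nt >= 0L)
  key_f <- paste(features$chrom, features$strand)
  key_s <- paste(sites$chrom, sites$strand)
  sarf <- logical(nrow(features))
  support <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    cand <- sites$pos[key_s == key_f[i]]
    if (length(cand) == 0L) next
    s <- features$start[i]; e <- features$end[i]
    hit <- (cand >= s & cand < e) |
      (abs(cand - s) <= window_nt) |
      (abs(cand - (e - 1L)) <= window_nt)
    sarf[i] <- any(hit)
    support[i] <- paste(sort(cand[hit]), collapse = ";")
  }
  features$sarf <- sarf
  features$support_sites <- support
  attr(features, "window_nt") <- window_nt
  features
}

#' Filter fold-change trajectories before clustering
#'
#' Keeps trajectories whose lag-1 Pearson autocorrelation (correlation of
#' consecutive time points) is at least `min_autocorr` and whose maximum
#' absolute log2 fold change lies within `[min_maxfc, max_maxfc]`.
#' Zero-variance trajectories (autocorrelation undefined) are dropped.
#'
#' @param traj numeric matrix, features x contrasts (>= 3 columns).
#' @param min_autocorr minimum lag-1 autocorrelation (default 0.1).
#' @param min_maxfc,max_maxfc bounds on the maximum |log2FC|
#'   (defaults 0.5 and 8.5).
#' @return list with `kept` (filtered matrix), `stats` (data.frame of
#'   autocorrelation, max |FC| and the kept flag for every input row).
#' @export
trajectory_filter <- function(traj, min_autocorr = 0.1, min_maxfc = 0.5,
                              max_maxfc = 8.5) {
  if (ncol(traj) < 3L) stop("trajectory length must be >= 3")
  ac <- apply(traj, 1L, function(x) {
    if (stats::sd(x[-length(x)]) == 0 || stats::sd(x[-1L]) == 0)
      return(NA_real_)
    stats::cor(x[-length(x)], x[-1L])
  })
  maxfc <- apply(abs(traj), 1L, max)
  keep <- !is.na(ac) & ac >= min_autocorr &
    maxfc >= min_maxfc & maxfc <= max_maxfc
  list(kept = traj[keep, , drop = FALSE],
       stats = data.frame(feature_id = rownames(traj), autocorr = ac,
                          max_abs_fc = maxfc, kept = keep,
                          stringsAsFactors = FALSE))
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centres with
# probability proportional to squared distance from the nearest centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1L]) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2 / sum(d2))
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster fold-change trajectories with seeded k-means
#'
#' k-means with k-means++ initialisation, `n_restarts` restarts and a
#' fixed seed; the restart with the lowest within-cluster sum of squares
#' wins.  Deterministic for a given seed.
#'
#' @param traj numeric matrix, features x contrasts.
#' @param k number of clusters (default 20).
#' @param seed integer seed.
#' @param n_restarts restarts (default 10).
#' @return list with `cluster` (named integer vector), `centers`,
#'   `inertia` (total within-cluster sum of squares).
#' @export
cluster_trajectories <- function(traj, k = 20L, seed = 1L,
                                 n_restarts = 10L) {
  if (nrow(traj) < k) stop("fewer trajectories than clusters")
  with_seed(substream_seed(seed, "kmeans"), {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(traj, k)
      centers <- centers + stats::rnorm(length(centers), sd = 1e-9) # break ties
      fit <- suppressWarnings(
        stats::kmeans(traj, centers = centers, iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(cluster = setNames(best$cluster, rownames(traj)),
         centers = best$centers, inertia = best$tot.withinss)
  })
}

#' Concentration of SARFs in the SARF-richest clusters
#'
#' Ranks clusters by SARF count and reports the fraction of all SARFs
#' falling in the `top_n` richest clusters alongside the fraction of all
#' clustered features those clusters hold, plus their ratio (enrichment).
#'
#' @param cluster named integer vector of cluster assignments.
#' @param sarf logical vector aligned with `cluster`.
#' @param top_n number of top clusters (default 3).
#' @return list with `sarf_fraction`, `feature_fraction`, `enrichment`,
#'   `top_clusters`, and the numerators/denominators for audit.
#' @export
sarf_cluster_summary <- function(cluster, sarf, top_n = 3L) {
  stopifnot(length(cluster) == length(sarf))
  if (sum(sarf) == 0L) stop("undefined summary: zero SARFs")
  per <- table(cluster[sarf])
  ranked <- names(sort(per, decreasing = TRUE))
  top <- ranked[seq_len(min(top_n, length(ranked)))]
  in_top <- cluster %in% as.integer(top)
  sarf_frac <- sum(sarf & in_top) / sum(sarf)
  feat_frac <- sum(in_top) / length(cluster)
  list(sarf_fraction = sarf_frac, feature_fraction = feat_frac,
       enrichment = sarf_frac / feat_frac, top_clusters = as.integer(top),
       n_sarf_top = sum(sarf & in_top), n_sarf = sum(sarf),
       n_feat_top = sum(in_top), n_feat = length(cluster))
}

frac_or_na <- function(num, den) {
  if (den == 0L) list(fraction = NA_real_, num = num, den = den)
  else list(fraction = num / den, num = num, den = den)
}

#' Detained-intron binding and regulation fractions
#'
#' Reports, with explicit numerators and denominators:
#' (i) the fraction of intronic SARFs classified as detained introns,
#' (ii) the fraction of regulated detained introns carrying >= 1 binding
#' site, (iii) the same for non-regulated detained introns, and (iv) the
#' fraction of detained-intron SARFs immediately flanking a regulated
#' exonic part (adjacency = shared boundary coordinate within the gene).
#' Empty denominators yield `NA`, not 0.
#'
#' @param features flat-feature data.frame with columns `feature_id`,
#'   `gene_id`, `kind`, `chrom`, `start`, `end`, `strand`, `status`
#'   (regulated/unregulated/untestable) and `sarf` (logical).
#' @param di data.frame of detained-intron intervals (`chrom`, `start`,
#'   `end`, `strand`).
#' @param sites a [binding_site_set()].
#' @return list of four named results, each with `fraction`, `num`, `den`.
#' @export
di_binding_fractions <- function(features, di, sites) {
  introns <- features[features$kind == "intron", , drop = FALSE]
  key_i <- paste(introns$chrom, introns$strand, introns$start, introns$end)
  key_d <- paste(di$chrom, di$strand, di$start, di$end)
  introns$is_di <- key_i %in% key_d
  key_s <- paste(sites$chrom, sites$strand)
  has_site <- vapply(seq_len(nrow(introns)), function(i) {
    cand <- sites$pos[key_s == paste(introns$chrom[i], introns$strand[i])]
    any(cand >= introns$start[i] & cand < introns$end[i])
  }, logical(1))
  reg <- introns$status == "regulated"
  # (i) intronic SARFs that are DIs
  f1 <- frac_or_na(sum(introns$sarf & introns$is_di), sum(introns$sarf))
  # (ii) regulated DIs with a site; (iii) non-regulated DIs with a site
  f2 <- frac_or_na(sum(introns$is_di & reg & has_site),
                   sum(introns$is_di & reg))
  f3 <- frac_or_na(sum(introns$is_di & !reg & has_site),
                   sum(introns$is_di & !reg))
  # (iv) DI SARFs flanking a regulated exonic part
  ex <- features[features$kind == "exonic_part", , drop = FALSE]
  flank_reg <- vapply(seq_len(nrow(introns)), function(i) {
    adj <- ex$gene_id == introns$gene_id[i] &
      (ex$end == introns$start[i] | ex$start == introns$end[i])
    any(adj & ex$status == "regulated")
  }, logical(1))
  f4 <- frac_or_na(sum(introns$sarf & introns$is_di & flank_reg),
                   sum(introns$sarf & introns$is_di))
  list(intronic_sarf_di = f1, regulated_di_bound = f2,
       nonregulated_di_bound = f3, di_sarf_flanking_regulated_exon = f4)
}

#' Differential-expression overlap statistics
#'
#' Applies the DEG thresholds (strict `fdr < fdr_max`, inclusive
#' `|log2FC| >= min_abs_lfc`), then reports the DEG count and up/down
#' split, the bound fraction overall and by direction, the fraction of
#' bound and unbound DEGs in the NMD gene/mRNA sets, and one-sided
#' hypergeometric enrichment p-values (population = all genes in the
#' table) for each overlap.
#'
#' @param deg data.frame with columns `gene_id`, `log2fc`, `fdr`, `bound`
#'   (logical) and optionally `nmd_gene`, `nmd_mrna` (logical).
#' @param fdr_max FDR threshold (default 0.05, strict).
#' @param min_abs_lfc minimum |log2FC| (default 1, inclusive).
#' @return nested list of counts, fractions and p-values; every fraction
#'   carries its numerator and denominator.
#' @export
deg_overlap_stats <- function(deg, fdr_max = 0.05, min_abs_lfc = 1) {
  stopifnot(all(c("gene_id", "log2fc", "fdr", "bound") %in% names(deg)))
  is_deg <- deg$fdr < fdr_max & abs(deg$log2fc) >= min_abs_lfc
  d <- deg[is_deg, , drop = FALSE]
  up <- d$log2fc > 0
  hyper_p <- function(n_obs, n_success, n_total, n_draw) {
    if (n_draw == 0L) return(NA_real_)
    stats::phyper(n_obs - 1, n_success, n_total - n_success, n_draw,
                  lower.tail = FALSE)
  }
  out <- list(
    n_deg = nrow(d), n_up = sum(up), n_down = sum(!up),
    bound_fraction = frac_or_na(sum(d$bound), nrow(d)),
    bound_fraction_up = frac_or_na(sum(d$bound & up), sum(up)),
    bound_fraction_down = frac_or_na(sum(d$bound & !up), sum(!up)),
    bound_enrichment_p = hyper_p(sum(d$bound), sum(deg$bound),
                                 nrow(deg), nrow(d)))
  for (set in c("nmd_gene", "nmd_mrna")) {
    if (!set %in% names(deg)) next
    in_set <- d[[set]]
    out[[paste0(set, "_bound_fraction")]] <-
      frac_or_na(sum(in_set & d$bound), sum(d$bound))
    out[[paste0(set, "_unbound_fraction")]] <-
      frac_or_na(sum(in_set & !d$bound), sum(!d$bound))
    out[[paste0(set, "_enrichment_p")]] <-
      hyper_p(sum(in_set & d$bound), sum(deg[[set]]), nrow(deg),
              sum(d$bound))
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected agreement between cluster assignments; used
#' to score clustering recovery against planted labels.
#'
#' @param a,b vectors of cluster labels (same length).
#' @return ARI in \\[-1, 1\\]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
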