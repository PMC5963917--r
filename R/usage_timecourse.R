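# Differential feature-usage testing across the reprogramming time course:
# a beta-binomial likelihood-ratio stand-in for NB-GLM exon/junction usage
# machinery, BH classification into regulated/unregulated/untestable, and
# variance-stabilised log2 fold-change trajectories.

#' Variance-stabilised log2 fold change
#'
#' `log2((x + c) / (y + c))`: a moderated fold change whose pseudocount
#' damps low-count noise, monotone in `x` and anti-monotone in `y`.
#'
#' @param x,y non-negative counts (vectorised).
#' @param c pseudocount (> 0, default 1).
#' @return numeric vector of log2 fold changes.
#' @export
vst_log2fc <- function(x, y, c = 1) {
  stopifnot(c > 0, all(x >= 0), all(y >= 0))
  log2((x + c) / (y + c))
}

# Beta-binomial log-likelihood of counts y out of n at mean mu with
# intra-class correlation rho (rho = 0 degenerates to binomial).
bb_loglik <- function(y, n, mu, rho) {
  mu <- min(max(mu, 1e-9), 1 - 1e-9)
  if (rho <= 1e-12) return(sum(stats::dbinom(y, n, mu, log = TRUE)))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

# Moment estimate of the beta-binomial intra-class correlation from
# replicate-level proportions, pooled over the two conditions; floored.
estimate_rho <- function(y_a, n_a, y_b, n_b, floor = 0) {
  chi2 <- 0; df <- 0; nbar <- c()
  for (cond in list(list(y = y_a, n = n_a), list(y = y_b, n = n_b))) {
    ok <- cond$n > 0
    y <- cond$y[ok]; n <- cond$n[ok]
    if (length(n) < 2L) next
    p <- sum(y) / sum(n)
    if (p <= 0 || p >= 1) next
    chi2 <- chi2 + sum((y - n * p)^2 / (n * p * (1 - p)))
    df <- df + length(n) - 1L
    nbar <- c(nbar, n)
  }
  if (df == 0L || length(nbar) == 0L) return(floor)
  phi <- chi2 / df
  rho <- (phi - 1) / (mean(nbar) - 1)
  max(min(rho, 0.99), floor)
}

#' Beta-binomial likelihood-ratio test of differential feature usage
#'
#' Tests whether the proportion of a gene's reads landing on one flat
#' feature differs between two time points.  Replicate (feature,
#' gene-rest) count pairs enter a beta-binomial likelihood with a shared
#' intra-class correlation estimated from the replicates (method of
#' moments, floored at `rho_floor`); the mean inclusion fraction is fit by
#' maximum likelihood per condition (alternative) and shared (null), and
#' the likelihood-ratio statistic is referred to chi-squared with 1 df.
#'
#' @param y_a,y_b per-replicate feature counts in the two time points.
#' @param rest_a,rest_b per-replicate gene-rest counts.
#' @param min_reads untestable threshold: the test is untestable when the
#'   summed feature reads are below `min_reads` in BOTH time points.
#' @param rho_floor lower bound for the overdispersion estimate.
#' @param pseudocount pseudocount for the reported usage fold change.
#' @return list with `p_value`, `vst_log2fc` (of the usage proportion),
#'   `untestable`, `rho`, `stat`.
#' @export
feature_usage_test <- function(y_a, rest_a, y_b, rest_b, min_reads = 5L,
                               rho_floor = 0, pseudocount = 1) {
  y_a <- as.numeric(y_a); y_b <- as.numeric(y_b)
  rest_a <- as.numeric(rest_a); rest_b <- as.numeric(rest_b)
  n_a <- y_a + rest_a; n_b <- y_b + rest_b
  untestable <- (sum(y_a) < min_reads && sum(y_b) < min_reads) ||
    sum(rest_a) == 0 || sum(rest_b) == 0
  prop_a <- (sum(y_a) + pseudocount) / (sum(n_a) + 2 * pseudocount)
  prop_b <- (sum(y_b) + pseudocount) / (sum(n_b) + 2 * pseudocount)
  fc <- log2(prop_a / prop_b)
  if (untestable)
    return(list(p_value = NA_real_, vst_log2fc = fc, untestable = TRUE,
                rho = NA_real_, stat = NA_real_))
  rho <- estimate_rho(y_a, n_a, y_b, n_b, floor = rho_floor)
  fit_mu <- function(y, n) {
    if (rho <= 1e-12) return(sum(y) / max(sum(n), 1))
    stats::optimize(function(m) -bb_loglik(y, n, m, rho),
                    interval = c(1e-6, 1 - 1e-6))$minimum
  }
  mu_a <- fit_mu(y_a, n_a); mu_b <- fit_mu(y_b, n_b)
  mu_0 <- fit_mu(c(y_a, y_b), c(n_a, n_b))
  l1 <- bb_loglik(y_a, n_a, mu_a, rho) + bb_loglik(y_b, n_b, mu_b, rho)
  l0 <- bb_loglik(y_a, n_a, mu_0, rho) + bb_loglik(y_b, n_b, mu_0, rho)
  stat <- max(0, 2 * (l1 - l0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(p_value = p, vst_log2fc = fc, untestable = FALSE, rho = rho,
       stat = stat)
}

#' Classify features into regulated / unregulated / untestable
#'
#' Benjamini-Hochberg FDR across the testable features of one contrast;
#' `regulated` iff `fdr < alpha`; untestable features are preserved and
#' excluded from the BH denominator.
#'
#' @param results data.frame with columns `p_value` and `untestable`.
#' @param alpha FDR threshold (default 0.05).
#' @return the data.frame with added `fdr` and `status` columns.
#' @export
classify_features <- function(results, alpha = 0.05) {
  results$fdr <- NA_real_
  testable <- !results$untestable & !is.na(results$p_value)
  results$fdr[testable] <- stats::p.adjust(results$p_value[testable],
                                           method = "BH")
  results$status <- ifelse(!testable, "untestable",
                           ifelse(results$fdr < alpha, "regulated",
                                  "unregulated"))
  results
}

#' Build a contrast plan over ordered time points
#'
#' @param timepoints ordered character vector of time-point labels.
#' @param mode `"cumulative"` (each time point vs the first),
#'   `"sequential"` (each vs the previous) or `"omnibus"` (all pairs vs
#'   first; alias of cumulative for the pairwise engine).
#' @return data.frame with columns `contrast`, `ref`, `alt`.
#' @export
contrast_plan <- function(timepoints, mode = c("cumulative", "sequential",
                                               "omnibus")) {
  mode <- match.arg(mode)
  if (length(timepoints) < 2L) stop("need >= 2 timepoints")
  T <- length(timepoints)
  ref <- switch(mode,
                cumulative = rep(timepoints[1L], T - 1L),
                omnibus = rep(timepoints[1L], T - 1L),
                sequential = timepoints[-T])
  alt <- timepoints[-1L]
  data.frame(contrast = paste(alt, "vs", ref), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Columns of a counts table belonging to one timepoint ("<tp>_<rep>").
tp_cols <- function(counts, tp) {
  grep(paste0("^", tp, "_"), names(counts), value = TRUE)
}

# Gene-rest counts: per sample, the summed exonic_part counts of the
# feature's gene minus the feature's own count when it is an exonic part.
gene_rest_counts <- function(counts, sample_cols) {
  exonic <- counts$kind == "exonic_part"
  gene_tot <- rowsum(as.matrix(counts[exonic, sample_cols, drop = FALSE]),
                     counts$gene_id[exonic])
  rest <- gene_tot[counts$gene_id, , drop = FALSE]
  own <- as.matrix(counts[, sample_cols, drop = FALSE])
  own[!exonic, ] <- 0
  rest - own
}

#' Run differential-usage contrasts over a time course
#'
#' For each contrast in the plan, runs [feature_usage_test()] per feature
#' against its gene-rest counts, classifies with [classify_features()] and
#' tallies regulated features.
#'
#' @param counts data.frame with columns `feature_id`, `gene_id`, `kind`
#'   and one count column per `<timepoint>_<replicate>` sample.
#' @param timepoints ordered time-point labels matching the column prefixes.
#' @param mode contrast mode, see [contrast_plan()].
#' @param alpha FDR threshold.
#' @param min_reads untestable threshold (see [feature_usage_test()]).
#' @return list with `plan`, `results` (one data.frame per contrast, each
#'   with p/fdr/status/vst_log2fc per feature) and `summary` (regulated
#'   count per contrast).
#' @export
run_contrasts <- function(counts, timepoints, mode = "cumulative",
                          alpha = 0.05, min_reads = 5L) {
  plan <- contrast_plan(timepoints, mode)
  results <- vector("list", nrow(plan))
  names(results) <- plan$contrast
  for (ci in seq_len(nrow(plan))) {
    ref_cols <- tp_cols(counts, plan$ref[ci])
    alt_cols <- tp_cols(counts, plan$alt[ci])
    if (length(ref_cols) == 0L || length(alt_cols) == 0L)
      stop("no count columns for contrast ", plan$contrast[ci])
    rest_ref <- gene_rest_counts(counts, ref_cols)
    rest_alt <- gene_rest_counts(counts, alt_cols)
    rows <- lapply(seq_len(nrow(counts)), function(i) {
      tst <- feature_usage_test(
        y_a = as.numeric(counts[i, alt_cols]),
        rest_a = as.numeric(rest_alt[i, ]),
        y_b = as.numeric(counts[i, ref_cols]),
        rest_b = as.numeric(rest_ref[i, ]),
        min_reads = min_reads)
      data.frame(feature_id = counts$feature_id[i],
                 gene_id = counts$gene_id[i], kind = counts$kind[i],
                 p_value = tst$p_value, vst_log2fc = tst$vst_log2fc,
                 untestable = tst$untestable, stringsAsFactors = FALSE)
    })
    res <- classify_features(do.call(rbind, rows), alpha = alpha)
    res$contrast <- plan$contrast[ci]
    results[[ci]] <- res
  }
  summary <- data.frame(
    contrast = plan$contrast,
    n_regulated = vapply(results, function(r) sum(r$status == "regulated"),
                         numeric(1)),
    n_untestable = vapply(results, function(r) sum(r$status == "untestable"),
                          numeric(1)),
    stringsAsFactors = FALSE)
  list(plan = plan, results = results, summary = summary)
}

#' Per-feature fold-change trajectories over a time course
#'
#' Mean counts per time point are contrasted (cumulative: against the
#' first time point; sequential: against the previous one) with
#' [vst_log2fc()], giving one trajectory vector per feature.
#'
#' @inheritParams run_contrasts
#' @param c pseudocount for [vst_log2fc()].
#' @return numeric matrix, features x contrasts, rownames = feature ids.
#' @export
feature_trajectories <- function(counts, timepoints, mode = "cumulative",
                                 c = 1) {
  plan <- contrast_plan(timepoints, mode)
  tp_mean <- sapply(timepoints, function(tp)
    rowMeans(as.matrix(counts[, tp_cols(counts, tp), drop = FALSE])))
  traj <- sapply(seq_len(nrow(plan)), function(ci)
    vst_log2fc(tp_mean[, plan$alt[ci]], tp_mean[, plan$ref[ci]], c = c))
  traj <- matrix(traj, nrow = nrow(counts),
                 dimnames = list(counts$feature_id, plan$contrast))
  traj
}
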