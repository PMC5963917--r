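# Crosslink-site calling: dedup of truncation events into per-nucleotide
# cDNA counts, permutation FDR within co-transcribed regions, control
# filtering and site-set comparison.

#' Construct a crosslink table
#'
#' @param df data.frame with columns `chrom`, `strand`, `pos` (0-based
#'   nucleotide) and `count` (unique cDNAs, positive integer).
#' @return the validated data.frame with class `CrosslinkTable`.
#' @export
crosslink_table <- function(df) {
  need <- c("chrom", "strand", "pos", "count")
  stopifnot(all(need %in% names(df)))
  if (nrow(df) > 0L) {
    if (any(df$count < 1L)) stop("crosslink counts must be >= 1")
    if (!all(df$strand %in% c("+", "-"))) stop("malformed strand")
    if (anyDuplicated(df[c("chrom", "strand", "pos")]))
      stop("duplicate crosslink positions")
  }
  class(df) <- c("CrosslinkTable", "data.frame")
  df
}

#' Construct a binding-site set
#'
#' @param df data.frame with columns `chrom`, `strand`, `pos`, `count`,
#'   `fdr`.
#' @param alpha the FDR threshold the set was called at.
#' @return data.frame with class `BindingSiteSet` and attribute `alpha`.
#' @export
binding_site_set <- function(df, alpha = 0.05) {
  need <- c("chrom", "strand", "pos", "count", "fdr")
  stopifnot(all(need %in% names(df)))
  if (nrow(df) > 0L && (any(df$fdr < 0) || any(df$fdr > 1)))
    stop("fdr must lie in [0, 1]")
  attr(df, "alpha") <- alpha
  class(df) <- c("BindingSiteSet", "data.frame")
  df
}

#' Collapse unique-mapping read records into a crosslink table
#'
#' Records with identical (chrom, strand, position, umi) are collapsed to a
#' single cDNA.  The crosslink position is the nucleotide immediately 5' of
#' the read start in transcript orientation: `start - 1` on the plus strand
#' and `fivep + 1` on the minus strand.
#'
#' @param reads data.frame with columns `chrom`, `strand`, `fivep`
#'   (0-based genomic position of the read 5' end) and `umi`.
#' @return a [crosslink_table()].
#' @export
reads_to_crosslinks <- function(reads) {
  stopifnot(all(c("chrom", "strand", "fivep", "umi") %in% names(reads)))
  if (!all(reads$strand %in% c("+", "-"))) stop("malformed strand")
  reads <- unique(reads[c("chrom", "strand", "fivep", "umi")])
  reads$pos <- ifelse(reads$strand == "+", reads$fivep - 1L, reads$fivep + 1L)
  agg <- stats::aggregate(list(count = reads$umi),
                          by = reads[c("chrom", "strand", "pos")],
                          FUN = length)
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), ]
  rownames(agg) <- NULL
  crosslink_table(agg)
}

# Monte-Carlo null for one region: redistribute N events uniformly over L
# positions n_rand times; for each height k in `ks` return the mean number
# of positions with count >= k.
null_tail_means <- function(L, N, ks, n_rand) {
  tails <- matrix(0, nrow = n_rand, ncol = length(ks))
  for (r in seq_len(n_rand)) {
    cnt <- tabulate(sample.int(L, N, replace = TRUE), nbins = L)
    cnt <- cnt[cnt > 0L]
    tails[r, ] <- vapply(ks, function(k) sum(cnt >= k), numeric(1))
  }
  colMeans(tails)
}

#' Call statistically significant crosslink sites by permutation FDR
#'
#' Within each co-transcribed region, the observed crosslink events are
#' redistributed uniformly at random over the region's positions `n_rand`
#' times (multinomial: the total event count is preserved and collisions
#' are allowed).  For each observed count height k,
#' `FDR(k) = mean_null(#positions with count >= k) / observed(#positions
#' with count >= k)`, capped at 1 and monotonised to be non-increasing in
#' k.  Sites with `FDR < alpha` are retained.
#'
#' Crosslinks falling outside every region are dropped with a warning.
#'
#' @param xlinks a [crosslink_table()].
#' @param regions data.frame of co-transcribed intervals with columns
#'   `chrom`, `start`, `end`, `strand` (see [cotranscribed_regions()]).
#' @param n_rand number of randomisations (>= 1).
#' @param alpha FDR threshold; retention uses strict `fdr < alpha`.
#' @param seed integer seed for the randomisations.
#' @return a [binding_site_set()] of retained sites with their counts and
#'   FDR values; the full per-site FDR table (including non-significant
#'   sites) is attached as attribute `all_sites`.
#' @export
call_significant_sites <- function(xlinks, regions, n_rand = 100L,
                                   alpha = 0.05, seed = 1L) {
  stopifnot(inherits(xlinks, "CrosslinkTable"))
  if (n_rand < 1L) stop("n_rand must be >= 1")
  if (nrow(regions) > 0L && any(regions$end <= regions$start))
    stop("region of length 0")
  res <- with_seed(substream_seed(seed, "callsites"), {
    out <- list()
    assigned <- rep(FALSE, nrow(xlinks))
    key_x <- paste(xlinks$chrom, xlinks$strand)
    key_r <- paste(regions$chrom, regions$strand)
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i, ]
      in_rg <- key_x == key_r[i] & xlinks$pos >= rg$start & xlinks$pos < rg$end
      assigned <- assigned | in_rg
      xl <- xlinks[in_rg, , drop = FALSE]
      if (nrow(xl) == 0L) next
      L <- rg$end - rg$start
      N <- sum(xl$count)
      ks <- sort(unique(xl$count))
      nulls <- null_tail_means(L, N, ks, n_rand)
      obs <- vapply(ks, function(k) sum(xl$count >= k), numeric(1))
      fdr_k <- pmin(1, nulls / obs)
      # monotonise: FDR never increases with the count height
      fdr_k <- cummin(fdr_k)
      fdr_map <- setNames(fdr_k, ks)
      xl$fdr <- unname(fdr_map[as.character(xl$count)])
      out[[length(out) + 1L]] <- xl
    }
    if (any(!assigned))
      warning(sprintf("%d crosslink position(s) outside all regions dropped",
                      sum(!assigned)))
    out
  })
  all_sites <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(chrom = character(0), strand = character(0),
               pos = integer(0), count = integer(0), fdr = numeric(0))
  rownames(all_sites) <- NULL
  keep <- all_sites[all_sites$fdr < alpha, , drop = FALSE]
  rownames(keep) <- NULL
  out <- binding_site_set(keep, alpha = alpha)
  attr(out, "all_sites") <- all_sites
  out
}

#' Filter significant sites against a control library
#'
#' Keeps sites with `count >= min_count` that have no control crosslink at
#' the identical (chrom, strand, position).
#'
#' @param sites a [binding_site_set()].
#' @param control a [crosslink_table()] from the control library.
#' @param min_count minimum crosslink count (default 2).
#' @return the filtered [binding_site_set()].
#' @export
filter_vs_control <- function(sites, control, min_count = 2L) {
  stopifnot(inherits(sites, "BindingSiteSet"))
  ctrl_key <- paste(control$chrom, control$strand, control$pos)
  site_key <- paste(sites$chrom, sites$strand, sites$pos)
  keep <- sites$count >= min_count & !(site_key %in% ctrl_key)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  binding_site_set(out, alpha = attr(sites, "alpha") %||% 0.05)
}

#' Fraction of one site set recovered in another
#'
#' @param a,b [binding_site_set()] objects (or data.frames with `chrom`,
#'   `strand`, `pos`).
#' @param tolerance_nt maximum distance (nt) for a site in `a` to count as
#'   matched by a site in `b` on the same chromosome and strand.
#' @return fraction in \\[0, 1\\] of `a` sites with >= 1 match in `b`.
#' @export
site_overlap_fraction <- function(a, b, tolerance_nt = 3L) {
  stopifnot(tolerance_nt >= 0L)
  if (nrow(a) == 0L) stop("undefined fraction: empty site set 'a'")
  if (nrow(b) == 0L) return(0)
  key_a <- paste(a$chrom, a$strand)
  key_b <- paste(b$chrom, b$strand)
  matched <- vapply(seq_len(nrow(a)), function(i) {
    cand <- b$pos[key_b == key_a[i]]
    length(cand) > 0L && any(abs(cand - a$pos[i]) <= tolerance_nt)
  }, logical(1))
  mean(matched)
}

#' Exact expected number of null positions at or above a count height
#'
#' Closed-form oracle for the permutation null used by
#' [call_significant_sites()]: for N events dropped uniformly on L
#' positions, the expected number of positions with count >= k is
#' `L * P(Binomial(N, 1/L) >= k)`.  Used in validation; exported because it
#' is handy for power calculations.
#'
#' @param L region length (positions).
#' @param N total crosslink events.
#' @param k count height.
#' @return expected number of positions with count >= k under the null.
#' @export
expected_null_positions <- function(L, N, k) {
  L * stats::pbinom(k - 1, size = N, prob = 1 / L, lower.tail = FALSE)
}
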