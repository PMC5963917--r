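# Windowed k-mer counting around crosslink sites, shuffled-null z-scores
# and a greedy consensus builder.
#
# K-mers are reported in the RNA alphabet (U not T); window extraction is
# strand-aware, with minus-strand windows reverse-complemented so that all
# sequence logic runs in transcript orientation.

fast_revcomp <- function(x) {
  x <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# K-mers per site over the union of the offset windows, vectorised over
# sites.  Returns a list (one character vector per site) of distinct
# k-mers (presence mode) or all occurrences.
window_kmers_by_site <- function(annotation, sites, k, offsets,
                                 distinct = TRUE) {
  n <- nrow(sites)
  chlens <- nchar(annotation$chromosomes)
  per_site <- rep(list(character(0)), n)
  if (n == 0L) return(per_site)
  pieces <- list()
  for (o in offsets) {
    plus <- sites$strand == "+"
    gs <- ifelse(plus, sites$pos + o[1L], sites$pos - o[2L])
    ge <- ifelse(plus, sites$pos + o[2L] + 1L, sites$pos - o[1L] + 1L)
    gs <- pmax(gs, 0L)
    ge <- pmin(ge, chlens[sites$chrom])
    inb <- sites$pos >= 0L & sites$pos < chlens[sites$chrom] & ge - gs >= k
    seqs <- rep(NA_character_, n)
    seqs[inb] <- substring(annotation$chromosomes[sites$chrom[inb]],
                           gs[inb] + 1L, ge[inb])
    minus <- inb & !plus
    seqs[minus] <- fast_revcomp(seqs[minus])
    pieces[[length(pieces) + 1L]] <- seqs
  }
  for (i in seq_len(n)) {
    kmers <- character(0)
    for (p in pieces) {
      s <- p[i]
      if (is.na(s)) next
      nn <- nchar(s)
      kmers <- c(kmers, substring(s, seq_len(nn - k + 1L),
                                  seq_len(nn - k + 1L) + k - 1L))
    }
    if (length(kmers) > 0L) {
      kmers <- toupper(dna_to_rna(kmers))
      kmers <- kmers[!grepl("[^ACGU]", kmers)]
      if (distinct) kmers <- unique(kmers)
    }
    per_site[[i]] <- kmers
  }
  per_site
}

# Enumerate the k-mers present in the union of the offset windows around
# one site.  Returns a character vector of distinct k-mers (presence mode)
# or all occurrences (occurrence mode).
site_window_kmers <- function(annotation, chrom, strand, pos, k, offsets,
                              distinct = TRUE) {
  window_kmers_by_site(annotation,
                       data.frame(chrom = chrom, strand = strand, pos = pos,
                                  stringsAsFactors = FALSE),
                       k, offsets, distinct)[[1L]]
}

#' Weighted k-mer counts in windows around binding sites
#'
#' Each site contributes weight 1.0 to every k-mer present at least once in
#' the union of its offset windows (presence weighting, the default); with
#' `mode = "occurrence"` every occurrence contributes 1.0 instead.  The
#' total weight of a k-mer is therefore the number of contributing sites
#' (or occurrences).  Windows clipped away entirely by a sequence edge
#' contribute nothing.
#'
#' @param annotation a [genome_annotation()] providing the sequences.
#' @param sites data.frame with columns `chrom`, `strand`, `pos`.
#' @param k k-mer length (window length must be >= k).
#' @param offsets list of closed offset intervals in transcript
#'   orientation; default `list(c(-30, -5), c(5, 30))`.
#' @param mode `"presence"` (default) or `"occurrence"`.
#' @return named numeric vector of weights for every k-mer observed in at
#'   least one window (RNA alphabet).
#' @export
site_kmer_weights <- function(annotation, sites, k = 5L,
                              offsets = list(c(-30L, -5L), c(5L, 30L)),
                              mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  wlen <- min(vapply(offsets, function(o) o[2L] - o[1L] + 1L, numeric(1)))
  if (k > wlen) stop("k exceeds window length")
  km <- window_kmers_by_site(annotation, sites, k, offsets,
                             distinct = (mode == "presence"))
  all <- unlist(km, use.names = FALSE)
  if (length(all) == 0L) return(setNames(numeric(0), character(0)))
  tb <- table(all)
  out <- setNames(as.numeric(tb), names(tb))
  sort(out, decreasing = TRUE)
}

#' K-mer enrichment z-scores against a shuffled positional null
#'
#' Sites are relocated uniformly at random within their assigned
#' co-transcribed region `n_shuffles` times and the k-mer weights
#' recomputed; `z = (observed - mean_null) / sd_null` per k-mer.  K-mers
#' with zero null standard deviation get `z = 0` and are flagged in the
#' `degenerate` column.
#'
#' @inheritParams site_kmer_weights
#' @param regions co-transcribed regions (see [cotranscribed_regions()]);
#'   each site must fall inside one region on its strand.
#' @param n_shuffles number of shuffles (>= 2).
#' @param seed integer seed.
#' @return data.frame of class `KmerZTable` with columns `kmer`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `degenerate`, sorted by
#'   decreasing z.
#' @export
kmer_zscores <- function(annotation, sites, regions, k = 5L,
                         offsets = list(c(-30L, -5L), c(5L, 30L)),
                         n_shuffles = 100L, seed = 1L,
                         mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  if (n_shuffles < 2L) stop("n_shuffles must be >= 2 (sd undefined)")
  key_r <- paste(regions$chrom, regions$strand)
  key_s <- paste(sites$chrom, sites$strand)
  region_of <- vapply(seq_len(nrow(sites)), function(i) {
    j <- which(key_r == key_s[i] & regions$start <= sites$pos[i] &
                 sites$pos[i] < regions$end)
    if (length(j) == 0L)
      stop(sprintf("site %s:%d (%s) not inside any region",
                   sites$chrom[i], sites$pos[i], sites$strand[i]))
    j[1L]
  }, integer(1))
  observed <- site_kmer_weights(annotation, sites, k, offsets, mode)
  null_w <- with_seed(substream_seed(seed, "kmer-shuffle"), {
    lapply(seq_len(n_shuffles), function(s) {
      shuf <- sites
      shuf$pos <- regions$start[region_of] +
        floor(stats::runif(nrow(sites)) *
                (regions$end[region_of] - regions$start[region_of]))
      site_kmer_weights(annotation, shuf, k, offsets, mode)
    })
  })
  kmers <- sort(unique(c(names(observed), unlist(lapply(null_w, names)))))
  obs <- setNames(numeric(length(kmers)), kmers)
  obs[names(observed)] <- observed
  nm <- matrix(0, nrow = n_shuffles, ncol = length(kmers),
               dimnames = list(NULL, kmers))
  for (s in seq_len(n_shuffles)) nm[s, names(null_w[[s]])] <- null_w[[s]]
  mu <- colMeans(nm)
  sdv <- apply(nm, 2L, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  out <- data.frame(kmer = kmers, observed = unname(obs),
                    null_mean = unname(mu), null_sd = unname(sdv),
                    z = unname(z), degenerate = unname(sdv == 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$kmer), ]
  rownames(out) <- NULL
  class(out) <- c("KmerZTable", "data.frame")
  attr(out, "k") <- k
  attr(out, "n_shuffles") <- n_shuffles
  out
}

IUPAC_RNA <- c(A = "A", C = "C", G = "G", U = "U",
               AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y", GU = "K",
               ACG = "V", ACU = "H", AGU = "D", CGU = "B", ACGU = "N")

# Best ungapped offset of `kmer` against the growing consensus profile:
# maximise the number of agreeing positions with the seed-anchored PWM
# consensus; ties resolved towards offset 0.  Offsets with < 2 aligned
# positions are never chosen.
best_offset <- function(seed_kmer, kmer) {
  k1 <- nchar(seed_kmer); k2 <- nchar(kmer)
  cand <- seq(-(k2 - 1L), k1 - 1L)
  score <- vapply(cand, function(off) {
    i <- seq_len(k2) + off          # position of each kmer letter on seed axis
    keep <- i >= 1L & i <= k1
    if (sum(keep) < 2L) return(-1L)
    sum(substring(seed_kmer, i[keep], i[keep]) ==
          substring(kmer, which(keep), which(keep)))
  }, integer(1))
  best <- max(score)
  if (best < 2L) return(NA_integer_)
  tied <- cand[score == best]
  tied[order(abs(tied), tied)][1L]
}

#' Build a consensus motif from top-ranked k-mers
#'
#' A documented stand-in for EM motif discovery: k-mers are greedily
#' aligned ungapped to the top-ranked seed at their best-overlap offset
#' (ties towards offset 0; k-mers with no agreement over >= 2 positions are
#' stacked at offset 0 with a warning), a weight-averaged position-weight
#' matrix is formed, and an IUPAC consensus letter is emitted per column
#' from the smallest base set reaching a 0.66 majority.
#'
#' @param kmers ranked character vector of k-mers (RNA or DNA alphabet, all
#'   the same length); the first is the alignment seed.
#' @param weights optional numeric weights, one per k-mer (default 1).
#' @return list with elements `pwm` (4 x width matrix, rows A/C/G/U) and
#'   `consensus` (IUPAC string).
#' @export
consensus_from_top_kmers <- function(kmers, weights = NULL) {
  if (length(kmers) == 0L) stop("empty k-mer list")
  kmers <- toupper(dna_to_rna(kmers))
  if (length(unique(nchar(kmers))) != 1L) stop("k-mers must share one length")
  if (is.null(weights)) weights <- rep(1, length(kmers))
  stopifnot(length(weights) == length(kmers))
  offs <- integer(length(kmers))
  for (i in seq_along(kmers)[-1L]) {
    o <- best_offset(kmers[1L], kmers[i])
    if (is.na(o)) {
      warning(sprintf("k-mer %s has no >= 2-nt agreement with seed; stacked at offset 0",
                      kmers[i]))
      o <- 0L
    }
    offs[i] <- o
  }
  k <- nchar(kmers[1L])
  lo <- min(offs); hi <- max(offs + k - 1L)
  width <- hi - lo + 1L
  pwm <- matrix(0, nrow = 4L, ncol = width,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  for (i in seq_along(kmers)) {
    cols <- offs[i] - lo + seq_len(k)
    letters_i <- strsplit(kmers[i], "")[[1L]]
    for (j in seq_len(k))
      pwm[letters_i[j], cols[j]] <- pwm[letters_i[j], cols[j]] + weights[i]
  }
  pwm <- sweep(pwm, 2L, pmax(colSums(pwm), .Machine$double.eps), "/")
  consensus <- vapply(seq_len(width), function(j) {
    p <- pwm[, j]
    for (size in 1:4) {
      sets <- utils::combn(names(p), size, simplify = FALSE)
      tot <- vapply(sets, function(s) sum(p[s]), numeric(1))
      ok <- which(tot >= 0.66)
      if (length(ok) > 0L) {
        best <- sets[ok][[which.max(tot[ok])]]
        return(IUPAC_RNA[[paste(sort(best), collapse = "")]])
      }
    }
    "N"
  }, character(1))
  list(pwm = pwm, consensus = paste(consensus, collapse = ""))
}
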