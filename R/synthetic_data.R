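# Seeded synthetic-data generators: a toy annotated genome with planted
# binding motifs, iCLIP signal/control libraries, a splicing/usage time
# course with planted trajectory clusters and detained-intron dynamics,
# and a DEG table -- each with recorded ground truth so every downstream
# caller can be scored without external data.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: a handful of multi-exon
#' genes on both strands, a pyrimidine-rich 5-mer binding motif, a 50:1
#' signal-to-background crosslink ratio over 20 planted sites, a 6-point
#' reprogramming time course (MEF, d3, d6, d9, d12, iPSC) with 2
#' replicates, 3 SARF-enriched trajectory clusters among 6 planted shapes,
#' and a detained-intron fraction of 0.15.
#'
#' @param seed master seed; every generator derives a named substream
#'   from it, so modules can be re-run independently and are
#'   byte-reproducible.
#' @param n_genes number of genes (> 0).
#' @param gene_length_range not used directly; gene extent emerges from
#'   `exon_count_range`, `exon_length_range`, `intron_length_range`.
#' @param exon_count_range,exon_length_range,intron_length_range integer
#'   ranges for gene structure.
#' @param noncoding_fraction fraction of genes without a CDS.
#' @param motif planted binding motif (RNA or DNA alphabet, default the
#'   pyrimidine-rich 5-mer `"CUCUC"`).
#' @param n_planted_sites number of planted crosslink sites.
#' @param signal_to_background ratio of the planted-site crosslink rate to
#'   the background rate (>= 1).
#' @param background_rate expected background crosslink events per
#'   co-transcribed nucleotide.
#' @param timepoints ordered time-point labels (>= 2).
#' @param n_replicates replicates per time point.
#' @param n_clusters_planted number of SARF-enriched trajectory shapes.
#' @param cluster_shapes optional matrix (shapes x timepoints) of planted
#'   log2 offsets; `NULL` builds the default 6-shape set,
#'   `"two_wave"` builds a two-shape set changing only at the first and
#'   last transitions.
#' @param regulated_fraction fraction of flat features assigned a planted
#'   (non-flat) trajectory shape.
#' @param sarf_prob_enriched,sarf_prob_background probability that a
#'   regulated feature is flagged SARF inside/outside the enriched shapes.
#' @param di_fraction fraction of introns flagged detained in truth.
#' @param baseline_count mean feature read count per replicate at baseline.
#' @param n_events number of alternative-splicing events.
#' @param event_depth mean junction reads per event, time point and
#'   replicate.
#' @param deg_fraction fraction of genes planted as differentially
#'   expressed.
#' @param deg_lfc planted |log2FC| for DEGs.
#' @return a validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L,
                       gene_length_range = c(2000L, 6000L),
                       exon_count_range = c(4L, 8L),
                       exon_length_range = c(80L, 300L),
                       intron_length_range = c(200L, 800L),
                       noncoding_fraction = 0.1,
                       motif = "CUCUC",
                       n_planted_sites = 20L,
                       signal_to_background = 50,
                       background_rate = 0.2,
                       timepoints = c("MEF", "d3", "d6", "d9", "d12",
                                      "iPSC"),
                       n_replicates = 2L,
                       n_clusters_planted = 3L,
                       cluster_shapes = NULL,
                       regulated_fraction = 0.4,
                       sarf_prob_enriched = 0.8,
                       sarf_prob_background = 0.1,
                       di_fraction = 0.15,
                       baseline_count = 100,
                       n_events = 120L,
                       event_depth = 50,
                       deg_fraction = 0.3,
                       deg_lfc = 2) {
  if (n_genes <= 0L) stop("empty simulation")
  props <- c(noncoding_fraction, regulated_fraction, sarf_prob_enriched,
             sarf_prob_background, di_fraction, deg_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (length(timepoints) < 2L) stop("need >= 2 timepoints")
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

# Planted trajectory shapes as per-timepoint log2 offsets (baseline 0 at
# the first time point).  The first n_clusters_planted shapes are the
# SARF-enriched, upwards-trending ones.
default_cluster_shapes <- function(cfg) {
  T <- length(cfg$timepoints)
  if (is.matrix(cfg$cluster_shapes)) return(cfg$cluster_shapes)
  if (identical(cfg$cluster_shapes, "two_wave")) {
    sh <- rbind(c(0, rep(1.5, T - 2L), 3),
                c(0, rep(-1.5, T - 2L), -3))
    rownames(sh) <- c("up_two_wave", "down_two_wave")
    return(sh)
  }
  grid <- function(v) stats::approx(seq_along(v), v, n = T)$y
  sh <- rbind(late_rise = grid(c(0, 0, 0.5, 1.5, 3)),
              early_rise = grid(c(0, 2, 2.5, 3, 3)),
              gradual_rise = grid(c(0, 0.8, 1.5, 2.2, 3)),
              late_fall = grid(c(0, 0, -0.5, -1.5, -3)),
              early_fall = grid(c(0, -2, -2.5, -3, -3)),
              transient = grid(c(0, 2.5, 1.2, 0.5, 0)))
  sh
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy annotated genome with planted motifs
#'
#' Random multi-exon genes are laid out with gaps on two chromosomes,
#' alternating strands; a configurable fraction carries no CDS.  Most
#' genes have a single TSL-1 transcript; every third gene gets an extra
#' TSL-2 transcript (skipping one internal exon) so support-level
#' filtering is exercised.  The binding motif is written into the sequence
#' (reverse-complemented on minus-strand genes) at recorded exonic and
#' intronic positions; the crosslink ground truth is the motif centre.
#' A `di_fraction` of introns is flagged detained in the truth.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a [genome_annotation()]) and `truth`
#'   (list with `planted_sites`, `motif`, `detained_introns`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  with_seed(substream_seed(cfg$seed, "genome"), {
    motif_dna <- toupper(rna_to_dna(cfg$motif))
    genes <- list()
    chrom_seqs <- c(chr1 = "", chr2 = "")
    cursor <- c(chr1 = 0L, chr2 = 0L)
    gene_meta <- list()
    for (gi in seq_len(cfg$n_genes)) {
      ch <- if (gi %% 2L == 1L) "chr1" else "chr2"
      strand <- if ((gi %/% 2L) %% 2L == 0L) "+" else "-"
      n_ex <- sample(cfg$exon_count_range[1L]:cfg$exon_count_range[2L], 1L)
      ex_len <- sample(cfg$exon_length_range[1L]:cfg$exon_length_range[2L],
                       n_ex, replace = TRUE)
      in_len <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L],
                       max(n_ex - 1L, 0L), replace = TRUE)
      start <- cursor[[ch]] + 200L
      starts <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
      exons <- cbind(start = starts, end = starts + ex_len)
      gid <- sprintf("G%03d", gi)
      coding <- stats::runif(1) > cfg$noncoding_fraction
      cds <- if (coding && n_ex >= 3L)
        c(exons[2L, "start"], exons[n_ex - 1L, "end"]) else NULL
      txs <- list(transcript(paste0(gid, ".t1"), exons, tsl = 1L, cds = cds))
      if (gi %% 3L == 0L && n_ex >= 3L) {
        skip <- sample(2:(n_ex - 1L), 1L)
        txs <- c(txs, list(transcript(paste0(gid, ".t2"),
                                      exons[-skip, , drop = FALSE],
                                      tsl = 2L)))
      }
      genes[[gid]] <- gene(gid, ch, strand, txs,
                           biotype = if (coding) "coding" else "noncoding")
      gene_len <- exons[n_ex, "end"] - cursor[[ch]]
      chrom_seqs[[ch]] <- paste0(chrom_seqs[[ch]], random_dna(gene_len))
      cursor[[ch]] <- exons[n_ex, "end"]
      gene_meta[[gid]] <- list(chrom = ch, strand = strand, exons = exons)
    }
    chrom_seqs <- vapply(names(chrom_seqs), function(ch)
      paste0(chrom_seqs[[ch]], random_dna(300L)), "")
    # plant motifs: half exonic, half intronic positions, motif centred on
    # the recorded crosslink site, >= 40 nt from region edges
    k <- nchar(motif_dna)
    half <- k %/% 2L
    planted <- list()
    gids <- sample(names(genes), cfg$n_planted_sites, replace = TRUE)
    used <- character(0)
    for (i in seq_len(cfg$n_planted_sites)) {
      gm <- gene_meta[[gids[i]]]
      exonic <- i %% 2L == 0L
      for (try in 1:50) {
        if (exonic) {
          ei <- sample(nrow(gm$exons), 1L)
          lo <- gm$exons[ei, "start"] + 40L; hi <- gm$exons[ei, "end"] - 40L
        } else {
          if (nrow(gm$exons) < 2L) { lo <- 1L; hi <- 0L }
          else {
            ii <- sample(nrow(gm$exons) - 1L, 1L)
            lo <- gm$exons[ii, "end"] + 40L
            hi <- gm$exons[ii + 1L, "start"] - 40L
          }
        }
        if (hi <= lo) next
        pos <- sample(lo:hi, 1L)
        key <- paste(gm$chrom, pos)
        if (any(abs(as.integer(sub(".* ", "", used[startsWith(used, gm$chrom)])) -
                      pos) < 50L)) next
        used <- c(used, key)
        # the motif sits inside the evaluated (+5,+30) window, at
        # transcript-orientation offsets +6..+(5+k), not on the crosslink
        # nucleotide itself
        if (gm$strand == "+") {
          # 0-based genomic [pos+6, pos+6+k)
          substr(chrom_seqs[[gm$chrom]], pos + 7L, pos + 6L + k) <- motif_dna
        } else {
          # 0-based genomic [pos-6-k+1, pos-6+1), reverse-complemented
          substr(chrom_seqs[[gm$chrom]], pos - 4L - k, pos - 5L) <-
            revcomp(motif_dna)
        }
        planted[[length(planted) + 1L]] <- data.frame(
          chrom = gm$chrom, strand = gm$strand, pos = pos,
          gene_id = gids[i], context = if (exonic) "exon" else "intron",
          stringsAsFactors = FALSE)
        break
      }
    }
    planted_sites <- do.call(rbind, planted)
    annotation <- genome_annotation(chrom_seqs, genes)
    # detained-intron truth over the TSL-1 flat introns
    feats <- suppressWarnings(flatten_features(annotation, tsl_max = 1L))
    introns <- feats[feats$kind == "intron", , drop = FALSE]
    di_flag <- stats::runif(nrow(introns)) < cfg$di_fraction
    detained <- introns[di_flag, c("feature_id", "gene_id", "chrom",
                                   "start", "end", "strand")]
    rownames(detained) <- NULL
    list(annotation = annotation,
         truth = list(planted_sites = planted_sites,
                      motif = toupper(dna_to_rna(cfg$motif)),
                      detained_introns = detained))
  })
}

#' Simulate iCLIP signal and control crosslink libraries
#'
#' Crosslink events are Poisson per nucleotide over the co-transcribed
#' regions: background rate everywhere, multiplied by
#' `signal_to_background` at the planted sites in the signal library.
#' The control library is background-only (no excess at planted sites).
#'
#' @param genome output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return list with `signal` and `control` [crosslink_table()]s.
#' @export
simulate_iclip <- function(genome, config) {
  cfg <- config
  if (cfg$signal_to_background < 1) stop("signal_to_background must be >= 1")
  truth <- genome$truth
  regions <- cotranscribed_regions(genome$annotation)
  with_seed(substream_seed(cfg$seed, "iclip"), {
    draw <- function(with_signal) {
      out <- list()
      for (i in seq_len(nrow(regions))) {
        rg <- regions[i, ]
        L <- rg$end - rg$start
        lambda <- rep(cfg$background_rate, L)
        if (with_signal && nrow(truth$planted_sites) > 0L) {
          ps <- truth$planted_sites
          here <- ps$chrom == rg$chrom & ps$strand == rg$strand &
            ps$pos >= rg$start & ps$pos < rg$end
          lambda[ps$pos[here] - rg$start + 1L] <-
            cfg$background_rate * cfg$signal_to_background
        }
        cnt <- stats::rpois(L, lambda)
        nz <- which(cnt > 0L)
        if (length(nz) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = rg$chrom, strand = rg$strand,
          pos = rg$start + nz - 1L, count = cnt[nz],
          stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, out)
      df <- df[order(df$chrom, df$strand, df$pos), ]
      rownames(df) <- NULL
      crosslink_table(df)
    }
    signal <- draw(with_signal = TRUE)
    control <- draw(with_signal = FALSE)
    list(signal = signal, control = control)
  })
}

#' Simulate the splicing / feature-usage time course
#'
#' Alternative-splicing events get true PSI trajectories (constant,
#' rising or falling) and per-sample inclusion/exclusion counts drawn
#' binomially at Poisson depths.  Flat features get Poisson counts whose
#' means follow planted trajectory shapes scaled to a baseline; a
#' configurable fraction of regulated features is flagged SARF with a
#' higher probability inside the `n_clusters_planted` enriched shapes.
#' Detained introns (from the genome truth) get a rising retention shape.
#'
#' @param genome output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return list with `events` (wide table with `inc_<tp>_r<j>` /
#'   `exc_<tp>_r<j>` columns), `features` (flat-feature counts with
#'   `<tp>_r<j>` columns) and `truth` (per-event true PSI matrix,
#'   per-feature shape/cluster id and SARF flag).
#' @export
simulate_timecourse <- function(genome, config) {
  cfg <- config
  if (length(cfg$timepoints) < 2L) stop("need >= 2 timepoints")
  ann <- genome$annotation
  shapes <- default_cluster_shapes(cfg)
  T <- length(cfg$timepoints)
  stopifnot(ncol(shapes) == T)
  feats <- suppressWarnings(flatten_features(ann, tsl_max = 1L))
  with_seed(substream_seed(cfg$seed, "timecourse"), {
    ## -- events ------------------------------------------------------
    types <- sample(c("SE", "IR", "MXE", "A5SS", "A3SS"), cfg$n_events,
                    replace = TRUE, prob = c(0.40, 0.20, 0.13, 0.13, 0.14))
    gids <- sample(names(ann$genes), cfg$n_events, replace = TRUE)
    ev <- vector("list", cfg$n_events)
    true_psi <- matrix(NA_real_, nrow = cfg$n_events, ncol = T,
                       dimnames = list(NULL, cfg$timepoints))
    for (i in seq_len(cfg$n_events)) {
      g <- ann$genes[[gids[i]]]
      ex <- g$transcripts[[1L]]$exons
      n_ex <- nrow(ex)
      coord <- if (types[i] == "IR" && n_ex >= 2L) {
        ii <- sample(n_ex - 1L, 1L)
        c(ex[ii, "end"], ex[ii + 1L, "start"])
      } else {
        ei <- if (n_ex >= 3L) sample(2:(n_ex - 1L), 1L) else 1L
        ex[ei, c("start", "end")]
      }
      pattern <- sample(c("constant", "rising", "falling"), 1L,
                        prob = c(0.6, 0.2, 0.2))
      psi <- switch(pattern,
                    constant = rep(stats::runif(1, 0.3, 0.7), T),
                    rising = seq(0.2, 0.8, length.out = T),
                    falling = seq(0.8, 0.2, length.out = T))
      true_psi[i, ] <- psi
      row <- data.frame(event_id = sprintf("EV%04d", i), type = types[i],
                        gene_id = gids[i], chrom = g$chrom,
                        strand = g$strand, coord_start = coord[1L],
                        coord_end = coord[2L], stringsAsFactors = FALSE)
      for (t in seq_len(T)) for (r in seq_len(cfg$n_replicates)) {
        depth <- stats::rpois(1L, cfg$event_depth)
        inc <- stats::rbinom(1L, depth, psi[t])
        row[[sprintf("inc_%s_r%d", cfg$timepoints[t], r)]] <- inc
        row[[sprintf("exc_%s_r%d", cfg$timepoints[t], r)]] <- depth - inc
      }
      ev[[i]] <- row
    }
    events <- do.call(rbind, ev)
    ## -- flat features -----------------------------------------------
    n_f <- nrow(feats)
    shape_id <- integer(n_f) # 0 = flat / unregulated
    reg <- stats::runif(n_f) < cfg$regulated_fraction
    shape_id[reg] <- sample(nrow(shapes), sum(reg), replace = TRUE)
    # detained introns follow the first enriched (rising) shape
    di_ids <- genome$truth$detained_introns$feature_id
    shape_id[feats$feature_id %in% di_ids & reg] <- 1L
    sarf <- logical(n_f)
    enriched <- shape_id >= 1L & shape_id <= cfg$n_clusters_planted
    sarf[enriched] <- stats::runif(sum(enriched)) < cfg$sarf_prob_enriched
    other_reg <- reg & !enriched
    sarf[other_reg] <- stats::runif(sum(other_reg)) < cfg$sarf_prob_background
    counts <- feats
    for (t in seq_len(T)) {
      offs <- ifelse(shape_id > 0L, shapes[pmax(shape_id, 1L), t], 0)
      mu <- cfg$baseline_count * 2^offs
      for (r in seq_len(cfg$n_replicates))
        counts[[sprintf("%s_r%d", cfg$timepoints[t], r)]] <-
          stats::rpois(n_f, mu)
    }
    truth <- list(
      true_psi = cbind(data.frame(event_id = events$event_id,
                                  type = events$type,
                                  stringsAsFactors = FALSE), true_psi),
      feature_truth = data.frame(feature_id = feats$feature_id,
                                 gene_id = feats$gene_id, kind = feats$kind,
                                 shape_id = shape_id,
                                 regulated = shape_id > 0L,
                                 sarf = sarf, stringsAsFactors = FALSE),
      shapes = shapes)
    list(events = events, features = counts, truth = truth)
  })
}

#' Simulate a differential-expression table with known labels
#'
#' A planted fraction of genes gets `|log2FC| = deg_lfc` (random sign)
#' and small FDR; the rest get near-zero fold changes and non-significant
#' FDRs.  The `bound` flag marks genes carrying a planted crosslink site;
#' NMD gene/mRNA flags are planted with higher probability among bound
#' DEGs.
#'
#' @param genome output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return list with `deg` (data.frame: gene_id, log2fc, fdr, bound,
#'   nmd_gene, nmd_mrna) and `truth` (logical `is_deg` per gene).
#' @export
simulate_deg_table <- function(genome, config) {
  cfg <- config
  gids <- names(genome$annotation$genes)
  bound_genes <- unique(genome$truth$planted_sites$gene_id)
  with_seed(substream_seed(cfg$seed, "deg"), {
    n <- length(gids)
    is_deg <- stats::runif(n) < cfg$deg_fraction
    sign <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.4, 0.6))
    log2fc <- ifelse(is_deg,
                     sign * (cfg$deg_lfc + stats::rnorm(n, 0, 0.3)),
                     stats::rnorm(n, 0, 0.2))
    fdr <- ifelse(is_deg, stats::runif(n, 0, 0.04), stats::runif(n, 0.1, 1))
    bound <- gids %in% bound_genes
    nmd_gene <- stats::runif(n) < ifelse(bound & is_deg, 0.3, 0.1)
    nmd_mrna <- stats::runif(n) < ifelse(bound & is_deg, 0.2, 0.05)
    deg <- data.frame(gene_id = gids, log2fc = log2fc, fdr = fdr,
                      bound = bound, nmd_gene = nmd_gene,
                      nmd_mrna = nmd_mrna, stringsAsFactors = FALSE)
    list(deg = deg, truth = data.frame(gene_id = gids, is_deg = is_deg,
                                       stringsAsFactors = FALSE))
  })
}
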