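# End-to-end orchestration (simulate -> callsites -> kmers -> psi ->
# usage -> integrate) plus a thin command-line front end.

#' Write a full synthetic data set to a directory
#'
#' Produces `genome.fa`, `annotation.gtf`, `signal.bed`, `control.bed`,
#' `events.tsv`, `features.tsv`, `deg.tsv` and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  clip <- simulate_iclip(genome, config)
  tc <- simulate_timecourse(genome, config)
  degres <- simulate_deg_table(genome, config)
  write_genome_fasta(genome$annotation$chromosomes,
                     file.path(outdir, "genome.fa"))
  write_annotation_gtf(genome$annotation,
                       file.path(outdir, "annotation.gtf"))
  write_sites_bed(clip$signal, file.path(outdir, "signal.bed"))
  write_sites_bed(clip$control, file.path(outdir, "control.bed"))
  write_tsv(tc$events, file.path(outdir, "events.tsv"))
  write_tsv(tc$features, file.path(outdir, "features.tsv"))
  write_tsv(degres$deg, file.path(outdir, "deg.tsv"))
  truth <- list(planted_sites = genome$truth$planted_sites,
                motif = genome$truth$motif,
                detained_introns = genome$truth$detained_introns,
                feature_truth = tc$truth$feature_truth,
                true_psi = tc$truth$true_psi,
                deg_truth = degres$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(list(genome = genome, clip = clip, timecourse = tc,
                 deg = degres))
}

#' Run the full analysis pipeline on a synthetic data set
#'
#' Generates data under `config`, calls significant crosslink sites,
#' filters them against the control library, computes k-mer z-scores and
#' a consensus motif, compares splicing events between the last and first
#' time points, runs cumulative and sequential usage contrasts, and runs
#' the integrative layer (SARFs, trajectory clustering, detained-intron
#' and DEG overlap statistics).  Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, all intermediate tables
#'   are written there (byte-reproducible for a fixed seed).
#' @param n_rand randomisations for site calling.
#' @param n_shuffles shuffles for k-mer z-scores.
#' @param k_clusters clusters for trajectory k-means (capped at the
#'   number of kept trajectories).
#' @return list with all stage outputs.
#' @export
run_pipeline <- function(config, outdir = NULL, n_rand = 100L,
                         n_shuffles = 20L, k_clusters = 6L) {
  # generate once, reusing objects for every stage
  genome <- generate_genome(config)
  clip <- simulate_iclip(genome, config)
  tc <- simulate_timecourse(genome, config)
  degres <- simulate_deg_table(genome, config)
  regions <- cotranscribed_regions(genome$annotation)

  sites <- call_significant_sites(clip$signal, regions, n_rand = n_rand,
                                  alpha = 0.05, seed = config$seed)
  sites_f <- filter_vs_control(sites, clip$control, min_count = 2L)
  kz <- kmer_zscores(genome$annotation, sites_f, regions,
                     k = nchar(config$motif), n_shuffles = n_shuffles,
                     seed = config$seed)
  top15 <- utils::head(kz$kmer[!kz$degenerate], 15L)
  consensus <- consensus_from_top_kmers(
    top15, weights = utils::head(kz$observed[!kz$degenerate], 15L))

  tps <- config$timepoints
  reps <- paste0("r", seq_len(config$n_replicates))
  samples_a <- paste0(tps[length(tps)], "_", reps)
  samples_b <- paste0(tps[1L], "_", reps)
  psi_res <- compare_events(tc$events, samples_a, samples_b)

  usage_cum <- run_contrasts(tc$features, tps, mode = "cumulative")
  usage_seq <- run_contrasts(tc$features, tps, mode = "sequential")
  traj <- feature_trajectories(tc$features, tps, mode = "cumulative")

  # regulated set: features regulated in any cumulative contrast
  reg_ids <- unique(unlist(lapply(usage_cum$results, function(r)
    r$feature_id[r$status == "regulated"])))
  feats <- tc$features[, c("feature_id", "gene_id", "kind", "chrom",
                           "start", "end", "strand")]
  regulated <- feats[feats$feature_id %in% reg_ids, , drop = FALSE]
  sarfs <- call_sarfs(regulated, sites_f, window_nt = 200L)

  tf <- trajectory_filter(traj[rownames(traj) %in% reg_ids, , drop = FALSE])
  k_use <- min(k_clusters, nrow(tf$kept))
  clust <- if (k_use >= 2L && nrow(tf$kept) >= k_use)
    cluster_trajectories(tf$kept, k = k_use, seed = config$seed) else NULL
  sarf_summary <- NULL
  if (!is.null(clust)) {
    sarf_flag <- names(clust$cluster) %in%
      sarfs$feature_id[sarfs$sarf]
    if (any(sarf_flag))
      sarf_summary <- sarf_cluster_summary(clust$cluster, sarf_flag,
                                           top_n = 3L)
  }
  # feature status from the final cumulative contrast for DI fractions
  final_res <- usage_cum$results[[length(usage_cum$results)]]
  feat_status <- feats
  feat_status$status <- final_res$status[match(feat_status$feature_id,
                                               final_res$feature_id)]
  feat_status$sarf <- feat_status$feature_id %in%
    sarfs$feature_id[sarfs$sarf]
  di <- genome$truth$detained_introns
  di_frac <- di_binding_fractions(feat_status, di, sites_f)
  deg_stats <- deg_overlap_stats(degres$deg)

  out <- list(config = config, sites = sites, sites_filtered = sites_f,
              kmer_z = kz, consensus = consensus, psi = psi_res,
              usage_cumulative = usage_cum, usage_sequential = usage_seq,
              trajectories = traj, trajectory_filter = tf,
              clusters = clust, sarfs = sarfs,
              sarf_summary = sarf_summary, di_fractions = di_frac,
              deg_stats = deg_stats, truth = list(
                genome = genome$truth, timecourse = tc$truth,
                deg = degres$truth))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_sites_bed(sites_f, file.path(outdir, "sites.bed"))
    write_tsv(data.frame(chrom = sites$chrom, strand = sites$strand,
                         pos = sites$pos, count = sites$count,
                         fdr = sites$fdr),
              file.path(outdir, "sites_fdr.tsv"))
    write_tsv(kz, file.path(outdir, "kmers.tsv"))
    write_meme_minimal(consensus$pwm, file.path(outdir, "consensus.meme"))
    write_tsv(psi_res, file.path(outdir, "psi.tsv"))
    write_tsv(usage_cum$summary, file.path(outdir, "usage_cumulative.tsv"))
    write_tsv(usage_seq$summary, file.path(outdir, "usage_sequential.tsv"))
    write_tsv(sarfs, file.path(outdir, "sarf.tsv"))
    if (!is.null(clust))
      write_tsv(data.frame(feature_id = names(clust$cluster),
                           cluster = unname(clust$cluster)),
                file.path(outdir, "clusters.tsv"))
    jsonlite::write_json(
      list(sarf_summary = sarf_summary, di_fractions = di_frac,
           deg_stats = deg_stats),
      file.path(outdir, "fractions.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

# --- minimal CLI ----------------------------------------------------

parse_cli_args <- function(argv) {
  args <- list()
  i <- 1L
  while (i <= length(argv)) {
    if (startsWith(argv[i], "--")) {
      key <- sub("^--", "", argv[i])
      args[[key]] <- if (i < length(argv) && !startsWith(argv[i + 1L], "--"))
        { i <- i + 1L; argv[i] } else TRUE
    }
    i <- i + 1L
  }
  args
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --outdir DIR`,
#' `callsites --xlinks BED --genome FA --annotation GTF --nrand N
#' --alpha A --seed S --out BED`,
#' `kmers --sites BED --genome FA --annotation GTF --k K --shuffles N
#' --seed S --out TSV`,
#' `psi --events TSV --a SAMPLES --b SAMPLES --out TSV`,
#' `usage --features TSV --timepoints T1,T2,... --mode M --out TSV`,
#' `pipeline --seed S --outdir DIR`.
#' Invoke via `Rscript -e 'splicelink::splicelink_cli()' <cmd> ...`.
#'
#' @param argv character vector of arguments (defaults to the command
#'   line).
#' @return invisibly, the subcommand's result.
#' @export
splicelink_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L)
    stop("usage: splicelink <simulate|callsites|kmers|psi|usage|pipeline> ...")
  cmd <- argv[1L]
  args <- parse_cli_args(argv[-1L])
  seed <- as.integer(args$seed %||% 1L)
  res <- switch(
    cmd,
    simulate = simulate_dataset(sim_config(seed = seed),
                                args$outdir %||% "."),
    callsites = {
      xl <- read_sites_bed(args$xlinks)
      ann <- read_annotation_gtf(args$annotation, args$genome)
      sites <- call_significant_sites(
        xl, cotranscribed_regions(ann),
        n_rand = as.integer(args$nrand %||% 100L),
        alpha = as.numeric(args$alpha %||% 0.05), seed = seed)
      write_sites_bed(sites, args$out %||% "sites.bed")
      sites
    },
    kmers = {
      sites <- read_sites_bed(args$sites)
      ann <- read_annotation_gtf(args$annotation, args$genome)
      kz <- kmer_zscores(ann, sites, cotranscribed_regions(ann),
                         k = as.integer(args$k %||% 5L),
                         n_shuffles = as.integer(args$shuffles %||% 100L),
                         seed = seed)
      write_tsv(kz, args$out %||% "kmers.tsv")
      kz
    },
    psi = {
      ev <- read_tsv(args$events)
      res <- compare_events(ev, strsplit(args$a, ",")[[1L]],
                            strsplit(args$b, ",")[[1L]])
      write_tsv(res, args$out %||% "psi.tsv")
      res
    },
    usage = {
      counts <- read_tsv(args$features)
      tps <- strsplit(args$timepoints, ",")[[1L]]
      out <- run_contrasts(counts, tps, mode = args$mode %||% "cumulative")
      write_tsv(out$summary, args$out %||% "usage_summary.tsv")
      out
    },
    pipeline = run_pipeline(sim_config(seed = seed),
                            outdir = args$outdir %||% "."),
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
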