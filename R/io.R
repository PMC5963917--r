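# Readers and writers for the standard interchange formats.  Internal
# coordinates are 0-based half-open; BED is written/read natively in that
# convention, GTF is converted from/to 1-based closed.

#' Read chromosome sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write chromosome sequences to a FASTA file
#'
#' @param chromosomes named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(chromosomes, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(chartr("Uu", "Tt", chromosomes)), path)
  invisible(path)
}

#' Write an annotation as ensembl-dialect GTF
#'
#' Emits gene, transcript, exon and (where present) CDS lines with
#' `gene_id`, `transcript_id`, `transcript_support_level` and
#' `gene_biotype` attributes.  Coordinates are converted to the 1-based
#' closed GTF convention.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, start0, end0, strand, attrs) {
    sprintf("%s\tsplicelink\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start0 + 1L, end0, strand, attrs)
  }
  for (g in annotation$genes) {
    sp <- gene_span(g)
    ga <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id,
                  if (g$biotype == "coding") "protein_coding" else "lncRNA")
    lines <- c(lines, fmt(g$chrom, "gene", sp[1L], sp[2L], g$strand, ga))
    for (tx in g$transcripts) {
      tsp <- tx_span(tx)
      ta <- sprintf('%s transcript_id "%s"; transcript_support_level "%d";',
                    ga, tx$tx_id, tx$tsl)
      lines <- c(lines, fmt(g$chrom, "transcript", tsp[1L], tsp[2L],
                            g$strand, ta))
      for (i in seq_len(nrow(tx$exons)))
        lines <- c(lines, fmt(g$chrom, "exon", tx$exons[i, "start"],
                              tx$exons[i, "end"], g$strand, ta))
      if (!is.null(tx$cds))
        lines <- c(lines, fmt(g$chrom, "CDS", tx$cds[1L], tx$cds[2L],
                              g$strand, ta))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
  ifelse(lengths(regmatches(attrs, gregexpr(sprintf('%s "[^"]*"', key),
                                            attrs))) > 0,
         sub(sprintf('%s "([^"]*)"', key), "\\1", m), NA_character_)
}

#' Read an annotation from an ensembl-dialect GTF file
#'
#' Parses exon and CDS records; recognises the `gene_id`,
#' `transcript_id`, `transcript_support_level` and `gene_biotype`
#' attributes.  Chromosome sequences come from `fasta`.
#'
#' @param path GTF file.
#' @param fasta FASTA file of chromosome sequences.
#' @return a [genome_annotation()].
#' @export
read_annotation_gtf <- function(path, fasta) {
  chromosomes <- read_genome_fasta(fasta)
  raw <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                           col.names = c("chrom", "source", "feature",
                                         "start", "end", "score", "strand",
                                         "frame", "attrs"),
                           stringsAsFactors = FALSE)
  raw <- raw[raw$feature %in% c("exon", "CDS"), , drop = FALSE]
  raw$gene_id <- vapply(raw$attrs, gtf_attr, "", key = "gene_id")
  raw$tx_id <- vapply(raw$attrs, gtf_attr, "", key = "transcript_id")
  raw$tsl <- suppressWarnings(as.integer(
    vapply(raw$attrs, gtf_attr, "", key = "transcript_support_level")))
  raw$tsl[is.na(raw$tsl)] <- 1L
  raw$biotype <- vapply(raw$attrs, gtf_attr, "", key = "gene_biotype")
  genes <- list()
  for (gid in unique(raw$gene_id)) {
    gr <- raw[raw$gene_id == gid, , drop = FALSE]
    txs <- lapply(unique(gr$tx_id), function(tid) {
      tr <- gr[gr$tx_id == tid, , drop = FALSE]
      ex <- tr[tr$feature == "exon", , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds_rows <- tr[tr$feature == "CDS", , drop = FALSE]
      cds <- if (nrow(cds_rows) > 0L)
        c(min(cds_rows$start) - 1L, max(cds_rows$end)) else NULL
      transcript(tid, cbind(start = ex$start - 1L, end = ex$end),
                 tsl = tr$tsl[1L], cds = cds)
    })
    bt <- gr$biotype[1L]
    genes[[gid]] <- gene(gid, gr$chrom[1L], gr$strand[1L], txs,
                         biotype = if (!is.na(bt) && bt != "protein_coding")
                           "noncoding" else "coding")
  }
  genome_annotation(chromosomes, genes)
}

#' Read an annotation from a BED12 file
#'
#' Each BED12 record becomes a single-transcript gene (gene_id =
#' transcript_id = the record name); block starts/sizes give the exons and
#' the thick interval, when non-empty, the CDS.
#'
#' @param path BED12 file.
#' @param fasta FASTA file of chromosome sequences.
#' @return a [genome_annotation()].
#' @export
read_annotation_bed12 <- function(path, fasta) {
  chromosomes <- read_genome_fasta(fasta)
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) stop("BED12 requires 12 columns")
  names(raw)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                        "thick_start", "thick_end", "rgb", "n_blocks",
                        "block_sizes", "block_starts")
  genes <- list()
  for (i in seq_len(nrow(raw))) {
    sizes <- as.integer(strsplit(raw$block_sizes[i], ",")[[1L]])
    starts <- as.integer(strsplit(raw$block_starts[i], ",")[[1L]])
    ex <- cbind(start = raw$start[i] + starts,
                end = raw$start[i] + starts + sizes)
    cds <- if (raw$thick_end[i] > raw$thick_start[i])
      c(raw$thick_start[i], raw$thick_end[i]) else NULL
    tx <- transcript(raw$name[i], ex, tsl = 1L, cds = cds)
    genes[[raw$name[i]]] <- gene(raw$name[i], raw$chrom[i], raw$strand[i],
                                 list(tx),
                                 biotype = if (is.null(cds)) "noncoding"
                                 else "coding")
  }
  genome_annotation(chromosomes, genes)
}

#' Write crosslinks or binding sites as BED6
#'
#' One single-nucleotide interval per entry; score = crosslink count.
#'
#' @param x data.frame with `chrom`, `strand`, `pos`, `count`.
#' @param path output file.
#' @param names optional feature names (default `site_<i>`).
#' @export
write_sites_bed <- function(x, path, names = NULL) {
  if (is.null(names)) names <- sprintf("site_%d", seq_len(nrow(x)))
  df <- data.frame(x$chrom, x$pos, x$pos + 1L, names, x$count, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read crosslinks or binding sites from BED6
#'
#' @param path BED6 file (0-based half-open; score column = count).
#' @return a [crosslink_table()].
#' @export
read_sites_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  df <- data.frame(chrom = raw[[1L]], strand = raw[[6L]], pos = raw[[2L]],
                   count = raw[[5L]], stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$strand, df$pos), ]
  rownames(df) <- NULL
  crosslink_table(df)
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a position-weight matrix in MEME minimal format
#'
#' @param pwm 4 x width matrix with rows A/C/G/U (see
#'   [consensus_from_top_kmers()]).
#' @param path output file.
#' @param name motif name.
#' @export
write_meme_minimal <- function(pwm, path, name = "motif1") {
  lines <- c("MEME version 4", "", "ALPHABET= ACGU", "",
             sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d",
                     ncol(pwm)))
  for (j in seq_len(ncol(pwm)))
    lines <- c(lines, paste(sprintf("%.6f", pwm[, j]), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
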