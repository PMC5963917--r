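# Genome data model: toy or real annotations, flat feature derivation,
# co-transcribed regions, window arithmetic and region-class densities.
#
# All coordinates are 0-based, half-open, on the forward genomic axis.
# Minus-strand logic is always done in transcript orientation and mapped
# back; nothing here is strand-naive.

ir_from0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
ir_to0 <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Construct a transcript model
#'
#' @param tx_id transcript identifier.
#' @param exons two-column matrix (or data.frame) of 0-based half-open
#'   exon intervals, sorted and non-overlapping.
#' @param tsl transcript support level (1 = most stringent).
#' @param cds optional length-2 vector, the 0-based half-open CDS span.
#' @return an object of class `Transcript`.
#' @export
transcript <- function(tx_id, exons, tsl = 1L, cds = NULL) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript needs >= 1 exon")
  if (any(exons[, "end"] <= exons[, "start"])) stop("empty exon interval")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE) ||
        any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
      stop("exons must be sorted and non-overlapping")
  }
  if (!is.null(cds)) {
    stopifnot(length(cds) == 2L, cds[2L] > cds[1L])
    cds <- as.integer(cds)
  }
  structure(list(tx_id = as.character(tx_id), exons = exons,
                 tsl = as.integer(tsl), cds = cds),
            class = "Transcript")
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of [transcript()] objects (>= 1).
#' @param biotype `"coding"` or `"noncoding"`.
#' @return an object of class `Gene`.
#' @export
gene <- function(gene_id, chrom, strand, transcripts,
                 biotype = c("coding", "noncoding")) {
  biotype <- match.arg(biotype)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(transcripts) < 1L) stop("gene needs >= 1 transcript")
  stopifnot(all(vapply(transcripts, inherits, TRUE, "Transcript")))
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, transcripts = transcripts, biotype = biotype),
            class = "Gene")
}

#' Construct a genome annotation
#'
#' Bundles chromosome sequences with gene models and validates the basic
#' invariants (unique chromosome names, genes within chromosome bounds,
#' non-empty sequences).
#'
#' @param chromosomes named character vector of nucleotide sequences
#'   (DNA or RNA alphabet).
#' @param genes list of [gene()] objects.
#' @return an object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(chromosomes, genes) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosome names must be present and unique")
  if (any(nchar(chromosomes) == 0L)) stop("empty chromosome sequence")
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(names(genes))) stop("duplicate gene_id")
  for (g in genes) {
    if (!g$chrom %in% names(chromosomes))
      stop(sprintf("gene %s on unknown chromosome %s", g$gene_id, g$chrom))
    sp <- gene_span(g)
    if (sp[1L] < 0L || sp[2L] > nchar(chromosomes[[g$chrom]]))
      stop(sprintf("gene %s outside chromosome bounds", g$gene_id))
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d chromosome(s) (%s nt), %d gene(s)\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              length(x$genes)))
  invisible(x)
}

tx_span <- function(tx) c(tx$exons[1L, "start"], tx$exons[nrow(tx$exons), "end"])

gene_span <- function(g) {
  sp <- vapply(g$transcripts, tx_span, integer(2))
  c(min(sp[1L, ]), max(sp[2L, ]))
}

# Introns of one transcript as a 0-based half-open matrix (0 rows if single
# exon).
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exons[-n, "end"], end = tx$exons[-1L, "start"])
}

#' Flatten transcript models into disjoint exonic parts, junctions and introns
#'
#' Per gene, the union of exons of all retained transcripts (those with
#' `tsl <= tsl_max`) is partitioned at every distinct exon boundary into
#' disjoint exonic parts; each distinct intron yields one junction feature
#' (anchored at its two splice-site coordinates) and one intron feature.
#' Genes whose retained-transcript set is empty are skipped with a warning.
#'
#' @param annotation a [genome_annotation()] object.
#' @param tsl_max maximum transcript support level to retain (>= 1).
#' @return data.frame with columns `feature_id`, `gene_id`, `kind`
#'   (`"exonic_part"`, `"junction"`, `"intron"`), `chrom`, `start`, `end`,
#'   `strand`.
#' @export
flatten_features <- function(annotation, tsl_max = 1L) {
  stopifnot(inherits(annotation, "GenomeAnnotation"), tsl_max >= 1L)
  out <- list()
  for (g in annotation$genes) {
    keep <- Filter(function(tx) tx$tsl <= tsl_max, g$transcripts)
    if (length(keep) == 0L) {
      warning(sprintf("gene %s: no transcript with tsl <= %d; skipped",
                      g$gene_id, tsl_max))
      next
    }
    ex <- do.call(rbind, lapply(keep, `[[`, "exons"))
    parts <- IRanges::disjoin(ir_from0(ex[, "start"], ex[, "end"]))
    p0 <- ir_to0(parts)
    introns <- unique(do.call(rbind, lapply(keep, tx_introns)))
    rows <- data.frame(
      feature_id = sprintf("%s:E%03d", g$gene_id, seq_len(nrow(p0))),
      gene_id = g$gene_id, kind = "exonic_part",
      chrom = g$chrom, start = p0$start, end = p0$end, strand = g$strand,
      stringsAsFactors = FALSE)
    if (!is.null(introns) && nrow(introns) > 0L) {
      introns <- introns[order(introns[, "start"], introns[, "end"]), ,
                         drop = FALSE]
      jr <- data.frame(
        feature_id = sprintf("%s:J%03d", g$gene_id, seq_len(nrow(introns))),
        gene_id = g$gene_id, kind = "junction",
        chrom = g$chrom, start = introns[, "start"], end = introns[, "end"],
        strand = g$strand, stringsAsFactors = FALSE)
      ir <- jr
      ir$feature_id <- sprintf("%s:I%03d", g$gene_id, seq_len(nrow(introns)))
      ir$kind <- "intron"
      rows <- rbind(rows, jr, ir)
    }
    out[[g$gene_id]] <- rows
  }
  if (length(out) == 0L)
    return(data.frame(feature_id = character(0), gene_id = character(0),
                      kind = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Co-transcribed region of a gene
#'
#' The union of all transcript spans (first exon start to last exon end per
#' transcript), merged into maximal intervals.  This is the randomisation
#' universe for crosslink-site significance and k-mer shuffling.
#'
#' @param g a [gene()] object.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
cotranscribed_region <- function(g) {
  stopifnot(inherits(g, "Gene"))
  sp <- t(vapply(g$transcripts, tx_span, integer(2)))
  merged <- ir_to0(IRanges::reduce(ir_from0(sp[, 1L], sp[, 2L])))
  data.frame(chrom = g$chrom, start = merged$start, end = merged$end,
             strand = g$strand, gene_id = g$gene_id, stringsAsFactors = FALSE)
}

#' Co-transcribed regions for all genes in an annotation
#'
#' Strands are treated independently: overlapping genes on opposite strands
#' keep separate regions.
#'
#' @param annotation a [genome_annotation()] object.
#' @return data.frame with one row per merged interval, columns `chrom`,
#'   `start`, `end`, `strand`, `gene_id`.
#' @export
cotranscribed_regions <- function(annotation) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  res <- do.call(rbind, lapply(annotation$genes, cotranscribed_region))
  rownames(res) <- NULL
  res
}

#' Map transcript-orientation offset windows around a site to genomic intervals
#'
#' Offsets are closed integer intervals in transcript orientation (negative =
#' 5' of the site); on the minus strand they are mirrored onto the genome.
#' Windows are clipped to `bounds`; a site outside `bounds` yields no windows.
#'
#' @param site_position 0-based genomic position of the site.
#' @param offsets list of length-2 closed offset intervals, e.g.
#'   `list(c(-30, -5), c(5, 30))`.
#' @param strand `"+"` or `"-"`.
#' @param bounds length-2 vector, 0-based half-open clipping interval.
#' @return data.frame with columns `start`, `end` (0-based half-open), one
#'   row per non-empty window, ordered as the input offsets.
#' @export
transcript_window <- function(site_position,
                              offsets = list(c(-30L, -5L), c(5L, 30L)),
                              strand = "+", bounds) {
  stopifnot(strand %in% c("+", "-"), length(bounds) == 2L)
  if (is.numeric(offsets) && length(offsets) == 2L) offsets <- list(offsets)
  if (site_position < bounds[1L] || site_position >= bounds[2L])
    return(data.frame(start = integer(0), end = integer(0)))
  res <- lapply(offsets, function(o) {
    stopifnot(length(o) == 2L, o[1L] <= o[2L])
    if (strand == "+") {
      s <- site_position + o[1L]; e <- site_position + o[2L] + 1L
    } else {
      s <- site_position - o[2L]; e <- site_position - o[1L] + 1L
    }
    s <- max(s, bounds[1L]); e <- min(e, bounds[2L])
    if (e <= s) NULL else data.frame(start = as.integer(s), end = as.integer(e))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0)) else out
}

REGION_CLASSES <- c("CDS", "5'UTR", "3'UTR", "ncRNA_exon", "intron",
                    "intergenic")

# Per-(chrom, strand) class intervals with the documented precedence
# (CDS > 5'UTR > 3'UTR > ncRNA exon > intron > intergenic) already applied:
# a position appears under exactly one class.
region_class_intervals <- function(annotation) {
  pools <- list()  # key: class|chrom|strand -> list of IRanges
  add <- function(cls, chrom, strand, ir) {
    key <- paste(cls, chrom, strand, sep = "|")
    pools[[key]] <<- c(pools[[key]], list(ir))
  }
  for (g in annotation$genes) {
    for (tx in g$transcripts) {
      ex <- ir_from0(tx$exons[, "start"], tx$exons[, "end"])
      if (!is.null(tx$cds)) {
        cds_ir <- ir_from0(tx$cds[1L], tx$cds[2L])
        add("CDS", g$chrom, g$strand, IRanges::intersect(ex, cds_ir))
        sp <- tx_span(tx)
        left <- IRanges::intersect(ex, ir_from0(sp[1L], tx$cds[1L]))
        right <- IRanges::intersect(ex, ir_from0(tx$cds[2L], sp[2L]))
        if (g$strand == "+") {
          add("5'UTR", g$chrom, g$strand, left)
          add("3'UTR", g$chrom, g$strand, right)
        } else {
          add("5'UTR", g$chrom, g$strand, right)
          add("3'UTR", g$chrom, g$strand, left)
        }
      } else {
        add("ncRNA_exon", g$chrom, g$strand, ex)
      }
      intr <- tx_introns(tx)
      if (nrow(intr) > 0L)
        add("intron", g$chrom, g$strand,
            ir_from0(intr[, "start"], intr[, "end"]))
    }
  }
  out <- list()
  keys <- names(pools)
  info <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  combos <- unique(data.frame(chrom = info[, 2L], strand = info[, 3L],
                              stringsAsFactors = FALSE))
  for (i in seq_len(nrow(combos))) {
    ch <- combos$chrom[i]; st <- combos$strand[i]
    taken <- IRanges::IRanges()
    for (cls in setdiff(REGION_CLASSES, "intergenic")) {
      key <- paste(cls, ch, st, sep = "|")
      if (is.null(pools[[key]])) next
      ir <- IRanges::reduce(do.call(c, pools[[key]]))
      ir <- IRanges::setdiff(ir, taken)
      taken <- IRanges::reduce(c(taken, ir))
      if (length(ir) > 0L) {
        d <- ir_to0(ir)
        out[[length(out) + 1L]] <- data.frame(
          class = cls, chrom = ch, strand = st,
          start = d$start, end = d$end, stringsAsFactors = FALSE)
      }
    }
    # intergenic: the chromosome remainder on this strand
    chlen <- nchar(annotation$chromosomes[[ch]])
    rest <- IRanges::setdiff(ir_from0(0L, chlen), taken)
    if (length(rest) > 0L) {
      d <- ir_to0(rest)
      out[[length(out) + 1L]] <- data.frame(
        class = "intergenic", chrom = ch, strand = st,
        start = d$start, end = d$end, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binding-site density per transcript region class
#'
#' Assigns every site to exactly one region class using the precedence
#' CDS > 5'UTR > 3'UTR > ncRNA exon > intron > intergenic, and normalises
#' the per-class site counts by the total class length (in nt, per strand).
#' Classes with zero length and zero sites are omitted.
#'
#' @param sites a [binding_site_set()] or any data.frame with columns
#'   `chrom`, `strand`, `pos`.
#' @param annotation a [genome_annotation()] object.
#' @return data.frame with columns `class`, `n_sites`, `length_nt`,
#'   `density` (sites per nt).
#' @export
region_density <- function(sites, annotation) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  classes <- region_class_intervals(annotation)
  lens <- tapply(classes$end - classes$start, classes$class, sum)
  counts <- setNames(numeric(length(REGION_CLASSES)), REGION_CLASSES)
  if (nrow(sites) > 0L) {
    key_s <- paste(sites$chrom, sites$strand)
    key_c <- paste(classes$chrom, classes$strand)
    for (kk in unique(key_s)) {
      si <- sites[key_s == kk, , drop = FALSE]
      cl <- classes[key_c == kk, , drop = FALSE]
      if (nrow(cl) == 0L) { # chromosome absent from annotation
        counts["intergenic"] <- counts["intergenic"] + nrow(si)
        next
      }
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(si$pos + 1L, si$pos + 1L),
        ir_from0(cl$start, cl$end), select = "first")
      assigned <- cl$class[hit]
      assigned[is.na(hit)] <- "intergenic"
      tb <- table(assigned)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  out <- data.frame(class = REGION_CLASSES,
                    n_sites = as.numeric(counts[REGION_CLASSES]),
                    length_nt = as.numeric(lens[REGION_CLASSES]),
                    stringsAsFactors = FALSE)
  out$length_nt[is.na(out$length_nt)] <- 0
  keep <- !(out$length_nt == 0 & out$n_sites == 0)
  out <- out[keep, , drop = FALSE]
  out$density <- ifelse(out$length_nt > 0, out$n_sites / out$length_nt, NA_real_)
  rownames(out) <- NULL
  out
}

#' Fetch the sequence of a genomic window in transcript orientation
#'
#' @param annotation a [genome_annotation()] object.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus-strand windows are
#'   reverse-complemented.
#' @return single character string (DNA alphabet).
#' @export
fetch_sequence <- function(annotation, chrom, start, end, strand = "+") {
  seqs <- annotation$chromosomes
  stopifnot(chrom %in% names(seqs), start >= 0, end <= nchar(seqs[[chrom]]))
  s <- substr(seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}
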