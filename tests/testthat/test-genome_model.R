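test_that("constructors validate their invariants", {
  expect_error(transcript("t", rbind(c(10L, 10L))), "empty exon")
  expect_error(transcript("t", rbind(c(10L, 50L), c(40L, 80L))),
               "sorted")
  expect_error(gene("g", "c", "*", list(transcript("t", rbind(c(0L, 10L))))),
               "strand")
  expect_error(genome_annotation(c(a = "ACGT", a = "ACGT"), list()),
               "unique")
  expect_error(
    genome_annotation(c(chr = "ACGT"),
                      list(gene("g", "chr", "+",
                                list(transcript("t", rbind(c(0L, 100L))))))),
    "bounds")
})

test_that("flatten_features partitions exon unions at every boundary", {
  # single transcript: forced partition
  ann <- genome_annotation(
    c(chr = strrep("A", 500)),
    list(gene("g", "chr", "+",
              list(transcript("t", rbind(c(100L, 200L), c(300L, 400L)))))))
  ff <- flatten_features(ann)
  ex <- ff[ff$kind == "exonic_part", ]
  expect_equal(nrow(ex), 2L)
  jn <- ff[ff$kind == "junction", ]
  expect_equal(c(jn$start, jn$end), c(200L, 300L))
  expect_equal(ff[ff$kind == "intron", c("start", "end")],
               data.frame(start = 200L, end = 300L), ignore_attr = TRUE)

  # overlapping transcripts split at internal boundaries
  ann2 <- genome_annotation(
    c(chr = strrep("A", 500)),
    list(gene("g", "chr", "+", list(
      transcript("t1", rbind(c(100L, 200L))),
      transcript("t2", rbind(c(150L, 250L)))))))
  ex2 <- flatten_features(ann2)
  ex2 <- ex2[ex2$kind == "exonic_part", ]
  expect_equal(ex2$start, c(100L, 150L, 200L))
  expect_equal(ex2$end, c(150L, 200L, 250L))

  # tsl filter removing everything -> empty with warning
  ann3 <- genome_annotation(
    c(chr = strrep("A", 500)),
    list(gene("g", "chr", "+",
              list(transcript("t", rbind(c(100L, 200L)), tsl = 2L)))))
  expect_warning(ff3 <- flatten_features(ann3, tsl_max = 1L), "skipped")
  expect_equal(nrow(ff3), 0L)
})

test_that("exonic parts exactly tile the exon union (property)", {
  for (seed in 1:3) {
    g <- generate_genome(sim_config(seed = seed, n_genes = 8L))
    ff <- suppressWarnings(flatten_features(g$annotation, tsl_max = 2L))
    for (gid in names(g$annotation$genes)) {
      gn <- g$annotation$genes[[gid]]
      ex <- do.call(rbind, lapply(gn$transcripts, `[[`, "exons"))
      union_len <- sum(BiocGenerics::width(IRanges::reduce(
        IRanges::IRanges(ex[, 1] + 1L, ex[, 2]))))
      parts <- ff[ff$gene_id == gid & ff$kind == "exonic_part", ]
      expect_equal(sum(parts$end - parts$start), union_len)
    }
  }
})

test_that("cotranscribed_region merges transcript spans", {
  mk <- function(spans) gene("g", "chr", "+", lapply(seq_along(spans),
    function(i) transcript(paste0("t", i),
                           rbind(c(spans[[i]][1], spans[[i]][1] + 10L),
                                 c(spans[[i]][2] - 10L, spans[[i]][2])))))
  r1 <- cotranscribed_region(mk(list(c(100L, 500L), c(300L, 800L))))
  expect_equal(c(r1$start, r1$end), c(100L, 800L))
  r2 <- cotranscribed_region(mk(list(c(100L, 200L), c(500L, 600L))))
  expect_equal(nrow(r2), 2L)
  g3 <- gene("g", "chr", "-", list(transcript("t", rbind(c(50L, 90L)))))
  r3 <- cotranscribed_region(g3)
  expect_equal(c(r3$start, r3$end, r3$strand), c("50", "90", "-"))
})

test_that("transcript_window maps offsets strand-aware and clips", {
  w <- transcript_window(1000L, list(c(-30L, -5L)), "+", c(0L, 10000L))
  expect_equal(c(w$start, w$end), c(970L, 996L)) # positions 970..995
  wm <- transcript_window(1000L, list(c(-30L, -5L)), "-", c(0L, 10000L))
  expect_equal(c(wm$start, wm$end), c(1005L, 1031L)) # positions 1005..1030
  # brute-force mirror check: per-offset genomic position on '-' strand
  offs <- -30:-5
  expect_equal(sort(wm$start:(wm$end - 1L)), sort(1000L - offs))
  # clipping at the chromosome start
  wc <- transcript_window(10L, list(c(-30L, -5L)), "+", c(0L, 100L))
  expect_true(nrow(wc) == 1L && wc$start == 0L && wc$end == 6L)
  # site outside bounds -> empty
  expect_equal(nrow(transcript_window(500L, list(c(-30L, -5L)), "+",
                                      c(0L, 100L))), 0L)
})

test_that("plus and minus strand windows are mirror images (property)", {
  offsets <- list(c(-30L, -5L), c(5L, 30L))
  for (p in c(100L, 555L, 1000L)) {
    wp <- transcript_window(p, offsets, "+", c(0L, 5000L))
    wm <- transcript_window(p, offsets, "-", c(0L, 5000L))
    plus_offsets <- sort(unlist(Map(`:`, wp$start, wp$end - 1L)) - p)
    minus_offsets <- sort(p - unlist(Map(`:`, wm$start, wm$end - 1L)))
    expect_equal(plus_offsets, minus_offsets)
  }
})

test_that("region_density assigns by precedence and normalises by length", {
  ann <- tiny_annotation()
  # 10 sites in g1 introns (introns: [200,300) + [400,500) = 200 nt)
  sites <- data.frame(chrom = "chrT", strand = "+",
                      pos = c(200:204, 400:404))
  rd <- region_density(sites, ann)
  # intron length pools both strands: 200 nt (g1, '+') + 100 nt (g2, '-')
  expect_equal(rd$density[rd$class == "intron"], 10 / 300)
  expect_equal(sum(rd$n_sites), 10)
  # zero sites -> all densities zero
  rd0 <- region_density(sites[0, ], ann)
  expect_true(all(rd0$density == 0))
  # CDS > intron precedence when transcripts disagree
  ann2 <- genome_annotation(
    c(chr = strrep("A", 1000)),
    list(gene("g", "chr", "+", list(
      transcript("t1", rbind(c(100L, 400L)), cds = c(100L, 400L)),
      transcript("t2", rbind(c(50L, 80L), c(600L, 700L)))))))
  rd2 <- region_density(data.frame(chrom = "chr", strand = "+", pos = 200L),
                        ann2)
  expect_equal(rd2$n_sites[rd2$class == "CDS"], 1)
  expect_equal(sum(rd2$n_sites), 1)
})

test_that("region class lengths are disjoint and exhaustive", {
  ann <- tiny_annotation()
  rd <- region_density(data.frame(chrom = character(0),
                                  strand = character(0),
                                  pos = integer(0)), ann)
  # both strands of a 2000 nt chromosome
  expect_equal(sum(rd$length_nt), 2 * 2000)
  # hand-checked classes for g1: CDS [150,200)+[300,400)+[500,550),
  # 5'UTR [100,150), 3'UTR [550,600), introns 200 nt
  expect_equal(rd$length_nt[rd$class == "CDS"], 200)
  expect_equal(rd$length_nt[rd$class == "5'UTR"], 50)
  expect_equal(rd$length_nt[rd$class == "3'UTR"], 50)
  expect_equal(rd$length_nt[rd$class == "ncRNA_exon"], 200)
})
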