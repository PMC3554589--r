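# annotation with a 4-exon gene and plenty of empty space
catalog_gm <- function() {
  gene_models(data.frame(
    chrom = "chr1",
    start = c(1000, 1400, 1800, 2200),
    end = c(1099, 1499, 1899, 2299),
    strand = "+", gene_id = "gP", tx_id = "gP.t1"))
}

test_that("a gapless multi-exon alignment at a gene-free locus becomes a retrocopy", {
  gm <- catalog_gm()
  aln <- transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L, 50399L,
                               1, list(data.frame(qstart = 1L,
                                                  tstart = 50000L,
                                                  size = 400L)))
  cat <- build_retrocopy_catalog(aln, gm)
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$n_exons_retained, 4L)
  expect_equal(cat$retained_exons[[1]], 1:4)
  expect_equal(cat$parent_gene_id, "gP")
})

test_that("alignments overlapping the parent locus or multi-exon exons are removed", {
  gm <- catalog_gm()
  # self-alignment back to the parent gene
  self_aln <- transcript_alignments("gP.t1", "gP", "chr1", "+", 1000L,
                                    2299L, 1,
                                    list(data.frame(
                                      qstart = c(1L, 101L, 201L, 301L),
                                      tstart = c(1000L, 1400L, 1800L,
                                                 2200L),
                                      size = rep(100L, 4))))
  expect_equal(nrow(build_retrocopy_catalog(self_aln, gm)), 0L)
  # alignment overlapping another multi-exon gene's exon
  gm2 <- gene_models(rbind(
    data.frame(chrom = "chr1", start = c(1000, 1400, 1800, 2200),
               end = c(1099, 1499, 1899, 2299), strand = "+",
               gene_id = "gP", tx_id = "gP.t1"),
    data.frame(chrom = "chr1", start = c(40000, 40500),
               end = c(40099, 40599), strand = "+", gene_id = "gQ",
               tx_id = "gQ.t1")))
  hit_exon <- transcript_alignments("gP.t1", "gP", "chr1", "+", 39950L,
                                    40349L, 1,
                                    list(data.frame(qstart = 1L,
                                                    tstart = 39950L,
                                                    size = 400L)))
  expect_equal(nrow(build_retrocopy_catalog(hit_exon, gm2)), 0L)
})

test_that("intron-containing and single-exon alignments are rejected", {
  gm <- catalog_gm()
  # two blocks separated by 300 bp on the genome: not intron-less
  gapped <- transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L,
                                  50699L, 1,
                                  list(data.frame(qstart = c(1L, 201L),
                                                  tstart = c(50000L,
                                                             50500L),
                                                  size = c(200L, 200L))))
  expect_equal(nrow(build_retrocopy_catalog(gapped, gm)), 0L)
  # a block covering only exon 1 sequence
  single <- transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L,
                                  50089L, 1,
                                  list(data.frame(qstart = 1L,
                                                  tstart = 50000L,
                                                  size = 90L)))
  expect_equal(nrow(build_retrocopy_catalog(single, gm)), 0L)
  # but a small genomic gap (<= max_gap) still counts as adjacent
  nicked <- transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L,
                                  50409L, 1,
                                  list(data.frame(qstart = c(1L, 201L),
                                                  tstart = c(50000L,
                                                             50210L),
                                                  size = c(200L, 200L))))
  expect_equal(nrow(build_retrocopy_catalog(nicked, gm)), 1L)
})

test_that("alignments to one genomic region group into a single retrocopy", {
  gm <- catalog_gm()
  aln <- rbind(
    transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L, 50399L, 1,
                          list(data.frame(qstart = 1L, tstart = 50000L,
                                          size = 400L))),
    transcript_alignments("gP.t1", "gP", "chr1", "+", 50100L, 50399L, 1,
                          list(data.frame(qstart = 101L,
                                          tstart = 50100L,
                                          size = 300L))))
  cat <- build_retrocopy_catalog(aln, gm)
  expect_equal(nrow(cat), 1L)
})

test_that("low identity, unknown genes and duplication candidates are handled", {
  gm <- catalog_gm()
  aln <- transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L, 50399L,
                               0.90, list(data.frame(qstart = 1L,
                                                     tstart = 50000L,
                                                     size = 400L)))
  expect_equal(nrow(build_retrocopy_catalog(aln, gm)), 0L)
  expect_equal(nrow(build_retrocopy_catalog(aln, gm,
                                            min_identity = 0.85)), 1L)
  bad <- transcript_alignments("zz.t1", "zz", "chr1", "+", 50000L, 50399L,
                               1, list(data.frame(qstart = 1L,
                                                  tstart = 50000L,
                                                  size = 400L)))
  expect_error(build_retrocopy_catalog(bad, gm), "missing-annotation")
  good <- transcript_alignments("gP.t1", "gP", "chr1", "+", 50000L,
                                50399L, 1,
                                list(data.frame(qstart = 1L,
                                                tstart = 50000L,
                                                size = 400L)))
  dropped <- build_retrocopy_catalog(
    good, gm, is_genomic_duplication = function(loc, gene) TRUE)
  expect_equal(nrow(dropped), 0L)
})

test_that("catalog construction is idempotent and recovers injected retrocopies", {
  sim <- simulate_reference_with_retrocopies(simulation_config(seed = 21))
  cat1 <- build_retrocopy_catalog(sim$alignments, sim$gm)
  # truth: n_fixed_retro + reference-present events, each >= 2 exons
  k_truth <- nrow(sim$fixed) + sum(sim$events$in_reference)
  expect_equal(nrow(cat1), k_truth)
  expect_true(all(cat1$n_exons_retained >= 2L))
  # no catalog entry overlaps exons of any multi-exon gene
  cat_gr <- GenomicRanges::GRanges(cat1$chrom,
                                   IRanges::IRanges(cat1$start, cat1$end))
  me <- sim$gm$exons[sim$gm$exons$gene_id %in% multi_exon_genes(sim$gm)]
  expect_equal(sum(GenomicRanges::countOverlaps(cat_gr, me)), 0L)
  # rebuilding from alignments regenerated off the catalog is stable
  aln2 <- do.call(rbind, lapply(seq_len(nrow(cat1)), function(i)
    transcript_alignments(
      paste0(cat1$parent_gene_id[i], ".t1"), cat1$parent_gene_id[i],
      cat1$chrom[i], cat1$strand[i], cat1$start[i], cat1$end[i], 1,
      list(data.frame(qstart = 1L, tstart = cat1$start[i],
                      size = cat1$end[i] - cat1$start[i] + 1L)))))
  cat2 <- build_retrocopy_catalog(aln2, sim$gm)
  expect_equal(cat2[, c("chrom", "start", "end")],
               cat1[, c("chrom", "start", "end")])
})

test_that("completeness requires both terminal exons of some isoform", {
  gm7 <- gene_models(data.frame(
    chrom = "chr1", start = seq(1000, 7000, by = 1000),
    end = seq(1099, 7099, by = 1000), strand = "+",
    gene_id = "g7", tx_id = "g7.t1"))
  # parts of exons 1 and 7 evidenced -> complete
  ev <- exon_intervals(gm7, "g7.t1", c(1, 3, 7))
  expect_equal(assess_completeness(ev, gm7, "g7"),
               "complete_or_near_complete")
  # exons 3..7 only, single isoform -> partial
  ev2 <- exon_intervals(gm7, "g7.t1", 3:7)
  expect_equal(assess_completeness(ev2, gm7, "g7"), "partial")
  # no evidence -> unknown
  expect_equal(assess_completeness(NULL, gm7, "g7"), "unknown")
  # isoform rescue: isoform B spans exons 2..3 only, so evidence for
  # exons 2-3 is complete via B though partial via the 3-exon isoform A
  gmAB <- gene_models(data.frame(
    chrom = "chr1", start = c(1000, 2000, 3000, 2000, 3000),
    end = c(1099, 2099, 3099, 2099, 3099), strand = "+",
    gene_id = "gI", tx_id = c("gI.tA", "gI.tA", "gI.tA", "gI.tB",
                              "gI.tB")))
  ev3 <- exon_intervals(gmAB, "gI.tA", 2:3)
  expect_equal(assess_completeness(ev3, gmAB, "gI"),
               "complete_or_near_complete")
})

test_that("catalog BED12 + TSV sidecar round-trips the key fields", {
  cat <- hand_catalog()
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  write_catalog(cat, bed, tsv)
  gr <- read_bed(bed)
  expect_equal(GenomicRanges::start(gr), cat$start)
  expect_equal(GenomicRanges::end(gr), cat$end)
  side <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(side$parent_gene_id, "gC")
  expect_equal(side$n_exons_retained, 2L)
})
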