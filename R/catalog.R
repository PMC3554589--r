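#' Read transcript-to-genome alignments in PSL format
#'
#' Parses BLAT's 21-column PSL (with or without the 5-line header).
#' Coordinates are converted from PSL's 0-based half-open convention to the
#' 1-based closed convention used internally.
#'
#' @param path PSL file
#' @param parent_gene_of optional named character vector mapping
#'   transcript ids (qName) to parental gene ids; by default the gene id is
#'   the transcript id with a trailing `.suffix` removed.
#' @return data.frame with one row per alignment: `transcript_id`,
#'   `parent_gene_id`, `chrom`, `strand`, `tstart`, `tend`, `pid`
#'   (fraction identity) and a `blocks` list-column of data.frames with
#'   1-based `qstart`, `tstart`, `size`.
#' @export
read_psl <- function(path, parent_gene_of = NULL) {
  lines <- readLines(path)
  if (length(lines) && grepl("^psLayout", lines[1]))
    lines <- lines[-seq_len(5L)]
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\t|\\s+")[[1]]
    if (length(f) < 21L) stop("malformed PSL line: ", l)
    f
  })
  parse_csv_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  out <- lapply(rows, function(f) {
    matches <- as.integer(f[1]); mism <- as.integer(f[2])
    rep_m <- as.integer(f[3]); ncount <- as.integer(f[4])
    aligned <- matches + mism + rep_m + ncount
    sizes <- parse_csv_ints(f[19])
    qs <- parse_csv_ints(f[20]); ts <- parse_csv_ints(f[21])
    tid <- f[10]
    list(transcript_id = tid,
         chrom = f[14], strand = substr(f[9], 1, 1),
         tstart = as.integer(f[16]) + 1L, tend = as.integer(f[17]),
         pid = if (aligned > 0) (matches + rep_m) / aligned else 0,
         blocks = data.frame(qstart = qs + 1L, tstart = ts + 1L,
                             size = sizes))
  })
  df <- data.frame(
    transcript_id = vapply(out, `[[`, "", "transcript_id"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    tstart = vapply(out, `[[`, 1L, "tstart"),
    tend = vapply(out, `[[`, 1L, "tend"),
    pid = vapply(out, `[[`, 1, "pid"))
  df$parent_gene_id <- if (is.null(parent_gene_of))
    sub("\\.[^.]*$", "", df$transcript_id)
  else unname(parent_gene_of[df$transcript_id])
  df$blocks <- lapply(out, `[[`, "blocks")
  df
}

#' Construct a transcript alignment table in code
#'
#' Convenience constructor mirroring [read_psl] output, used by the
#' simulator and in tests.
#'
#' @param transcript_id,parent_gene_id,chrom,strand,tstart,tend,pid
#'   per-alignment scalars (recycled)
#' @param blocks list of block data.frames (`qstart`, `tstart`, `size`,
#'   1-based)
#' @return data.frame as from [read_psl]
#' @export
transcript_alignments <- function(transcript_id, parent_gene_id, chrom,
                                  strand, tstart, tend, pid = 1,
                                  blocks = list()) {
  df <- data.frame(transcript_id = transcript_id,
                   parent_gene_id = parent_gene_id,
                   chrom = chrom, strand = strand,
                   tstart = tstart, tend = tend, pid = pid)
  df$blocks <- blocks
  df
}

# exon ranks of transcript `tx_id` covered by the aligned query blocks
.covered_exons <- function(blocks, gm, tx_id) {
  ex <- gm$exons[gm$exons$tx_id == tx_id]
  if (length(ex) == 0L) return(integer(0))
  ex <- ex[order(ex$exon_rank)]
  len <- GenomicRanges::width(ex)
  qend_cum <- cumsum(len)
  qstart_cum <- c(1L, head(qend_cum, -1) + 1L)
  covered <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    b1 <- blocks$qstart[b]; b2 <- blocks$qstart[b] + blocks$size[b] - 1L
    hit <- which(qstart_cum <= b2 & qend_cum >= b1)
    covered <- union(covered, ex$exon_rank[hit])
  }
  sort(covered)
}

#' Build the reference retrocopy catalog
#'
#' Implements the four-step catalog pipeline over transcript-to-genome
#' alignments: (i) alignments are taken as given; (ii) alignments that
#' overlap exons of any multi-exon gene, or the parental gene's own locus,
#' are removed; (iii) intron-less alignments are kept -- consecutive
#' aligned blocks separated by at most `max_gap` bases on the genome --
#' provided they cover at least two distinct parental exons; (iv)
#' alignments to the same genomic region are grouped into a single
#' retrocopy and candidates judged to arise from DNA-level (genomic)
#' duplication are dropped.
#'
#' @param alignments data.frame from [read_psl] / [transcript_alignments]
#' @param gm gene_models annotation; every `parent_gene_id` must be present
#' @param max_gap maximum genomic gap (bp) between consecutive aligned
#'   blocks still counted as "adjacent without gaps" (default 20)
#' @param min_identity minimum alignment identity (default 0.95)
#' @param is_genomic_duplication optional predicate taking a single-locus
#'   `GRanges` and the parent gene id, returning TRUE when the candidate
#'   looks like a genomic (DNA-level) duplication rather than a retrocopy;
#'   such candidates are dropped. See [flank_duplication_filter].
#' @return data.frame of retrocopies: `retro_id`, `parent_gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_exons_retained` and a
#'   `retained_exons` list-column of exon ranks.
#' @export
build_retrocopy_catalog <- function(alignments, gm, max_gap = 20L,
                                    min_identity = 0.95,
                                    is_genomic_duplication = NULL) {
  if (nrow(alignments) == 0L)
    return(.empty_catalog())
  missing <- setdiff(alignments$parent_gene_id, names(gm$genes))
  if (length(missing))
    stop("missing-annotation: unknown parent gene(s): ",
         paste(missing, collapse = ", "))
  keep <- alignments$pid >= min_identity
  alignments <- alignments[keep, , drop = FALSE]
  if (nrow(alignments) == 0L) return(.empty_catalog())

  aln_gr <- GenomicRanges::GRanges(alignments$chrom,
                                   IRanges::IRanges(alignments$tstart,
                                                    alignments$tend))
  me <- multi_exon_genes(gm)
  me_exons <- gm$exons[gm$exons$gene_id %in% me]
  ov_exon <- GenomicRanges::countOverlaps(aln_gr, me_exons,
                                          ignore.strand = TRUE) > 0L
  parent_span <- gm$genes[alignments$parent_gene_id]
  ov_parent <-
    as.character(GenomicRanges::seqnames(aln_gr)) ==
      as.character(GenomicRanges::seqnames(parent_span)) &
    GenomicRanges::start(aln_gr) <= GenomicRanges::end(parent_span) &
    GenomicRanges::end(aln_gr) >= GenomicRanges::start(parent_span)
  keep <- !(ov_exon | ov_parent)
  alignments <- alignments[keep, , drop = FALSE]
  if (nrow(alignments) == 0L) return(.empty_catalog())

  # step iii: intron-less, >= 2 exons
  ok <- logical(nrow(alignments))
  retained <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    b <- alignments$blocks[[i]]
    b <- b[order(b$tstart), , drop = FALSE]
    gaps <- if (nrow(b) > 1)
      b$tstart[-1] - (b$tstart[-nrow(b)] + b$size[-nrow(b)])
    else integer(0)
    if (length(gaps) && any(gaps > max_gap)) next
    cov <- .covered_exons(b, gm, alignments$transcript_id[i])
    if (length(cov) >= 2L) {
      ok[i] <- TRUE
      retained[[i]] <- cov
    }
  }
  alignments <- alignments[ok, , drop = FALSE]
  retained <- retained[ok]
  if (nrow(alignments) == 0L) return(.empty_catalog())

  # step iv: group by genomic region
  aln_gr <- GenomicRanges::GRanges(alignments$chrom,
                                   IRanges::IRanges(alignments$tstart,
                                                    alignments$tend))
  regions <- GenomicRanges::reduce(aln_gr, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(aln_gr, regions, ignore.strand = TRUE))
  out <- lapply(split(seq_len(nrow(alignments)), grp), function(idx) {
    parent <- names(sort(table(alignments$parent_gene_id[idx]),
                         decreasing = TRUE))[1]
    idx_p <- idx[alignments$parent_gene_id[idx] == parent]
    ret <- sort(unique(unlist(retained[idx_p])))
    r <- regions[grp[idx[1]]]
    data.frame(parent_gene_id = parent,
               chrom = as.character(GenomicRanges::seqnames(r)),
               start = GenomicRanges::start(r),
               end = GenomicRanges::end(r),
               strand = alignments$strand[idx_p[1]],
               n_exons_retained = length(ret),
               retained_exons = I(list(ret)))
  })
  cat <- do.call(rbind, out)
  rownames(cat) <- NULL
  if (!is.null(is_genomic_duplication)) {
    dup <- vapply(seq_len(nrow(cat)), function(i) {
      loc <- GenomicRanges::GRanges(cat$chrom[i],
                                    IRanges::IRanges(cat$start[i],
                                                     cat$end[i]))
      isTRUE(is_genomic_duplication(loc, cat$parent_gene_id[i]))
    }, logical(1))
    cat <- cat[!dup, , drop = FALSE]
  }
  if (nrow(cat) == 0L) return(.empty_catalog())
  cat <- cat[order(cat$chrom, cat$start), , drop = FALSE]
  cat$retro_id <- sprintf("retro_%s_%d", cat$parent_gene_id,
                          seq_len(nrow(cat)))
  rownames(cat) <- NULL
  cat[, c("retro_id", "parent_gene_id", "chrom", "start", "end", "strand",
          "n_exons_retained", "retained_exons")]
}

.empty_catalog <- function() {
  data.frame(retro_id = character(0), parent_gene_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), n_exons_retained = integer(0),
             retained_exons = I(list()))
}

#' Flanking-identity filter for genomic duplications
#'
#' Returns a predicate usable as `is_genomic_duplication` in
#' [build_retrocopy_catalog]: a candidate locus is flagged when its
#' flanking sequence (`flank` bp either side) aligns to the parental
#' locus flanks at or above `min_identity`, the signature of a DNA-level
#' segmental duplication carrying the gene and its surroundings.
#'
#' @param genome named DNAStringSet (reference sequences)
#' @param gm gene_models annotation
#' @param flank flank length in bp (default 2000)
#' @param min_identity identity threshold (default 0.9)
#' @return function(locus GRanges, parent_gene_id) -> logical
#' @export
flank_duplication_filter <- function(genome, gm, flank = 2000L,
                                     min_identity = 0.9) {
  get_flanks <- function(chrom, start, end) {
    s <- genome[[chrom]]
    left <- Biostrings::subseq(s, max(1L, start - flank),
                               max(1L, start - 1L))
    right <- Biostrings::subseq(s, min(length(s), end + 1L),
                                min(length(s), end + flank))
    list(left = left, right = right)
  }
  function(locus, parent_gene_id) {
    g <- gm$genes[parent_gene_id]
    fl_c <- get_flanks(as.character(GenomicRanges::seqnames(locus)),
                       GenomicRanges::start(locus),
                       GenomicRanges::end(locus))
    fl_p <- get_flanks(as.character(GenomicRanges::seqnames(g)),
                       GenomicRanges::start(g), GenomicRanges::end(g))
    idy <- function(a, b) {
      if (length(a) < 50L || length(b) < 50L) return(0)
      al <- Biostrings::pairwiseAlignment(a, b, type = "local")
      score_len <- Biostrings::nchar(Biostrings::alignedPattern(al))
      if (score_len < 0.5 * min(length(a), length(b))) return(0)
      Biostrings::pid(al) / 100
    }
    idy(fl_c$left, fl_p$left) >= min_identity &&
      idy(fl_c$right, fl_p$right) >= min_identity
  }
}

#' Assess completeness of a retrocopy's retained sequence
#'
#' A retrocopy is complete or near-complete when at least one isoform of
#' the parental gene has both its 5'-most and 3'-most exons at least
#' partially present in (or evidenced for) the retrocopy. Evidence is
#' supplied as genomic exon intervals so that isoforms with different exon
#' numbering are handled uniformly: an isoform "explains" the retrocopy as
#' complete when the evidence overlaps both of its terminal exons.
#'
#' @param evidence GRanges of evidenced exon intervals (genomic
#'   coordinates of the parental exons retained in / supported for the
#'   retrocopy), or `NULL`/empty when nothing is known
#' @param gm gene_models annotation
#' @param gene_id parental gene
#' @return one of `"complete_or_near_complete"`, `"partial"`, `"unknown"`
#' @export
assess_completeness <- function(evidence, gm, gene_id) {
  if (is.null(evidence) || length(evidence) == 0L) return("unknown")
  txs <- unique(gm$exons$tx_id[gm$exons$gene_id == gene_id])
  for (tx in txs) {
    ex <- gm$exons[gm$exons$tx_id == tx]
    first <- ex[ex$exon_rank == 1L]
    last <- ex[ex$exon_rank == max(ex$exon_rank)]
    hit_first <- length(GenomicRanges::findOverlaps(
      evidence, first, ignore.strand = TRUE)) > 0L
    hit_last <- length(GenomicRanges::findOverlaps(
      evidence, last, ignore.strand = TRUE)) > 0L
    if (hit_first && hit_last) return("complete_or_near_complete")
  }
  "partial"
}

#' Genomic intervals of a transcript's exons by rank
#'
#' Helper translating exon ranks (e.g. a retrocopy's retained exon
#' indices) into genomic intervals, the evidence currency of
#' [assess_completeness].
#'
#' @param gm gene_models annotation
#' @param tx_id transcript
#' @param ranks integer exon ranks; default all
#' @return GRanges of the requested exons
#' @export
exon_intervals <- function(gm, tx_id, ranks = NULL) {
  ex <- gm$exons[gm$exons$tx_id == tx_id]
  if (!is.null(ranks)) ex <- ex[ex$exon_rank %in% ranks]
  GenomicRanges::granges(ex)
}

#' Write a retrocopy catalog as BED12 plus a TSV sidecar
#'
#' @param catalog data.frame from [build_retrocopy_catalog]
#' @param bed_path BED output (one block per retrocopy)
#' @param tsv_path sidecar TSV (parent gene, exon count)
#' @return invisibly, the two paths
#' @export
write_catalog <- function(catalog, bed_path, tsv_path) {
  gr <- GenomicRanges::GRanges(catalog$chrom,
                               IRanges::IRanges(catalog$start, catalog$end),
                               strand = catalog$strand)
  gr$name <- catalog$retro_id
  rtracklayer::export(gr, bed_path, format = "bed")
  side <- catalog[, c("retro_id", "parent_gene_id", "n_exons_retained")]
  side$retained_exons <- vapply(catalog$retained_exons, paste,
                                "", collapse = ",")
  write.table(side, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
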