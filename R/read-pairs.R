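#' Construct a paired-end read table
#'
#' The package's tabular currency for mapped mate pairs: one row per pair,
#' 1-based closed coordinates, `NA` chromosome for an unmapped read.
#'
#' @param sample_id,qname identifiers (recycled)
#' @param chrom1,start1,end1,strand1 first read placement
#' @param chrom2,start2,end2,strand2 second read placement
#' @return data.frame of pairs
#' @export
read_pairs <- function(sample_id, qname, chrom1, start1, end1, strand1,
                       chrom2, start2, end2, strand2) {
  data.frame(sample_id = sample_id, qname = qname,
             chrom1 = chrom1, start1 = start1, end1 = end1,
             strand1 = strand1,
             chrom2 = chrom2, start2 = start2, end2 = end2,
             strand2 = strand2, stringsAsFactors = FALSE)
}

# outer span of a pair on one chromosome (fragment length); NA if split
.pair_span <- function(p) {
  ifelse(!is.na(p$chrom1) & !is.na(p$chrom2) & p$chrom1 == p$chrom2,
         pmax(p$end1, p$end2) - pmin(p$start1, p$start2) + 1L,
         NA_integer_)
}

#' Read mate pairs from a SAM or BAM file
#'
#' Uses [Rsamtools::scanBam]; SAM input is converted on the fly. Mates are
#' joined on query name; reads whose mate is absent are dropped.
#'
#' @param path SAM or BAM file
#' @param sample_id sample label attached to every pair
#' @return data.frame as from [read_pairs]
#' @export
read_pairs_sam <- function(path, sample_id) {
  bam <- path
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "strand")))[[1]]
  flag <- res$flag
  first <- bitwAnd(flag, 64L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  df <- data.frame(qname = res$qname, first = first,
                   chrom = ifelse(unmapped, NA_character_,
                                  as.character(res$rname)),
                   start = ifelse(unmapped, NA_integer_, res$pos),
                   end = ifelse(unmapped, NA_integer_,
                                res$pos + res$qwidth - 1L),
                   strand = ifelse(unmapped, NA_character_,
                                   as.character(res$strand)))
  r1 <- df[df$first, ]
  r2 <- df[!df$first, ]
  m <- match(r1$qname, r2$qname)
  ok <- !is.na(m)
  r1 <- r1[ok, ]; r2 <- r2[m[ok], ]
  read_pairs(sample_id, r1$qname,
             r1$chrom, r1$start, r1$end, r1$strand,
             r2$chrom, r2$start, r2$end, r2$strand)
}

#' Write a pair table as SAM
#'
#' Emits a minimal coordinate-unsorted SAM with proper pairing flags; read
#' sequences are written when a `seq1`/`seq2` column pair is present and
#' `*` otherwise. The result converts cleanly with samtools/Rsamtools.
#'
#' @param pairs data.frame from [read_pairs]
#' @param ref_lengths named integer vector of reference sequence lengths
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_sam <- function(pairs, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(ref_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths)[i],
                       ref_lengths[i]), con)
  emit <- function(qname, this, mate, first) {
    flag <- 1L + if (first) 64L else 128L
    if (is.na(this$chrom)) flag <- flag + 4L
    if (is.na(mate$chrom)) flag <- flag + 8L
    if (!is.na(this$chrom) && this$strand == "-") flag <- flag + 16L
    if (!is.na(mate$chrom) && mate$strand == "-") flag <- flag + 32L
    len <- if (is.na(this$chrom)) 0L else this$end - this$start + 1L
    cigar <- if (is.na(this$chrom)) "*" else sprintf("%dM", len)
    rnext <- if (is.na(mate$chrom)) "*"
             else if (!is.na(this$chrom) && mate$chrom == this$chrom) "="
             else mate$chrom
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
            qname, flag,
            if (is.na(this$chrom)) "*" else this$chrom,
            if (is.na(this$chrom)) 0L else this$start,
            if (is.na(this$chrom)) 0L else 60L,
            cigar, rnext,
            if (is.na(mate$chrom)) 0L else mate$start,
            if (is.null(this$seq) || is.na(this$seq)) "*" else this$seq)
  }
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    a <- list(chrom = p$chrom1, start = p$start1, end = p$end1,
              strand = p$strand1, seq = p$seq1)
    b <- list(chrom = p$chrom2, start = p$start2, end = p$end2,
              strand = p$strand2, seq = p$seq2)
    writeLines(emit(p$qname, a, b, TRUE), con)
    writeLines(emit(p$qname, b, a, FALSE), con)
  }
  invisible(path)
}

#' Fit the library insert-size model
#'
#' Estimates the fragment-length distribution from concordant pairs (both
#' reads mapped to one chromosome on opposite strands) and sets the
#' concordance limit to `mean + k * SD`: pairs mapping further apart are
#' treated as discordant (deletion-signature) evidence.
#'
#' @param pairs data.frame from [read_pairs]
#' @param k SD multiplier for the concordance limit (default 3)
#' @param min_pairs minimum concordant pairs required (default 100)
#' @return object of class `insert_size_model` with `mean`, `sd`, `limit`
#' @export
fit_insert_size_model <- function(pairs, k = 3, min_pairs = 100L) {
  conc <- !is.na(pairs$chrom1) & !is.na(pairs$chrom2) &
    pairs$chrom1 == pairs$chrom2 & pairs$strand1 != pairs$strand2
  spans <- .pair_span(pairs[conc, , drop = FALSE])
  spans <- spans[!is.na(spans)]
  if (length(spans) < min_pairs)
    stop("insufficient-data: need >= ", min_pairs,
         " concordant pairs, found ", length(spans))
  m <- mean(spans)
  s <- stats::sd(spans)
  if (is.na(s)) s <- 0
  insert_size_model(m, s, k)
}

#' Construct an insert-size model directly
#' @param mean,sd fragment-length mean and SD in bp
#' @param k SD multiplier; `limit = mean + k * sd`
#' @return `insert_size_model` object
#' @export
insert_size_model <- function(mean, sd, k = 3) {
  stopifnot(mean > 0, sd >= 0)
  structure(list(mean = mean, sd = sd, k = k, limit = mean + k * sd),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("insert_size_model: mean %.1f bp, sd %.1f, limit %.1f\n",
              x$mean, x$sd, x$limit))
  invisible(x)
}
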