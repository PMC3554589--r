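#' Build spliced transcript sequences with junction offsets
#'
#' Splices each transcript's exons out of the reference to produce the
#' mRNA sequences that unmapped reads are aligned against, recording the
#' exon-exon junction offsets (junction j sits between transcript
#' positions J and J+1, where J is the cumulative length of exons 1..j).
#'
#' @param gm gene_models annotation
#' @param genome named [Biostrings::DNAStringSet] of reference sequences
#' @return object of class `transcript_set`: list with `seqs`
#'   (DNAStringSet named by transcript id), `junctions` (named list of
#'   integer offsets) and `gene_id` (named character)
#' @export
transcript_set <- function(gm, genome) {
  txs <- unique(gm$exons$tx_id)
  seqs <- vector("list", length(txs))
  juncs <- vector("list", length(txs))
  genes <- character(length(txs))
  for (i in seq_along(txs)) {
    ex <- gm$exons[gm$exons$tx_id == txs[i]]
    ex <- ex[order(ex$exon_rank)]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    pieces <- lapply(seq_along(ex), function(j)
      Biostrings::subseq(genome[[chrom]], GenomicRanges::start(ex)[j],
                         GenomicRanges::end(ex)[j]))
    neg <- as.character(GenomicRanges::strand(ex))[1] == "-"
    if (neg) pieces <- lapply(pieces, Biostrings::reverseComplement)
    seqs[[i]] <- do.call(Biostrings::xscat, pieces)
    lens <- GenomicRanges::width(ex)
    juncs[[i]] <- cumsum(lens)[-length(lens)]
    genes[i] <- ex$gene_id[1]
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- txs
  names(juncs) <- txs
  names(genes) <- txs
  structure(list(seqs = ss, junctions = juncs, gene_id = genes),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", length(x$seqs), "transcripts\n")
  invisible(x)
}

#' Read unmapped reads from FASTQ
#'
#' @param path FASTQ file
#' @param sample_id sample label
#' @return data.frame with `read_id`, `sample_id`, `seq`
#' @export
read_unmapped_fastq <- function(path, sample_id) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                 error = function(e)
                   stop("FASTQ parse error in ", path, ": ",
                        conditionMessage(e)))
  data.frame(read_id = names(ss), sample_id = sample_id,
             seq = as.character(ss))
}

#' Align unmapped reads across transcript exon-exon junctions
#'
#' Matches each read (both orientations) against the spliced transcript
#' sequences with up to `floor(mismatch_frac * read length)` mismatches
#' and keeps hits crossing at least one junction, subject to the mismatch
#' rule: the mismatch count may exceed neither `mismatch_frac` of the read
#' length (default 4%) nor `side_frac * min(l, r)` (default 0.2), where
#' `l` and `r` are the bases aligned left and right of the junction.
#'
#' @param reads data.frame with `read_id`, `sample_id`, `seq` (see
#'   [read_unmapped_fastq])
#' @param txset [transcript_set]
#' @param mismatch_frac whole-read mismatch fraction cap (default 0.04)
#' @param side_frac per-side mismatch cap multiplier (default 0.2)
#' @return data.frame of junction evidence: `read_id`, `sample_id`,
#'   `transcript_id`, `parent_gene_id`, `junction`, `l`, `r`,
#'   `mismatches`, `seq`
#' @export
align_junction_reads <- function(reads, txset, mismatch_frac = 0.04,
                                 side_frac = 0.2) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    rlen <- nchar(reads$seq[i])
    max_mm <- floor(mismatch_frac * rlen)
    for (orient in c("fwd", "rev")) {
      pat <- Biostrings::DNAString(reads$seq[i])
      if (orient == "rev") pat <- Biostrings::reverseComplement(pat)
      for (tx in names(txset$seqs)) {
        juncs <- txset$junctions[[tx]]
        if (length(juncs) == 0L) next
        m <- Biostrings::matchPattern(pat, txset$seqs[[tx]],
                                      max.mismatch = max_mm,
                                      with.indels = FALSE)
        for (h in seq_along(m)) {
          s <- Biostrings::start(m)[h]
          e <- Biostrings::end(m)[h]
          mm <- Biostrings::neditAt(pat, txset$seqs[[tx]], at = s)
          crossed <- juncs[juncs >= s & juncs < e]
          for (J in crossed) {
            l <- J - s + 1L
            r <- e - J
            if (mm > mismatch_frac * rlen) next
            if (mm > side_frac * min(l, r)) next
            out[[length(out) + 1L]] <- data.frame(
              read_id = reads$read_id[i],
              sample_id = reads$sample_id[i],
              transcript_id = tx,
              parent_gene_id = unname(txset$gene_id[tx]),
              junction = which(juncs == J),
              l = l, r = r, mismatches = mm,
              seq = reads$seq[i])
          }
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), sample_id = character(0),
                      transcript_id = character(0),
                      parent_gene_id = character(0),
                      junction = integer(0), l = integer(0),
                      r = integer(0), mismatches = integer(0),
                      seq = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Junction-context genome hits and calling-cutoff adjustments
#'
#' Each exon-exon junction's context sequence (`context` bp either side)
#' is searched against the reference genome. A junction whose context hits
#' the genome at `min_identity` or better with at least `min_side` bp
#' aligned on both sides of the junction could mimic a junction read by
#' chance and is disqualified. A hit spanning the junction by `s <
#' min_side` bp raises the read-crossing cutoffs for that junction by `s`.
#' No qualifying hit leaves the cutoffs unchanged (adjustment 0).
#'
#' Hit discovery is pluggable: supply `hits` (a precomputed table with
#' columns `transcript_id`, `junction`, `identity`, `left_bp`,
#' `right_bp`), or a `genome` to search with a local aligner
#' ([Biostrings::pairwiseAlignment]; only hits covering at least half the
#' context are considered).
#'
#' @param txset [transcript_set]
#' @param genome named DNAStringSet, or NULL when `hits` is given
#' @param hits optional precomputed hit table (see above; best hit per
#'   junction)
#' @param context bases either side of the junction (default 20)
#' @param min_identity identity threshold for a qualifying hit
#'   (default 0.9)
#' @param min_side bp on each side that disqualifies a junction
#'   (default 10)
#' @return data.frame: `transcript_id`, `junction`, `adjustment`,
#'   `disqualified`
#' @export
compute_junction_genome_adjustment <- function(txset, genome = NULL,
                                               hits = NULL, context = 20L,
                                               min_identity = 0.9,
                                               min_side = 10L) {
  all_j <- do.call(rbind, lapply(names(txset$junctions), function(tx) {
    nj <- length(txset$junctions[[tx]])
    if (nj == 0L) return(NULL)
    data.frame(transcript_id = tx, junction = seq_len(nj))
  }))
  if (is.null(all_j))
    return(data.frame(transcript_id = character(0), junction = integer(0),
                      adjustment = integer(0), disqualified = logical(0)))
  all_j$adjustment <- 0L
  all_j$disqualified <- FALSE
  if (is.null(hits)) {
    if (is.null(genome))
      stop("dependency error: supply either `hits` or `genome`")
    hits <- .junction_context_hits(txset, genome, context, min_identity)
  }
  for (i in seq_len(nrow(all_j))) {
    h <- hits[hits$transcript_id == all_j$transcript_id[i] &
                hits$junction == all_j$junction[i], , drop = FALSE]
    if (nrow(h) == 0L) next
    h <- h[which.max(pmin(h$left_bp, h$right_bp)), ]
    if (h$identity < min_identity) next
    if (h$left_bp >= min_side && h$right_bp >= min_side) {
      all_j$disqualified[i] <- TRUE
    } else {
      s <- min(h$left_bp, h$right_bp)
      if (s > 0L) all_j$adjustment[i] <- as.integer(s)
    }
  }
  all_j
}

# local-alignment search of 2*context-bp junction contexts vs the genome
.junction_context_hits <- function(txset, genome, context, min_identity) {
  rows <- list()
  for (tx in names(txset$junctions)) {
    juncs <- txset$junctions[[tx]]
    seq <- txset$seqs[[tx]]
    for (j in seq_along(juncs)) {
      J <- juncs[j]
      s <- max(1L, J - context + 1L)
      e <- min(length(seq), J + context)
      ctx <- Biostrings::subseq(seq, s, e)
      jpos <- J - s + 1L  # left side length within context
      best <- NULL
      for (chrom in names(genome)) {
        for (strand_rc in c(FALSE, TRUE)) {
          subj <- if (strand_rc)
            Biostrings::reverseComplement(genome[[chrom]])
          else genome[[chrom]]
          al <- Biostrings::pairwiseAlignment(ctx, subj, type = "local")
          qr <- Biostrings::pattern(al)
          alen <- Biostrings::nchar(al)
          if (alen < (e - s + 1L) / 2) next
          idy <- Biostrings::pid(al) / 100
          qs <- Biostrings::start(qr@range)
          qe <- Biostrings::end(qr@range)
          left <- max(0L, jpos - qs + 1L)
          right <- max(0L, qe - jpos)
          cand <- list(identity = idy, left_bp = left, right_bp = right)
          if (is.null(best) ||
              min(cand$left_bp, cand$right_bp) * cand$identity >
              min(best$left_bp, best$right_bp) * best$identity)
            best <- cand
        }
      }
      if (!is.null(best) && best$identity >= min_identity)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx, junction = j, identity = best$identity,
          left_bp = best$left_bp, right_bp = best$right_bp)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), junction = integer(0),
                      identity = numeric(0), left_bp = integer(0),
                      right_bp = integer(0)))
  do.call(rbind, rows)
}

#' Call retroCNVs from exon-exon junction evidence
#'
#' A gene is called retrotransposed when, at any non-disqualified
#' junction, either (i) at least one read crosses the junction by at least
#' `one_read_bp` plus that junction's adjustment, or (ii) at least two
#' reads with distinct sequences (from any individuals) each cross it by
#' at least `two_read_bp` plus the adjustment. The crossing depth of a
#' read is `min(l, r)`. The retained exon set is the union of exons
#' flanking junctions with qualifying (rule-ii level) evidence.
#'
#' @param evidence data.frame from [align_junction_reads]
#' @param adjustments data.frame from
#'   [compute_junction_genome_adjustment]; NULL means all adjustments 0
#' @param one_read_bp single-read crossing cutoff (default 10)
#' @param two_read_bp two-distinct-read crossing cutoff (default 5)
#' @return data.frame of calls: `call_id`, `parent_gene_id`,
#'   `in_reference` (FALSE), `evidence` ("junction_reads"),
#'   `retained_exons` and `samples` list-columns
#' @export
call_junction_retrocnvs <- function(evidence, adjustments = NULL,
                                    one_read_bp = 10L, two_read_bp = 5L) {
  empty <- data.frame(call_id = character(0),
                      parent_gene_id = character(0),
                      in_reference = logical(0), evidence = character(0),
                      retained_exons = I(list()), samples = I(list()))
  if (nrow(evidence) == 0L) return(empty)
  ev <- evidence
  ev$adj <- 0L
  ev$disq <- FALSE
  if (!is.null(adjustments) && nrow(adjustments)) {
    m <- match(paste(ev$transcript_id, ev$junction),
               paste(adjustments$transcript_id, adjustments$junction))
    hit <- !is.na(m)
    ev$adj[hit] <- adjustments$adjustment[m[hit]]
    ev$disq[hit] <- adjustments$disqualified[m[hit]]
  }
  ev <- ev[!ev$disq, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  ev$cross <- pmin(ev$l, ev$r)
  calls <- list()
  for (gene in unique(ev$parent_gene_id)) {
    gv <- ev[ev$parent_gene_id == gene, , drop = FALSE]
    called <- FALSE
    qualifying <- gv[0, ]
    for (key in unique(paste(gv$transcript_id, gv$junction))) {
      jv <- gv[paste(gv$transcript_id, gv$junction) == key, , drop = FALSE]
      adj <- jv$adj[1]
      rule1 <- any(jv$cross >= one_read_bp + adj)
      qual <- jv[jv$cross >= two_read_bp + adj, , drop = FALSE]
      rule2 <- length(unique(qual$seq)) >= 2L
      if (rule1 || rule2) called <- TRUE
      qualifying <- rbind(qualifying, qual)
    }
    if (!called) next
    retained <- sort(unique(c(qualifying$junction,
                              qualifying$junction + 1L)))
    calls[[length(calls) + 1L]] <- data.frame(
      call_id = paste0("junc:", gene), parent_gene_id = gene,
      in_reference = FALSE, evidence = "junction_reads",
      retained_exons = I(list(retained)),
      samples = I(list(sort(unique(qualifying$sample_id)))))
  }
  if (length(calls) == 0L) return(empty)
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}
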