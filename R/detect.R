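#' Detect reference-present retroCNVs from deletion-signature pairs
#'
#' A retrocopy in the reference catalog is called polymorphic when, in at
#' least one individual (or pooled across individuals), more than
#' `min_support - 1` non-redundant read pairs (i) lie within `window` bp of
#' the retrocopy, (ii) map further apart than the library concordance
#' limit, and (iii) bracket the retrocopy without either read overlapping
#' it -- the signature of a haplotype lacking the insertion.
#'
#' Non-redundancy is per sample on the duplicate key
#' `(start1, start2)`.
#'
#' @param pairs data.frame of read pairs (all samples; see [read_pairs])
#' @param catalog retrocopy catalog from [build_retrocopy_catalog]
#' @param model [insert_size_model]
#' @param min_support minimum supporting pairs (default 6, i.e. strictly
#'   more than five)
#' @param window search window around each retrocopy in bp (default 5000)
#' @param pooled count support summed across samples instead of requiring
#'   `min_support` within one sample (default FALSE)
#' @return data.frame of calls: `call_id`, `retro_id`, `parent_gene_id`,
#'   `in_reference`, `chrom`, `start`, `end`, `evidence`, `support`
#'   (the maximal per-sample, or pooled, non-redundant count) and a
#'   `sample_support` list-column (named per-sample counts)
#' @export
detect_reference_retrocnvs <- function(pairs, catalog, model,
                                       min_support = 6L, window = 5000L,
                                       pooled = FALSE) {
  if (nrow(catalog) == 0L) return(.empty_ref_calls())
  same <- !is.na(pairs$chrom1) & !is.na(pairs$chrom2) &
    pairs$chrom1 == pairs$chrom2
  p <- pairs[same, , drop = FALSE]
  p$span <- .pair_span(p)
  p <- p[p$span > model$limit, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    r <- catalog[i, ]
    cand <- p[p$chrom1 == r$chrom, , drop = FALSE]
    if (nrow(cand) == 0L) next
    lo <- pmin(cand$start1, cand$start2)
    hi <- pmax(cand$end1, cand$end2)
    near <- hi >= r$start - window & lo <= r$end + window
    cand <- cand[near, , drop = FALSE]
    if (nrow(cand) == 0L) next
    left_end <- pmin(cand$end1, cand$end2)
    right_start <- pmax(cand$start1, cand$start2)
    bracket <- left_end < r$start & right_start > r$end
    cand <- cand[bracket, , drop = FALSE]
    if (nrow(cand) == 0L) next
    key <- paste(cand$start1, cand$start2)
    nr <- !duplicated(paste(cand$sample_id, key))
    cand <- cand[nr, , drop = FALSE]
    per_sample <- table(cand$sample_id)
    support <- if (pooled) sum(per_sample) else max(per_sample)
    if (support >= min_support) {
      out[[length(out) + 1L]] <- data.frame(
        call_id = paste0("ref:", r$retro_id),
        retro_id = r$retro_id, parent_gene_id = r$parent_gene_id,
        in_reference = TRUE, chrom = r$chrom, start = r$start,
        end = r$end, evidence = "spanning_pairs",
        support = as.integer(support),
        sample_support = I(list(c(per_sample))))
    }
  }
  if (length(out) == 0L) return(.empty_ref_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_ref_calls <- function() {
  data.frame(call_id = character(0), retro_id = character(0),
             parent_gene_id = character(0), in_reference = logical(0),
             chrom = character(0), start = integer(0), end = integer(0),
             evidence = character(0), support = integer(0),
             sample_support = I(list()))
}

# shared clustering engine for insertion-site discovery.
# anchor_exons: GRanges with mcol gene_id restricting where the anchored
# read may fall. pooled: count non-redundant support across samples.
.cluster_insertion_sites <- function(pairs, anchor_exons, catalog, repeats,
                                     model, min_support, exclusion_bp,
                                     pooled) {
  empty_sites <- data.frame(site_id = character(0), chrom = character(0),
                            point = integer(0),
                            parent_gene_id = character(0),
                            support = integer(0), n_samples = integer(0))
  empty_report <- data.frame(chrom = character(0), point = integer(0),
                             genes = character(0), support = integer(0),
                             reason = character(0))
  anchored <- list()
  for (side in 1:2) {
    a <- if (side == 1) c("chrom1", "start1", "end1", "strand1")
         else c("chrom2", "start2", "end2", "strand2")
    b <- if (side == 1) c("chrom2", "start2", "end2", "strand2")
         else c("chrom1", "start1", "end1", "strand1")
    ok <- !is.na(pairs[[a[1]]]) & !is.na(pairs[[b[1]]])
    pp <- pairs[ok, , drop = FALSE]
    if (nrow(pp) == 0L) next
    rd <- GenomicRanges::GRanges(pp[[a[1]]],
                                 IRanges::IRanges(pp[[a[2]]], pp[[a[3]]]))
    hits <- GenomicRanges::findOverlaps(rd, anchor_exons, type = "within",
                                        ignore.strand = TRUE)
    if (length(hits) == 0L) next
    genes_by_read <- split(anchor_exons$gene_id[S4Vectors::subjectHits(hits)],
                           S4Vectors::queryHits(hits))
    idx <- as.integer(names(genes_by_read))
    sel <- pp[idx, , drop = FALSE]
    span <- ifelse(sel[[a[1]]] == sel[[b[1]]],
                   pmax(sel[[a[3]]], sel[[b[3]]]) -
                     pmin(sel[[a[2]]], sel[[b[2]]]) + 1L, NA_integer_)
    distinct <- is.na(span) | span > model$limit
    sel <- sel[distinct, , drop = FALSE]
    genes_by_read <- genes_by_read[distinct]
    if (nrow(sel) == 0L) next
    anchored[[side]] <- data.frame(
      sample_id = sel$sample_id, qname = sel$qname,
      genes = I(lapply(genes_by_read, function(g) sort(unique(g)))),
      mate_chrom = sel[[b[1]]], mate_start = sel[[b[2]]],
      mate_end = sel[[b[3]]], mate_strand = sel[[b[4]]],
      key = paste(sel$start1, sel$start2))
  }
  anchored <- do.call(rbind, anchored)
  if (is.null(anchored) || nrow(anchored) == 0L)
    return(list(sites = empty_sites, report = empty_report))

  # assign each anchored pair to its parental gene(s); pairs whose
  # anchoring read hits exons of several genes count toward each
  anchored <- do.call(rbind, lapply(seq_len(nrow(anchored)), function(i) {
    gs <- anchored$genes[[i]]
    cbind(anchored[rep(i, length(gs)), c("sample_id", "qname",
                                         "mate_chrom", "mate_start",
                                         "mate_end", "mate_strand",
                                         "key")],
          gene = gs)
  }))

  # mate-side clustering per parental gene
  cand <- list()
  for (gene in unique(anchored$gene)) {
    ga <- anchored[anchored$gene == gene, , drop = FALSE]
    mates <- GenomicRanges::GRanges(ga$mate_chrom,
                                    IRanges::IRanges(ga$mate_start,
                                                     ga$mate_end))
    clusters <- GenomicRanges::reduce(
      mates, ignore.strand = TRUE,
      min.gapwidth = as.integer(model$limit))
    grp <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(mates, clusters, ignore.strand = TRUE))
    for (g in unique(grp)) {
      cl <- ga[grp == g, , drop = FALSE]
      # insertion point: midpoint between innermost mate edges by strand
      left <- cl$mate_strand == "+"
      pt <- if (any(left) && any(!left)) {
        a <- max(cl$mate_end[left]); b <- min(cl$mate_start[!left])
        as.integer(floor((a + b) / 2))
      } else if (any(left)) max(cl$mate_end[left])
      else min(cl$mate_start[!left])
      nr <- cl[!duplicated(paste(cl$sample_id, cl$key)), , drop = FALSE]
      support <- if (pooled) nrow(nr) else max(table(nr$sample_id))
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = cl$mate_chrom[1], point = pt, gene = gene,
        support = as.integer(support),
        n_samples = length(unique(cl$sample_id)))
    }
  }
  cand <- do.call(rbind, cand)

  sites <- list(); report <- list()
  gene_span <- attr(anchor_exons, "gene_span")
  # intra-mRNA discordant pairs (reads in two exons of the parent gene
  # separated by introns) cluster at the parental locus itself; the
  # parent gene can never be its own insertion site. These artifact
  # candidates are removed first so they cannot shadow genuine sites in
  # the two-gene ambiguity check below.
  at_parent <- vapply(seq_len(nrow(cand)), function(i) {
    if (is.null(gene_span) || !(cand$gene[i] %in% names(gene_span)))
      return(FALSE)
    site_gr <- GenomicRanges::GRanges(
      cand$chrom[i], IRanges::IRanges(cand$point[i], cand$point[i]))
    length(GenomicRanges::findOverlaps(site_gr, gene_span[cand$gene[i]],
                                       ignore.strand = TRUE)) > 0L
  }, logical(1))
  for (i in which(at_parent))
    report[[length(report) + 1L]] <- data.frame(
      chrom = cand$chrom[i], point = cand$point[i],
      genes = cand$gene[i], support = cand$support[i],
      reason = "parental_locus")
  cand <- cand[!at_parent, , drop = FALSE]

  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    rec <- function(reason)
      data.frame(chrom = cc$chrom, point = cc$point, genes = cc$gene,
                 support = cc$support, reason = reason)
    site_gr <- GenomicRanges::GRanges(cc$chrom,
                                      IRanges::IRanges(cc$point,
                                                       cc$point))
    # (d) the same locus implicated by two or more parental genes
    ambiguous <- any(cand$gene != cc$gene & cand$chrom == cc$chrom &
                       abs(cand$point - cc$point) <= model$limit)
    if (ambiguous) {
      report[[length(report) + 1L]] <- rec("multiple_parental_genes")
      next
    }
    if (nrow(catalog) > 0L) {
      cat_gr <- GenomicRanges::GRanges(
        catalog$chrom,
        IRanges::IRanges(pmax(1L, catalog$start - exclusion_bp),
                         catalog$end + exclusion_bp))
      if (length(GenomicRanges::findOverlaps(site_gr, cat_gr,
                                             ignore.strand = TRUE))) {
        report[[length(report) + 1L]] <- rec("near_known_retrocopy")
        next
      }
    }
    if (!is.null(repeats) && length(repeats) > 0L &&
        length(GenomicRanges::findOverlaps(site_gr, repeats,
                                           ignore.strand = TRUE))) {
      report[[length(report) + 1L]] <- rec("overlaps_repeat")
      next
    }
    if (cc$support < min_support) {
      report[[length(report) + 1L]] <- rec("insufficient_support")
      next
    }
    sites[[length(sites) + 1L]] <- data.frame(
      chrom = cc$chrom, point = cc$point, parent_gene_id = cc$gene,
      support = cc$support, n_samples = cc$n_samples)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else empty_sites
  if (nrow(sites)) {
    sites <- sites[order(sites$chrom, sites$point), , drop = FALSE]
    sites <- cbind(site_id = sprintf("site_%s_%d", sites$parent_gene_id,
                                     seq_len(nrow(sites))), sites)
    rownames(sites) <- NULL
  }
  report <- if (length(report)) do.call(rbind, report) else empty_report
  list(sites = sites, report = report)
}

#' Detect non-reference retroCNV insertion sites
#'
#' Clusters read pairs in which one read maps entirely inside exonic
#' sequence of a single putative parental gene while its mate maps to a
#' distinct region (another chromosome, or the same chromosome beyond the
#' concordance limit). Clusters are then excluded when (a) the insertion
#' point lies within `exclusion_bp` of a catalogued retrocopy, (b) it
#' overlaps a repeat interval, (c) non-redundant exon-anchored support is
#' at most `min_support - 1` pairs, or (d) the anchoring reads implicate
#' two or more parental genes. Excluded clusters are returned in a
#' machine-readable curation report.
#'
#' @inheritParams detect_reference_retrocnvs
#' @param gm gene_models annotation
#' @param repeats GRanges of repeat intervals (or NULL)
#' @param exclusion_bp exclusion distance around known retrocopies
#'   (default 2000)
#' @return list with `sites` (data.frame: `site_id`, `chrom`, `point`,
#'   `parent_gene_id`, `support`, `n_samples`) and `report` (excluded
#'   clusters with a `reason` each)
#' @export
detect_nonreference_insertion_sites <- function(pairs, gm, catalog, repeats,
                                                model, min_support = 6L,
                                                exclusion_bp = 2000L) {
  anchor <- gm$exons
  attr(anchor, "gene_span") <- gm$genes
  .cluster_insertion_sites(pairs, anchor, catalog, repeats, model,
                           min_support, exclusion_bp, pooled = FALSE)
}

#' Locate insertion sites for junction-only calls
#'
#' For retroCNVs discovered from exon-exon junction reads alone, pools
#' read pairs across all individuals (anchored in the 5'-most or 3'-most
#' exon of the putative parental gene) and attaches an insertion site when
#' more than `min_support - 1` pooled non-redundant pairs support one
#' locus, applying the same exclusion rules as
#' [detect_nonreference_insertion_sites].
#'
#' @param calls junction-call data.frame from [call_junction_retrocnvs]
#' @inheritParams detect_nonreference_insertion_sites
#' @return list with `calls` (input with `site_chrom`, `site_point`,
#'   `site_support` columns filled where located) and `report`
#' @export
locate_junction_insertion_sites <- function(calls, pairs, gm, catalog,
                                            repeats, model,
                                            min_support = 6L,
                                            exclusion_bp = 2000L) {
  calls$site_chrom <- NA_character_
  calls$site_point <- NA_integer_
  calls$site_support <- NA_integer_
  reports <- list()
  for (i in seq_len(nrow(calls))) {
    gene <- calls$parent_gene_id[i]
    ex <- gm$exons[gm$exons$gene_id == gene]
    terminal <- ex[ex$exon_rank == 1L |
                     ex$exon_rank == max(ex$exon_rank)]
    attr(terminal, "gene_span") <- gm$genes
    res <- .cluster_insertion_sites(pairs, terminal, catalog, repeats,
                                    model, min_support, exclusion_bp,
                                    pooled = TRUE)
    reports[[i]] <- res$report
    hit <- res$sites[res$sites$parent_gene_id == gene, , drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[which.max(hit$support), ]
      calls$site_chrom[i] <- hit$chrom
      calls$site_point[i] <- hit$point
      calls$site_support[i] <- hit$support
    }
  }
  list(calls = calls, report = do.call(rbind, reports))
}

#' Apply the discovery-set ascertainment scheme
#'
#' Harmonises ascertainment across reference-present and
#' reference-absent calls for frequency-sensitive contrasts: a call is
#' retained only when it has more than `min_pairs` supporting read pairs
#' for the non-reference allele in at least one of the discovery genomes.
#' Junction-read evidence is ignored entirely.
#'
#' @param calls data.frame of calls (must carry `call_id`)
#' @param support data.frame with `call_id`, `sample_id`, `n_pairs`:
#'   per-genome non-redundant read-pair support for the non-reference
#'   allele
#' @param discovery_samples character vector of discovery-genome ids
#' @param min_pairs support threshold (default 5; "more than five")
#' @return the retained subset of `calls`
#' @export
apply_discovery_ascertainment <- function(calls, support, discovery_samples,
                                          min_pairs = 5L) {
  ok <- support$sample_id %in% discovery_samples &
    support$n_pairs > min_pairs
  keep_ids <- unique(support$call_id[ok])
  calls[calls$call_id %in% keep_ids, , drop = FALSE]
}
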