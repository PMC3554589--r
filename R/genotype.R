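#' Genotype one retroCNV in one individual
#'
#' Applies the single-read genotyping rule: one supporting read or read
#' pair suffices for each evidence class, and an individual showing both
#' presence and absence evidence is heterozygous.
#'
#' For calls present in the reference genome, presence evidence is a pair
#' with one read inside the retrocopy and its mate in the flank; absence
#' evidence is a pair spanning the retrocopy without overlapping it at
#' deletion-signature distance (beyond the concordance limit). For calls
#' absent from the reference, presence evidence is a pair with one read in
#' a parental exon and its mate at the insertion point, or a junction read
#' crossing by at least `junction_bp` plus the junction's adjustment;
#' absence evidence is a pair mapping across the insertion point at
#' concordant distance and orientation.
#'
#' States: both classes -> `het`; presence only -> `hom_present`
#' (or `present_unknown_zygosity` when the only presence evidence is
#' junction reads and no informative pairs exist); absence only ->
#' `hom_absent`; neither -> `unknown`.
#'
#' @param call one-row data.frame describing the retroCNV. Reference-
#'   present calls need `chrom`, `start`, `end`; reference-absent calls
#'   need `site_chrom`, `site_point` and `parent_gene_id`.
#' @param pairs this sample's read pairs (see [read_pairs])
#' @param junctions this sample's junction evidence
#'   ([align_junction_reads] rows, optionally with an `adj` column), or
#'   NULL
#' @param model [insert_size_model]
#' @param gm gene_models annotation (required for reference-absent calls)
#' @param junction_bp junction crossing depth counting as presence
#'   (default 5)
#' @param flank bp of flank in which a presence-pair mate may fall
#'   (defaults to the concordance limit)
#' @return data.frame row: `sample_id`, `call_id`, `state`,
#'   `n_presence_reads`, `n_absence_reads`, `junction_only`
#' @export
genotype_retrocnv <- function(call, pairs, junctions = NULL, model,
                              gm = NULL, junction_bp = 5L, flank = NULL) {
  if (is.null(flank)) flank <- model$limit
  sample_id <- if (nrow(pairs)) pairs$sample_id[1]
    else if (!is.null(junctions) && nrow(junctions)) junctions$sample_id[1]
    else NA_character_
  n_pres <- 0L; n_abs <- 0L; junction_pres <- 0L
  p <- pairs
  if (isTRUE(call$in_reference)) {
    same <- !is.na(p$chrom1) & !is.na(p$chrom2) &
      p$chrom1 == call$chrom & p$chrom2 == call$chrom
    pp <- p[same, , drop = FALSE]
    if (nrow(pp)) {
      in1 <- pp$end1 >= call$start & pp$start1 <= call$end
      in2 <- pp$end2 >= call$start & pp$start2 <= call$end
      near1 <- !in1 & pp$end1 >= call$start - flank &
        pp$start1 <= call$end + flank
      near2 <- !in2 & pp$end2 >= call$start - flank &
        pp$start2 <= call$end + flank
      n_pres <- sum((in1 & near2) | (in2 & near1))
      span <- .pair_span(pp)
      left_end <- pmin(pp$end1, pp$end2)
      right_start <- pmax(pp$start1, pp$start2)
      n_abs <- sum(left_end < call$start & right_start > call$end &
                     span > model$limit, na.rm = TRUE)
    }
  } else {
    if (is.na(call$site_chrom) || is.null(gm)) {
      # junction-only call: presence evidence can still come from
      # junction reads below; pairs are uninformative
      pp <- p[0, , drop = FALSE]
    }
    if (!is.na(call$site_chrom)) {
      ex <- gm$exons[gm$exons$gene_id == call$parent_gene_id]
      pt <- call$site_point
      for (side in 1:2) {
        a <- if (side == 1) c("chrom1", "start1", "end1")
             else c("chrom2", "start2", "end2")
        b <- if (side == 1) c("chrom2", "start2", "end2")
             else c("chrom1", "start1", "end1")
        ok <- !is.na(p[[a[1]]]) & !is.na(p[[b[1]]])
        pp <- p[ok, , drop = FALSE]
        if (!nrow(pp)) next
        rd <- GenomicRanges::GRanges(pp[[a[1]]],
                                     IRanges::IRanges(pp[[a[2]]],
                                                      pp[[a[3]]]))
        in_exon <- GenomicRanges::countOverlaps(rd, ex, type = "within",
                                                ignore.strand = TRUE) > 0L
        at_site <- pp[[b[1]]] == call$site_chrom &
          pp[[b[3]]] >= pt - flank & pp[[b[2]]] <= pt + flank
        n_pres <- n_pres + sum(in_exon & at_site)
      }
      same <- !is.na(p$chrom1) & !is.na(p$chrom2) &
        p$chrom1 == call$site_chrom & p$chrom2 == call$site_chrom
      pp <- p[same, , drop = FALSE]
      if (nrow(pp)) {
        span <- .pair_span(pp)
        left_end <- pmin(pp$end1, pp$end2)
        right_start <- pmax(pp$start1, pp$start2)
        opp <- pp$strand1 != pp$strand2
        n_abs <- sum(left_end < pt & right_start > pt & opp &
                       span <= model$limit, na.rm = TRUE)
      }
    }
    if (!is.null(junctions) && nrow(junctions)) {
      jv <- junctions[junctions$parent_gene_id == call$parent_gene_id, ,
                      drop = FALSE]
      if (nrow(jv)) {
        adj <- if (!is.null(jv$adj)) jv$adj else 0L
        junction_pres <- sum(pmin(jv$l, jv$r) >= junction_bp + adj)
      }
    }
  }
  total_pres <- n_pres + junction_pres
  state <- if (total_pres > 0L && n_abs > 0L) "het"
  else if (total_pres > 0L) {
    if (n_pres == 0L && junction_pres > 0L) "present_unknown_zygosity"
    else "hom_present"
  } else if (n_abs > 0L) "hom_absent"
  else "unknown"
  data.frame(sample_id = sample_id, call_id = call$call_id, state = state,
             n_presence_reads = as.integer(total_pres),
             n_absence_reads = as.integer(n_abs),
             junction_only = n_pres == 0L & junction_pres > 0L)
}

#' Genotype a retroCNV across a cohort
#'
#' Convenience loop over [genotype_retrocnv] for a multi-sample pair
#' table.
#'
#' @inheritParams genotype_retrocnv
#' @param pairs all samples' read pairs
#' @param junctions all samples' junction evidence (or NULL)
#' @param samples sample ids to genotype (default: those present in
#'   `pairs`)
#' @return data.frame with one row per sample
#' @export
genotype_cohort <- function(call, pairs, junctions = NULL, model,
                            gm = NULL, samples = NULL, ...) {
  if (is.null(samples)) samples <- sort(unique(pairs$sample_id))
  res <- lapply(samples, function(s) {
    g <- genotype_retrocnv(
      call, pairs[pairs$sample_id == s, , drop = FALSE],
      if (is.null(junctions)) NULL
      else junctions[junctions$sample_id == s, , drop = FALSE],
      model, gm, ...)
    g$sample_id <- s
    g
  })
  do.call(rbind, res)
}

#' Estimate retroCNV allele frequency under Hardy-Weinberg equilibrium
#'
#' Because low coverage undercalls heterozygotes and junction reads give
#' no zygosity, frequency estimation starts from the carrier fraction
#' `f` (individuals with any presence evidence over individuals with any
#' evidence). Under HWE, `f = p^2 + 2pq` and `1 - f = q^2`, so
#' `q = sqrt(1 - f)` and `p = 1 - sqrt(1 - f)`.
#'
#' @param genotypes data.frame with a `state` column (as produced by
#'   [genotype_retrocnv])
#' @param population optional population label
#' @return data.frame row: `population`, `f`, `p`, `q`, `n_genotyped`,
#'   `at_fixation` (TRUE when `f == 1`: the true frequency is below but
#'   approaching 1)
#' @export
estimate_allele_frequency <- function(genotypes, population = NA_character_) {
  known <- genotypes$state != "unknown"
  n <- sum(known)
  if (n == 0L) stop("no-data: all genotypes unknown")
  carrier <- genotypes$state %in%
    c("hom_present", "het", "present_unknown_zygosity")
  f <- sum(carrier & known) / n
  q <- sqrt(1 - f)
  p <- 1 - q
  data.frame(population = population, f = f, p = p, q = q,
             n_genotyped = n, at_fixation = f == 1)
}

#' Expected pairwise copy-number differences
#'
#' The expected number of gene copy-number differences between two random
#' individuals contributed by a set of retroCNVs is the sum over loci of
#' `2 p q` (the chance the two differ at a locus under HWE, per
#' chromosome pair).
#'
#' @param frequencies data.frame with columns `p` and `q` (one row per
#'   retroCNV; see [estimate_allele_frequency])
#' @return numeric: sum of `2 p q` across loci
#' @export
expected_pairwise_differences <- function(frequencies) {
  sum(2 * frequencies$p * frequencies$q)
}

#' Prepare the genotype matrix for external phasing
#'
#' Adjusts reference-absent retroCNV genotypes before handing them to a
#' phasing tool, using junction-read evidence: (1) an individual called
#' homozygous absent from pairs but with junction support becomes
#' heterozygous; (2) an individual with no pair data but junction support
#' is set to carrying the retroCNV on one chromosome with the other
#' chromosome unknown (code `"P"`).
#'
#' @param genotypes character/numeric matrix, samples x calls, with
#'   values in `0` (hom absent), `1` (het), `2` (hom present), `NA`
#'   (unknown)
#' @param junction_presence logical matrix of the same shape: junction
#'   evidence of presence
#' @return character matrix with values in `{"0","1","2","P",NA}`
#' @export
prepare_phased_input <- function(genotypes, junction_presence) {
  stopifnot(all(dim(genotypes) == dim(junction_presence)))
  out <- matrix(as.character(genotypes), nrow = nrow(genotypes),
                dimnames = dimnames(genotypes))
  rule1 <- !is.na(genotypes) & genotypes == 0 & junction_presence
  out[rule1] <- "1"
  rule2 <- is.na(genotypes) & junction_presence
  out[rule2] <- "P"
  out
}

#' Write / read the genotype matrix TSV
#'
#' Rows are samples, columns are call ids; values are `0`, `1`, `2`,
#' `P` (present, zygosity unknown) or `NA`.
#'
#' @param mat matrix as from [prepare_phased_input]
#' @param path output file
#' @return `path` invisibly (writer); matrix (reader)
#' @export
write_genotype_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Detect chimeric host-retrocopy transcripts from RNA-seq pairs
#'
#' For a retroCNV inserted inside a host gene, counts RNA-seq read pairs
#' with one read in an exon of the retroCNV's parental gene (or in the
#' retrocopy itself when present in the reference) and the mate in an
#' exon of the host gene. The locus is called chimeric when at least
#' `min_support` such pairs exist.
#'
#' @param rna_pairs RNA-seq read pairs (see [read_pairs])
#' @param call one-row call data.frame with `parent_gene_id`,
#'   `host_gene_id` and, for reference-present calls, `chrom`, `start`,
#'   `end`
#' @param gm gene_models annotation
#' @param min_support minimum supporting pairs (default 5)
#' @return list with `n_support` and `chimeric`
#' @export
detect_chimeric_read_pairs <- function(rna_pairs, call, gm,
                                       min_support = 5L) {
  if (is.null(call$host_gene_id) || is.na(call$host_gene_id))
    stop("not-applicable: retroCNV is not inserted in a gene")
  parent_ex <- GenomicRanges::granges(
    gm$exons[gm$exons$gene_id == call$parent_gene_id])
  if (isTRUE(call$in_reference) && !is.null(call$chrom) &&
      !is.na(call$chrom))
    parent_ex <- c(parent_ex,
                   GenomicRanges::GRanges(call$chrom,
                                          IRanges::IRanges(call$start,
                                                           call$end)))
  host_ex <- GenomicRanges::granges(
    gm$exons[gm$exons$gene_id == call$host_gene_id])
  in_set <- function(chrom, start, end, set) {
    ok <- !is.na(chrom)
    res <- logical(length(chrom))
    if (any(ok)) {
      gr <- GenomicRanges::GRanges(chrom[ok],
                                   IRanges::IRanges(start[ok], end[ok]))
      res[ok] <- GenomicRanges::countOverlaps(gr, set,
                                              ignore.strand = TRUE) > 0L
    }
    res
  }
  p1_parent <- in_set(rna_pairs$chrom1, rna_pairs$start1, rna_pairs$end1,
                      parent_ex)
  p2_parent <- in_set(rna_pairs$chrom2, rna_pairs$start2, rna_pairs$end2,
                      parent_ex)
  p1_host <- in_set(rna_pairs$chrom1, rna_pairs$start1, rna_pairs$end1,
                    host_ex)
  p2_host <- in_set(rna_pairs$chrom2, rna_pairs$start2, rna_pairs$end2,
                    host_ex)
  n <- sum((p1_parent & p2_host) | (p2_parent & p1_host))
  list(n_support = as.integer(n), chimeric = n >= min_support)
}
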