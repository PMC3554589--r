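#' Classify the genomic context of a retrocopy insertion site
#'
#' Assigns each insertion site to one of three categories: `exonic` (the
#' site overlaps an exon of the host gene), `intronic` (the site falls
#' inside a gene's span but overlaps no exon), or `intergenic`. When a site
#' overlaps several genes the host is the gene with the smallest span
#' (ties broken lexicographically by gene id); a site touching both an exon
#' of one transcript and an intron of another transcript of the host gene
#' is called exonic. The relative strand is `sense` when the retrocopy and
#' host gene strands agree, `antisense` otherwise, and `n/a` for
#' intergenic sites.
#'
#' @param site GRanges of length 1 (the insertion point or interval)
#' @param gm gene_models annotation
#' @param retro_strand strand of the inserted retrocopy ("+", "-" or "*")
#' @param known_chroms chromosome names considered part of the annotation;
#'   defaults to the chromosomes carrying genes. A site on a chromosome
#'   outside this set raises an `unknown_chromosome` error.
#' @return list with `category`, `host_gene_id` (NA for intergenic) and
#'   `relative_strand`
#' @examples
#' gm <- gene_models(data.frame(
#'   chrom = "chr1", start = c(101, 901), end = c(200, 1000),
#'   strand = "+", gene_id = "gA", tx_id = "gA.t1"))
#' site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 500))
#' classify_insertion_context(site, gm, "-")
#' @export
classify_insertion_context <- function(site, gm, retro_strand = "*",
                                       known_chroms = NULL) {
  stopifnot(length(site) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(site))
  if (is.null(known_chroms))
    known_chroms <- unique(as.character(GenomicRanges::seqnames(gm$genes)))
  if (!chrom %in% known_chroms)
    stop("unknown_chromosome: ", chrom)
  if (!chrom %in% unique(as.character(GenomicRanges::seqnames(gm$genes))))
    return(list(category = "intergenic", host_gene_id = NA_character_,
                relative_strand = "n/a"))
  hits <- GenomicRanges::findOverlaps(site, gm$genes, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(list(category = "intergenic", host_gene_id = NA_character_,
                relative_strand = "n/a"))
  cand <- S4Vectors::subjectHits(hits)
  spans <- GenomicRanges::width(gm$genes)[cand]
  ids <- names(gm$genes)[cand]
  host_i <- cand[order(spans, ids)][1L]
  host_id <- names(gm$genes)[host_i]
  host_strand <- as.character(GenomicRanges::strand(gm$genes)[host_i])
  host_exons <- gm$exons[gm$exons$gene_id == host_id]
  exonic <- length(GenomicRanges::findOverlaps(
    site, host_exons, ignore.strand = TRUE)) > 0L
  list(
    category = if (exonic) "exonic" else "intronic",
    host_gene_id = host_id,
    relative_strand = if (retro_strand %in% c("+", "-") &&
                          host_strand %in% c("+", "-")) {
      if (retro_strand == host_strand) "sense" else "antisense"
    } else "n/a")
}

#' Classify retrocopy movement between chromosome classes
#'
#' Labels each parent-to-insertion movement by whether the parental gene
#' and the new copy reside on the X chromosome or an autosome:
#' `"A->A"`, `"X->X"`, `"X->A"` or `"A->X"`. Vectorised.
#'
#' @param parent_chrom chromosome of the parental gene
#' @param target_chrom chromosome of the insertion
#' @param x_names chromosome names treated as X
#' @return character vector of movement classes
#' @examples
#' classify_movement(c("chr2", "chrX"), c("chr7", "chr7"))
#' @export
classify_movement <- function(parent_chrom, target_chrom,
                              x_names = c("chrX", "X")) {
  stopifnot(length(parent_chrom) == length(target_chrom),
            all(nzchar(parent_chrom)), all(nzchar(target_chrom)))
  from_x <- parent_chrom %in% x_names
  to_x <- target_chrom %in% x_names
  paste0(ifelse(from_x, "X", "A"), "->", ifelse(to_x, "X", "A"))
}

#' Collapse movement classes for contingency contrasts
#'
#' Groups movements into the two rows used when contrasting polymorphic
#' against fixed retrocopies: movements staying within a chromosome class
#' (`A->A` or `X->X`) versus movements between classes (`A->X` or `X->A`).
#'
#' @param movement character vector from [classify_movement]
#' @return factor with levels `"within"` and `"between"`
#' @export
movement_group <- function(movement) {
  factor(ifelse(movement %in% c("A->A", "X->X"), "within", "between"),
         levels = c("within", "between"))
}
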