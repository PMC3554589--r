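#' Gene model container
#'
#' Bundles per-transcript exon structures into the annotation object used
#' throughout the package. Internally everything is a [GenomicRanges::GRanges]
#' of exons (1-based, closed coordinates) with `gene_id`, `tx_id` and
#' `exon_rank` metadata columns; gene and transcript spans are derived.
#'
#' `exon_rank` numbers exons 1..m in transcript (5' to 3') order, so rank 1
#' is the 5'-most exon regardless of strand.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `tx_id` and optionally `exon_rank` (assigned by coordinate
#'   order, strand-aware, when absent). Coordinates are 1-based closed.
#' @return An object of class `gene_models` with elements `exons`
#'   (a `GRanges`), `genes` (per-gene span `GRanges`, names = gene ids) and
#'   `tx` (per-transcript span `GRanges`, names = transcript ids).
#' @examples
#' gm <- gene_models(data.frame(
#'   chrom = "chr1", start = c(101, 501, 901), end = c(200, 600, 1000),
#'   strand = "+", gene_id = "gA", tx_id = "gA.t1"))
#' n_exons(gm, "gA.t1")
#' @export
gene_models <- function(exons) {
  stopifnot(is.data.frame(exons),
            all(c("chrom", "start", "end", "strand", "gene_id", "tx_id")
                %in% names(exons)))
  if (any(exons$end < exons$start))
    stop("exon end < start")
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand,
    gene_id = as.character(exons$gene_id),
    tx_id = as.character(exons$tx_id))
  if (!is.null(exons$exon_rank)) {
    gr$exon_rank <- as.integer(exons$exon_rank)
  } else {
    gr$exon_rank <- NA_integer_
    for (tx in unique(gr$tx_id)) {
      i <- which(gr$tx_id == tx)
      o <- order(GenomicRanges::start(gr)[i])
      if (as.character(GenomicRanges::strand(gr)[i][1]) == "-") o <- rev(o)
      gr$exon_rank[i[o]] <- seq_along(i)
    }
  }
  # within-transcript exons must be disjoint
  for (tx in unique(gr$tx_id)) {
    i <- which(gr$tx_id == tx)
    if (length(IRanges::reduce(GenomicRanges::ranges(gr[i]))) != length(i) &&
        !all(IRanges::width(IRanges::reduce(GenomicRanges::ranges(gr[i])))
             == sum(IRanges::width(GenomicRanges::ranges(gr[i])))))
      stop("overlapping exons within transcript ", tx)
  }
  genes <- unlist(range(GenomicRanges::split(gr, gr$gene_id)))
  tx <- unlist(range(GenomicRanges::split(gr, gr$tx_id)))
  structure(list(exons = gr, genes = genes, tx = tx),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,", length(x$tx),
      "transcripts,", length(x$exons), "exons\n")
  invisible(x)
}

#' Number of exons of a transcript
#' @param gm gene_models object
#' @param tx_id transcript identifier
#' @return integer exon count
#' @export
n_exons <- function(gm, tx_id) {
  sum(gm$exons$tx_id == tx_id)
}

#' Multi-exon gene identifiers
#' @param gm gene_models object
#' @return character vector of genes having >= 2 exons in any transcript
#' @export
multi_exon_genes <- function(gm) {
  tab <- table(gm$exons$tx_id)
  multi_tx <- names(tab)[tab >= 2]
  unique(gm$exons$gene_id[gm$exons$tx_id %in% multi_tx])
}

#' Read gene models from GFF3
#'
#' Thin wrapper over [rtracklayer::import] keeping exon features. Expects
#' `ID`/`Parent` style attributes with exons carrying `gene_id` and
#' `transcript_id` (as written by [write_gene_models_gff3]) or standard
#' `Parent` chains.
#'
#' @param path GFF3 file
#' @return gene_models object
#' @export
read_gene_models_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  ex <- g[g$type == "exon"]
  gene_id <- ex$gene_id
  tx_id <- ex$transcript_id
  if (is.null(gene_id) || all(is.na(gene_id))) {
    # fall back to Parent chains: exon Parent = transcript ID "gene.tx"
    par <- as.character(S4Vectors::unstrand(ex)$Parent)
    tx_id <- par
    gene_id <- sub("\\.[^.]*$", "", par)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = gene_id, tx_id = tx_id)
  if (!is.null(ex$exon_rank)) df$exon_rank <- as.integer(ex$exon_rank)
  gene_models(df)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features with `gene_id`, `transcript_id` and
#' `exon_rank` attributes. Coordinates round-trip exactly through
#' [read_gene_models_gff3].
#'
#' @param gm gene_models object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gene_models_gff3 <- function(gm, path) {
  ex <- gm$exons
  exg <- ex
  exg$type <- "exon"
  exg$ID <- paste0(ex$tx_id, ".exon", ex$exon_rank)
  exg$Parent <- ex$tx_id
  exg$transcript_id <- ex$tx_id
  txg <- gm$tx
  txg$type <- "mRNA"
  txg$ID <- names(txg)
  txg$transcript_id <- names(txg)
  txg$gene_id <- ex$gene_id[match(names(txg), ex$tx_id)]
  txg$Parent <- txg$gene_id
  gg <- gm$genes
  gg$type <- "gene"
  gg$ID <- names(gg)
  gg$gene_id <- names(gg)
  all <- suppressWarnings(c(gg, txg, exg))
  names(all) <- NULL
  all$source <- "retrocnv"
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read repeat annotation
#'
#' Accepts either a RepeatMasker `.out` file (whitespace-delimited, three
#' header lines) or a BED file, producing a `GRanges` with a `family`
#' metadata column.
#'
#' @param path input file; format guessed from extension (`.out` vs `.bed`)
#'   unless `format` is given
#' @param format `"repeatmasker"` or `"bed"`
#' @return GRanges of repeat intervals with `family`
#' @export
read_repeats <- function(path, format = c("auto", "repeatmasker", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "repeatmasker"
  if (format == "bed") {
    r <- rtracklayer::import(path, format = "bed")
    fam <- if (is.null(r$name)) rep(NA_character_, length(r)) else r$name
    r$family <- fam
    return(r)
  }
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]  # RM header block
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges(family = character(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  mat <- do.call(rbind, lapply(fields, function(f) f[c(5, 6, 7, 10)]))
  GenomicRanges::GRanges(
    seqnames = mat[, 1],
    ranges = IRanges::IRanges(as.integer(mat[, 2]), as.integer(mat[, 3])),
    family = mat[, 4])
}

#' Write genomic intervals as BED
#'
#' @param gr GRanges, optionally with `name` and `score` metadata
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into a GRanges
#' @param path BED file
#' @return GRanges
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}
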