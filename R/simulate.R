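#' Simulation configuration
#'
#' Defines a toy study: a small multi-chromosome reference with
#' multi-exon genes, fixed retrocopies, and segregating retroCNV events
#' realised in a diploid cohort sequenced with paired-end reads. The
#' defaults emulate the study conditions used throughout the package's
#' tests: a 20-individual cohort at 20x coverage with 100-bp reads and a
#' 400 +/- 50 bp fragment library, and three retroCNV events (one present
#' in the reference, one inserted into an intron of another gene, one
#' intergenic and absent from the reference).
#'
#' @param seed mandatory integer seed
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param n_genes number of multi-exon genes (placed round-robin)
#' @param exons_per_gene exons per gene
#' @param exon_bp,intron_bp exon and intron lengths
#' @param n_fixed_retro fixed (monomorphic) retrocopies
#' @param events data.frame of retroCNV events with columns `parent`
#'   (gene index), `in_reference`, `frequency` (presence allele
#'   frequency), `truncation` (fraction of the 5' mRNA removed),
#'   `context` ("intergenic" or "intronic"), or NULL for the default
#'   three events
#' @param cohort_n diploid individuals
#' @param coverage haploid-pair coverage (total read bases / genome)
#' @param read_len read length (bp)
#' @param insert_mean,insert_sd fragment length distribution (bp)
#' @param n_repeats repeat intervals to annotate in intergenic space
#' @return `simulation_config` list
#' @export
simulation_config <- function(seed,
                              chrom_lengths = c(chr1 = 40000,
                                                chr2 = 40000),
                              n_genes = 6L, exons_per_gene = 5L,
                              exon_bp = 150L, intron_bp = 350L,
                              n_fixed_retro = 2L, events = NULL,
                              cohort_n = 20L, coverage = 20,
                              read_len = 100L, insert_mean = 400,
                              insert_sd = 50, n_repeats = 2L) {
  stopifnot(!missing(seed), coverage > 0, cohort_n >= 1)
  if (is.null(events))
    events <- data.frame(
      parent = c(1L, 2L, 3L),
      in_reference = c(TRUE, FALSE, FALSE),
      frequency = c(0.5, 0.3, 0.3),
      truncation = c(0, 0, 0),
      context = c("intergenic", "intergenic", "intronic"))
  stopifnot(all(events$frequency > 0 & events$frequency < 1))
  structure(list(seed = seed, chrom_lengths = chrom_lengths,
                 n_genes = n_genes, exons_per_gene = exons_per_gene,
                 exon_bp = exon_bp, intron_bp = intron_bp,
                 n_fixed_retro = n_fixed_retro, events = events,
                 cohort_n = cohort_n, coverage = coverage,
                 read_len = read_len, insert_mean = insert_mean,
                 insert_sd = insert_sd, n_repeats = n_repeats),
            class = "simulation_config")
}

.rand_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate a reference genome carrying retrocopies
#'
#' Builds a random-sequence genome with multi-exon genes, injects
#' `n_fixed_retro` fixed retrocopies (spliced parent mRNA sequence placed
#' in intergenic space), materialises the configured retroCNV events
#' (reference-present events are written into the reference; reference-
#' absent events get a planned insertion point only), annotates repeat
#' intervals, and draws per-sample diploid genotypes at each event from
#' its allele frequency (Hardy-Weinberg: each haplotype carries the
#' insertion independently with probability `frequency`).
#'
#' @param config [simulation_config]
#' @return `simulation` list: `genome` (DNAStringSet), `gm`
#'   ([gene_models]), `repeats` (GRanges), `events` (truth table, one row
#'   per event: locations, retained exons), `fixed` (fixed retrocopy
#'   table), `haplotypes` (cohort x 2 x events carrier array),
#'   `genotypes` (cohort x events matrix), `alignments` (synthetic
#'   transcript-to-genome alignments for catalog construction), `config`
#' @export
simulate_reference_with_retrocopies <- function(config) {
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  n_chrom <- length(chroms)

  # abstract gene designs
  genes <- lapply(seq_len(config$n_genes), function(i) {
    m <- config$exons_per_gene
    list(gene_id = sprintf("g%02d", i),
         tx_id = sprintf("g%02d.t1", i),
         chrom = chroms[((i - 1) %% n_chrom) + 1],
         strand = "+",
         exon_len = rep(config$exon_bp, m),
         intron_len = rep(config$intron_bp, m - 1),
         exon_seq = vapply(seq_len(m),
                           function(k) .rand_dna(config$exon_bp), ""))
  })
  names(genes) <- vapply(genes, `[[`, "", "gene_id")

  ev <- config$events
  ev$event_id <- sprintf("ev%d", seq_len(nrow(ev)))
  ev$parent_gene <- vapply(ev$parent, function(i) genes[[i]]$gene_id, "")

  # mRNA (5'->3') of a gene is the concatenation of its exon sequences
  mrna_of <- function(g) paste(g$exon_seq, collapse = "")
  retro_seq_of <- function(g, trunc_frac) {
    s <- mrna_of(g)
    drop <- floor(nchar(s) * trunc_frac)
    substr(s, drop + 1L, nchar(s))
  }
  retained_of <- function(g, trunc_frac) {
    cum <- cumsum(g$exon_len)
    drop <- floor(sum(g$exon_len) * trunc_frac)
    which(cum > drop)
  }

  # fixed retrocopies use the last genes as parents (distinct from events)
  fixed_parents <- rev(seq_len(config$n_genes))[seq_len(config$n_fixed_retro)]
  fixed <- if (config$n_fixed_retro > 0)
    data.frame(retro_id = sprintf("fix%d", seq_len(config$n_fixed_retro)),
               parent_gene = vapply(fixed_parents,
                                    function(i) genes[[i]]$gene_id, ""))
  else data.frame(retro_id = character(0), parent_gene = character(0))

  # chromosome layout: alternating spacers / genes, then retro slots.
  # Retro elements (fixed + reference-present events) land on the next
  # chromosome after their parent's so flanking evidence is unambiguous.
  layout <- lapply(chroms, function(ch) list())
  names(layout) <- chroms
  add <- function(ch, el) layout[[ch]][[length(layout[[ch]]) + 1L]] <<- el
  for (ch in chroms) add(ch, list(type = "spacer", len = 2000L))
  for (g in genes) {
    add(g$chrom, list(type = "gene", id = g$gene_id))
    add(g$chrom, list(type = "spacer", len = 2500L))
  }
  other_chrom <- function(ch) chroms[(match(ch, chroms) %% n_chrom) + 1L]
  for (i in seq_len(nrow(fixed))) {
    g <- genes[[fixed$parent_gene[i]]]
    ch <- other_chrom(g$chrom)
    add(ch, list(type = "retro", id = fixed$retro_id[i],
                 seq = retro_seq_of(g, 0), parent = g$gene_id,
                 strand = "+"))
    add(ch, list(type = "spacer", len = 2500L))
  }
  for (i in seq_len(nrow(ev))) {
    g <- genes[[ev$parent_gene[i]]]
    ch <- other_chrom(g$chrom)
    if (isTRUE(ev$in_reference[i])) {
      add(ch, list(type = "retro", id = ev$event_id[i],
                   seq = retro_seq_of(g, ev$truncation[i]),
                   parent = g$gene_id, strand = "+"))
      add(ch, list(type = "spacer", len = 2500L))
    } else if (ev$context[i] == "intergenic") {
      add(ch, list(type = "ins_point", id = ev$event_id[i]))
      add(ch, list(type = "spacer", len = 2500L))
    }
    # intronic insertion points are resolved after coordinates are known
  }
  for (r in seq_len(config$n_repeats)) {
    ch <- chroms[((r - 1) %% n_chrom) + 1]
    add(ch, list(type = "repeat", id = sprintf("rep%d", r), len = 600L))
    add(ch, list(type = "spacer", len = 1500L))
  }

  # realise coordinates and sequence
  exon_rows <- list()
  retro_rows <- list()
  repeat_rows <- list()
  ins_points <- list()
  seqs <- character(n_chrom)
  names(seqs) <- chroms
  for (ch in chroms) {
    cursor <- 1L
    parts <- character(0)
    for (el in layout[[ch]]) {
      if (el$type == "spacer" || el$type == "repeat") {
        parts <- c(parts, .rand_dna(el$len))
        if (el$type == "repeat")
          repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
            chrom = ch, start = cursor, end = cursor + el$len - 1L,
            family = "SimSat")
        cursor <- cursor + el$len
      } else if (el$type == "gene") {
        g <- genes[[el$id]]
        gene_seq <- character(0)
        pos <- cursor
        for (k in seq_along(g$exon_len)) {
          exon_rows[[length(exon_rows) + 1L]] <- data.frame(
            chrom = ch, start = pos, end = pos + g$exon_len[k] - 1L,
            strand = g$strand, gene_id = g$gene_id, tx_id = g$tx_id,
            genomic_order = k)
          gene_seq <- c(gene_seq, g$exon_seq[k])
          pos <- pos + g$exon_len[k]
          if (k < length(g$exon_len)) {
            gene_seq <- c(gene_seq, .rand_dna(g$intron_len[k]))
            pos <- pos + g$intron_len[k]
          }
        }
        parts <- c(parts, paste(gene_seq, collapse = ""))
        cursor <- pos
      } else if (el$type == "retro") {
        len <- nchar(el$seq)
        retro_rows[[length(retro_rows) + 1L]] <- data.frame(
          id = el$id, parent_gene = el$parent, chrom = ch,
          start = cursor, end = cursor + len - 1L, strand = el$strand)
        parts <- c(parts, el$seq)
        cursor <- cursor + len
      } else if (el$type == "ins_point") {
        ins_points[[el$id]] <- list(chrom = ch, point = cursor)
        # zero-length in the reference
      }
    }
    tail_len <- config$chrom_lengths[[ch]] - (cursor - 1L)
    if (tail_len < 0)
      stop("placement failure: chromosome ", ch, " too short by ",
           -tail_len, " bp")
    parts <- c(parts, .rand_dna(tail_len))
    seqs[ch] <- paste(parts, collapse = "")
  }

  exon_df <- do.call(rbind, exon_rows)
  # exon_rank is 5'->3' in the transcript: reverse for minus-strand genes
  exon_df$exon_rank <- exon_df$genomic_order
  for (g in genes)
    if (g$strand == "-") {
      i <- which(exon_df$gene_id == g$gene_id)
      exon_df$exon_rank[i] <- max(exon_df$genomic_order[i]) + 1L -
        exon_df$genomic_order[i]
    }
  gm <- gene_models(exon_df[, c("chrom", "start", "end", "strand",
                                "gene_id", "tx_id", "exon_rank")])
  # genes are simulated on the plus strand so the spliced mRNA is the
  # plain concatenation of exon sequences; strand-aware classification is
  # exercised with hand-built annotations in the unit tests instead
  retro_df <- if (length(retro_rows)) do.call(rbind, retro_rows)
  else data.frame(id = character(0), parent_gene = character(0),
                  chrom = character(0), start = integer(0),
                  end = integer(0), strand = character(0))

  # resolve intronic insertion points: first intron of a host gene on a
  # chromosome other than the parent's
  for (i in seq_len(nrow(ev))) {
    if (!isTRUE(ev$in_reference[i]) && ev$context[i] == "intronic") {
      g <- genes[[ev$parent_gene[i]]]
      host <- Filter(function(h) h$chrom != g$chrom &&
                       h$gene_id != g$gene_id, genes)[[1]]
      hx <- exon_df[exon_df$gene_id == host$gene_id, ]
      hx <- hx[order(hx$genomic_order), ]
      pt <- as.integer(floor((hx$end[1] + hx$start[2]) / 2))
      ins_points[[ev$event_id[i]]] <- list(chrom = hx$chrom[1],
                                           point = pt,
                                           host = host$gene_id)
    }
  }

  ev$chrom <- rep(NA_character_, nrow(ev))
  ev$start <- rep(NA_integer_, nrow(ev))
  ev$end <- rep(NA_integer_, nrow(ev))
  ev$point <- rep(NA_integer_, nrow(ev))
  ev$host_gene <- rep(NA_character_, nrow(ev))
  ev$retained <- I(vector("list", nrow(ev)))
  for (i in seq_len(nrow(ev))) {
    g <- genes[[ev$parent_gene[i]]]
    ev$retained[[i]] <- retained_of(g, ev$truncation[i])
    if (isTRUE(ev$in_reference[i])) {
      r <- retro_df[retro_df$id == ev$event_id[i], ]
      ev$chrom[i] <- r$chrom
      ev$start[i] <- r$start
      ev$end[i] <- r$end
    } else {
      ip <- ins_points[[ev$event_id[i]]]
      ev$chrom[i] <- ip$chrom
      ev$point[i] <- ip$point
      if (!is.null(ip$host)) ev$host_gene[i] <- ip$host
    }
  }

  # diploid cohort: each haplotype carries each event w.p. frequency
  samples <- sprintf("s%02d", seq_len(config$cohort_n))
  hap <- array(0L, dim = c(config$cohort_n, 2L, nrow(ev)),
               dimnames = list(samples, c("h1", "h2"), ev$event_id))
  for (i in seq_len(nrow(ev)))
    hap[, , i] <- matrix(rbinom(2L * config$cohort_n, 1L,
                                ev$frequency[i]),
                         ncol = 2L)
  genotypes <- apply(hap, c(1, 3), sum)

  # synthetic transcript-to-genome alignments (catalog input): each
  # parent transcript aligns to its own locus (one block per exon) and
  # each retro locus aligns as a single gapless block
  aln <- list()
  for (g in genes) {
    gx <- exon_df[exon_df$gene_id == g$gene_id, ]
    gx <- gx[order(gx$genomic_order), ]
    cum <- cumsum(g$exon_len)
    qstarts <- c(1L, head(cum, -1) + 1L)
    aln[[length(aln) + 1L]] <- transcript_alignments(
      g$tx_id, g$gene_id, g$chrom, g$strand,
      min(gx$start), max(gx$end), 1,
      list(data.frame(qstart = qstarts, tstart = gx$start,
                      size = g$exon_len)))
  }
  all_retro <- rbind(
    if (nrow(fixed)) data.frame(id = fixed$retro_id,
                                parent_gene = fixed$parent_gene,
                                trunc = 0),
    if (any(ev$in_reference)) data.frame(
      id = ev$event_id[ev$in_reference],
      parent_gene = ev$parent_gene[ev$in_reference],
      trunc = ev$truncation[ev$in_reference]))
  for (i in seq_len(NROW(all_retro))) {
    r <- retro_df[retro_df$id == all_retro$id[i], ]
    g <- genes[[all_retro$parent_gene[i]]]
    drop <- floor(sum(g$exon_len) * all_retro$trunc[i])
    aln[[length(aln) + 1L]] <- transcript_alignments(
      g$tx_id, g$gene_id, r$chrom, r$strand, r$start, r$end, 1,
      list(data.frame(qstart = drop + 1L, tstart = r$start,
                      size = r$end - r$start + 1L)))
  }
  alignments <- do.call(rbind, aln)

  genome <- Biostrings::DNAStringSet(seqs)
  repeats <- if (length(repeat_rows)) {
    rp <- do.call(rbind, repeat_rows)
    GenomicRanges::GRanges(rp$chrom, IRanges::IRanges(rp$start, rp$end),
                           family = rp$family)
  } else GenomicRanges::GRanges()

  structure(list(genome = genome, gm = gm, repeats = repeats,
                 events = ev, fixed = merge(fixed, retro_df,
                                            by.x = "retro_id", by.y = "id")[
                   , c("retro_id", "parent_gene.x", "chrom", "start",
                       "end", "strand")] |>
                   stats::setNames(c("retro_id", "parent_gene", "chrom",
                                     "start", "end", "strand")),
                 haplotypes = hap, genotypes = genotypes,
                 alignments = alignments,
                 genes = genes, samples = samples, config = config),
            class = "simulation")
}

#' @export
print.simulation <- function(x, ...) {
  cat("simulation:", length(x$genome), "chromosomes,",
      length(x$gm$genes), "genes,", nrow(x$events), "retroCNV events,",
      length(x$samples), "samples\n")
  invisible(x)
}

# transcript metadata needed to project insert-mapped reads back onto
# parental exons: cumulative transcript offsets and genomic exon coords
.tx_meta <- function(sim, gene_id) {
  g <- sim$genes[[gene_id]]
  gx <- sim$gm$exons[sim$gm$exons$gene_id == gene_id]
  gx <- gx[order(GenomicRanges::start(gx))]
  # transcript-order exon list equals genomic order for '+' parents; the
  # default configs only use '+' parents for events
  cum <- cumsum(g$exon_len)
  list(qstart = c(1L, head(cum, -1) + 1L), qend = cum,
       gstart = GenomicRanges::start(gx), gend = GenomicRanges::end(gx),
       junctions = head(cum, -1), total = sum(g$exon_len))
}

#' Simulate cohort paired-end reads
#'
#' Realises each individual's two haplotypes per chromosome (applying the
#' event insertions/deletions that the haplotype carries), draws
#' fragments at the configured coverage with Normal(insert_mean,
#' insert_sd) lengths, and projects each read back onto the reference the
#' way a short-read mapper would see it: reads inside an inserted
#' retrocopy map to the parental gene's exons (or fail to map when they
#' cross an exon-exon junction -- these become the unmapped junction
#' reads), reads spanning an insertion breakpoint fail to map, and reads
#' spanning a deleted reference retrocopy map with inflated separation
#' (the deletion signature).
#'
#' @param sim simulation from [simulate_reference_with_retrocopies]
#' @param samples subset of sample ids (default all)
#' @return list with `pairs` (mapped mate pairs, all samples) and
#'   `unmapped` (data.frame `read_id`, `sample_id`, `seq`)
#' @export
simulate_cohort_reads <- function(sim, samples = NULL) {
  config <- sim$config
  if (is.null(samples)) samples <- sim$samples
  set.seed(config$seed + 1L)
  rl <- config$read_len
  pairs_out <- list()
  unmapped_out <- list()
  ev <- sim$events
  for (s in samples) {
    for (h in 1:2) {
      for (ch in names(sim$genome)) {
        ref_seq <- as.character(sim$genome[[ch]])
        ref_len <- nchar(ref_seq)
        # modifications on this chromosome for this haplotype
        mods <- list()
        for (i in seq_len(nrow(ev))) {
          carrier <- sim$haplotypes[s, h, ev$event_id[i]] == 1L
          if (isTRUE(ev$in_reference[i]) && !carrier &&
              ev$chrom[i] == ch)
            mods[[length(mods) + 1L]] <- list(kind = "del",
                                              start = ev$start[i],
                                              end = ev$end[i])
          if (!isTRUE(ev$in_reference[i]) && carrier &&
              ev$chrom[i] == ch) {
            g <- sim$genes[[ev$parent_gene[i]]]
            mrna <- paste(g$exon_seq, collapse = "")
            drop <- floor(nchar(mrna) * ev$truncation[i])
            mods[[length(mods) + 1L]] <- list(
              kind = "ins", point = ev$point[i],
              seq = substr(mrna, drop + 1L, nchar(mrna)),
              m0 = drop, gene = ev$parent_gene[i])
          }
        }
        # build segment map (haplotype coords -> reference/insert)
        segs <- list()
        hap_parts <- character(0)
        cur_ref <- 1L
        cur_hap <- 1L
        ord <- order(vapply(mods, function(m)
          if (m$kind == "del") m$start else m$point, 1))
        for (m in mods[ord]) {
          if (m$kind == "del") {
            pre_len <- m$start - cur_ref
            if (pre_len > 0) {
              segs[[length(segs) + 1L]] <- list(
                kind = "ref", hs = cur_hap, he = cur_hap + pre_len - 1L,
                ref_start = cur_ref)
              hap_parts <- c(hap_parts,
                             substr(ref_seq, cur_ref, m$start - 1L))
              cur_hap <- cur_hap + pre_len
            }
            cur_ref <- m$end + 1L
          } else {
            pre_len <- m$point - cur_ref + 1L
            if (pre_len > 0) {
              segs[[length(segs) + 1L]] <- list(
                kind = "ref", hs = cur_hap, he = cur_hap + pre_len - 1L,
                ref_start = cur_ref)
              hap_parts <- c(hap_parts,
                             substr(ref_seq, cur_ref, m$point))
              cur_hap <- cur_hap + pre_len
              cur_ref <- m$point + 1L
            }
            ins_len <- nchar(m$seq)
            segs[[length(segs) + 1L]] <- list(
              kind = "ins", hs = cur_hap, he = cur_hap + ins_len - 1L,
              m0 = m$m0, gene = m$gene)
            hap_parts <- c(hap_parts, m$seq)
            cur_hap <- cur_hap + ins_len
          }
        }
        if (cur_ref <= ref_len) {
          segs[[length(segs) + 1L]] <- list(
            kind = "ref", hs = cur_hap,
            he = cur_hap + (ref_len - cur_ref), ref_start = cur_ref)
          hap_parts <- c(hap_parts, substr(ref_seq, cur_ref, ref_len))
          cur_hap <- cur_hap + (ref_len - cur_ref) + 1L
        }
        hap_seq <- paste(hap_parts, collapse = "")
        hap_len <- nchar(hap_seq)
        seg_hs <- vapply(segs, `[[`, 1L, "hs")
        seg_he <- vapply(segs, `[[`, 1L, "he")

        map_read <- function(a, b, strand) {
          i1 <- findInterval(a, seg_hs)
          i2 <- findInterval(b, seg_hs)
          if (i1 != i2 || i1 == 0L)
            return(NULL)                  # breakpoint-spanning: unmapped
          sg <- segs[[i1]]
          if (sg$kind == "ref")
            return(list(chrom = ch,
                        start = sg$ref_start + (a - sg$hs),
                        end = sg$ref_start + (b - sg$hs),
                        strand = strand))
          tm <- .tx_meta(sim, sg$gene)
          ma <- sg$m0 + (a - sg$hs) + 1L
          mb <- sg$m0 + (b - sg$hs) + 1L
          if (any(tm$junctions >= ma & tm$junctions < mb))
            return(NULL)                  # junction-crossing: unmapped
          k <- which(tm$qstart <= ma & tm$qend >= mb)[1]
          list(chrom = as.character(GenomicRanges::seqnames(
                 sim$gm$genes[sg$gene])),
               start = tm$gstart[k] + (ma - tm$qstart[k]),
               end = tm$gstart[k] + (mb - tm$qstart[k]),
               strand = strand)
        }

        n_frag <- rpois(1, hap_len * config$coverage /
                          (4 * rl))
        if (n_frag == 0L) next
        flen <- pmax(2L * rl + 10L,
                     round(rnorm(n_frag, config$insert_mean,
                                 config$insert_sd)))
        fs <- floor(runif(n_frag, 1, hap_len - flen + 1))
        ok <- fs >= 1 & fs + flen - 1 <= hap_len
        fs <- fs[ok]; flen <- flen[ok]
        nf <- length(fs)
        c1 <- c2 <- s1c <- s2c <- rep(NA_character_, nf)
        p1 <- p2 <- e1 <- e2 <- rep(NA_integer_, nf)
        qn <- sprintf("%s_h%d_%s_%d", s, h, ch, seq_len(nf))
        for (f in seq_len(nf)) {
          a1 <- fs[f]; b1 <- a1 + rl - 1L
          b2 <- fs[f] + flen[f] - 1L; a2 <- b2 - rl + 1L
          m1 <- map_read(a1, b1, "+")
          m2 <- map_read(a2, b2, "-")
          if (is.null(m1)) {
            unmapped_out[[length(unmapped_out) + 1L]] <- data.frame(
              read_id = paste0(qn[f], "/1"), sample_id = s,
              seq = substr(hap_seq, a1, b1))
          } else {
            c1[f] <- m1$chrom; p1[f] <- m1$start; e1[f] <- m1$end
            s1c[f] <- m1$strand
          }
          if (is.null(m2)) {
            unmapped_out[[length(unmapped_out) + 1L]] <- data.frame(
              read_id = paste0(qn[f], "/2"), sample_id = s,
              seq = as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(substr(hap_seq, a2, b2)))))
          } else {
            c2[f] <- m2$chrom; p2[f] <- m2$start; e2[f] <- m2$end
            s2c[f] <- m2$strand
          }
        }
        pairs_out[[length(pairs_out) + 1L]] <- data.frame(
          sample_id = s, qname = qn, chrom1 = c1, start1 = p1, end1 = e1,
          strand1 = s1c, chrom2 = c2, start2 = p2, end2 = e2,
          strand2 = s2c)
      }
    }
  }
  pairs <- do.call(rbind, pairs_out)
  pairs <- pairs[!(is.na(pairs$chrom1) & is.na(pairs$chrom2)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  unmapped <- if (length(unmapped_out)) do.call(rbind, unmapped_out)
  else data.frame(read_id = character(0), sample_id = character(0),
                  seq = character(0))
  list(pairs = pairs, unmapped = unmapped)
}

#' Write a simulation to disk in standard formats
#'
#' Emits reference FASTA, gene models GFF3, repeats BED, truth TSVs, the
#' per-sample SAM files and the unmapped-read FASTQ, so the pipeline can
#' be run from files alone.
#'
#' @param sim simulation object
#' @param reads result of [simulate_cohort_reads] (or NULL to skip reads)
#' @param dir output directory (created)
#' @return named vector of paths, invisibly
#' @export
write_simulation <- function(sim, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             gff = file.path(dir, "genes.gff3"),
             repeats = file.path(dir, "repeats.bed"),
             events = file.path(dir, "truth_events.tsv"),
             genotypes = file.path(dir, "truth_genotypes.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["fasta"])
  write_gene_models_gff3(sim$gm, paths["gff"])
  if (length(sim$repeats)) write_bed(sim$repeats, paths["repeats"])
  evout <- sim$events
  evout$retained <- vapply(evout$retained, paste, "", collapse = ",")
  write.table(evout, paths["events"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = rownames(sim$genotypes),
                         sim$genotypes, check.names = FALSE),
              paths["genotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(reads)) {
    ref_len <- stats::setNames(Biostrings::width(sim$genome),
                               names(sim$genome))
    for (s in unique(reads$pairs$sample_id)) {
      p <- file.path(dir, paste0(s, ".sam"))
      write_sam(reads$pairs[reads$pairs$sample_id == s, , drop = FALSE],
                ref_len, p)
      paths[paste0("sam_", s)] <- p
    }
    fq <- file.path(dir, "unmapped.fastq")
    con <- file(fq, "w")
    for (i in seq_len(nrow(reads$unmapped)))
      writeLines(c(paste0("@", reads$unmapped$read_id[i]),
                   reads$unmapped$seq[i], "+",
                   strrep("I", nchar(reads$unmapped$seq[i]))), con)
    close(con)
    paths["fastq"] <- fq
  }
  invisible(paths)
}
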