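# shared fixture builders and independent oracles

# small hand-built annotation: three multi-exon genes on two chromosomes
hand_gm <- function() {
  gene_models(data.frame(
    chrom = c("chrA", "chrA", "chrA", "chrA", "chrA", "chrB", "chrB"),
    start = c(1000, 1500, 2000, 5000, 5400, 1000, 1400),
    end = c(1199, 1699, 2199, 5199, 5599, 1199, 1599),
    strand = c("+", "+", "+", "-", "-", "+", "+"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC", "gC"),
    tx_id = c("gA.t1", "gA.t1", "gA.t1", "gB.t1", "gB.t1", "gC.t1",
              "gC.t1")))
}

hand_catalog <- function() {
  data.frame(retro_id = "retroZ", parent_gene_id = "gC", chrom = "chrB",
             start = 12000L, end = 12800L, strand = "+",
             n_exons_retained = 2L, retained_exons = I(list(1:2)))
}

hand_repeats <- function() {
  GenomicRanges::GRanges("chrB", IRanges::IRanges(9500, 9700),
                         family = "AluSim")
}

hand_model <- function() insert_size_model(400, 50, 3)  # limit 550

# build an exon-anchored pair: read1 inside an exon, read2 at the mate
# locus; reads are 100 bp
anchored_pair <- function(sample, i, anchor_chrom, anchor_start,
                          mate_chrom, mate_start, mate_strand = "+") {
  read_pairs(sample, sprintf("%s_q%d", sample, i),
             anchor_chrom, anchor_start, anchor_start + 99L, "+",
             mate_chrom, mate_start, mate_start + 99L, mate_strand)
}

# exact two-sided Fisher p by hypergeometric enumeration (independent of
# stats::fisher.test): sums point probabilities <= observed
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  x <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) -
                 lchoose(n, r1))
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force per-site pi: mean Hamming distance over all row pairs
pi_brute <- function(mat) {
  k <- nrow(mat)
  tot <- 0
  for (i in seq_len(k - 1))
    for (j in (i + 1):k)
      tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / (choose(k, 2) * ncol(mat))
}

# brute-force junction filter: recompute l, r and apply the mismatch
# rule directly from a read, a transcript sequence and a hit position
junction_filter_brute <- function(read, txseq, start, junctions,
                                  mismatch_frac = 0.04, side_frac = 0.2) {
  len <- nchar(read)
  hit <- substr(txseq, start, start + len - 1)
  mm <- sum(strsplit(read, "")[[1]] != strsplit(hit, "")[[1]])
  out <- list()
  for (J in junctions) {
    if (J < start || J >= start + len - 1) next
    l <- J - start + 1
    r <- (start + len - 1) - J
    keep <- mm <= mismatch_frac * len && mm <= side_frac * min(l, r)
    out[[length(out) + 1]] <- data.frame(junction = J, l = l, r = r,
                                         mismatches = mm, keep = keep)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

rand_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# mutate k positions of a DNA string (guaranteed different base)
mutate_str <- function(s, at) {
  v <- strsplit(s, "")[[1]]
  for (i in at) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  paste(v, collapse = "")
}
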