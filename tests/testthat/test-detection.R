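test_that("insert-size model estimates mean/SD and concordance limit", {
  # 150 pairs spanning exactly 2000 bp (outer fragment length)
  starts <- seq(1000, by = 37, length.out = 150)
  p <- read_pairs("s1", paste0("q", 1:150), "chr1", starts, starts + 49,
                  "+", "chr1", starts + 1950, starts + 1999, "-")
  m <- fit_insert_size_model(p)
  expect_equal(m$mean, 2000)
  expect_equal(m$sd, 0)
  expect_equal(m$limit, 2000)
  # limit arithmetic: mean 400, sd 50, k = 3 -> 550
  expect_equal(insert_size_model(400, 50, 3)$limit, 550)
  # too few concordant pairs
  expect_error(fit_insert_size_model(p[1:20, ]), "insufficient-data")
  # sampling recovery from Normal(mu, sigma)
  set.seed(7)
  n <- 400; mu <- 400; sigma <- 50
  flen <- round(rnorm(n, mu, sigma))
  st <- sample(1:100000, n)
  p2 <- read_pairs("s1", paste0("r", 1:n), "chr1", st, st + 99, "+",
                   "chr1", st + flen - 100, st + flen - 1, "-")
  m2 <- fit_insert_size_model(p2)
  expect_lt(abs(m2$mean - mu), 3 * sigma / sqrt(n))
})

# bracketing deletion-signature pairs around the hand catalog retrocopy
# (chrB:12000-12800), spans ~1300 > limit 550
bracket_pairs <- function(sample, n, jitter = 0) {
  starts <- 11800 - seq_len(n) * 7 + jitter
  read_pairs(sample, sprintf("%s_b%d", sample, seq_len(n)),
             "chrB", starts, starts + 99, "+",
             "chrB", starts + 1200, starts + 1299, "-")
}

test_that("reference retroCNV calling needs more than five bracketing pairs", {
  catalog <- hand_catalog()
  model <- hand_model()
  calls6 <- detect_reference_retrocnvs(bracket_pairs("s1", 6), catalog,
                                       model)
  expect_equal(nrow(calls6), 1L)
  expect_equal(calls6$retro_id, "retroZ")
  expect_equal(calls6$support, 6L)
  expect_true(calls6$in_reference)
  calls5 <- detect_reference_retrocnvs(bracket_pairs("s1", 5), catalog,
                                       model)
  expect_equal(nrow(calls5), 0L)
  # duplicate pairs (same start coordinates) are not double counted
  dup <- rbind(bracket_pairs("s1", 5), bracket_pairs("s1", 5))
  expect_equal(nrow(detect_reference_retrocnvs(dup, catalog, model)), 0L)
  # pooled mode sums across samples
  pooled <- rbind(bracket_pairs("s1", 3), bracket_pairs("s2", 3,
                                                        jitter = 3))
  expect_equal(nrow(detect_reference_retrocnvs(pooled, catalog, model)),
               0L)
  expect_equal(nrow(detect_reference_retrocnvs(pooled, catalog, model,
                                               pooled = TRUE)), 1L)
  # empty catalog -> empty result
  expect_equal(nrow(detect_reference_retrocnvs(
    bracket_pairs("s1", 6), catalog[0, ], model)), 0L)
})

test_that("pairs overlapping or not bracketing the retrocopy never support a call", {
  catalog <- hand_catalog()
  model <- hand_model()
  # one read overlaps the retrocopy
  st <- 11950 - seq_len(8) * 5
  overl <- read_pairs("s1", paste0("o", 1:8), "chrB", st, st + 99, "+",
                      "chrB", st + 1200, st + 1299, "-")
  expect_equal(nrow(detect_reference_retrocnvs(overl, catalog, model)),
               0L)
  # concordant-distance pairs on one side
  st2 <- 10800 - seq_len(8) * 5
  conc <- read_pairs("s1", paste0("c", 1:8), "chrB", st2, st2 + 99, "+",
                     "chrB", st2 + 300, st2 + 399, "-")
  expect_equal(nrow(detect_reference_retrocnvs(conc, catalog, model)),
               0L)
})

test_that("raising min_support never adds reference calls (monotonicity)", {
  sim <- simulate_reference_with_retrocopies(simulation_config(seed = 31,
                                                               cohort_n = 6L))
  reads <- simulate_cohort_reads(sim)
  model <- fit_insert_size_model(reads$pairs)
  catalog <- build_retrocopy_catalog(sim$alignments, sim$gm)
  prev <- NULL
  for (ms in c(2L, 6L, 12L, 25L)) {
    calls <- detect_reference_retrocnvs(reads$pairs, catalog, model,
                                        min_support = ms)
    if (!is.null(prev))
      expect_true(all(calls$retro_id %in% prev))
    prev <- calls$retro_id
  }
})

test_that("insertion-site clustering applies the published exclusion rules", {
  gm <- hand_gm()
  catalog <- hand_catalog()
  repeats <- hand_repeats()
  model <- hand_model()
  mk_cluster <- function(sample, n, mate_start, anchor_start = 1000,
                         chrom = "chrB") {
    do.call(rbind, lapply(seq_len(n), function(i)
      anchored_pair(sample, i, "chrA", anchor_start + i * 3, chrom,
                    mate_start + i * 5, "+")))
  }
  # 6 non-redundant anchored pairs, no exclusions -> site near chrB:8000
  res <- detect_nonreference_insertion_sites(mk_cluster("s1", 6, 7600),
                                             gm, catalog, repeats, model)
  expect_equal(nrow(res$sites), 1L)
  expect_equal(res$sites$parent_gene_id, "gA")
  expect_equal(res$sites$support, 6L)
  expect_lt(abs(res$sites$point - 7729), 60)
  # (c) five pairs are insufficient; the exclusion is reported
  res5 <- detect_nonreference_insertion_sites(mk_cluster("s1", 5, 7600),
                                              gm, catalog, repeats, model)
  expect_equal(nrow(res5$sites), 0L)
  expect_equal(res5$report$reason, "insufficient_support")
  # (a) insertion point within 2 kb of the catalog retrocopy
  resa <- detect_nonreference_insertion_sites(mk_cluster("s1", 6, 10600),
                                              gm, catalog, repeats, model)
  expect_equal(nrow(resa$sites), 0L)
  expect_true("near_known_retrocopy" %in% resa$report$reason)
  # (b) insertion point overlapping a repeat
  resb <- detect_nonreference_insertion_sites(mk_cluster("s1", 6, 9450),
                                              gm, catalog, repeats, model)
  expect_equal(nrow(resb$sites), 0L)
  expect_true("overlaps_repeat" %in% resb$report$reason)
  # (d) anchors implicating two parental genes at one locus
  two_genes <- rbind(mk_cluster("s1", 6, 7600),
                     do.call(rbind, lapply(1:6, function(i)
                       anchored_pair("s1", 100 + i, "chrA", 5000 + i * 3,
                                     "chrB", 7600 + i * 5, "+"))))
  resd <- detect_nonreference_insertion_sites(two_genes, gm, catalog,
                                              repeats, model)
  expect_equal(nrow(resd$sites), 0L)
  expect_true(all(resd$report$reason == "multiple_parental_genes"))
})

test_that("junction read filtering applies both mismatch caps", {
  # transcript: two 60-bp exons; junction after position 60
  set.seed(5)
  exon1 <- rand_dna_str(60); exon2 <- rand_dna_str(60)
  genome_seq <- paste0(rand_dna_str(200), exon1, rand_dna_str(80), exon2,
                       rand_dna_str(200))
  gm <- gene_models(data.frame(chrom = "chrT",
                               start = c(201, 341), end = c(260, 400),
                               strand = "+", gene_id = "gT",
                               tx_id = "gT.t1"))
  genome <- Biostrings::DNAStringSet(c(chrT = genome_seq))
  txset <- transcript_set(gm, genome)
  expect_equal(txset$junctions[["gT.t1"]], 60L)
  tx <- as.character(txset$seqs[["gT.t1"]])
  # 50-bp read crossing with l = 20, r = 30
  base <- substr(tx, 41, 90)
  reads <- data.frame(
    read_id = c("keep2mm", "rej3mm", "rej_l5"),
    sample_id = "s1",
    seq = c(mutate_str(base, c(5, 10)),
            mutate_str(base, c(5, 10, 15)),
            mutate_str(substr(tx, 56, 105), c(20, 30))))  # l=5, r=45
  ev <- align_junction_reads(reads, txset)
  expect_equal(sort(unique(ev$read_id)), "keep2mm")
  expect_equal(ev$l[ev$read_id == "keep2mm"], 20L)
  expect_equal(ev$r[ev$read_id == "keep2mm"], 30L)
  expect_equal(ev$mismatches[ev$read_id == "keep2mm"], 2L)
})

test_that("streaming junction filter matches brute-force on random fixtures", {
  set.seed(11)
  for (rep in 1:20) {
    exons <- replicate(3, rand_dna_str(70))
    gm <- gene_models(data.frame(
      chrom = "chrT", start = c(101, 301, 501), end = c(170, 370, 570),
      strand = "+", gene_id = "gT", tx_id = "gT.t1"))
    genome <- Biostrings::DNAStringSet(c(chrT = paste0(
      rand_dna_str(100), exons[1], rand_dna_str(130), exons[2],
      rand_dna_str(130), exons[3], rand_dna_str(100))))
    txset <- transcript_set(gm, genome)
    tx <- as.character(txset$seqs[["gT.t1"]])
    start <- sample(1:160, 1)
    nmm <- sample(0:3, 1)
    read <- substr(tx, start, start + 49)
    if (nmm > 0) read <- mutate_str(read, sample(1:50, nmm))
    ev <- align_junction_reads(
      data.frame(read_id = "r", sample_id = "s", seq = read), txset)
    brute <- junction_filter_brute(read, tx, start,
                                   txset$junctions[["gT.t1"]])
    kept_brute <- if (is.null(brute)) 0L else sum(brute$keep)
    expect_equal(nrow(ev), kept_brute)
    if (kept_brute > 0) {
      b <- brute[brute$keep, ]
      expect_setequal(ev$l, b$l)
      expect_setequal(ev$mismatches, b$mismatches)
    }
  }
})

test_that("junction-context genome hits adjust or disqualify junctions", {
  txset <- structure(list(
    seqs = Biostrings::DNAStringSet(c(gJ.t1 = strrep("ACGT", 30))),
    junctions = list(gJ.t1 = c(40L, 80L)),
    gene_id = c(gJ.t1 = "gJ")), class = "transcript_set")
  hits <- data.frame(transcript_id = "gJ.t1", junction = c(1L, 2L),
                     identity = c(0.95, 0.95),
                     left_bp = c(7L, 20L), right_bp = c(20L, 15L))
  adj <- compute_junction_genome_adjustment(txset, hits = hits)
  # hit spanning the junction by 7 bp raises cutoffs by 7 (10->17, 5->12)
  expect_equal(adj$adjustment[adj$junction == 1L], 7L)
  expect_false(adj$disqualified[adj$junction == 1L])
  # >= 10 bp on both sides at >= 90% identity disqualifies
  expect_true(adj$disqualified[adj$junction == 2L])
  # no hit at all -> adjustment 0
  adj0 <- compute_junction_genome_adjustment(
    txset, hits = hits[0, ])
  expect_equal(adj0$adjustment, c(0L, 0L))
  expect_false(any(adj0$disqualified))
  # low-identity hit is ignored
  weak <- data.frame(transcript_id = "gJ.t1", junction = 1L,
                     identity = 0.8, left_bp = 7L, right_bp = 20L)
  expect_equal(compute_junction_genome_adjustment(
    txset, hits = weak)$adjustment[1], 0L)
})

test_that("junction calling rules: one deep read or two distinct shallow reads", {
  mk_ev <- function(l, r, seq, sample = "s1")
    data.frame(read_id = paste0("r", seq), sample_id = sample,
               transcript_id = "gJ.t1", parent_gene_id = "gJ",
               junction = 1L, l = l, r = r, mismatches = 0L, seq = seq)
  # one read crossing by 10 -> call
  expect_equal(nrow(call_junction_retrocnvs(mk_ev(10L, 40L, "AAA"))), 1L)
  # one read crossing by 9 -> no call
  expect_equal(nrow(call_junction_retrocnvs(mk_ev(9L, 41L, "AAA"))), 0L)
  # 9-bp read plus a distinct 5-bp read -> call (rule ii)
  two <- rbind(mk_ev(9L, 41L, "AAA"), mk_ev(45L, 5L, "CCC"))
  expect_equal(nrow(call_junction_retrocnvs(two)), 1L)
  # two identical sequences do not satisfy rule ii
  same <- rbind(mk_ev(9L, 41L, "AAA"), mk_ev(9L, 41L, "AAA", "s2"))
  expect_equal(nrow(call_junction_retrocnvs(same)), 0L)
  # adjustment 7: 16 bp is not enough (needs 17), 17 calls
  adj <- data.frame(transcript_id = "gJ.t1", junction = 1L,
                    adjustment = 7L, disqualified = FALSE)
  expect_equal(nrow(call_junction_retrocnvs(mk_ev(16L, 34L, "AAA"),
                                            adj)), 0L)
  expect_equal(nrow(call_junction_retrocnvs(mk_ev(17L, 33L, "AAA"),
                                            adj)), 1L)
  # disqualified junction contributes nothing
  disq <- data.frame(transcript_id = "gJ.t1", junction = 1L,
                     adjustment = 0L, disqualified = TRUE)
  expect_equal(nrow(call_junction_retrocnvs(mk_ev(30L, 20L, "AAA"),
                                            disq)), 0L)
})

test_that("junction-only calls acquire insertion sites from pooled pairs", {
  gm <- hand_gm()
  catalog <- hand_catalog()
  repeats <- hand_repeats()
  model <- hand_model()
  calls <- data.frame(call_id = "junc:gA", parent_gene_id = "gA",
                      in_reference = FALSE, evidence = "junction_reads")
  # anchors must fall in the terminal exons of gA (ranks 1 and 3)
  mk <- function(samples_n, mate_start) {
    do.call(rbind, lapply(seq_len(sum(samples_n)), function(i) {
      s <- rep(paste0("s", seq_along(samples_n)), samples_n)[i]
      anchored_pair(s, i, "chrA", 1000 + i * 3, "chrB",
                    mate_start + i * 5, "+")
    }))
  }
  # 2 pairs from each of 3 individuals (6 pooled) -> site attached
  res <- locate_junction_insertion_sites(calls, mk(c(2, 2, 2), 7600),
                                         gm, catalog, repeats, model)
  expect_false(is.na(res$calls$site_chrom))
  expect_equal(res$calls$site_support, 6L)
  # 5 pooled pairs -> no site, call remains junction-only
  res5 <- locate_junction_insertion_sites(calls, mk(c(2, 2, 1), 7600),
                                          gm, catalog, repeats, model)
  expect_true(is.na(res5$calls$site_chrom))
  # 7 pooled pairs on a repeat -> no site, reason logged
  resr <- locate_junction_insertion_sites(calls, mk(c(3, 2, 2), 9450),
                                          gm, catalog, repeats, model)
  expect_true(is.na(resr$calls$site_chrom))
  expect_true("overlaps_repeat" %in% resr$report$reason)
})

test_that("discovery ascertainment keeps only pair-supported calls in the discovery set", {
  calls <- data.frame(call_id = c("c1", "c2", "c3"),
                      parent_gene_id = c("g1", "g2", "g3"))
  support <- data.frame(
    call_id = c("c1", "c1", "c2", "c3"),
    sample_id = c("d1", "x9", "x9", "d2"),
    n_pairs = c(6L, 50L, 50L, 5L))
  kept <- apply_discovery_ascertainment(calls, support, c("d1", "d2"))
  # c1: 6 pairs in discovery genome d1 -> kept (boundary: > 5)
  # c2: support only outside the discovery set -> removed
  # c3: exactly 5 pairs -> removed
  expect_equal(kept$call_id, "c1")
  # junction-only calls have no pair support rows at all -> removed
  calls4 <- rbind(calls, data.frame(call_id = "junc:g4",
                                    parent_gene_id = "g4"))
  expect_false("junc:g4" %in%
                 apply_discovery_ascertainment(calls4, support,
                                               c("d1", "d2"))$call_id)
})
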