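test_that("nucleotide diversity matches the all-pairs definition", {
  # identical haplotypes -> 0
  expect_equal(nucleotide_diversity(matrix(0L, 4, 10)), 0)
  # complete difference over 2 sites -> 1 per site
  expect_equal(nucleotide_diversity(rbind(c(0, 0), c(1, 1))), 1.0)
  expect_error(nucleotide_diversity(matrix(0L, 1, 5)),
               "insufficient-haplotypes")
  # random matrices against the brute-force all-pairs oracle
  set.seed(4)
  for (i in 1:200) {
    m <- matrix(rbinom(6 * 30, 1, runif(1, 0.1, 0.9)), 6, 30)
    expect_equal(nucleotide_diversity(m), pi_brute(m), tolerance = 1e-12)
  }
})

test_that("pi is invariant to row and column permutations", {
  set.seed(9)
  m <- matrix(rbinom(8 * 40, 1, 0.3), 8, 40)
  base <- nucleotide_diversity(m)
  expect_equal(nucleotide_diversity(m[sample(8), ]), base)
  expect_equal(nucleotide_diversity(m[, sample(40)]), base)
})

test_that("pi_der/pi_anc partitions by the focal allele", {
  # derived class monomorphic, ancestral variable -> ratio 0
  m <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0),  # derived, identical
             c(0, 1, 0, 1), c(0, 0, 1, 0))  # ancestral, variable
  r <- pi_ratio(m, focal = 1)
  expect_equal(r$ratio, 0)
  expect_equal(r$n_der, 2L)
  # focal frequency below 2 in either class is a precondition error
  m2 <- rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 1))
  expect_error(pi_ratio(m2, focal = 1), "insufficient-haplotypes")
  # monomorphic ancestral class -> undefined ratio
  m3 <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 0, 0), c(0, 0, 0))
  expect_error(pi_ratio(m3, focal = 1), "undefined-ratio")
  # label permutation: expected ratio ~ 1 when classes are exchangeable
  set.seed(10)
  ratios <- replicate(300, {
    m <- matrix(rbinom(12 * 40, 1, 0.4), 12, 40)
    foc <- c(rep(1L, 6), rep(0L, 6))[sample(12)]
    r <- tryCatch(pi_ratio(cbind(foc, m), focal = 1)$ratio,
                  error = function(e) NA)
    r
  })
  expect_lt(abs(median(ratios, na.rm = TRUE) - 1), 0.1)
})

test_that("vectorised per-column ratios agree with pi_ratio", {
  set.seed(14)
  m <- matrix(rbinom(10 * 25, 1, 0.35), 10, 25)
  stats <- retrocnv:::.all_focal_ratios(m)
  for (cc in which(stats$derived_count >= 2 &
                     stats$derived_count <= 8)) {
    direct <- tryCatch(pi_ratio(m, focal = cc), error = function(e) NULL)
    if (is.null(direct)) next
    expect_equal(stats$pi_der[cc], direct$pi_der, tolerance = 1e-12)
    expect_equal(stats$pi_anc[cc], direct$pi_anc, tolerance = 1e-12)
  }
})

test_that("neutral coalescent replicates have fixed S, seeded determinism", {
  for (S in c(1, 17, 60)) {
    hm <- simulate_neutral_haplotypes(9, S, rho = 3, seed = S)
    expect_equal(ncol(hm$mat), S)
    expect_true(all(colSums(hm$mat) >= 1 & colSums(hm$mat) <= 8))
    expect_false(is.unsorted(hm$pos))
  }
  a <- simulate_neutral_haplotypes(12, 40, rho = 10,
                                   demography = demography_ceu(),
                                   seed = 5)
  b <- simulate_neutral_haplotypes(12, 40, rho = 10,
                                   demography = demography_ceu(),
                                   seed = 5)
  expect_identical(a$mat, b$mat)
  expect_identical(a$pos, b$pos)
  # n = 2: every segregating site has derived count exactly 1
  h2 <- simulate_neutral_haplotypes(2, 25, seed = 3)
  expect_true(all(colSums(h2$mat) == 1))
})

test_that("neutral site-frequency spectrum and diversity match coalescent theory", {
  set.seed(20)
  n <- 10
  sfs <- numeric(n - 1)
  pis <- numeric(400)
  for (i in 1:400) {
    hm <- simulate_neutral_haplotypes(n, 50)
    cnt <- colSums(hm$mat)
    sfs <- sfs + tabulate(cnt, nbins = n - 1)
    pis[i] <- nucleotide_diversity(hm$mat)
  }
  prop <- sfs / sum(sfs)
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  expect_lt(max(abs(prop - expected)), 0.04)
  # fixed-S per-site diversity has closed form E[pi] = 1 / a_{n-1}
  expect_lt(abs(mean(pis) - 1 / sum(1 / (1:(n - 1)))), 0.02)
})

test_that("coalescent null p-value behaves at the extremes", {
  null <- data.frame(rep = 1, derived_count = rep(5L, 40),
                     ratio = seq(0.1, 4, length.out = 40))
  # observed larger than every matched ratio -> p = 1
  res <- coalescent_null_pvalue(5.0, focal_count = 5, null = null)
  expect_equal(res$p_value, 1)
  # observed below all -> p = 0
  expect_equal(coalescent_null_pvalue(0.01, focal_count = 5,
                                      null = null)$p_value, 0)
  # no frequency-matched polymorphisms -> uninformative
  expect_error(coalescent_null_pvalue(1, focal_count = 30, null = null),
               "uninformative")
  # +/-1 matching tolerance rescues sparse counts
  null2 <- data.frame(rep = 1, derived_count = c(4L, 6L),
                      ratio = c(0.5, 2))
  expect_error(coalescent_null_pvalue(1, focal_count = 5, null = null2))
  expect_equal(coalescent_null_pvalue(1, focal_count = 5, null = null2,
                                      match_tol = 1)$n_matched, 2L)
})

test_that("sweep generator depresses derived-class diversity", {
  set.seed(33)
  # near-fixed sweep: derived class is nearly monomorphic
  hm99 <- simulate_sweep_haplotypes(30, 80, alpha = 800, freq = 0.9)
  der <- hm99$mat[hm99$mat[, hm99$focal] == 1, -hm99$focal]
  anc <- hm99$mat[hm99$mat[, hm99$focal] == 0, -hm99$focal]
  expect_lt(nucleotide_diversity(der), nucleotide_diversity(anc))
  # median ratio under a strong sweep is below the neutral median
  rat <- function(alpha) median(replicate(40, {
    hm <- simulate_sweep_haplotypes(30, 60, alpha = alpha, freq = 0.7)
    tryCatch(pi_ratio(hm)$ratio, error = function(e) NA)
  }), na.rm = TRUE)
  expect_lt(rat(500), rat(0))
  # alpha = 0 delegates to the neutral generator with a matched focal
  hm0 <- simulate_sweep_haplotypes(20, 50, alpha = 0, freq = 0.5,
                                   seed = 2)
  expect_equal(ncol(hm0$mat), 50L)
  expect_false(is.na(hm0$focal))
})

test_that("windowed diversity profile tracks class-specific structure", {
  # all haplotypes identical away from the focal site -> all-zero tracks
  m <- cbind(0L, c(1L, 1L, 0L, 0L), matrix(0L, 4, 5))
  hm <- haplotype_matrix(m, pos = c(1000, 5000, seq(9000, 25000,
                                                    by = 4000)),
                         span = 30000, focal = 2)
  prof <- windowed_diversity_profile(hm, window_bp = 10000)
  expect_true(all(prof$pi_der[!is.na(prof$pi_der)] == 0))
  expect_true(all(prof$pi_anc[!is.na(prof$pi_anc)] == 0))
  # empty windows are NA, not zero
  m2 <- cbind(c(1L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L))
  hm2 <- haplotype_matrix(m2, pos = c(500, 900), span = 30000, focal = 1)
  prof2 <- windowed_diversity_profile(hm2, window_bp = 10000)
  expect_true(is.na(prof2$pi_der[2]))
  # constructed dip: derived class monomorphic near the focal site,
  # ancestral class variable there; both variable far away
  set.seed(61)
  focal_col <- c(rep(1L, 3), rep(0L, 3))
  near <- rbind(matrix(0L, 3, 4),                 # derived: no variation
                matrix(rbinom(12, 1, 0.5), 3))    # ancestral: varies
  far <- matrix(rbinom(6 * 5, 1, 0.5), 6, 5)
  m3 <- cbind(near[, 1:2, drop = FALSE], focal_col,
              near[, 3:4, drop = FALSE], far)
  hm3 <- haplotype_matrix(
    m3, pos = c(1000, 1500, 2000, 3000, 4000,
                seq(11000, 19000, by = 2000)),
    span = 20000, focal = 3)
  prof3 <- windowed_diversity_profile(hm3, window_bp = 10000)
  expect_equal(prof3$pi_der[1], 0)
  expect_gt(prof3$pi_anc[1], 0)
})

test_that("empirical SNP percentile selects one frequency-matched SNP per window", {
  set.seed(40)
  mk_window <- function(focal_count, n = 20, S = 30, span = 200000) {
    m <- matrix(rbinom(n * S, 1, 0.3), n, S)
    ctr_site <- 15
    m[, ctr_site] <- c(rep(1, focal_count), rep(0, n - focal_count))
    pos <- sort(runif(S, 0, span))
    pos[ctr_site] <- span / 2 + runif(1, -5000, 5000)
    haplotype_matrix(m[, order(pos)], pos = sort(pos), span = span)
  }
  windows <- lapply(rep(8, 30), mk_window)
  obs <- 0.001
  res <- empirical_snp_percentile(obs, 0.4, windows)
  expect_equal(res$fraction, 0)
  # observed equal to the single comparison SNP's ratio -> 1
  w1 <- windows[1]
  snp_ratio <- local({
    hm <- w1[[1]]
    near <- which(abs(hm$pos - hm$span / 2) <= 10000)
    freq <- colSums(hm$mat[, near, drop = FALSE]) / nrow(hm$mat)
    ok <- near[floor(freq / 0.05) == floor(0.4 / 0.05)]
    snp <- ok[order(hm$pos[ok])][1]
    pi_ratio(hm$mat, focal = snp)$ratio
  })
  expect_equal(empirical_snp_percentile(snp_ratio, 0.4, w1)$fraction, 1.0)
  # brute-force recomputation over all windows
  brute <- mean(vapply(windows, function(hm) {
    near <- which(abs(hm$pos - hm$span / 2) <= 10000)
    freq <- colSums(hm$mat[, near, drop = FALSE]) / nrow(hm$mat)
    ok <- near[floor(freq / 0.05) == floor(0.4 / 0.05)]
    snp <- ok[order(hm$pos[ok])][1]
    pi_ratio(hm$mat, focal = snp)$ratio
  }, 1) <= snp_ratio)
  expect_equal(empirical_snp_percentile(snp_ratio, 0.4,
                                        windows)$fraction, brute)
  # frequency bin with no qualifying SNPs
  expect_error(empirical_snp_percentile(1, 0.99, windows),
               "uninformative")
})

test_that("iHS region test scores extreme-score density against random regions", {
  set.seed(55)
  n_snps <- 4000
  ihs <- data.frame(chrom = rep(c("chr1", "chr2"), each = n_snps / 2),
                    pos = rep(seq(1000, by = 500,
                                  length.out = n_snps / 2), 2),
                    ihs = rnorm(n_snps))
  # plant a cluster of extreme scores on chr2
  hot <- ihs$chrom == "chr2" & ihs$pos >= 800000 & ihs$pos <= 840000
  ihs$ihs[hot] <- 4 + rnorm(sum(hot), 0, 0.1)
  res <- ihs_region_test(ihs, list(chrom = "chr2", start = 800000,
                                   end = 840000), flank = 10000,
                         n_random = 400, seed = 1)
  expect_lt(res$empirical_fraction, 0.05)
  expect_gt(res$extreme_fraction, 0.5)
  # hand arithmetic: 100 SNPs, 10 extreme -> chi2 ~ 5.26
  expect_equal(100 * ((0.1 - 0.05)^2 / 0.05 + (0.9 - 0.95)^2 / 0.95),
               5.263158, tolerance = 1e-6)
  # a region at exactly the expected extreme fraction scores chi2 = 0
  # and nearly all random regions beat it
  cold <- ihs
  cold$ihs[hot] <- rnorm(sum(hot))
  lo <- quantile(cold$ihs, 0.025); hi <- quantile(cold$ihs, 0.975)
  idx <- which(cold$chrom == "chr1" & cold$pos >= 500000 &
                 cold$pos <= 600000)
  k <- round(0.05 * length(idx))
  cold$ihs[idx] <- abs(rnorm(length(idx), 0, 0.1))        # none extreme
  cold$ihs[idx[seq_len(k)]] <- hi + 1                     # exactly 5%
  res0 <- ihs_region_test(cold, list(chrom = "chr1", start = 550000,
                                     end = 550000), flank = 50000,
                          n_random = 200, seed = 2)
  expect_gt(res0$empirical_fraction, 0.5)
  expect_error(ihs_region_test(ihs, list(chrom = "chr9", start = 1,
                                         end = 2)), "uninformative")
})

test_that("ms format round-trips haplotype matrices", {
  set.seed(17)
  hms <- list(simulate_neutral_haplotypes(6, 12, seed = 1),
              simulate_neutral_haplotypes(4, 7, seed = 2))
  f <- tempfile(fileext = ".ms")
  write_ms(hms, f)
  back <- read_ms(f, span = hms[[1]]$span)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$mat, hms[[i]]$mat)
    expect_lt(max(abs(back[[i]]$pos - hms[[i]]$pos)), 1)
  }
})
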