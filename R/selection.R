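# per-column focal statistics via the site x site cross-product:
# treating each column c as the focal allele, the derived-class count of
# site j is crossprod(X)[c, j], giving vectorised pi_der / pi_anc for
# every candidate focal column at once.
.all_focal_ratios <- function(mat) {
  n <- nrow(mat)
  S <- ncol(mat)
  X <- mat
  storage.mode(X) <- "double"
  C <- crossprod(X)              # C[c, j] = derived-class count at j
  tot <- colSums(X)
  kd <- diag(C)
  ka <- n - kd
  A <- matrix(tot, S, S, byrow = TRUE) - C
  num_d <- C * (kd - C)          # row c: d_j * (kd_c - d_j)
  num_a <- A * (ka - A)
  sum_d <- rowSums(num_d) - (num_d[cbind(seq_len(S), seq_len(S))])
  sum_a <- rowSums(num_a) - (num_a[cbind(seq_len(S), seq_len(S))])
  L <- S - 1
  pi_der <- ifelse(kd >= 2, sum_d / (choose(kd, 2) * L), NA_real_)
  pi_anc <- ifelse(ka >= 2, sum_a / (choose(ka, 2) * L), NA_real_)
  data.frame(derived_count = as.integer(kd), pi_der = pi_der,
             pi_anc = pi_anc)
}

#' Null distribution of diversity ratios from coalescent replicates
#'
#' Runs `n_sims` neutral coalescent replicates matched to the observed
#' data (same number of chromosomes `n`, the same number of segregating
#' sites `S`, a single flat recombination rate `rho`, and the
#' population's demographic history) and, within each replicate, treats
#' every polymorphism in the medial fraction of the span as a candidate
#' focal allele, recording its derived count and pi_der/pi_anc ratio
#' computed over all remaining sites. Candidates whose ancestral class is
#' monomorphic contribute no ratio and are counted separately.
#'
#' @inheritParams simulate_neutral_haplotypes
#' @param n_sims number of replicates
#' @param medial_frac central fraction of the span from which candidate
#'   polymorphisms are taken (default 0.25)
#' @param seed optional seed
#' @return data.frame with `rep`, `derived_count`, `ratio`; attribute
#'   `n_excluded` counts ancestral-monomorphic candidates
#' @export
coalescent_null_ratios <- function(n, S, rho = 0,
                                   demography = demography_constant(),
                                   n_sims = 10000L, medial_frac = 0.25,
                                   span_bp = 200000, seed = NULL) {
  if (n_sims < 1L) stop("invalid n_sims")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_sims)
  n_excluded <- 0L
  ctr <- span_bp / 2
  half <- span_bp * medial_frac / 2
  for (i in seq_len(n_sims)) {
    hm <- simulate_neutral_haplotypes(n, S, rho, demography, span_bp)
    medial <- hm$pos >= ctr - half & hm$pos <= ctr + half
    if (!any(medial)) next
    stats <- .all_focal_ratios(hm$mat)
    stats <- stats[medial, , drop = FALSE]
    usable <- !is.na(stats$pi_der) & !is.na(stats$pi_anc)
    zero_anc <- usable & stats$pi_anc == 0
    n_excluded <- n_excluded + sum(zero_anc)
    keep <- usable & !zero_anc
    if (!any(keep)) next
    out[[i]] <- data.frame(rep = i,
                           derived_count = stats$derived_count[keep],
                           ratio = stats$pi_der[keep] /
                             stats$pi_anc[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(rep = integer(0), derived_count = integer(0),
                      ratio = numeric(0))
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Coalescent p-value for a depressed diversity ratio
#'
#' Compares an observed pi_der/pi_anc ratio with ratios of
#' frequency-matched polymorphisms pooled across neutral coalescent
#' replicates: the p-value is the fraction of matched null polymorphisms
#' whose ratio is at most the observed one. Frequency matching is exact
#' derived-count equality by default; `match_tol` relaxes it by +/- that
#' many copies when matched counts are small.
#'
#' @param observed observed ratio, or the list returned by [pi_ratio]
#' @param focal_count derived count of the focal allele in the sample
#'   (taken from `observed$n_der` when a [pi_ratio] result is given)
#' @param n,S,rho,demography,span_bp observed-data matching parameters
#'   (see [coalescent_null_ratios]); ignored when `null` is supplied
#' @param n_sims replicates (default 10000)
#' @param match_tol derived-count matching tolerance (default 0)
#' @param null optional precomputed table from [coalescent_null_ratios]
#' @param seed optional seed
#' @return data.frame row: `pi_der`, `pi_anc`, `ratio`, `p_value`,
#'   `n_matched`, `n_excluded`
#' @export
coalescent_null_pvalue <- function(observed, focal_count = NULL, n = NULL,
                                   S = NULL, rho = 0,
                                   demography = demography_constant(),
                                   n_sims = 10000L, match_tol = 0,
                                   span_bp = 200000, null = NULL,
                                   seed = NULL) {
  if (is.list(observed) && !is.null(observed$ratio)) {
    if (is.null(focal_count)) focal_count <- observed$n_der
    obs <- list(pi_der = observed$pi_der, pi_anc = observed$pi_anc,
                ratio = observed$ratio)
  } else {
    obs <- list(pi_der = NA_real_, pi_anc = NA_real_,
                ratio = as.numeric(observed))
  }
  if (is.null(focal_count)) stop("focal_count required")
  if (is.null(null)) {
    if (is.null(n) || is.null(S))
      stop("supply n and S (or a precomputed null table)")
    null <- coalescent_null_ratios(n, S, rho, demography, n_sims,
                                   span_bp = span_bp, seed = seed)
  }
  matched <- abs(null$derived_count - focal_count) <= match_tol
  n_matched <- sum(matched)
  if (n_matched == 0L)
    stop("uninformative: no frequency-matched null polymorphisms")
  p <- mean(null$ratio[matched] <= obs$ratio)
  data.frame(pi_der = obs$pi_der, pi_anc = obs$pi_anc, ratio = obs$ratio,
             p_value = p, n_matched = n_matched,
             n_excluded = attr(null, "n_excluded") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-wide empirical percentile of a diversity ratio
#'
#' Places an observed pi_der/pi_anc ratio within the distribution of
#' ratios at comparison SNPs drawn from non-overlapping genomic windows:
#' in each window, at most one SNP lying within `center_margin` of the
#' window centre and whose derived allele frequency falls in the same
#' `bin_width` bin as the focal allele is selected (first by position at
#' ties), its ratio computed within the window, and the fraction of
#' comparison SNPs with ratio at most the observed value returned.
#'
#' @param observed_ratio observed pi_der/pi_anc
#' @param focal_freq derived allele frequency of the focal allele
#' @param windows list of [haplotype_matrix], one per non-overlapping
#'   window
#' @param center_margin bp around the window centre (default 10000)
#' @param bin_width frequency bin width (default 0.05)
#' @return list with `fraction` (empirical percentile), `n_snps`
#'   (comparison SNPs used)
#' @export
empirical_snp_percentile <- function(observed_ratio, focal_freq, windows,
                                     center_margin = 10000,
                                     bin_width = 0.05) {
  focal_bin <- floor(focal_freq / bin_width)
  ratios <- numeric(0)
  for (hm in windows) {
    n <- nrow(hm$mat)
    ctr <- hm$span / 2
    near <- which(abs(hm$pos - ctr) <= center_margin)
    if (length(near) == 0L) next
    freq <- colSums(hm$mat[, near, drop = FALSE]) / n
    ok <- near[floor(freq / bin_width) == focal_bin]
    if (length(ok) == 0L) next
    snp <- ok[order(hm$pos[ok])][1L]
    r <- tryCatch(pi_ratio(hm$mat, focal = snp)$ratio,
                  error = function(e) NA_real_)
    if (!is.na(r)) ratios <- c(ratios, r)
  }
  if (length(ratios) == 0L)
    stop("uninformative: no qualifying comparison SNPs")
  list(fraction = mean(ratios <= observed_ratio), n_snps = length(ratios))
}

#' iHS extreme-score density test for a region
#'
#' Tests whether a region (extended by `flank` bp on each side) is
#' enriched for SNPs with extreme integrated haplotype scores. Extreme
#' scores are those in the upper or lower `tail` of the genome-wide
#' empirical iHS distribution (2 x 2.5% = 5% combined by default); the
#' region's extreme fraction is compared with the 0.05 expectation by a
#' two-cell chi-square statistic, and the statistic is calibrated against
#' `n_random` random length-matched regions (each required to contain at
#' least one scored SNP), reporting the fraction of random regions with a
#' larger chi-square.
#'
#' Note the two-cell chi-square also grows when extreme SNPs are
#' depleted; the returned `extreme_fraction` disambiguates direction.
#'
#' @param ihs data.frame with `chrom`, `pos`, `ihs` (genome-wide)
#' @param region list or data.frame with `chrom`, `start`, `end`
#' @param flank extension on each side in bp (default 50000)
#' @param tail per-tail fraction defining extreme scores (default 0.025)
#' @param n_random random comparison regions (default 10000)
#' @param seed optional seed
#' @return data.frame: `n_snps`, `extreme_fraction`, `chisq`,
#'   `empirical_fraction`
#' @export
ihs_region_test <- function(ihs, region, flank = 50000, tail = 0.025,
                            n_random = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- stats::quantile(ihs$ihs, tail, names = FALSE)
  hi <- stats::quantile(ihs$ihs, 1 - tail, names = FALSE)
  extreme <- ihs$ihs <= lo | ihs$ihs >= hi
  p0 <- 2 * tail
  chisq_of <- function(idx) {
    nn <- length(idx)
    f <- sum(extreme[idx])
    e1 <- p0 * nn
    (f - e1)^2 / e1 + ((nn - f) - (1 - p0) * nn)^2 / ((1 - p0) * nn)
  }
  start <- region$start - flank
  end <- region$end + flank
  len <- end - start
  idx <- which(ihs$chrom == region$chrom & ihs$pos >= start &
                 ihs$pos <= end)
  if (length(idx) == 0L)
    stop("uninformative: no scored SNPs in region")
  obs_chisq <- chisq_of(idx)
  obs_frac <- mean(extreme[idx])
  chroms <- unique(ihs$chrom)
  lim <- vapply(chroms, function(ch) {
    p <- ihs$pos[ihs$chrom == ch]
    c(min(p), max(p))
  }, numeric(2))
  usable <- pmax(0, lim[2, ] - lim[1, ] - len)
  if (all(usable <= 0))
    stop("uninformative: genome too small for length-matched regions")
  exceed <- 0L
  drawn <- 0L
  attempts <- 0L
  while (drawn < n_random && attempts < 50L * n_random) {
    attempts <- attempts + 1L
    ch <- sample(chroms[usable > 0], 1L,
                 prob = usable[usable > 0] / sum(usable[usable > 0]))
    s <- runif(1, lim[1, ch], lim[2, ch] - len)
    ridx <- which(ihs$chrom == ch & ihs$pos >= s & ihs$pos <= s + len)
    if (length(ridx) == 0L) next
    drawn <- drawn + 1L
    if (chisq_of(ridx) > obs_chisq) exceed <- exceed + 1L
  }
  data.frame(n_snps = length(idx), extreme_fraction = obs_frac,
             chisq = obs_chisq,
             empirical_fraction = exceed / max(drawn, 1L))
}

#' Read a per-SNP iHS score table
#'
#' @param path TSV with columns `chrom`, `pos`, `ihs` (header required)
#' @return data.frame
#' @export
read_ihs_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("chrom", "pos", "ihs") %in% names(df)))
  df
}
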