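#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the standard two-sided convention: the
#' p-value sums the probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table.
#' Delegates to [stats::fisher.test].
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return the two-sided p-value
#' @examples
#' fisher_exact_two_sided(matrix(c(36, 3, 70, 29), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("empty margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square goodness-of-fit test
#'
#' @param observed vector of observed counts
#' @param expected_prop expected proportions (must sum to 1, all > 0)
#' @return list with `statistic` and `p_value` (k - 1 degrees of freedom)
#' @export
chi_square_gof <- function(observed, expected_prop) {
  stopifnot(length(observed) == length(expected_prop))
  if (abs(sum(expected_prop) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (any(expected_prop <= 0))
    stop("invalid expectation: zero expected count")
  res <- suppressWarnings(stats::chisq.test(observed, p = expected_prop))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Benjamini-Hochberg false discovery rates with an external test count
#'
#' BH step-up adjustment where the multiplier is the total number of
#' tests performed (`m`), which may exceed the number of p-values
#' supplied -- appropriate when only a subset of a test family is being
#' adjusted and the remaining tests are conservatively assumed
#' non-significant.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @param m total number of tests (default `length(p_values)`)
#' @return adjusted values (FDR), same order as input
#' @examples
#' bh_adjust(c(1.1e-4, 0.0083, 0.0094), m = 46)
#' @export
bh_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  if (m < length(p_values))
    stop("inconsistent m: fewer total tests than p-values supplied")
  stats::p.adjust(p_values, method = "BH", n = m)
}

#' Discovery sensitivity from doubled-threshold trials
#'
#' Estimates the per-chromosome detection probability `d` of the
#' paired-end discovery step by re-detecting fixed (always homozygous)
#' retrocopies with a doubled support threshold, which emulates
#' discovering a heterozygous singleton. The probability of discovering a
#' retroCNV carried by `i` chromosomes in the discovery set is then
#' `1 - (1 - d)^i`.
#'
#' @param trials logical vector (or data.frame with a `detected` column):
#'   one doubled-threshold detection outcome per (retrocopy, genome)
#'   trial. Alternatively pass `d` directly.
#' @param d per-chromosome detection probability, if already known
#' @return object of class `sensitivity_estimate` with `d`, `miss` and
#'   `detect(i)` lookup
#' @examples
#' est <- estimate_discovery_sensitivity(d = 0.774)
#' est$detect(2)  # ~0.95
#' @export
estimate_discovery_sensitivity <- function(trials = NULL, d = NULL) {
  if (is.null(d)) {
    if (is.data.frame(trials)) trials <- trials$detected
    if (is.null(trials) || length(trials) == 0L)
      stop("no-data: no detection trials supplied")
    d <- mean(trials)
  }
  stopifnot(d >= 0, d <= 1)
  structure(list(d = d, miss = 1 - d,
                 detect = function(i) 1 - (1 - d)^i),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("sensitivity_estimate: d = %.3f (miss %.3f); 2-carrier %.3f\n",
              x$d, x$miss, x$detect(2)))
  invisible(x)
}

#' Build the movement and insertion-context contrast tables
#'
#' Constructs the two 2x2 contingency tables contrasting polymorphic
#' retroCNVs against fixed retrocopies and computes Fisher's exact test
#' on each: (1) chromosomal movement -- within-class (`A->A` or `X->X`)
#' versus between-class (`A->X` or `X->A`); (2) insertion context --
#' intronic versus intergenic (exonic insertions are excluded from this
#' contrast).
#'
#' @param calls data.frame of polymorphic calls with `movement` (from
#'   [classify_movement]) and `category` (from
#'   [classify_insertion_context]) columns
#' @param fixed data.frame of fixed retrocopies with the same columns
#' @return list with `movement` and `context`, each containing `table`
#'   (2x2 matrix, columns = polymorphic / fixed) and `p_value`
#' @export
build_contrast_tables <- function(calls, fixed) {
  mv <- function(df) table(movement_group(df$movement))
  movement <- cbind(retroCNV = as.integer(mv(calls)),
                    fixed = as.integer(mv(fixed)))
  rownames(movement) <- c("within", "between")
  ctx <- function(df) {
    d <- df[df$category %in% c("intronic", "intergenic"), , drop = FALSE]
    c(intronic = sum(d$category == "intronic"),
      intergenic = sum(d$category == "intergenic"))
  }
  context <- cbind(retroCNV = ctx(calls), fixed = ctx(fixed))
  list(
    movement = list(table = movement,
                    p_value = fisher_exact_two_sided(movement)),
    context = list(table = context,
                   p_value = fisher_exact_two_sided(context)))
}
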