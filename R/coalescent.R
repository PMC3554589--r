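#' Piecewise-constant demographic model
#'
#' Population-size history in coalescent units: time is measured in units
#' of 4N0 generations looking backward from the present, and each event
#' `(time, size)` sets the relative population size to `size` for all
#' times at or beyond `time`. The size before the first event is 1.
#'
#' @param times non-negative, increasing event times
#' @param sizes relative sizes, one per event
#' @param label population label
#' @return object of class `demography_model`
#' @export
demography_model <- function(times = numeric(0), sizes = numeric(0),
                             label = "custom") {
  stopifnot(length(times) == length(sizes),
            all(times >= 0), !is.unsorted(times, strictly = TRUE) ||
              length(times) <= 1)
  if (length(sizes) && any(sizes <= 0))
    stop("config error: population sizes must be positive")
  structure(list(times = as.numeric(times), sizes = as.numeric(sizes),
                 label = label),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat("demography_model:", x$label)
  if (length(x$times))
    cat(" [", paste(sprintf("(t=%g, x=%g)", x$times, x$sizes),
                    collapse = " "), "]")
  cat("\n")
  invisible(x)
}

#' Preset demographies
#'
#' Out-of-Africa bottleneck for European/Asian samples (size halved
#' between 0.05 and 0.15 coalescent time units, ancestrally 1.5) and a
#' recent expansion for the African sample (current size 1.5 throughout).
#'
#' @return `demography_model`
#' @rdname demography_presets
#' @export
demography_ceu <- function()
  demography_model(c(0.05, 0.15), c(0.5, 1.5), "CEU")

#' @rdname demography_presets
#' @export
demography_asi <- function()
  demography_model(c(0.05, 0.15), c(0.5, 1.5), "ASI")

#' @rdname demography_presets
#' @export
demography_yri <- function()
  demography_model(0, 1.5, "YRI")

#' @rdname demography_presets
#' @export
demography_constant <- function()
  demography_model(label = "constant")

#' Simulate neutral haplotypes under the coalescent with recombination
#'
#' Fixed-S semantics: exactly `S` segregating sites placed uniformly on
#' the span, one mutation per site dropped on the site's marginal
#' genealogy proportional to branch length. Recombination is scaled as
#' `rho = 4 N0 r L` over the whole span.
#'
#' @param n number of chromosomes (>= 2)
#' @param S number of segregating sites (>= 1)
#' @param rho population-scaled recombination rate over the span
#' @param demography [demography_model]
#' @param span_bp span represented by the unit interval, for bp positions
#'   (default 200000, a 100-kb flank either side of a focal locus)
#' @param seed optional integer seed
#' @return [haplotype_matrix] (focal column unset)
#' @export
simulate_neutral_haplotypes <- function(n, S, rho = 0,
                                        demography = demography_constant(),
                                        span_bp = 200000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- .coalescent_sim_cpp(as.integer(n), as.integer(S), as.numeric(rho),
                             demography$times, demography$sizes)
  haplotype_matrix(res$mat, pos = res$positions * span_bp, span = span_bp)
}

#' Simulate haplotypes under a partial selective sweep
#'
#' Positive-control generator: the focal allele follows a deterministic
#' logistic frequency trajectory (strength `alpha = 2 N s` in coalescent
#' scaling) ending at `freq` today, and the sample genealogy is drawn
#' from the structured coalescent conditioned on that trajectory
#' (derived and ancestral allelic classes as demes with sizes `x p(t)`
#' and `x (1 - p(t))`). No recombination is modelled within the sweep
#' genealogy. `S - 1` ordinary mutations are dropped on the tree and the
#' focal column (class membership) is inserted at the centre of the span,
#' so the matrix is directly comparable to the neutral generator with a
#' chosen focal site. With `alpha = 0` the generator reduces to the
#' neutral coalescent with a frequency-matched focal site.
#'
#' @param n chromosomes
#' @param S total sites including the focal column
#' @param alpha scaled selection strength 2Ns (0 = neutral)
#' @param freq current derived (focal) allele frequency in (0, 1)
#' @param demography [demography_model]
#' @param span_bp span in bp
#' @param seed optional seed
#' @return [haplotype_matrix] with `focal` set
#' @export
simulate_sweep_haplotypes <- function(n, S, alpha, freq,
                                      demography = demography_constant(),
                                      span_bp = 200000, seed = NULL) {
  stopifnot(freq > 0, freq < 1, S >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_der <- max(2L, min(n - 2L, round(n * freq)))
  if (alpha <= 0) {
    repeat {
      hm <- simulate_neutral_haplotypes(n, S, rho = 0, demography,
                                        span_bp)
      f <- choose_focal_site(hm, n_der, medial_frac = 1)
      if (!is.na(f)) {
        hm$focal <- f
        return(hm)
      }
    }
  }
  tree <- .sweep_tree(n, n_der, alpha, freq, demography)
  mat <- .drop_mutations(tree, n, S - 1L)
  pos <- sort(runif(S - 1L)) * span_bp
  focal_col <- as.integer(rep(0L, n))
  focal_col[seq_len(n_der)] <- 1L
  at <- findInterval(span_bp / 2, pos)
  mat <- cbind(mat[, seq_len(at), drop = FALSE], focal_col,
               mat[, setdiff(seq_len(S - 1L), seq_len(at)),
                   drop = FALSE])
  pos <- c(pos[seq_len(at)], span_bp / 2,
           pos[setdiff(seq_len(S - 1L), seq_len(at))])
  haplotype_matrix(mat, pos = pos, span = span_bp, focal = at + 1L)
}

# structured coalescent for a deterministic logistic sweep trajectory.
# Returns list(parent, time) over nodes 1..(2n-1); leaves 1..n, leaves
# 1..n_der carry the derived allele.
.sweep_tree <- function(n, n_der, alpha, freq, demography) {
  size_at <- function(t) {
    x <- 1
    for (i in seq_along(demography$times))
      if (t >= demography$times[i]) x <- demography$sizes[i]
    x
  }
  p_at <- function(t) freq / (freq + (1 - freq) * exp(alpha * t))
  eps <- 1 / (2 * 1e4)  # trajectory floor ~ one copy in 2N = 1e4
  parent <- integer(2 * n - 1)
  time <- numeric(2 * n - 1)
  der <- seq_len(n_der)
  anc <- setdiff(seq_len(n), der)
  nxt <- n + 1L
  t <- 0
  dt <- 0.1 / max(alpha, 10)  # fine steps relative to sweep speed
  coalesce_pair <- function(group, t) {
    pick <- sample(group, 2L)
    v <- nxt
    parent[pick] <<- v
    time[v] <<- t
    nxt <<- nxt + 1L
    c(setdiff(group, pick), v)
  }
  while (p_at(t) > eps && (length(der) + length(anc)) > 1L) {
    x <- size_at(t)
    p <- p_at(t)
    kd <- length(der); ka <- length(anc)
    r_d <- kd * (kd - 1) / (x * p)
    r_a <- ka * (ka - 1) / (x * (1 - p))
    if (runif(1) < r_d * dt && kd >= 2L) der <- coalesce_pair(der, t)
    else if (runif(1) < r_a * dt && ka >= 2L) anc <- coalesce_pair(anc, t)
    t <- t + dt
  }
  # sweep origin reached: force remaining derived lineages together,
  # then move the survivor onto the ancestral background
  while (length(der) > 1L) {
    t <- t + 1e-4
    der <- coalesce_pair(der, t)
  }
  anc <- c(anc, der)
  while (length(anc) > 1L) {
    x <- size_at(t)
    k <- length(anc)
    rate <- k * (k - 1) / x
    t_prop <- t + rexp(1, rate)
    bnd <- demography$times[demography$times > t]
    if (length(bnd) && t_prop > min(bnd)) { t <- min(bnd); next }
    t <- t_prop
    anc <- coalesce_pair(anc, t)
  }
  list(parent = parent, time = time)
}

# place S mutations on a tree (parent/time arrays), branch ~ length
.drop_mutations <- function(tree, n, S) {
  nn <- length(tree$parent)
  has_parent <- tree$parent > 0L
  blen <- numeric(nn)
  blen[has_parent] <- tree$time[tree$parent[has_parent]] -
    tree$time[has_parent]
  kids <- split(which(has_parent), tree$parent[has_parent])
  below <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (v <= n) below[[v]] <- v
    else below[[v]] <- unlist(below[kids[[as.character(v)]]])
  }
  mat <- matrix(0L, n, S)
  branch <- sample(nn, S, replace = TRUE, prob = blen)
  for (s in seq_len(S)) mat[below[[branch[s]]], s] <- 1L
  mat
}

#' Choose a focal site by derived count
#'
#' Picks the first site (by position) within the medial fraction of the
#' span whose derived count equals `count` (within `tol`). Used to match
#' observed focal alleles when drawing from the neutral generator.
#'
#' @param hm [haplotype_matrix]
#' @param count target derived count
#' @param medial_frac central fraction of the span to search (default
#'   0.25)
#' @param tol absolute tolerance on the derived count (default 0)
#' @return column index, or NA when no site qualifies
#' @export
choose_focal_site <- function(hm, count, medial_frac = 0.25, tol = 0) {
  ctr <- hm$span / 2
  half <- hm$span * medial_frac / 2
  ok <- hm$pos >= ctr - half & hm$pos <= ctr + half
  dc <- colSums(hm$mat)
  cand <- which(ok & abs(dc - count) <= tol)
  if (length(cand) == 0L) return(NA_integer_)
  cand[1L]
}
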