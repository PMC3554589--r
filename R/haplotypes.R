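#' Haplotype matrix container
#'
#' A binary matrix of phased chromosomes (rows) by segregating sites
#' (columns), 0 = ancestral, 1 = derived, with site positions on a
#' declared span and an optional focal column marking the retroCNV
#' presence allele.
#'
#' @param mat integer matrix of 0/1
#' @param pos site positions (bp, strictly increasing, length = ncol)
#' @param span total span in bp covered by the matrix
#' @param focal column index of the focal (retroCNV) allele, or NA
#' @return object of class `haplotype_matrix`
#' @export
haplotype_matrix <- function(mat, pos = NULL, span = NULL, focal = NA) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(all(mat %in% c(0L, 1L)))
  if (is.null(pos)) pos <- seq_len(ncol(mat))
  if (is.null(span)) span <- max(pos)
  stopifnot(length(pos) == ncol(mat), !is.unsorted(pos, strictly = FALSE))
  if (!is.na(focal))
    stopifnot(focal >= 1, focal <= ncol(mat))
  structure(list(mat = mat, pos = as.numeric(pos), span = as.numeric(span),
                 focal = focal),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d chromosomes x %d sites over %g bp%s\n",
              nrow(x$mat), ncol(x$mat), x$span,
              if (is.na(x$focal)) "" else sprintf(" (focal site %d)",
                                                  x$focal)))
  invisible(x)
}

#' Nucleotide diversity (pi)
#'
#' The average number of pairwise differences per site among a set of
#' haplotypes: the sum over sites of `c * (k - c)` (c = derived count,
#' k = haplotypes) divided by `choose(k, 2)` and by the window length
#' `L` -- the number of sites by default, or a length in bp for windowed
#' profiles.
#'
#' @param mat 0/1 matrix (haplotypes x sites) or `haplotype_matrix`
#' @param L window length used for normalisation; defaults to the number
#'   of sites (per-site pi)
#' @return pi per unit of `L`
#' @export
nucleotide_diversity <- function(mat, L = NULL) {
  if (inherits(mat, "haplotype_matrix")) mat <- mat$mat
  k <- nrow(mat)
  if (k < 2L) stop("insufficient-haplotypes: need >= 2, got ", k)
  if (is.null(L)) L <- ncol(mat)
  if (ncol(mat) == 0L) return(0)
  c_der <- colSums(mat)
  sum(c_der * (k - c_der)) / (choose(k, 2) * L)
}

#' Derived/ancestral diversity ratio at a focal allele
#'
#' Splits haplotypes by the focal column into the derived class (carrying
#' the retroCNV) and ancestral class, computes per-site pi within each
#' class over all non-focal sites, and returns their ratio. A sweeping
#' allele depresses `pi_der` relative to neutral expectations at the same
#' frequency.
#'
#' @param hm `haplotype_matrix` with a focal column, or a plain matrix
#'   plus `focal`
#' @param focal focal column index when `hm` is a plain matrix
#' @return list with `pi_der`, `pi_anc`, `ratio`, `n_der`, `n_anc`
#' @export
pi_ratio <- function(hm, focal = NULL) {
  if (inherits(hm, "haplotype_matrix")) {
    mat <- hm$mat
    if (is.null(focal)) focal <- hm$focal
  } else mat <- hm
  if (is.na(focal)) stop("no focal column declared")
  der <- mat[, focal] == 1L
  if (sum(der) < 2L || sum(!der) < 2L)
    stop("insufficient-haplotypes: need >= 2 chromosomes in each class (",
         sum(der), " derived, ", sum(!der), " ancestral)")
  rest <- mat[, -focal, drop = FALSE]
  pi_der <- nucleotide_diversity(rest[der, , drop = FALSE])
  pi_anc <- nucleotide_diversity(rest[!der, , drop = FALSE])
  if (pi_anc == 0)
    stop("undefined-ratio: ancestral class is monomorphic")
  list(pi_der = pi_der, pi_anc = pi_anc, ratio = pi_der / pi_anc,
       n_der = sum(der), n_anc = sum(!der))
}

#' Windowed diversity profile by allelic class
#'
#' Per-window pi (bp-normalised) for the derived and ancestral classes
#' along the span, the track plotted around candidate sweeps. The focal
#' column is excluded; windows without sites give `NA`.
#'
#' @param hm `haplotype_matrix` with focal column and bp positions
#' @param window_bp window width (default 10000)
#' @return data.frame: `window_start`, `window_end`, `pi_der`, `pi_anc`
#' @export
windowed_diversity_profile <- function(hm, window_bp = 10000) {
  der <- hm$mat[, hm$focal] == 1L
  starts <- seq(0, hm$span - 1e-9, by = window_bp)
  res <- lapply(starts, function(ws) {
    we <- min(ws + window_bp, hm$span)
    in_w <- which(hm$pos > ws & hm$pos <= we)
    in_w <- setdiff(in_w, hm$focal)
    if (length(in_w) == 0L)
      return(data.frame(window_start = ws, window_end = we,
                        pi_der = NA_real_, pi_anc = NA_real_))
    sub <- hm$mat[, in_w, drop = FALSE]
    data.frame(window_start = ws, window_end = we,
               pi_der = nucleotide_diversity(sub[der, , drop = FALSE],
                                             L = we - ws),
               pi_anc = nucleotide_diversity(sub[!der, , drop = FALSE],
                                             L = we - ws))
  })
  do.call(rbind, res)
}

#' Read haplotype blocks in ms format
#'
#' Parses Hudson's ms output (`//` blocks with `segsites:` and
#' `positions:` lines followed by 0/1 haplotype strings).
#'
#' @param path ms-format file
#' @param span span in bp that the unit interval of positions represents
#'   (default 1: keep positions as fractions)
#' @return list of `haplotype_matrix`
#' @export
read_ms <- function(path, span = 1) {
  lines <- readLines(path)
  starts <- grep("^//", lines)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    j <- starts[i] + 1L
    segsites <- as.integer(sub("segsites:\\s*", "", lines[j]))
    if (segsites == 0L) {
      out[[i]] <- haplotype_matrix(matrix(integer(0), nrow = 0),
                                   pos = numeric(0), span = span)
      next
    }
    pos <- as.numeric(strsplit(sub("positions:\\s*", "",
                                   lines[j + 1L]), "\\s+")[[1]])
    k <- j + 2L
    haps <- character(0)
    while (k <= length(lines) && grepl("^[01]+$", lines[k])) {
      haps <- c(haps, lines[k])
      k <- k + 1L
    }
    mat <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
    out[[i]] <- haplotype_matrix(mat, pos = pos * span, span = span)
  }
  out
}

#' Write haplotype matrices in ms format
#'
#' @param hms list of `haplotype_matrix` (or a single one)
#' @param path output file
#' @param header command-like first line (informational)
#' @return `path`, invisibly
#' @export
write_ms <- function(hms, path, header = "ms") {
  if (inherits(hms, "haplotype_matrix")) hms <- list(hms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, ""), con)
  for (hm in hms) {
    writeLines("//", con)
    writeLines(paste0("segsites: ", ncol(hm$mat)), con)
    if (ncol(hm$mat) > 0L) {
      writeLines(paste0("positions: ",
                        paste(sprintf("%.6f", hm$pos / hm$span),
                              collapse = " ")), con)
      writeLines(apply(hm$mat, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
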