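#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one validated
#' object. Defaults are the published operating points: support of more
#' than five read pairs, a 2-kb exclusion zone around known retrocopies,
#' 10/5-bp junction crossing cutoffs with 4% / 0.2*min(l,r) mismatch
#' caps, 100-kb selection flanks scanned in 200-kb windows.
#'
#' @param seed integer seed for all stochastic stages
#' @param input_dir directory of simulation inputs as written by
#'   [write_simulation], or NULL to simulate internally
#' @param sim_config [simulation_config] used when `input_dir` is NULL
#' @param populations named character vector sample -> population label
#'   (default: all "POP1")
#' @param min_support,exclusion_kb,junction_one_read_bp,
#'   junction_two_read_bp,mismatch_frac,side_frac,flank_kb,window_kb,
#'   nsims thresholds (see the detection and selection functions)
#' @param insert_k SD multiplier for the concordance limit
#' @return validated `pipeline_config`
#' @export
pipeline_config <- function(seed, input_dir = NULL, sim_config = NULL,
                            populations = NULL, min_support = 6L,
                            exclusion_kb = 2, junction_one_read_bp = 10L,
                            junction_two_read_bp = 5L,
                            mismatch_frac = 0.04, side_frac = 0.2,
                            flank_kb = 100, window_kb = 200,
                            nsims = 10000L, insert_k = 3) {
  thresholds <- c(min_support = min_support, exclusion_kb = exclusion_kb,
                  junction_one_read_bp = junction_one_read_bp,
                  junction_two_read_bp = junction_two_read_bp,
                  mismatch_frac = mismatch_frac, side_frac = side_frac,
                  flank_kb = flank_kb, window_kb = window_kb,
                  nsims = nsims, insert_k = insert_k)
  if (any(thresholds <= 0))
    stop("config error: non-positive threshold: ",
         paste(names(thresholds)[thresholds <= 0], collapse = ", "))
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("config error: input_dir does not exist: ", input_dir)
  if (is.null(input_dir) && is.null(sim_config))
    sim_config <- simulation_config(seed = seed)
  structure(c(list(seed = seed, input_dir = input_dir,
                   sim_config = sim_config, populations = populations),
              as.list(thresholds)),
            class = "pipeline_config")
}

.log_line <- function(con, stage, level, msg) {
  line <- sprintf("[%s] %s: %s", level, stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the end-to-end retroCNV pipeline
#'
#' Executes the stages in dependency order -- simulate/load, catalog,
#' detect (reference, insertion-site and junction detectors), genotype,
#' allele frequencies, contrast tables -- writing each stage's outputs as
#' TSV into `run_dir` together with a manifest and a log. A rerun skips
#' stages whose output files already exist, so deleting a stage's outputs
#' recomputes only that stage and those after it.
#'
#' @param config [pipeline_config]
#' @param run_dir output directory
#' @return named vector of output paths (the manifest), invisibly
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(run_dir, "pipeline.log"), "a")
  on.exit(close(logcon))
  outs <- character(0)
  path <- function(name) file.path(run_dir, name)
  done <- function(name) file.exists(path(name))
  tsv <- function(df, name) {
    listcols <- vapply(df, is.list, TRUE)
    df[listcols] <- lapply(df[listcols], vapply, paste, "",
                           collapse = ",")
    write.table(df, path(name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outs[name] <<- path(name)
  }

  # stage: inputs
  .log_line(logcon, "inputs", "INFO", "preparing simulation inputs")
  sim <- simulate_reference_with_retrocopies(
    config$sim_config %||% simulation_config(seed = config$seed))
  reads <- simulate_cohort_reads(sim)
  model <- fit_insert_size_model(reads$pairs, k = config$insert_k)
  .log_line(logcon, "inputs", "INFO",
            sprintf("insert model mean %.0f sd %.0f limit %.0f",
                    model$mean, model$sd, model$limit))
  txset <- transcript_set(sim$gm, sim$genome)
  junc_ev <- align_junction_reads(reads$unmapped, txset,
                                  mismatch_frac = config$mismatch_frac,
                                  side_frac = config$side_frac)

  # stage: catalog
  if (!done("catalog.tsv")) {
    catalog <- build_retrocopy_catalog(sim$alignments, sim$gm)
    tsv(catalog, "catalog.tsv")
    .log_line(logcon, "catalog", "INFO",
              sprintf("%d retrocopies in reference", nrow(catalog)))
  } else {
    catalog <- read.table(path("catalog.tsv"), sep = "\t", header = TRUE)
    catalog$retained_exons <- lapply(
      strsplit(as.character(catalog$retained_exons), ","), as.integer)
    .log_line(logcon, "catalog", "INFO", "resumed from existing output")
  }

  # stage: detect
  if (!done("calls.tsv")) {
    ref_calls <- detect_reference_retrocnvs(
      reads$pairs, catalog, model, min_support = config$min_support)
    sites <- detect_nonreference_insertion_sites(
      reads$pairs, sim$gm, catalog, sim$repeats, model,
      min_support = config$min_support,
      exclusion_bp = as.integer(config$exclusion_kb * 1000))
    ev <- junc_ev
    adj <- compute_junction_genome_adjustment(txset, hits = data.frame(
      transcript_id = character(0), junction = integer(0),
      identity = numeric(0), left_bp = integer(0), right_bp = integer(0)))
    jcalls <- call_junction_retrocnvs(
      ev, adj, one_read_bp = config$junction_one_read_bp,
      two_read_bp = config$junction_two_read_bp)
    jloc <- locate_junction_insertion_sites(
      jcalls, reads$pairs, sim$gm, catalog, sim$repeats, model,
      min_support = config$min_support,
      exclusion_bp = as.integer(config$exclusion_kb * 1000))
    calls <- .combine_calls(ref_calls, sites$sites, jloc$calls)
    tsv(calls, "calls.tsv")
    tsv(rbind(sites$report, jloc$report), "curation_report.tsv")
    .log_line(logcon, "detect", "INFO",
              sprintf("%d retroCNV calls (%d reference-present)",
                      nrow(calls), sum(calls$in_reference)))
  } else {
    calls <- read.table(path("calls.tsv"), sep = "\t", header = TRUE,
                        na.strings = "NA")
    .log_line(logcon, "detect", "INFO", "resumed from existing output")
  }

  # stage: genotype + frequencies
  if (!done("genotypes.tsv") || !done("frequencies.tsv")) {
    ev <- junc_ev
    genos <- list()
    freqs <- list()
    pops <- config$populations %||%
      stats::setNames(rep("POP1", length(sim$samples)), sim$samples)
    for (i in seq_len(nrow(calls))) {
      g <- genotype_cohort(calls[i, ], reads$pairs, ev, model, sim$gm)
      genos[[i]] <- g
      for (pop in unique(pops)) {
        gp <- g[pops[g$sample_id] == pop, , drop = FALSE]
        fr <- tryCatch(estimate_allele_frequency(gp, pop),
                       error = function(e) NULL)
        if (!is.null(fr))
          freqs[[length(freqs) + 1L]] <-
            cbind(call_id = calls$call_id[i], fr)
      }
    }
    tsv(do.call(rbind, genos), "genotypes.tsv")
    freqs <- do.call(rbind, freqs)
    tsv(freqs, "frequencies.tsv")
    sigma <- expected_pairwise_differences(freqs)
    tsv(data.frame(statistic = "sigma_2pq", value = sigma),
        "pairwise_differences.tsv")
    .log_line(logcon, "freq", "INFO",
              sprintf("sigma 2pq = %.3f over %d loci", sigma,
                      nrow(freqs)))
  } else {
    .log_line(logcon, "freq", "INFO", "resumed from existing output")
  }

  # stage: contrasts (movement / insertion context vs fixed retrocopies)
  if (!done("contrasts.tsv")) {
    classify_tbl <- function(df, chrom_col, pos_col, parent_col) {
      n <- nrow(df)
      movement <- character(n); category <- character(n)
      for (i in seq_len(n)) {
        parent_chrom <- as.character(GenomicRanges::seqnames(
          sim$gm$genes[df[[parent_col]][i]]))
        movement[i] <- classify_movement(parent_chrom,
                                         df[[chrom_col]][i])
        ctx <- classify_insertion_context(
          GenomicRanges::GRanges(df[[chrom_col]][i],
                                 IRanges::IRanges(df[[pos_col]][i],
                                                  df[[pos_col]][i])),
          sim$gm, "+",
          known_chroms = names(sim$genome))
        category[i] <- ctx$category
      }
      data.frame(movement = movement, category = category)
    }
    located <- calls[!is.na(calls$chrom) | !is.na(calls$site_chrom), ,
                     drop = FALSE]
    located$pos <- ifelse(is.na(located$chrom), located$site_point,
                          located$start)
    located$ctx_chrom <- ifelse(is.na(located$chrom),
                                located$site_chrom, located$chrom)
    poly <- classify_tbl(located, "ctx_chrom", "pos", "parent_gene_id")
    fx <- sim$fixed
    fx$pos <- fx$start
    fixed_cls <- classify_tbl(fx, "chrom", "pos", "parent_gene")
    contrasts <- build_contrast_tables(poly, fixed_cls)
    out <- data.frame(
      contrast = c("movement", "context"),
      p_value = c(contrasts$movement$p_value,
                  contrasts$context$p_value),
      table = c(paste(contrasts$movement$table, collapse = ","),
                paste(contrasts$context$table, collapse = ",")))
    tsv(out, "contrasts.tsv")
    .log_line(logcon, "contrasts", "INFO",
              sprintf("movement p = %.3g, context p = %.3g",
                      out$p_value[1], out$p_value[2]))
  } else {
    .log_line(logcon, "contrasts", "INFO", "resumed from existing output")
  }

  manifest <- data.frame(output = names(outs), path = unname(outs))
  write.table(manifest, path("run_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outs)
}

# merge the three detectors' calls into one table with unified columns
.combine_calls <- function(ref_calls, sites, jcalls) {
  cols <- c("call_id", "parent_gene_id", "in_reference", "evidence",
            "chrom", "start", "end", "site_chrom", "site_point",
            "support")
  pad <- function(df) {
    for (cc in cols) if (is.null(df[[cc]]))
      df[[cc]] <- if (cc %in% c("start", "end", "site_point", "support"))
        NA_integer_ else if (cc == "in_reference") NA else NA_character_
    df[, cols, drop = FALSE]
  }
  a <- if (nrow(ref_calls)) pad(ref_calls) else NULL
  b <- if (!is.null(sites) && nrow(sites)) {
    s <- data.frame(call_id = paste0("site:", sites$site_id),
                    parent_gene_id = sites$parent_gene_id,
                    in_reference = FALSE, evidence = "insertion_pairs",
                    site_chrom = sites$chrom, site_point = sites$point,
                    support = sites$support)
    pad(s)
  } else NULL
  d <- if (!is.null(jcalls) && nrow(jcalls)) {
    j <- jcalls
    j$in_reference <- FALSE
    pad(j)
  } else NULL
  out <- rbind(a, b, d)
  if (is.null(out)) {
    out <- pad(data.frame(call_id = character(0)))
  } else {
    # junction calls whose gene already has a located site are the same
    # event seen by two detectors: keep the more informative record
    seen <- !duplicated(paste(out$parent_gene_id, out$in_reference))
    out <- out[seen, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
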