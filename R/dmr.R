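#' Call DMRs by merging adjacent significant windows
#'
#' Windows with `p_value < p_threshold` (strict inequality) are grouped
#' into maximal runs of genomically contiguous tested windows on the same
#' chromosome: adjacency means consecutive genome-wide window indices, so
#' windows separated by a filtered-out (untested) window are NOT adjacent
#' and start a new run. Each run becomes one DMR spanning the first
#' window's start to the last window's end; boundaries never extend into
#' flanking non-significant windows.
#'
#' Per DMR the table records the number of significant windows, the
#' minimum window p-value and q-value, and the signed log2 fold change of
#' the constituent window with the largest absolute fold change (maxLFC;
#' positive = methylation gain in cases). Names are `DMR_<chrom>_<k>` in
#' genomic order.
#'
#' @param results Per-window results from [diff_test()] (needs `chrom`,
#'   `start`, `end`, `index`, `p_value`, `log_fc`, and `q_value`).
#' @param p_threshold Significance cutoff, in (0, 1]; default 1e-4.
#' @param comparison_label Label stored on the set.
#' @param cutoffs Ladder of cutoffs for the threshold table.
#' @return A `dmr_set`: list with `dmrs` (data frame), `p_threshold`,
#'   `comparison_label`, and `threshold_table`.
#' @export
call_dmrs <- function(results, p_threshold = 1e-4, comparison_label = "comparison",
                      cutoffs = c(1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7)) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]")
  }
  dmrs <- .merge_significant(results, p_threshold)
  structure(
    list(
      comparison_label = comparison_label,
      p_threshold = p_threshold,
      dmrs = dmrs,
      threshold_table = threshold_ladder(results, cutoffs)
    ),
    class = "dmr_set"
  )
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("dmr_set '", x$comparison_label, "': ", nrow(x$dmrs),
      " DMRs at p < ", format(x$p_threshold), "\n", sep = "")
  invisible(x)
}

# Run-merging core: returns the completed DMR data frame.
.merge_significant <- function(results, p_threshold) {
  empty <- data.frame(
    name = character(), chrom = character(), start = integer(),
    stop = integer(), length = integer(), n_sig_windows = integer(),
    min_p = numeric(), min_fdr = numeric(), max_lfc = numeric(),
    stringsAsFactors = FALSE
  )
  sig <- results[results$p_value < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$index), , drop = FALSE]
  run <- cumsum(c(1L, (diff(sig$index) != 1L) |
                    (sig$chrom[-1] != sig$chrom[-nrow(sig)])))
  pieces <- lapply(split(seq_len(nrow(sig)), run), function(rows) {
    s <- sig[rows, , drop = FALSE]
    data.frame(
      chrom = s$chrom[1],
      start = min(s$start),
      stop = max(s$end),
      length = max(s$end) - min(s$start),
      n_sig_windows = nrow(s),
      min_p = min(s$p_value),
      min_fdr = if (!is.null(s$q_value)) min(s$q_value) else NA_real_,
      max_lfc = s$log_fc[which.max(abs(s$log_fc))],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(match(out$chrom, unique(results$chrom)), out$start), ,
             drop = FALSE]
  k <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
  out <- cbind(name = sprintf("DMR_%s_%d", out$chrom, k), out)
  rownames(out) <- NULL
  out
}

#' DMR counts across a ladder of p-value cutoffs
#'
#' For each cutoff, counts all DMRs and the subset containing at least two
#' adjacent significant windows. Counts are non-increasing as the cutoff
#' tightens.
#'
#' @param results Per-window results table.
#' @param cutoffs Numeric cutoffs (any order).
#' @return Data frame `cutoff`, `n_all`, `n_multi`.
#' @export
threshold_ladder <- function(results,
                             cutoffs = c(1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7)) {
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  rows <- lapply(cutoffs, function(ct) {
    d <- .merge_significant(results, ct)
    data.frame(cutoff = ct, n_all = nrow(d),
               n_multi = sum(d$n_sig_windows >= 2))
  })
  do.call(rbind, rows)
}

#' Complete a DMR table with CpG counts and densities
#'
#' Counts CG dinucleotides in each DMR span `[start, stop)` of the genome
#' sequence and derives the density per 100 bp.
#'
#' @param dmr_set A `dmr_set` (or its `dmrs` data frame).
#' @param genome A `genome_model` (or named character vector of sequences).
#' @return The `dmr_set` with `cpg_count` and `cpg_density` columns filled.
#' @export
summarize_dmr <- function(dmr_set, genome) {
  dmrs <- if (inherits(dmr_set, "dmr_set")) dmr_set$dmrs else dmr_set
  seqs <- if (inherits(genome, "genome_model")) genome$sequence else genome
  lens <- nchar(seqs)
  if (nrow(dmrs)) {
    bad <- dmrs$stop > lens[dmrs$chrom]
    if (any(bad)) {
      stop("DMR span beyond chromosome end: ",
           paste(dmrs$name[bad], collapse = ", "))
    }
  }
  dmrs$cpg_count <- vapply(seq_len(nrow(dmrs)), function(i) {
    span <- substr(seqs[[dmrs$chrom[i]]], dmrs$start[i] + 1L, dmrs$stop[i])
    length(cg_positions(span))
  }, integer(1))
  dmrs$cpg_density <- dmrs$cpg_count * 100 / dmrs$length
  if (inherits(dmr_set, "dmr_set")) {
    dmr_set$dmrs <- dmrs
    dmr_set
  } else {
    dmrs
  }
}

#' DMR size and CpG-density distributions
#'
#' Histogram tables of DMR lengths (1 kb bins, labelled by kb) and CpG
#' densities (1 CpG/100 bp bins). Bin counts sum to the number of DMRs.
#'
#' @param dmr_set A `dmr_set` whose table has `cpg_density` (run
#'   [summarize_dmr()] first, or pass `genome`).
#' @param genome Optional genome to fill CpG columns if absent.
#' @return List with `length_hist` (`kb`, `count`) and `density_hist`
#'   (`density_lo`, `density_hi`, `count`).
#' @export
size_and_density_distributions <- function(dmr_set, genome = NULL) {
  if (!is.null(genome)) dmr_set <- summarize_dmr(dmr_set, genome)
  dmrs <- dmr_set$dmrs
  if (nrow(dmrs) == 0) {
    return(list(length_hist = data.frame(kb = integer(), count = integer()),
                density_hist = data.frame(density_lo = numeric(),
                                          density_hi = numeric(),
                                          count = integer())))
  }
  kb <- ceiling(dmrs$length / 1000)
  length_hist <- as.data.frame(table(kb = factor(kb, levels = seq_len(max(kb)))),
                               stringsAsFactors = FALSE)
  names(length_hist) <- c("kb", "count")
  length_hist$kb <- as.integer(length_hist$kb)

  if (is.null(dmrs$cpg_density)) {
    stop("cpg_density missing; run summarize_dmr() or supply genome")
  }
  hi <- max(1, ceiling(max(dmrs$cpg_density)))
  bins <- cut(dmrs$cpg_density, breaks = 0:hi, include.lowest = TRUE,
              right = FALSE)
  # right-open [lo, hi) bins except the last, which is closed to catch the max
  bins[dmrs$cpg_density == hi] <- levels(bins)[hi]
  density_hist <- data.frame(
    density_lo = 0:(hi - 1),
    density_hi = 1:hi,
    count = as.integer(table(bins))
  )
  list(length_hist = length_hist, density_hist = density_hist)
}

#' Write a DMR table as TSV
#'
#' Columns mirror the per-region summary schema: name, location, length,
#' number of significant 1 kb windows, minimum p and FDR, maxLFC, CpG count
#' and density, and associated genes/categories when annotated.
#'
#' @param dmr_set A `dmr_set`.
#' @param path Output path.
#' @export
write_dmr_tsv <- function(dmr_set, path) {
  dmrs <- dmr_set$dmrs
  for (col in c("cpg_count", "cpg_density", "genes", "categories")) {
    if (is.null(dmrs[[col]])) dmrs[[col]] <- NA
  }
  data.table::fwrite(dmrs, path, sep = "\t")
  invisible(path)
}

#' Write DMRs as BED6 (score = -log10 min p)
#'
#' @param dmr_set A `dmr_set`.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmr_set, path) {
  d <- dmr_set$dmrs
  data.table::fwrite(
    data.frame(chrom = d$chrom, start = d$start, end = d$stop, name = d$name,
               score = round(-log10(pmax(d$min_p, 1e-300)), 3), strand = "."),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}
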