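#' Venn-style overlap of DMR sets
#'
#' Two DMRs overlap when their half-open intervals intersect by at least
#' 1 bp on the same chromosome. The pooled intervals of all sets are
#' merged into union components; each component is assigned the full
#' pattern of sets with at least one DMR intersecting it, and components
#' are counted per pattern. Pattern counts therefore sum to the number of
#' union components.
#'
#' @param dmr_sets Named list of `dmr_set` objects (or DMR data frames).
#' @return Data frame `pattern` (set names joined by `&`), `count`, with
#'   attribute `set_totals` (DMRs per input set).
#' @export
venn_overlap <- function(dmr_sets) {
  if (is.null(names(dmr_sets)) || any(names(dmr_sets) == "")) {
    stop("dmr_sets must be a named list")
  }
  tabs <- lapply(dmr_sets, function(x) if (inherits(x, "dmr_set")) x$dmrs else x)
  pooled <- do.call(rbind, lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]
    if (nrow(t) == 0) return(NULL)
    data.frame(chrom = t$chrom, start = t$start, end = t$stop, set = nm,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- data.frame(pattern = character(), count = integer())
    attr(out, "set_totals") <- vapply(tabs, nrow, integer(1))
    return(out)
  }
  comp <- merge_intervals(pooled)
  patterns <- vapply(seq_len(nrow(comp)), function(i) {
    member <- vapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      any(t$chrom == comp$chrom[i] & t$start < comp$end[i] &
            t$stop > comp$start[i])
    }, logical(1))
    paste(names(tabs)[member], collapse = "&")
  }, character(1))
  tab <- table(patterns)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "set_totals") <- vapply(tabs, nrow, integer(1))
  out
}

#' Merge overlapping intervals into union components
#'
#' Half-open intervals; abutting intervals (end == next start) are NOT
#' merged, since they share no bp.
#'
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @return Data frame of disjoint components, sorted.
#' @export
merge_intervals <- function(intervals) {
  iv <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                  drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(iv))) {
    if (!is.null(cur) && iv$chrom[i] == cur$chrom && iv$start[i] < cur$end) {
      cur$end <- max(cur$end, iv$end[i])
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(chrom = iv$chrom[i], start = iv$start[i], end = iv$end[i])
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  do.call(rbind, lapply(out, as.data.frame))
}

#' Extended overlap of strict DMRs against relaxed windows
#'
#' Entry (i, j) counts the DMRs of comparison i (called at the strict
#' threshold) that intersect at least one window of comparison j
#' significant at the relaxed threshold, with the percent of comparison
#' i's total. Since every strict DMR is built from windows significant at
#' p < p_strict <= p_relaxed, the diagonal is exactly 100% whenever the
#' row set is non-empty.
#'
#' @param strict_sets Named list of `dmr_set` objects (rows).
#' @param relaxed_results Named list of per-window results tables
#'   (columns); every name in `strict_sets` must be present.
#' @param p_relaxed Relaxed window threshold (default 0.05).
#' @return An `overlap_matrix`: list with `counts`, `percents` (rows x
#'   cols matrices) and `row_totals`.
#' @export
extended_overlap <- function(strict_sets, relaxed_results, p_relaxed = 0.05) {
  rn <- names(strict_sets)
  cn <- names(relaxed_results)
  missing_cols <- setdiff(rn, cn)
  if (length(missing_cols)) {
    stop("missing relaxed results for comparison: ",
         paste(missing_cols, collapse = ", "))
  }
  counts <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
  percents <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))
  totals <- stats::setNames(integer(length(rn)), rn)
  for (i in rn) {
    d <- strict_sets[[i]]$dmrs
    totals[i] <- nrow(d)
    for (j in cn) {
      rr <- relaxed_results[[j]]
      win <- rr[rr$p_value < p_relaxed, , drop = FALSE]
      n_hit <- if (nrow(d) == 0) 0L else sum(vapply(seq_len(nrow(d)), function(k) {
        any(win$chrom == d$chrom[k] & win$start < d$stop[k] &
              win$end > d$start[k])
      }, logical(1)))
      counts[i, j] <- n_hit
      percents[i, j] <- if (nrow(d) > 0) 100 * n_hit / nrow(d) else NA_real_
    }
  }
  structure(list(counts = counts, percents = percents, row_totals = totals),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("extended overlap (percent of row DMRs):\n")
  print(round(x$percents, 1))
  invisible(x)
}

#' Chromosomal clusters of DMRs
#'
#' Deterministic single-linkage chaining of DMR midpoints: maximal groups
#' of at least `min_dmrs` DMRs on one chromosome in which consecutive
#' midpoints are at most `span` bp apart.
#'
#' @param dmr_set A `dmr_set` or DMR data frame.
#' @param span Maximum gap between consecutive DMR midpoints, bp.
#' @param min_dmrs Minimum DMRs per cluster (>= 2).
#' @return Data frame `chrom`, `start`, `end`, `dmr_count` (cluster span =
#'   min start to max stop of members).
#' @export
find_clusters <- function(dmr_set, span = 2e6, min_dmrs = 3) {
  stopifnot(span > 0, min_dmrs >= 2)
  d <- if (inherits(dmr_set, "dmr_set")) dmr_set$dmrs else dmr_set
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      dmr_count = integer(), stringsAsFactors = FALSE)
  if (nrow(d) == 0) return(empty)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  mid <- (d$start + d$stop) %/% 2
  grp <- cumsum(c(1L, (diff(mid) > span) | (d$chrom[-1] != d$chrom[-nrow(d)])))
  pieces <- lapply(split(seq_len(nrow(d)), grp), function(rows) {
    if (length(rows) < min_dmrs) return(NULL)
    data.frame(chrom = d$chrom[rows[1]], start = min(d$start[rows]),
               end = max(d$stop[rows]), dmr_count = length(rows),
               stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write an overlap matrix as TSV
#'
#' @param overlap An `overlap_matrix`.
#' @param path Output path.
#' @export
write_overlap_tsv <- function(overlap, path) {
  df <- data.frame(
    comparison = rownames(overlap$counts),
    total = overlap$row_totals,
    stringsAsFactors = FALSE
  )
  for (j in colnames(overlap$counts)) {
    df[[paste0(j, "_n")]] <- overlap$counts[, j]
    df[[paste0(j, "_pct")]] <- overlap$percents[, j]
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
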