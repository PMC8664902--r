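#' Tile a genome into fixed-size windows
#'
#' Partitions every chromosome into contiguous, non-overlapping windows of
#' `window_size` bp (default 1 kb, the analysis unit of the workflow). The
#' final window of each chromosome is truncated at the chromosome end rather
#' than dropped, so the tiling is an exact partition of the genome. All
#' coordinates are 0-based half-open (BED convention).
#'
#' @param chrom_sizes Chromosome lengths: a named numeric vector, a
#'   two-column data frame (`chrom`, `size`), a path to a two-column
#'   `chrom.sizes` TSV, or a [genome_model] object.
#' @param window_size Window width in bp; must be >= 100.
#' @return A `window_set`: a data frame with columns `chrom`, `start`,
#'   `end` and `index` (ordinal over the whole genome), sorted by
#'   (chrom, start), with attributes `window_size` and `chrom_sizes`.
#' @examples
#' tile_genome(c(chr1 = 2500), window_size = 1000)
#' @export
tile_genome <- function(chrom_sizes, window_size = 1000) {
  cs <- as_chrom_sizes(chrom_sizes)
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 100) {
    stop("window_size must be a single number >= 100")
  }
  window_size <- as.integer(window_size)
  per_chrom <- lapply(names(cs), function(ch) {
    len <- cs[[ch]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(
      chrom = ch,
      start = starts,
      end = pmin(starts + window_size, len),
      stringsAsFactors = FALSE
    )
  })
  w <- do.call(rbind, per_chrom)
  w$index <- seq_len(nrow(w))
  rownames(w) <- NULL
  attr(w, "window_size") <- window_size
  attr(w, "chrom_sizes") <- cs
  class(w) <- c("window_set", "data.frame")
  w
}

#' Normalize chromosome-size input
#'
#' @param x Named numeric vector, data frame, file path, or `genome_model`.
#' @return Named integer vector of chromosome lengths.
#' @keywords internal
as_chrom_sizes <- function(x) {
  if (inherits(x, "genome_model")) {
    cs <- x$chrom_lengths
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    tab <- data.table::fread(x, header = FALSE, col.names = c("chrom", "size"))
    cs <- stats::setNames(tab$size, tab$chrom)
  } else if (is.data.frame(x)) {
    cs <- stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else if (is.numeric(x) && !is.null(names(x))) {
    cs <- x
  } else {
    stop("cannot interpret chrom_sizes input")
  }
  if (anyDuplicated(names(cs))) {
    stop("duplicate chromosome names: ",
         paste(unique(names(cs)[duplicated(names(cs))]), collapse = ", "))
  }
  if (any(cs < 1)) {
    stop("zero-length chromosome: ",
         paste(names(cs)[cs < 1], collapse = ", "))
  }
  storage.mode(cs) <- "integer"
  cs
}

#' Construct a window-count container
#'
#' Internal constructor for the windows x samples count matrix used
#' throughout the workflow. Library sizes are the column sums at
#' construction time.
#'
#' @param counts Integer matrix, windows in rows, samples in columns.
#' @param windows The `window_set` rows corresponding to `counts` rows.
#' @param library_sizes Optional per-sample totals; defaults to column sums.
#' @param skipped Optional named tally of fragments not assignable to any
#'   window (unknown chromosome / out of bounds).
#' @keywords internal
medip_counts <- function(counts, windows, library_sizes = NULL, skipped = NULL) {
  stopifnot(nrow(counts) == nrow(windows))
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  rownames(counts) <- sprintf("%s:%d-%d", windows$chrom, windows$start, windows$end)
  structure(
    list(
      counts = counts,
      windows = windows,
      samples = colnames(counts),
      library_sizes = library_sizes,
      skipped = skipped
    ),
    class = "medip_counts"
  )
}

#' @export
print.medip_counts <- function(x, ...) {
  cat("medip_counts:", nrow(x$counts), "windows x", ncol(x$counts), "samples\n")
  cat("  library sizes:", paste(range(x$library_sizes), collapse = " - "), "\n")
  if (!is.null(x$skipped) && any(x$skipped > 0)) {
    cat("  skipped fragments:", sum(x$skipped), "\n")
  }
  invisible(x)
}

#' @export
dim.medip_counts <- function(x) dim(x$counts)

#' Count fragments per window by midpoint
#'
#' Assigns each fragment to exactly one window: the window containing its
#' midpoint `floor((start + end) / 2)`. Fragments on chromosomes absent
#' from the window set, or with midpoints outside chromosome bounds, are
#' tallied as skipped (reported in the result) rather than silently dropped.
#'
#' @param fragments A named list of per-sample fragment tables (data frames
#'   with columns `chrom`, `start`, `end`, 0-based half-open), or a named
#'   character vector of BED3 file paths (plain or gzipped).
#' @param windows A `window_set` from [tile_genome()].
#' @return A `medip_counts` object; `$skipped` holds the per-sample tally
#'   of unassignable fragments.
#' @export
count_fragments <- function(fragments, windows) {
  stopifnot(inherits(windows, "window_set"))
  cs <- attr(windows, "chrom_sizes")
  wsize <- attr(windows, "window_size")
  n_per_chrom <- vapply(names(cs), function(ch) sum(windows$chrom == ch), integer(1))
  offset <- stats::setNames(cumsum(c(0L, n_per_chrom[-length(n_per_chrom)])), names(cs))

  if (is.character(fragments)) {
    paths <- fragments
    if (is.null(names(paths)) || any(names(paths) == "")) {
      names(paths) <- sub("\\.bed(\\.gz)?$", "", basename(paths))
    }
    fragments <- lapply(paths, function(p) {
      data.table::fread(p, header = FALSE, col.names = c("chrom", "start", "end"),
                        colClasses = list(character = 1, integer = 2:3))
    })
  }
  if (is.null(names(fragments))) {
    stop("fragments must be named by sample id")
  }

  total <- nrow(windows)
  mats <- matrix(0L, nrow = total, ncol = length(fragments),
                 dimnames = list(NULL, names(fragments)))
  skipped <- stats::setNames(integer(length(fragments)), names(fragments))
  for (s in seq_along(fragments)) {
    fr <- fragments[[s]]
    mid <- (as.numeric(fr$start) + as.numeric(fr$end)) %/% 2
    chrom <- as.character(fr$chrom)
    known <- chrom %in% names(cs)
    inb <- known
    inb[known] <- mid[known] >= 0 & mid[known] < cs[chrom[known]]
    skipped[s] <- sum(!inb)
    if (any(inb)) {
      idx <- offset[chrom[inb]] + mid[inb] %/% wsize + 1L
      mats[, s] <- tabulate(idx, nbins = total)
    }
  }
  medip_counts(mats, windows, skipped = skipped)
}

#' Filter low-count windows
#'
#' Retains windows whose mean raw count across all samples is at least
#' `min_avg_count` (inclusive). The `index` column of the retained windows
#' preserves genomic identity, so downstream adjacency logic treats windows
#' separated by a filtered-out window as non-adjacent. Library sizes are
#' kept at their full-depth (pre-filter) values, since they describe
#' sequencing depth, not the tested subset.
#'
#' @param counts A `medip_counts` object.
#' @param min_avg_count Minimum mean count per window across samples.
#' @return A `medip_counts` subset with attribute `kept_index` mapping
#'   retained rows to original window indices.
#' @export
filter_windows <- function(counts, min_avg_count = 5) {
  stopifnot(inherits(counts, "medip_counts"), min_avg_count >= 0)
  keep <- rowMeans(counts$counts) >= min_avg_count
  if (!any(keep)) {
    stop("filtering removed all windows; reduce min_avg_count (currently ",
         min_avg_count, ")")
  }
  out <- medip_counts(
    counts$counts[keep, , drop = FALSE],
    counts$windows[keep, , drop = FALSE],
    library_sizes = counts$library_sizes,
    skipped = counts$skipped
  )
  attr(out, "kept_index") <- counts$windows$index[keep]
  out
}

#' Write a count matrix as TSV
#'
#' Rows are labelled `chrom:start-end`; columns are sample ids.
#'
#' @param counts A `medip_counts` object.
#' @param path Output file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.table::data.table(window = rownames(counts$counts))
  df <- cbind(df, data.table::as.data.table(counts$counts))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write windows as BED3
#'
#' @param windows A `window_set`.
#' @param path Output file path.
#' @export
write_windows_bed <- function(windows, path) {
  data.table::fwrite(windows[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}
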