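#' Normalized log-CPM matrix over DMR windows
#'
#' log2(CPM + 1) using TMM effective library sizes, restricted to the
#' DMR-constituent windows, samples in rows. Doubling a sample's counts
#' together with its library size leaves its row unchanged (CPM
#' invariance).
#'
#' @param counts A `medip_counts` object.
#' @param window_index Genome-wide indices of the DMR-constituent windows.
#' @param normalization A `norm_state` from [tmm_factors()].
#' @return Numeric matrix, samples x windows, rownames = sample ids.
#' @export
normalize_for_pca <- function(counts, window_index, normalization) {
  rows <- match(window_index, counts$windows$index)
  if (length(rows) == 0 || anyNA(rows)) {
    stop("empty or unmatched DMR window set; call DMRs (with at least one ",
         "significant window) before PCA")
  }
  eff <- normalization$effective_lib_sizes
  cpm <- sweep(counts$counts[rows, , drop = FALSE], 2, eff / 1e6, "/")
  t(log2(cpm + 1))
}

#' Indices of the significant windows composing a DMR set
#'
#' @param dmr_set A `dmr_set`.
#' @param results The per-window results table the set was called from.
#' @return Integer vector of genome-wide window indices.
#' @export
dmr_window_indices <- function(dmr_set, results) {
  d <- dmr_set$dmrs
  sig <- results[results$p_value < dmr_set$p_threshold, , drop = FALSE]
  keep <- vapply(seq_len(nrow(sig)), function(i) {
    any(d$chrom == sig$chrom[i] & d$start <= sig$start[i] &
          d$stop >= sig$end[i])
  }, logical(1))
  sort(sig$index[keep])
}

#' Principal component analysis with a deterministic sign convention
#'
#' Column-centered SVD. Scores are the projections onto the right singular
#' directions; each component's sign is fixed by making its
#' largest-magnitude loading positive, so results are byte-stable across
#' runs and sample orderings. A constant matrix yields zero scores and
#' zero variance explained.
#'
#' @param x Numeric matrix, samples x features.
#' @param n_components Components to retain (default 2, for a PC1/PC2
#'   view; capped at the matrix rank bound).
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `variance_explained` (fraction per component over total variance),
#'   `loadings`, and `component_count`.
#' @export
compute_pca <- function(x, n_components = 2) {
  if (nrow(x) < 2 || ncol(x) < 2) stop("PCA needs >= 2 samples and >= 2 features")
  xc <- sweep(x, 2, colMeans(x))
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  s <- svd(xc)
  total <- sum(s$d^2)
  if (total < 1e-12) {
    scores <- matrix(0, nrow(x), k,
                     dimnames = list(rownames(x), paste0("PC", seq_len(k))))
    return(structure(list(scores = scores,
                          variance_explained = rep(0, k),
                          loadings = matrix(0, ncol(x), k),
                          component_count = k),
                     class = "pca_result"))
  }
  u <- s$u[, seq_len(k), drop = FALSE]
  v <- s$v[, seq_len(k), drop = FALSE]
  d <- s$d[seq_len(k)]
  for (j in seq_len(k)) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- sweep(u, 2, d, "*")
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  structure(
    list(scores = scores,
         variance_explained = (s$d^2 / total)[seq_len(k)],
         loadings = v,
         component_count = k),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", x$component_count,
      "components; variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write PCA scores as TSV
#'
#' @param pca A `pca_result`.
#' @param groups Optional group labels aligned with score rows.
#' @param path Output path.
#' @export
write_pca_tsv <- function(pca, groups = NULL, path) {
  df <- data.frame(sample_id = rownames(pca$scores), stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- as.character(groups)
  df <- cbind(df, as.data.frame(pca$scores))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
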