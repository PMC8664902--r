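# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the package's own code paths.

# Per-bp window assignment: linear scan over windows for each fragment midpoint.
oracle_count_fragments <- function(fragments, windows) {
  mats <- matrix(0L, nrow(windows), length(fragments),
                 dimnames = list(NULL, names(fragments)))
  for (s in seq_along(fragments)) {
    fr <- fragments[[s]]
    for (i in seq_len(nrow(fr))) {
      mid <- (fr$start[i] + fr$end[i]) %/% 2
      for (wi in seq_len(nrow(windows))) {
        if (windows$chrom[wi] == fr$chrom[i] &&
            mid >= windows$start[wi] && mid < windows$end[wi]) {
          mats[wi, s] <- mats[wi, s] + 1L
          break
        }
      }
    }
  }
  mats
}

# O(n^2) run merging: grow connected components over significant windows,
# where two windows connect iff their genome-wide indices differ by 1 and
# they share a chromosome.
oracle_merge_runs <- function(sig) {
  n <- nrow(sig)
  if (n == 0) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          sig$chrom[i] == sig$chrom[j] &&
          abs(sig$index[i] - sig$index[j]) == 1) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), comp), function(rows) {
    c(start = min(sig$start[rows]), stop = max(sig$end[rows]),
      n = length(rows))
  }))
}

# Sliding 2-mer scan for CG counting.
oracle_cg_count <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(0L)
  sum(vapply(1:(n - 1), function(i) substr(seq, i, i + 1) == "CG", logical(1)))
}

# All-pairs half-open interval intersection.
oracle_any_overlap <- function(a, b) {
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          b$start[j] < a$end[i]) {
        hits[i] <- TRUE
        break
      }
    }
  }
  hits
}

# All-pairs single-linkage chaining of midpoints within `span`.
oracle_clusters <- function(d, span, min_dmrs) {
  n <- nrow(d)
  if (n == 0) return(integer())
  mid <- (d$start + d$stop) %/% 2
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && d$chrom[i] == d$chrom[j] &&
          abs(mid[i] - mid[j]) <= span) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  sort(as.integer(sizes[sizes >= min_dmrs]), decreasing = TRUE)
}

# Mean silhouette of a 2-group labelling on a score matrix (euclidean).
mean_silhouette <- function(scores, labels) {
  dmat <- as.matrix(dist(scores))
  n <- nrow(scores)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(dmat[i, own])
    b <- mean(dmat[i, !own & seq_len(n) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Small per-window results table over a toy tiling, for DMR-caller tests.
toy_results <- function(p, chrom = "chr1", window_size = 1000,
                        lfc = rep(1, length(p)), q = NULL) {
  n <- length(p)
  data.frame(
    chrom = chrom,
    start = (seq_len(n) - 1L) * window_size,
    end = seq_len(n) * window_size,
    index = seq_len(n),
    log_fc = lfc,
    log_cpm = 5,
    p_value = p,
    q_value = if (is.null(q)) pmin(1, p * 2) else q,
    stringsAsFactors = FALSE
  )
}

# Shared moderate-scale synthetic dataset with injected DMRs, built once
# per test file that sources it via fixture_injected().
fixture_injected_cache <- new.env()
fixture_injected <- function() {
  if (!is.null(fixture_injected_cache$obj)) return(fixture_injected_cache$obj)
  spec <- default_genome_spec(n_chrom = 2, chrom_length = 5e5)
  genome <- generate_genome(spec, seed = 7)
  windows <- tile_genome(genome)
  cohort <- simulate_cohort(13, 13, seed = 11, mean_lib = 1.25e5)
  truth <- ground_truth(windows, n_regions = 8, n_windows_range = c(1, 3),
                        lfc = c(-2, 2), dispersion = 0.1, seed = 3)
  counts <- simulate_window_counts(genome, windows, cohort, truth, seed = 5)
  filtered <- filter_windows(counts, 5)
  results <- diff_test(filtered, cohort$group)
  dmrs <- summarize_dmr(call_dmrs(results, 1e-4, "synthetic"), genome)
  obj <- list(genome = genome, windows = windows, cohort = cohort,
              truth = truth, counts = counts, filtered = filtered,
              results = results, dmrs = dmrs)
  fixture_injected_cache$obj <- obj
  obj
}
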