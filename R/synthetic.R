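#' Default synthetic genome design
#'
#' Desk-scale genome: `n_chrom` chromosomes of `chrom_length` bp, divided
#' into `block` bp regions whose CpG-density targets cycle through
#' `densities` (CpG per 100 bp). The defaults span the low-density
#' "CpG desert" range (1-3 CpG/100 bp) that dominates MeDIP DMRs, plus
#' occasional denser blocks, so that window baselines vary realistically.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param block Region size for CpG-density targets, bp.
#' @param densities CpG-density targets cycled across blocks, per 100 bp.
#' @return A genome-spec list consumable by [generate_genome()].
#' @export
default_genome_spec <- function(n_chrom = 2, chrom_length = 1e6, block = 5e4,
                                densities = c(1, 2, 3, 2, 1, 2, 3, 8)) {
  chroms <- lapply(seq_len(n_chrom), function(i) {
    starts <- seq(0, chrom_length - 1, by = block)
    ends <- pmin(starts + block, chrom_length)
    d <- rep_len(densities, length(starts))
    list(
      name = paste0("chr", i),
      length = as.integer(chrom_length),
      regions = data.frame(start = starts, end = ends, density = d)
    )
  })
  list(chroms = chroms)
}

#' Generate a synthetic genome with a designed CpG landscape
#'
#' Builds each chromosome from a CG-free random background, then plants
#' `round(L * d / 100)` CG dinucleotides into each designed region of
#' length `L` and target density `d` (CpG per 100 bp), at random
#' non-overlapping positions. Realized density therefore matches the
#' target exactly up to rounding, and a region designed at density 0
#' contains no CG at all.
#'
#' @param spec Genome spec as from [default_genome_spec()]: a list with
#'   `chroms`, each holding `name`, `length` and a `regions` data frame
#'   (`start`, `end`, `density`). Regions must tile the chromosome.
#' @param seed Integer seed; the generator is reproducible for a fixed seed.
#' @return A `genome_model`: list with `chrom_names`, `chrom_lengths`
#'   (named), `sequence` (named character vector) and `cpg_profile`
#'   (data frame `chrom`, `start`, `end`, `density`).
#' @export
generate_genome <- function(spec = default_genome_spec(), seed = 1) {
  local_seed(seed)
  seqs <- list()
  profile <- list()
  for (ch in spec$chroms) {
    if (is.null(ch$length) || ch$length < 1) {
      stop("zero-length chromosome: ", ch$name)
    }
    len <- as.integer(ch$length)
    reg <- ch$regions
    if (any(reg$density < 0 | reg$density > 50)) {
      stop("CpG density targets must lie in [0, 50] per 100 bp (", ch$name, ")")
    }
    # CG-free background: random bases, then break every CG by replacing its
    # G with A or T (cannot create a new CG).
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    s <- paste(bases, collapse = "")
    hits <- cg_positions(s)
    if (length(hits)) {
      bases[hits + 1L] <- sample(c("A", "T"), length(hits), replace = TRUE)
    }
    # Plant CGs region by region at even offsets (guarantees >= 2 bp spacing,
    # supporting densities up to 50/100 bp).
    for (r in seq_len(nrow(reg))) {
      L <- reg$end[r] - reg$start[r]
      n_cpg <- round(L * reg$density[r] / 100)
      if (n_cpg > 0) {
        slots <- seq.int(reg$start[r] + 1L, by = 2L, length.out = L %/% 2)
        pos <- sort(sample(slots, n_cpg))
        bases[pos] <- "C"
        bases[pos + 1L] <- "G"
      }
    }
    seqs[[ch$name]] <- paste(bases, collapse = "")
    profile[[ch$name]] <- data.frame(chrom = ch$name, reg,
                                     stringsAsFactors = FALSE)
  }
  structure(
    list(
      chrom_names = names(seqs),
      chrom_lengths = vapply(spec$chroms, function(ch) as.integer(ch$length),
                             integer(1), USE.NAMES = FALSE) |>
        stats::setNames(names(seqs)),
      sequence = unlist(seqs),
      cpg_profile = do.call(rbind, c(profile, make.row.names = FALSE))
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_names), "chromosomes,",
      sum(x$chrom_lengths), "bp total\n")
  invisible(x)
}

#' Positions of CG dinucleotides in a sequence
#'
#' 1-based positions of the C of every CG occurrence.
#'
#' @param sequence A single nucleotide string.
#' @return Integer vector of match start positions (possibly empty).
#' @keywords internal
cg_positions <- function(sequence) {
  Biostrings::start(Biostrings::matchPattern("CG", Biostrings::DNAString(sequence)))
}

#' Per-window CpG counts for a genome
#'
#' @param genome A `genome_model`.
#' @param windows A `window_set` over the same chromosomes.
#' @return Integer vector of CG counts, one per window. A CG straddling a
#'   window boundary is attributed to the window containing its C.
#' @export
window_cpg_counts <- function(genome, windows) {
  wsize <- attr(windows, "window_size")
  out <- integer(nrow(windows))
  for (ch in genome$chrom_names) {
    rows <- which(windows$chrom == ch)
    if (!length(rows)) next
    pos0 <- cg_positions(genome$sequence[[ch]]) - 1L  # 0-based C position
    if (length(pos0)) {
      out[rows] <- tabulate(pos0 %/% wsize + 1L, nbins = length(rows))
    }
  }
  out
}

#' Simulate a two-arm cohort
#'
#' Generates control and case samples with unique ids, ages drawn uniformly
#' on `age_range`, and expected library sizes drawn log-normally around
#' `mean_lib`. Defaults mirror a study-scale cohort of 13 per arm at a
#' 1/100 miniature of ~25 million fragments per sample.
#'
#' @param n_control,n_case Samples per arm; each must be >= 2 (dispersion
#'   estimation needs within-group replication).
#' @param age_range Two-element numeric, years.
#' @param seed Integer seed.
#' @param mean_lib Mean expected library size (fragments per sample).
#' @param cv_lib Coefficient of variation of library sizes.
#' @param race,cell_type Labels recorded on every sample.
#' @return Data frame (class `cohort`) with columns `sample_id`, `group`
#'   (factor, levels control < case), `age`, `race`, `cell_type`,
#'   `library_size`.
#' @export
simulate_cohort <- function(n_control = 13, n_case = 13, age_range = c(30, 75),
                            seed = 1, mean_lib = 2.5e5, cv_lib = 0.15,
                            race = "synthetic", cell_type = "buccal") {
  if (n_control < 2 || n_case < 2) {
    stop("each arm needs n >= 2 (within-group dispersion estimation)")
  }
  local_seed(seed)
  n <- n_control + n_case
  group <- factor(rep(c("control", "case"), c(n_control, n_case)),
                  levels = c("control", "case"))
  ids <- c(sprintf("CTRL%02d", seq_len(n_control)),
           sprintf("CASE%02d", seq_len(n_case)))
  sdlog <- sqrt(log(1 + cv_lib^2))
  lib <- round(stats::rlnorm(n, log(mean_lib) - sdlog^2 / 2, sdlog))
  data.frame(
    sample_id = ids,
    group = group,
    age = round(stats::runif(n, age_range[1], age_range[2])),
    race = race,
    cell_type = cell_type,
    library_size = pmax(lib, 1),
    stringsAsFactors = FALSE
  ) |> structure(class = c("cohort", "data.frame"))
}

#' Define injected ground-truth DMR regions
#'
#' Picks `n_regions` non-overlapping runs of whole windows and assigns each
#' a signed log2 fold change (positive = methylation gain in cases). Region
#' boundaries always coincide with window boundaries.
#'
#' @param windows A `window_set`.
#' @param n_regions Number of regions to inject.
#' @param n_windows_range Inclusive range of run lengths (windows) sampled
#'   per region.
#' @param lfc Log2 fold changes sampled (with sign) per region; all must be
#'   non-zero.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2); >= 0.
#' @param seed Integer seed.
#' @return A `ground_truth`: list with `regions` (data frame `chrom`,
#'   `start`, `end`, `true_lfc`, `n_windows`, `window_index` list-column)
#'   and `dispersion`.
#' @export
ground_truth <- function(windows, n_regions = 8, n_windows_range = c(1, 3),
                         lfc = c(-2, 2), dispersion = 0.1, seed = 1) {
  stopifnot(dispersion >= 0, all(lfc != 0))
  local_seed(seed)
  taken <- logical(nrow(windows))
  regions <- list()
  guard <- 0
  while (length(regions) < n_regions && guard < 1000 * n_regions) {
    guard <- guard + 1
    k <- sample(seq(n_windows_range[1], n_windows_range[2]), 1)
    i <- sample(nrow(windows) - k + 1L, 1)
    run <- i:(i + k - 1L)
    ok <- !any(taken[run]) &&
      length(unique(windows$chrom[run])) == 1 &&
      all(diff(windows$index[run]) == 1)
    # keep a one-window buffer so injected regions never merge
    buffer <- unique(pmax(1L, pmin(nrow(windows), c(min(run) - 1L, max(run) + 1L))))
    if (ok && !any(taken[buffer])) {
      taken[c(run, buffer)] <- TRUE
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = windows$chrom[i],
        start = windows$start[i],
        end = windows$end[max(run)],
        true_lfc = lfc[sample.int(length(lfc), 1)],
        n_windows = k
      )
      regions[[length(regions)]]$window_index <- I(list(windows$index[run]))
    }
  }
  if (length(regions) == 0) {
    reg <- data.frame(chrom = character(), start = integer(), end = integer(),
                      true_lfc = numeric(), n_windows = integer())
    reg$window_index <- I(list())
  } else {
    reg <- do.call(rbind, regions)
    reg <- reg[order(match(reg$chrom, unique(windows$chrom)), reg$start), ]
    rownames(reg) <- NULL
  }
  structure(list(regions = reg, dispersion = dispersion),
            class = "ground_truth")
}

#' Simulate per-window MeDIP fragment counts
#'
#' Each window's baseline expectation tracks its CpG density (MeDIP enriches
#' methylated, CpG-containing fragments): `mu ~ mu0 * (1 + 0.5 * d)` with
#' `d` in CpG/100 bp, scaled per sample so expected column totals equal the
#' sample's library size. Case samples have expectation multiplied by
#' `2^true_lfc` inside ground-truth regions. Counts are negative binomial
#' with dispersion `truth$dispersion` (Poisson when the dispersion is 0).
#'
#' @param genome A `genome_model`.
#' @param windows A `window_set` over the genome.
#' @param cohort A `cohort` data frame from [simulate_cohort()].
#' @param truth A `ground_truth` (regions may be empty for a null dataset).
#' @param seed Integer seed.
#' @return A `medip_counts` with attribute `baseline_mu` (per-window,
#'   library-size-1 scale x mean library) recording the expectation model.
#' @export
simulate_window_counts <- function(genome, windows, cohort, truth, seed = 1) {
  local_seed(seed)
  d <- window_cpg_counts(genome, windows) * 100 /
    (windows$end - windows$start)
  shape <- 1 + 0.5 * d
  prop <- shape / sum(shape)

  effect <- matrix(1, nrow = nrow(windows), ncol = nrow(cohort))
  if (!is.null(truth$regions) && nrow(truth$regions) > 0) {
    cs <- attr(windows, "chrom_sizes")
    bad <- !(truth$regions$chrom %in% names(cs)) |
      truth$regions$end > cs[truth$regions$chrom] | truth$regions$start < 0
    if (any(bad)) {
      stop("ground-truth region outside genome bounds: ",
           paste(truth$regions$chrom[bad], truth$regions$start[bad], sep = ":",
                 collapse = ", "))
    }
    case_cols <- which(cohort$group == "case")
    for (r in seq_len(nrow(truth$regions))) {
      idx <- truth$regions$window_index[[r]]
      if (is.null(idx)) {
        idx <- which(windows$chrom == truth$regions$chrom[r] &
                       windows$start >= truth$regions$start[r] &
                       windows$end <= truth$regions$end[r])
      }
      effect[idx, case_cols] <- 2^truth$regions$true_lfc[r]
    }
  }

  phi <- truth$dispersion
  mu <- outer(prop, cohort$library_size) * effect
  n <- length(mu)
  counts <- if (phi <= 0) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = 1 / phi, mu = mu)
  }
  counts <- matrix(as.integer(counts), nrow = nrow(windows),
                   dimnames = list(NULL, cohort$sample_id))
  out <- medip_counts(counts, windows)
  attr(out, "baseline_mu") <- prop * mean(cohort$library_size)
  out
}

#' Emit per-window counts as sonicated fragments
#'
#' Inverse of [count_fragments()]: for every count in the matrix, emits a
#' fragment whose midpoint lies inside the source window. Lengths are
#' uniform on `frag_len_range` (sonication to 150-300 bp by default);
#' fragments are placed by first drawing the midpoint uniformly inside the
#' window, then trimming both ends symmetrically if the fragment would
#' extend beyond a chromosome end (which preserves the midpoint), so
#' re-counting by midpoint reproduces the input matrix exactly.
#'
#' @param counts A `medip_counts` object.
#' @param windows A `window_set` (defaults to `counts$windows`).
#' @param frag_len_range Two integers within [50, 1000].
#' @param seed Integer seed.
#' @return Named list (one per sample) of sorted BED3 data frames
#'   (`chrom`, `start`, `end`).
#' @export
emit_fragments <- function(counts, windows = counts$windows,
                           frag_len_range = c(150, 300), seed = 1) {
  stopifnot(inherits(counts, "medip_counts"))
  if (frag_len_range[1] < 50 || frag_len_range[2] > 1000 ||
      frag_len_range[1] > frag_len_range[2]) {
    stop("frag_len_range must lie within [50, 1000]")
  }
  local_seed(seed)
  cs <- attr(windows, "chrom_sizes")
  out <- vector("list", ncol(counts$counts))
  names(out) <- colnames(counts$counts)
  for (s in seq_along(out)) {
    n_per_win <- counts$counts[, s]
    total <- sum(n_per_win)
    wrow <- rep.int(seq_len(nrow(windows)), n_per_win)
    wstart <- windows$start[wrow]
    wend <- windows$end[wrow]
    chrom <- windows$chrom[wrow]
    chrom_len <- as.numeric(cs[chrom])
    mid <- wstart + floor(stats::runif(total) * (wend - wstart))
    len <- frag_len_range[1] +
      floor(stats::runif(total) * (frag_len_range[2] - frag_len_range[1] + 1))
    fs <- mid - len %/% 2
    fe <- fs + len
    # symmetric trim at chromosome bounds keeps start+end (hence midpoint) fixed
    trim <- pmax(0, pmax(-fs, fe - chrom_len))
    fs <- fs + trim
    fe <- fe - trim
    degenerate <- fe <= fs
    fs[degenerate] <- mid[degenerate]
    fe[degenerate] <- mid[degenerate] + 1
    df <- data.frame(chrom = chrom, start = as.integer(fs), end = as.integer(fe),
                     stringsAsFactors = FALSE)
    out[[s]] <- df[order(match(df$chrom, names(cs)), df$start), , drop = FALSE]
    rownames(out[[s]]) <- NULL
  }
  out
}

#' Write a genome as FASTA
#'
#' @param genome A `genome_model`.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  xs <- Biostrings::DNAStringSet(genome$sequence)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return A `genome_model` (without a designed `cpg_profile`).
#' @export
read_genome_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  names(xs) <- sub("\\s.*$", "", names(xs))
  structure(
    list(
      chrom_names = names(xs),
      chrom_lengths = stats::setNames(Biostrings::width(xs), names(xs)),
      sequence = stats::setNames(as.character(xs), names(xs)),
      cpg_profile = NULL
    ),
    class = "genome_model"
  )
}

#' Write per-sample fragments as BED3 files
#'
#' @param fragments Named list of fragment data frames.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_fragments_bed <- function(fragments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, paste0(names(fragments), ".bed")),
                           names(fragments))
  for (s in names(fragments)) {
    data.table::fwrite(fragments[[s]], paths[[s]], sep = "\t", col.names = FALSE)
  }
  paths
}

#' Write a cohort sample sheet as TSV
#'
#' @param cohort A `cohort` data frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(cohort, path) {
  data.table::fwrite(
    cohort[, c("sample_id", "group", "age", "race", "cell_type")],
    path, sep = "\t"
  )
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Expects the header `sample_id group age race cell_type`; `group` is
#' coerced to a factor with `control` as the reference level when present.
#'
#' @param path TSV path.
#' @return Data frame with a `group` factor column.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  lev <- unique(df$group)
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  df$group <- factor(df$group, levels = lev)
  df
}

#' Write ground-truth regions as BED6
#'
#' The signed log2 fold change is stored in the score column.
#'
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  reg <- truth$regions
  data.table::fwrite(
    data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
               name = sprintf("truth_%d", seq_len(nrow(reg))),
               score = reg$true_lfc, strand = "."),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}

#' Write chromosome sizes as a two-column TSV
#'
#' @param genome A `genome_model` or named sizes vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  cs <- as_chrom_sizes(genome)
  data.table::fwrite(data.frame(chrom = names(cs), size = as.integer(cs)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Run code with a temporarily fixed RNG seed
#'
#' Sets the seed for the calling frame and restores the previous RNG state
#' when that frame exits, so generators are reproducible without disturbing
#' the session RNG.
#'
#' @param seed Integer seed (NULL leaves the RNG untouched).
#' @keywords internal
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(restore, TRUE), envir = env)
  set.seed(seed)
  invisible()
}
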