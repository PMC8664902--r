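#' Cohort descriptive statistics
#'
#' Per-group sample size, mean age and SEM (sample standard deviation with
#' n-1 denominator over sqrt(n)), plus a two-sample t-test between the two
#' groups (pooled-variance Student test by default, Welch behind a flag).
#' Values are stored at full precision; rounding to one decimal happens
#' only in the print method.
#'
#' @param sample_sheet Data frame with `group` and `age` columns (ages
#'   positive), or a path to a sample-sheet TSV.
#' @param welch Use the Welch (unequal-variance) test instead of Student.
#' @return A `cohort_summary`: list with `per_group` (data frame `group`,
#'   `n`, `mean_age`, `sem_age`) and `t_test` (`statistic`, `p_value`), the
#'   latter NULL unless exactly two groups are present.
#' @export
summarize_cohort <- function(sample_sheet, welch = FALSE) {
  df <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
        else sample_sheet
  if (is.null(df$age) || any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("ages must be present and positive")
  }
  g <- factor(df$group)
  per_group <- do.call(rbind, lapply(levels(g), function(lv) {
    a <- df$age[g == lv]
    sem <- if (length(a) >= 2) stats::sd(a) / sqrt(length(a)) else NA_real_
    if (length(a) < 2) warning("group '", lv, "' has one sample; SEM undefined")
    data.frame(group = lv, n = length(a), mean_age = mean(a), sem_age = sem,
               stringsAsFactors = FALSE)
  }))
  tt <- NULL
  if (nlevels(g) == 2 && all(per_group$n >= 2)) {
    fit <- stats::t.test(age ~ g, data = df, var.equal = !welch)
    tt <- list(statistic = unname(fit$statistic), p_value = fit$p.value)
  }
  structure(list(per_group = per_group, t_test = tt),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  pg <- x$per_group
  for (i in seq_len(nrow(pg))) {
    cat(sprintf("%s: n = %d, mean age %.1f +/- %.1f (SEM)\n",
                pg$group[i], pg$n[i], pg$mean_age[i], pg$sem_age[i]))
  }
  if (!is.null(x$t_test)) {
    cat(sprintf("t = %.2f, p = %.3f\n", x$t_test$statistic, x$t_test$p_value))
  }
  invisible(x)
}

#' Default comparison configuration
#'
#' @param label Comparison label.
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(label = "comparison", ...) {
  cfg <- list(
    label = label,
    sample_sheet = NULL,
    fragments_dir = NULL,
    genome = NULL,
    annotation = NULL,
    category_map = NULL,
    truth = NULL,
    window_size = 1000,
    p_threshold = 1e-4,
    relaxed_threshold = 0.05,
    gene_distance = 10000,
    min_avg_count = 5,
    seed = 1
  )
  utils::modifyList(cfg, list(...))
}

#' Validate a comparison configuration
#'
#' @param config Configuration list.
#' @return The config, invisibly, after checks.
#' @export
validate_config <- function(config) {
  if (config$p_threshold <= 0 || config$p_threshold > 1 ||
      config$relaxed_threshold <= 0 || config$relaxed_threshold > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  if (config$p_threshold > config$relaxed_threshold) {
    stop("p_threshold must be <= relaxed_threshold")
  }
  for (field in c("sample_sheet", "fragments_dir", "genome")) {
    if (is.null(config[[field]]) || !file.exists(config[[field]])) {
      stop("missing input path: ", field)
    }
  }
  invisible(config)
}

#' Read / write a YAML comparison configuration
#'
#' The YAML file mirrors the configuration list field for field; missing
#' fields take their defaults, so serialize -> parse round-trips to the
#' identical effective settings.
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, c(list(label = raw$label %||% "comparison"),
                            raw[setdiff(names(raw), "label")]))
}

#' @rdname read_config
#' @param config Configuration list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full synthetic dataset onto disk
#'
#' Generates genome, cohort, ground truth, counts and fragments, and
#' writes FASTA, chrom.sizes, sample sheet, per-sample BED3 fragments and
#' a truth BED6 under `dir`. The written files are the inputs
#' [run_comparison()] consumes, so the on-disk round trip is exercised.
#'
#' @param dir Output directory.
#' @param seed Integer seed controlling every random draw.
#' @param genome_spec Genome design (default [default_genome_spec()]).
#' @param n_control,n_case Arm sizes.
#' @param mean_lib Mean library size (fragments/sample).
#' @param n_regions,n_windows_range,lfc,dispersion Ground-truth injection
#'   parameters (see [ground_truth()]).
#' @return Named list of written paths plus the in-memory objects.
#' @export
simulate_dataset <- function(dir, seed = 1, genome_spec = default_genome_spec(),
                             n_control = 13, n_case = 13, mean_lib = 2.5e5,
                             n_regions = 8, n_windows_range = c(1, 3),
                             lfc = c(-2, 2), dispersion = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(genome_spec, seed = seed)
  windows <- tile_genome(genome)
  cohort <- simulate_cohort(n_control, n_case, seed = seed + 1,
                            mean_lib = mean_lib)
  truth <- ground_truth(windows, n_regions = n_regions,
                        n_windows_range = n_windows_range, lfc = lfc,
                        dispersion = dispersion, seed = seed + 2)
  counts <- simulate_window_counts(genome, windows, cohort, truth,
                                   seed = seed + 3)
  frags <- emit_fragments(counts, windows, seed = seed + 4)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    fragments_dir = file.path(dir, "fragments"),
    truth = file.path(dir, "truth.bed")
  )
  write_genome_fasta(genome, paths$genome)
  write_chrom_sizes(genome, paths$chrom_sizes)
  write_sample_sheet(cohort, paths$sample_sheet)
  write_fragments_bed(frags, paths$fragments_dir)
  write_truth_bed(truth, paths$truth)
  c(paths, list(genome_obj = genome, windows = windows, cohort = cohort,
                truth = truth, counts = counts))
}

#' Run one complete comparison
#'
#' End-to-end orchestration from files: tile the genome, count fragments
#' by midpoint, filter low-count windows, TMM-normalize, estimate
#' dispersion, run the exact test with BH FDR, call and summarize DMRs,
#' annotate genes (when an annotation is configured), compute the DMR
#' PCA, and write every output table plus a manifest JSON with md5
#' checksums and row counts. Deterministic for a fixed config: rerunning
#' reproduces byte-identical tables.
#'
#' @param config Configuration list (see [default_config()]); `sample_sheet`,
#'   `fragments_dir` and `genome` (FASTA) must exist.
#' @param outdir Output directory.
#' @return Invisibly, a list with the intermediate objects (`counts`,
#'   `filtered`, `results`, `dmr_set`, `associations`, `pca`, `manifest`).
#' @export
run_comparison <- function(config, outdir) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  genome <- stage("genome", read_genome_fasta(config$genome))
  windows <- stage("tiling", tile_genome(genome, config$window_size))
  sheet <- stage("sample_sheet", read_sample_sheet(config$sample_sheet))
  beds <- stats::setNames(
    file.path(config$fragments_dir, paste0(sheet$sample_id, ".bed")),
    sheet$sample_id
  )
  counts <- stage("counting", count_fragments(beds, windows))
  filtered <- stage("filtering", filter_windows(counts, config$min_avg_count))
  message(sprintf("[%s] %d/%d windows kept after filtering",
                  config$label, nrow(filtered$counts), nrow(windows)))

  results <- stage("difftest", diff_test(filtered, sheet$group))
  dmr_set <- stage("dmr_calling",
                   call_dmrs(results, config$p_threshold,
                             comparison_label = config$label))
  dmr_set <- stage("dmr_summary", summarize_dmr(dmr_set, genome))
  message(sprintf("[%s] %d DMRs at p < %g", config$label,
                  nrow(dmr_set$dmrs), config$p_threshold))

  associations <- NULL
  if (!is.null(config$annotation)) {
    genes <- stage("annotation_read",
                   read_gene_annotation(config$annotation, config$category_map))
    associations <- stage("annotation",
                          associate_genes(dmr_set, genes, config$gene_distance))
    dmr_set <- attach_gene_annotations(dmr_set, associations)
  }

  pca <- NULL
  if (nrow(dmr_set$dmrs) > 0) {
    norm <- attr(results, "normalization")
    idx <- dmr_window_indices(dmr_set, results)
    mat <- stage("pca", normalize_for_pca(filtered, idx, norm))
    if (ncol(mat) >= 2) pca <- compute_pca(mat)
  }

  files <- c(
    counts = write_counts_tsv(filtered, file.path(outdir, "counts.tsv")),
    results = write_results_tsv(results, file.path(outdir, "results.tsv")),
    dmrs = write_dmr_tsv(dmr_set, file.path(outdir, "dmrs.tsv")),
    dmrs_bed = write_dmr_bed(dmr_set, file.path(outdir, "dmrs.bed")),
    thresholds = {
      p <- file.path(outdir, "threshold_table.tsv")
      data.table::fwrite(dmr_set$threshold_table, p, sep = "\t")
      p
    }
  )
  if (!is.null(associations)) {
    p <- file.path(outdir, "annotations.tsv")
    data.table::fwrite(associations, p, sep = "\t")
    files <- c(files, annotations = p)
  }
  if (!is.null(pca)) {
    files <- c(files, pca = write_pca_tsv(
      pca, sheet$group, file.path(outdir, "pca_scores.tsv")))
  }

  recall <- NA_real_
  if (!is.null(config$truth) && file.exists(config$truth)) {
    recall <- truth_window_recall(config$truth, dmr_set, windows)
    message(sprintf("[%s] injected-window recall: %.3f", config$label, recall))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("medipdmr")),
    r_version = R.version.string,
    config = config[!vapply(config, is.null, logical(1))],
    config_hash = config_hash(config),
    seed = config$seed,
    n_windows = nrow(windows),
    n_windows_tested = nrow(filtered$counts),
    n_dmrs = nrow(dmr_set$dmrs),
    truth_window_recall = recall,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = lapply(files, function(f) {
      list(md5 = unname(tools::md5sum(f)),
           rows = length(data.table::fread(f, sep = "\t", header = FALSE,
                                           select = 1L)[[1]]))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, filtered = filtered, results = results,
                 dmr_set = dmr_set, associations = associations, pca = pca,
                 manifest = manifest))
}

#' Window-level recall of injected truth regions
#'
#' Fraction of whole windows inside ground-truth regions (BED6, score =
#' true log2 fold change) that fall within called DMR spans.
#'
#' @param truth_bed Path to the truth BED6 file.
#' @param dmr_set A `dmr_set`.
#' @param windows The genome `window_set`.
#' @return Recall in [0, 1] (NaN when the truth file has no regions).
#' @export
truth_window_recall <- function(truth_bed, dmr_set, windows) {
  tr <- data.table::fread(truth_bed, header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  in_truth <- rep(FALSE, nrow(windows))
  for (r in seq_len(nrow(tr))) {
    in_truth <- in_truth | (windows$chrom == tr$chrom[r] &
                              windows$start >= tr$start[r] &
                              windows$end <= tr$end[r])
  }
  d <- dmr_set$dmrs
  covered <- rep(FALSE, nrow(windows))
  for (r in seq_len(nrow(d))) {
    covered <- covered | (windows$chrom == d$chrom[r] &
                            windows$start >= d$start[r] &
                            windows$end <= d$stop[r])
  }
  sum(in_truth & covered) / sum(in_truth)
}

#' Stable hash of a configuration
#'
#' md5 of the canonical JSON serialization.
#'
#' @param config Configuration list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  cfg <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
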