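#' CpG density of a sequence
#'
#' Count of CG dinucleotide occurrences per 100 bp. `N` bases are allowed
#' and never counted (a CG must be a literal C followed by G).
#'
#' @param sequence A single non-empty nucleotide string.
#' @return CpG density per 100 bp.
#' @examples
#' cpg_density("CGCGCG")  # 50
#' @export
cpg_density <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty string")
  }
  length(cg_positions(sequence)) * 100 / nchar(sequence)
}

#' Associate genes with DMRs within a distance
#'
#' A gene is associated with a DMR when the gap between the half-open
#' intervals `[start, stop)` and `[gene start, gene end)` is at most
#' `max_dist` bp (inclusive; a gap of exactly 10,000 bp qualifies at the
#' default). Overlapping intervals have distance 0. All qualifying genes
#' are reported, not only the nearest; gene strand never enters the
#' distance (gap to the gene body, not the TSS). Intervals that merely
#' abut also get distance 0.
#'
#' @param dmrs A `dmr_set` or its `dmrs` data frame.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`, and
#'   optionally `strand` and `category`.
#' @param max_dist Maximum gap in bp (default 10 kb, covering proximal and
#'   distal promoters).
#' @return Data frame `dmr_name`, `gene_id`, `distance`, `category`.
#'   DMRs with no gene in range contribute no rows.
#' @export
associate_genes <- function(dmrs, genes, max_dist = 10000) {
  d <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  if (is.null(genes$category)) genes$category <- "unclassified"
  genes$category[is.na(genes$category) | genes$category == ""] <- "unclassified"
  out <- list()
  for (ch in unique(d$chrom)) {
    di <- d[d$chrom == ch, , drop = FALSE]
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(di) == 0 || nrow(gi) == 0) next
    for (i in seq_len(nrow(di))) {
      gap <- pmax(0, pmax(gi$start - di$stop[i], di$start[i] - gi$end))
      hit <- which(gap <= max_dist)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          dmr_name = di$name[i],
          gene_id = gi$gene_id[hit],
          distance = as.integer(gap[hit]),
          category = gi$category[hit],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dmr_name = character(), gene_id = character(),
                      distance = integer(), category = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally DMRs per gene functional category
#'
#' Each DMR contributes once to every distinct category among its
#' associated genes (two genes of the same category count once; a DMR with
#' genes in two categories counts in both).
#'
#' @param associations Output of [associate_genes()].
#' @return Data frame `category`, `n_dmrs`, sorted by decreasing count.
#' @export
category_tally <- function(associations) {
  if (nrow(associations) == 0) {
    return(data.frame(category = character(), n_dmrs = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- unique(associations[, c("dmr_name", "category")])
  tab <- sort(table(pairs$category), decreasing = TRUE)
  data.frame(category = names(tab), n_dmrs = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Attach gene lists to a DMR table
#'
#' Fills the `genes` and `categories` columns of a DMR table from an
#' association list (comma-separated, deduplicated, genomic order of
#' input associations).
#'
#' @param dmr_set A `dmr_set`.
#' @param associations Output of [associate_genes()].
#' @return The `dmr_set` with `genes` and `categories` columns.
#' @export
attach_gene_annotations <- function(dmr_set, associations) {
  d <- dmr_set$dmrs
  collapse <- function(v) paste(unique(v), collapse = ",")
  g <- vapply(d$name, function(nm) {
    rows <- associations$dmr_name == nm
    if (any(rows)) collapse(associations$gene_id[rows]) else ""
  }, character(1))
  ct <- vapply(d$name, function(nm) {
    rows <- associations$dmr_name == nm
    if (any(rows)) collapse(associations$category[rows]) else ""
  }, character(1))
  d$genes <- unname(g)
  d$categories <- unname(ct)
  dmr_set$dmrs <- d
  dmr_set
}

#' Read a gene annotation (BED6 or GFF3)
#'
#' BED6 files are read directly (columns chrom, start, end, gene_id,
#' score, strand; 0-based half-open). GFF3 files (`.gff`/`.gff3`) are
#' imported via rtracklayer and reduced to `gene` features with a
#' `gene_id` attribute (falling back to `ID`), converting to 0-based
#' half-open coordinates. An optional two-column TSV (`gene_id`,
#' `category`) supplies the functional category vocabulary; genes absent
#' from the map are `"unclassified"`.
#'
#' @param path Annotation file path.
#' @param category_map Optional path to the gene -> category TSV.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `category`.
#' @export
read_gene_annotation <- function(path, category_map = NULL) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- as.data.frame(rtracklayer::import(path))
    if (!is.null(gr$type) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene", , drop = FALSE]
    }
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
    genes <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(gr$seqnames),
      start = gr$start - 1L,  # GRanges is 1-based closed
      end = gr$end,
      strand = as.character(gr$strand),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.table::fread(path, header = FALSE)
    genes <- data.frame(
      chrom = as.character(tab[[1]]),
      start = as.integer(tab[[2]]),
      end = as.integer(tab[[3]]),
      gene_id = as.character(tab[[4]]),
      strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+",
      stringsAsFactors = FALSE
    )[, c("gene_id", "chrom", "start", "end", "strand")]
  }
  genes$category <- "unclassified"
  if (!is.null(category_map)) {
    cm <- data.table::fread(category_map, header = FALSE,
                            col.names = c("gene_id", "category"))
    hit <- match(genes$gene_id, cm$gene_id)
    genes$category[!is.na(hit)] <- cm$category[hit[!is.na(hit)]]
  }
  genes
}

#' Count DMR-associated genes present in user-supplied gene sets
#'
#' Plain overlap counting against named gene lists (no enrichment
#' statistics): for each set, how many of its members appear among the
#' associated genes.
#'
#' @param associations Output of [associate_genes()].
#' @param gene_sets Named list of character vectors.
#' @return Data frame `set`, `n_genes`.
#' @export
gene_set_overlap <- function(associations, gene_sets) {
  found <- unique(associations$gene_id)
  data.frame(
    set = names(gene_sets),
    n_genes = vapply(gene_sets, function(g) sum(g %in% found), integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
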