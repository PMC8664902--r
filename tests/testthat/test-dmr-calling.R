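test_that("adjacent significant windows merge; gaps split", {
  p <- rep(0.5, 10)
  p[c(5, 6)] <- 1e-6
  d <- call_dmrs(toy_results(p), 1e-4)$dmrs
  expect_equal(nrow(d), 1)
  expect_equal(d$n_sig_windows, 2)
  expect_equal(d$length, 2000)
  expect_equal(d$start, 4000)
  expect_equal(d$stop, 6000)
  expect_equal(d$name, "DMR_chr1_1")

  p2 <- rep(0.5, 10)
  p2[c(3, 7)] <- 1e-6
  d2 <- call_dmrs(toy_results(p2), 1e-4)$dmrs
  expect_equal(nrow(d2), 2)
  expect_equal(d2$n_sig_windows, c(1, 1))
})

test_that("windows separated by a filtered-out window are not adjacent", {
  res <- toy_results(c(1e-6, 1e-6, 1e-6), lfc = c(1, 1, 1))
  res$index <- c(3L, 4L, 6L)  # window 5 was filtered out before testing
  d <- call_dmrs(res, 1e-4)$dmrs
  expect_equal(nrow(d), 2)
  expect_equal(d$n_sig_windows, c(2, 1))
})

test_that("an empty result set yields an empty DMR set with a zero ladder", {
  dset <- call_dmrs(toy_results(rep(0.5, 8)), 1e-4)
  expect_equal(nrow(dset$dmrs), 0)
  expect_true(all(dset$threshold_table$n_all == 0))
  expect_error(call_dmrs(toy_results(rep(0.5, 8)), 0), "0, 1")
})

test_that("significant windows are conserved across DMRs", {
  set.seed(31)
  p <- 10^runif(300, -8, 0)
  dset <- call_dmrs(toy_results(p), 1e-4)
  expect_equal(sum(dset$dmrs$n_sig_windows), sum(p < 1e-4))
  # strict inequality at the threshold
  pb <- rep(1, 5)
  pb[3] <- 1e-4
  expect_equal(nrow(call_dmrs(toy_results(pb), 1e-4)$dmrs), 0)
})

test_that("threshold ladder is monotone and consistent with the caller", {
  set.seed(32)
  # sparse significance (isolated windows): tightening the cutoff can only
  # drop DMRs, so counts are non-increasing down the ladder
  p <- rep(0.9, 600)
  iso <- seq(2, 599, by = 3)
  p[iso] <- 10^runif(length(iso), -8, -1)
  res <- toy_results(p)
  tab <- threshold_ladder(res)
  expect_true(all(diff(tab$n_all) <= 0))
  expect_true(all(tab$n_multi <= tab$n_all))
  expect_equal(tab$n_all[tab$cutoff == 1e-4],
               nrow(call_dmrs(res, 1e-4)$dmrs))

  # dense significance: the significant-window total is still a subset
  # property even when run splitting perturbs DMR counts
  pd <- 10^runif(500, -8, 0)
  resd <- toy_results(pd)
  tabd <- threshold_ladder(resd)
  nsig <- vapply(tabd$cutoff, function(ct) sum(pd < ct), numeric(1))
  expect_true(all(diff(nsig) <= 0))
  expect_true(all(tabd$n_multi <= tabd$n_all))

  # degenerate cutoff reports every maximal run
  tab1 <- threshold_ladder(resd, cutoffs = 1)
  expect_equal(tab1$n_all, nrow(call_dmrs(resd, 1)$dmrs))
})

test_that("maxLFC keeps its sign and CpG columns come from the sequence", {
  res <- toy_results(c(1e-6, 1e-6, 0.5), lfc = c(1.2, -2.0, 0))
  dset <- call_dmrs(res, 1e-4)
  expect_equal(dset$dmrs$max_lfc, -2.0)

  toy <- data.frame(name = "DMR_chr1_1", chrom = "chr1", start = 0L,
                    stop = 6L, length = 6L)
  out <- summarize_dmr(toy, c(chr1 = "ACGCGT"))
  expect_equal(out$cpg_count, 2L)
  expect_equal(out$cpg_density, 2 * 100 / 6)
  expect_error(summarize_dmr(
    data.frame(name = "d", chrom = "chr1", start = 0L, stop = 10L, length = 10L),
    c(chr1 = "ACGCGT")), "beyond chromosome end")
})

test_that("CpG counts agree with a sliding-scan oracle on random DMRs", {
  fx <- fixture_injected()
  set.seed(33)
  starts <- sample(seq(0, 4.8e5, by = 1000), 100)
  dmrs <- data.frame(
    name = sprintf("d%03d", 1:100),
    chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
    start = starts, stop = starts + sample(1:4, 100, replace = TRUE) * 1000
  )
  dmrs$length <- dmrs$stop - dmrs$start
  out <- summarize_dmr(dmrs, fx$genome)
  oracle <- vapply(seq_len(100), function(i) {
    oracle_cg_count(substr(fx$genome$sequence[[dmrs$chrom[i]]],
                           dmrs$start[i] + 1, dmrs$stop[i]))
  }, integer(1))
  expect_equal(out$cpg_count, oracle)
})

test_that("run merging matches the brute-force component oracle", {
  set.seed(34)
  for (rep in 1:5) {
    p <- ifelse(runif(100) < 0.3, 1e-6, 0.5)
    res <- toy_results(p)
    # random holes to emulate filtered-out windows
    res <- res[sort(sample(100, 80)), ]
    d <- call_dmrs(res, 1e-4)$dmrs
    oracle <- oracle_merge_runs(res[res$p_value < 1e-4, ])
    expect_equal(nrow(d), length(oracle))
    o <- do.call(rbind, oracle)
    o <- o[order(o[, "start"]), , drop = FALSE]
    expect_equal(d$start, unname(o[, "start"]))
    expect_equal(d$stop, unname(o[, "stop"]))
    expect_equal(d$n_sig_windows, unname(o[, "n"]))
  }
})

test_that("calling DMRs on a DMR set's own windows reproduces the set", {
  fx <- fixture_injected()
  res <- fx$results
  sig <- res[res$p_value < 1e-4, ]
  again <- call_dmrs(sig, 1e-4)$dmrs
  expect_equal(again$start, fx$dmrs$dmrs$start)
  expect_equal(again$stop, fx$dmrs$dmrs$stop)
  expect_equal(again$n_sig_windows, fx$dmrs$dmrs$n_sig_windows)
})

test_that("injected multi-window DMRs are recovered as single merged regions", {
  fx <- fixture_injected()
  d <- fx$dmrs$dmrs
  w <- fx$windows
  tw <- unlist(fx$truth$regions$window_index)
  covered <- vapply(tw, function(i) {
    any(d$chrom == w$chrom[i] & d$start <= w$start[i] & d$stop >= w$end[i])
  }, logical(1))
  expect_gte(mean(covered), 0.8)
  # every fully recovered multi-window region is one DMR, not several
  for (r in seq_len(nrow(fx$truth$regions))) {
    reg <- fx$truth$regions[r, ]
    if (reg$n_windows < 2) next
    idx <- reg$window_index[[1]]
    full <- all(vapply(idx, function(i) {
      any(d$chrom == w$chrom[i] & d$start <= w$start[i] & d$stop >= w$end[i])
    }, logical(1)))
    if (full) {
      hits <- sum(d$chrom == reg$chrom & d$start < reg$end & d$stop > reg$start)
      expect_equal(hits, 1)
    }
  }
  # min_fdr dominates min_p per DMR
  expect_true(all(d$min_fdr >= d$min_p))
})

test_that("size and density distributions conserve counts and hit the design", {
  fx <- fixture_injected()
  dist <- size_and_density_distributions(fx$dmrs)
  expect_equal(sum(dist$length_hist$count), nrow(fx$dmrs$dmrs))
  expect_equal(sum(dist$density_hist$count), nrow(fx$dmrs$dmrs))

  # all single-window DMRs put all mass in the 1 kb bin
  res <- toy_results(c(1e-6, 0.5, 1e-6, 0.5, 1e-6))
  dset <- summarize_dmr(call_dmrs(res, 1e-4),
                        c(chr1 = paste(rep("ACGT", 1250), collapse = "")))
  d1 <- size_and_density_distributions(dset)
  expect_equal(d1$length_hist$count[d1$length_hist$kb == 1],
               nrow(dset$dmrs))

  # genome designed at 2 CpG/100 bp in the DMR spans: modal bin covers 2
  spec <- list(chroms = list(list(
    name = "chr1", length = 50000L,
    regions = data.frame(start = 0, end = 50000, density = 2)
  )))
  g2 <- generate_genome(spec, seed = 17)
  res2 <- toy_results(ifelse(seq_len(50) %% 5 == 0, 1e-6, 0.5))
  dset2 <- summarize_dmr(call_dmrs(res2, 1e-4), g2)
  d2 <- size_and_density_distributions(dset2)
  modal <- which.max(d2$density_hist$count)
  expect_true(d2$density_hist$density_lo[modal] <= 2 &&
                d2$density_hist$density_hi[modal] >= 2)
})
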