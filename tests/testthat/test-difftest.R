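# NB-count matrix helper with exact column structure control.
nb_matrix <- function(w, samples, mu = 100, phi = 0.1, seed = 1) {
  set.seed(seed)
  matrix(rnbinom(w * samples, mu = mu, size = 1 / phi), nrow = w,
         dimnames = list(NULL, sprintf("s%02d", seq_len(samples))))
}
as_counts <- function(m, window_size = 1000) {
  w <- tile_genome(c(chr1 = nrow(m) * window_size), window_size)
  medipdmr:::medip_counts(m, w)
}

test_that("TMM factors are 1 for identical columns and equivariant to permutation", {
  m <- nb_matrix(500, 6, seed = 2)
  ident <- as_counts(matrix(m[, 1], nrow(m), 6,
                            dimnames = list(NULL, colnames(m))))
  expect_equal(unname(tmm_factors(ident)$tmm_factors), rep(1, 6))

  f <- tmm_factors(as_counts(m), reference = "s01")$tmm_factors
  perm <- c(3, 1, 2, 6, 5, 4)
  fp <- tmm_factors(as_counts(m[, perm]), reference = "s01")$tmm_factors
  expect_equal(fp, f[perm])
})

test_that("doubling one sample's counts re-equalizes its normalized abundances", {
  m <- nb_matrix(2000, 6, seed = 3)
  m2 <- m
  m2[, 4] <- 2L * m[, 4]
  norm1 <- tmm_factors(as_counts(m))
  norm2 <- tmm_factors(as_counts(m2))
  # doubled depth with unchanged composition: factors stay ~1 ...
  expect_equal(unname(norm2$tmm_factors), rep(1, 6), tolerance = 0.01)
  # ... so the doubled sample's normalized abundances re-equalize with its
  # own pre-doubling profile
  cpm1 <- m[, 4] / norm1$effective_lib_sizes[4] * 1e6
  cpm2 <- m2[, 4] / norm2$effective_lib_sizes[4] * 1e6
  expect_equal(cpm2, cpm1, tolerance = 0.01)
})

test_that("TMM rejects zero-library samples by name", {
  m <- nb_matrix(50, 3, seed = 4)
  m[, 2] <- 0L
  expect_error(tmm_factors(as_counts(m)), "s02")
})

test_that("TMM factors agree with the edgeR reference implementation", {
  fx <- fixture_injected()
  ours <- tmm_factors(fx$filtered)$tmm_factors
  ref <- edgeR::calcNormFactors(edgeR::DGEList(
    fx$filtered$counts, lib.size = fx$filtered$library_sizes
  ))$samples$norm.factors
  expect_equal(unname(ours), ref, tolerance = 0.01)
})

test_that("dispersion estimation recovers the simulating value", {
  spec <- default_genome_spec(n_chrom = 2, chrom_length = 5e5)
  g <- generate_genome(spec, seed = 7)
  w <- tile_genome(g)
  co <- simulate_cohort(13, 13, seed = 11, mean_lib = 1.25e5)
  tr <- ground_truth(w, n_regions = 0, dispersion = 0.1, seed = 3)
  cnt <- filter_windows(simulate_window_counts(g, w, co, tr, seed = 15), 5)
  norm <- tmm_factors(cnt)
  est <- estimate_dispersion(cnt, co$group, norm)
  expect_gte(est$common_phi, 0.07)
  expect_lte(est$common_phi, 0.13)
  # tagwise estimates shrink around the common value
  expect_lt(abs(median(est$tagwise_phi) - est$common_phi), 0.05)

  # cross-check against edgeR's qCML estimator
  ref <- edgeR::estimateCommonDisp(edgeR::DGEList(
    cnt$counts, group = co$group, lib.size = cnt$library_sizes
  ))$common.dispersion
  expect_equal(est$common_phi, ref, tolerance = 0.1)

  # window order does not matter
  perm <- sample(nrow(cnt$counts))
  cntp <- medipdmr:::medip_counts(cnt$counts[perm, ], cnt$windows[perm, ],
                                  library_sizes = cnt$library_sizes)
  estp <- estimate_dispersion(cntp, co$group, norm, tagwise = FALSE)
  expect_equal(estp$common_phi, est$common_phi, tolerance = 1e-6)

  # Poisson data drive the estimate to (near) zero
  tr0 <- ground_truth(w, n_regions = 0, dispersion = 0, seed = 3)
  cnt0 <- filter_windows(simulate_window_counts(g, w, co, tr0, seed = 16), 5)
  est0 <- estimate_dispersion(cnt0, co$group, tmm_factors(cnt0),
                              tagwise = FALSE)
  expect_lte(est0$common_phi, 0.01)

  expect_error(estimate_dispersion(cnt, factor(c("a", rep("b", 25))), norm),
               "size < 2")
})

test_that("exact test is symmetric under group-label swap", {
  fx <- fixture_injected()
  norm <- attr(fx$results, "normalization")
  disp <- attr(fx$results, "dispersion")
  swapped <- factor(ifelse(fx$cohort$group == "control", "case", "control"),
                    levels = c("control", "case"))
  res_sw <- exact_test(fx$filtered, swapped, norm, disp)
  expect_equal(res_sw$p_value, fx$results$p_value)
  expect_equal(res_sw$log_fc, -fx$results$log_fc)
})

test_that("a perfectly balanced window is untestable by construction", {
  m <- nb_matrix(200, 3, mu = 80, seed = 8)
  m <- cbind(m, m)  # case columns identical to control columns
  colnames(m) <- sprintf("s%02d", 1:6)
  cnt <- as_counts(m)
  groups <- factor(rep(c("control", "case"), each = 3),
                   levels = c("control", "case"))
  norm <- tmm_factors(cnt)
  disp <- estimate_dispersion(cnt, groups, norm, tagwise = FALSE)
  res <- exact_test(cnt, groups, norm, disp)
  expect_equal(res$log_fc, rep(0, nrow(m)))
  expect_equal(res$p_value, rep(1, nrow(m)))
})

test_that("null simulation yields calibrated, uniform p-values", {
  spec <- default_genome_spec(n_chrom = 2, chrom_length = 5e5)
  g <- generate_genome(spec, seed = 7)
  w <- tile_genome(g)
  co <- simulate_cohort(13, 13, seed = 11, mean_lib = 1.25e5)
  tr <- ground_truth(w, n_regions = 0, dispersion = 0.1, seed = 3)
  cnt <- filter_windows(simulate_window_counts(g, w, co, tr, seed = 5), 5)
  res <- diff_test(cnt, co$group)
  n <- nrow(res)
  expect_true(abs(mean(res$p_value < 0.05) - 0.05) <=
                3 * sqrt(0.05 * 0.95 / n))
  expect_true(abs(mean(res$p_value < 0.01) - 0.01) <=
                3 * sqrt(0.01 * 0.99 / n))
  expect_lt(suppressWarnings(
    ks.test(res$p_value, "punif")$statistic), 0.05)

  # p-values track the edgeR exact test closely
  dge <- edgeR::estimateTagwiseDisp(edgeR::estimateCommonDisp(edgeR::DGEList(
    cnt$counts, group = co$group, lib.size = cnt$library_sizes)))
  ref <- edgeR::exactTest(dge)$table$PValue
  expect_gt(cor(-log10(res$p_value), -log10(ref), method = "spearman"), 0.98)
})

test_that("the far tail stays calibrated in a pooled null simulation", {
  spec <- default_genome_spec(n_chrom = 1, chrom_length = 1e6)
  g <- generate_genome(spec, seed = 7)
  w <- tile_genome(g)
  co <- simulate_cohort(13, 13, seed = 11, mean_lib = 3e4)
  tr0 <- ground_truth(w, n_regions = 0, dispersion = 0.1, seed = 3)
  ps <- unlist(lapply(1:100, function(r) {
    cnt <- filter_windows(simulate_window_counts(g, w, co, tr0,
                                                 seed = 1000 + r), 5)
    norm <- tmm_factors(cnt)
    disp <- estimate_dispersion(cnt, co$group, norm, tagwise = FALSE)
    exact_test(cnt, co$group, norm, disp)$p_value
  }))
  # never anti-conservative at any alpha at pooled precision
  for (a in c(0.05, 0.01, 1e-3)) {
    se <- sqrt(a * (1 - a) / length(ps))
    expect_lt(mean(ps < a), a + 3 * se)
  }
  # two-sided calibration at the smallest alpha
  a <- 1e-3
  se <- sqrt(a * (1 - a) / length(ps))
  expect_gt(mean(ps < a), a - 3 * se)
})

test_that("rejection rate rises with the injected effect and FDR is controlled", {
  spec <- default_genome_spec(n_chrom = 1, chrom_length = 1e6)
  g <- generate_genome(spec, seed = 7)
  w <- tile_genome(g)
  co <- simulate_cohort(13, 13, seed = 11, mean_lib = 1.25e5)
  idx <- seq(10, 990, by = 20)  # 50 injected single-window regions (5%)
  rates <- vapply(c(0, 0.5, 1, 2), function(lfc) {
    tr <- ground_truth(w, n_regions = 0, dispersion = 0.1, seed = 3)
    if (lfc > 0) {
      tr$regions <- data.frame(chrom = "chr1", start = w$start[idx],
                               end = w$end[idx], true_lfc = lfc,
                               n_windows = 1)
      tr$regions$window_index <- I(as.list(idx))
    }
    cnt <- filter_windows(
      simulate_window_counts(g, w, co, tr, seed = 300 + round(10 * lfc)), 5)
    res <- diff_test(cnt, co$group)
    if (lfc == 2) {
      hit <- res$q_value < 0.1
      truth <- res$index %in% idx
      expect_lte(sum(hit & !truth) / max(1, sum(hit)), 0.15)  # empirical FDR
    }
    mean(res$p_value[match(idx, res$index)] < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) > -0.03))
  expect_gt(rates[4], rates[1])
})

test_that("p-values are invariant to a global library-size rescaling", {
  fx <- fixture_injected()
  f2 <- fx$filtered
  f2$library_sizes <- f2$library_sizes * 10
  norm1 <- tmm_factors(fx$filtered)
  norm2 <- tmm_factors(f2)
  d1 <- estimate_dispersion(fx$filtered, fx$cohort$group, norm1, tagwise = FALSE)
  d2 <- estimate_dispersion(f2, fx$cohort$group, norm2, tagwise = FALSE)
  p1 <- exact_test(fx$filtered, fx$cohort$group, norm1, d1)$p_value
  p2 <- exact_test(f2, fx$cohort$group, norm2, d2)$p_value
  # invariance holds exactly up to the integer rounding of adjusted group
  # sums; a global rescaling may flip a rounding on isolated windows
  rel <- abs(log10(p1) - log10(p2)) / pmax(abs(log10(p1)), 1)
  expect_lt(max(rel), 0.01)
  expect_gte(mean(rel < 1e-6), 0.95)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
  # q >= p and order preservation
  set.seed(9)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  expect_equal(q, stats::p.adjust(p, "BH"))
})
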