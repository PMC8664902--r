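#' TMM between-sample normalization factors
#'
#' Trimmed mean of M-values: each sample is compared to a reference sample
#' (the one whose 0.75 count-proportion quantile is closest to the mean of
#' those quantiles). Per window, M = log2 relative abundance ratio and
#' A = average log abundance; windows with a zero in either sample are
#' excluded, then the most extreme 30% of M-values and 5% of A-values are
#' trimmed on each side, and the factor is the precision-weighted mean of
#' the surviving M-values. Factors are rescaled to geometric mean 1.
#'
#' @param counts A `medip_counts` object (>= 2 samples, not all zero).
#' @param reference Optional sample id or column index to use as reference;
#'   default picks it automatically as above.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return A `norm_state`: list with `tmm_factors` (named, geometric mean 1)
#'   and `effective_lib_sizes` (`library_size * factor`).
#' @export
tmm_factors <- function(counts, reference = NULL, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(counts, "medip_counts"))
  y <- counts$counts
  lib <- counts$library_sizes
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  if (any(lib == 0)) {
    stop("sample with zero library size: ",
         paste(colnames(y)[lib == 0], collapse = ", "))
  }
  if (all(y == 0)) stop("all counts are zero")

  prop <- sweep(y, 2, lib, "/")
  if (is.null(reference)) {
    q75 <- apply(prop, 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(q75 - mean(q75)))
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(y))
  } else {
    ref <- as.integer(reference)
  }

  f <- vapply(seq_len(ncol(y)), function(s) {
    .tmm_pair(y[, s], y[, ref], lib[s], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(
    list(
      tmm_factors = stats::setNames(f, colnames(y)),
      effective_lib_sizes = stats::setNames(lib * f, colnames(y))
    ),
    class = "norm_state"
  )
}

# One sample's trimmed mean of M-values against the reference.
.tmm_pair <- function(ys, yr, ls, lr, trim_m, trim_a) {
  keep <- ys > 0 & yr > 0
  if (!any(keep)) return(1)
  ps <- ys[keep] / ls
  pr <- yr[keep] / lr
  M <- log2(ps / pr)
  A <- 0.5 * log2(ps * pr)
  # asymptotic delta-method variance of M
  w <- (ls - ys[keep]) / (ls * ys[keep]) + (lr - yr[keep]) / (lr * yr[keep])
  fin <- is.finite(M) & is.finite(A) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0 || max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) return(1)
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

#' Estimate NB dispersion by conditional maximum likelihood
#'
#' Counts are first mapped to a common library size (the geometric mean of
#' the effective library sizes) by a quantile-to-quantile negative-binomial
#' adjustment, then the common dispersion maximizes the conditional
#' log-likelihood of the adjusted counts given each window's group totals,
#' summed over windows and groups. Optionally, per-window (tagwise)
#' dispersions are obtained by maximizing a weighted likelihood that adds
#' `prior_df` residual degrees of freedom worth of the genome-wide average
#' likelihood, shrinking each window toward the common value.
#'
#' @param counts A `medip_counts` object.
#' @param groups Factor of length `ncol(counts)` with exactly 2 levels,
#'   each represented by >= 2 samples; the first level is the reference
#'   (control) group.
#' @param normalization A `norm_state` from [tmm_factors()].
#' @param prior_df Shrinkage weight for tagwise estimation (default 10).
#' @param tagwise Compute per-window dispersions as well?
#' @return A `dispersion_estimate`: list with `common_phi`, `tagwise_phi`
#'   (or NULL), `prior_df`, and `common_lib` (the common library size used
#'   for the adjustment).
#' @export
estimate_dispersion <- function(counts, groups, normalization,
                                prior_df = 10, tagwise = TRUE) {
  y <- counts$counts
  groups <- .check_groups(groups, ncol(y))
  eff <- normalization$effective_lib_sizes
  common_lib <- exp(mean(log(eff)))

  phi <- 0.01
  pseudo <- NULL
  for (it in 1:2) {
    pseudo <- .equalize_counts(y, eff, groups, phi, common_lib)
    opt <- stats::optimize(
      function(delta) .cond_ll_total(pseudo, groups, delta / (1 - delta)),
      interval = c(1e-4, 0.95), maximum = TRUE, tol = 1e-6
    )
    phi <- opt$maximum / (1 - opt$maximum)
  }

  tag <- NULL
  if (tagwise) {
    grid_phi <- pmax(phi, 1e-4) * 2^seq(-6, 6, length.out = 25)
    ll <- vapply(grid_phi, function(p) .cond_ll_by_window(pseudo, groups, p),
                 numeric(nrow(y)))
    prior_n <- prior_df / max(1, ncol(y) - nlevels(groups))
    obj <- ll + matrix(prior_n * colMeans(ll), nrow = nrow(ll),
                       ncol = ncol(ll), byrow = TRUE)
    tag <- grid_phi[max.col(obj, ties.method = "first")]
  }

  structure(
    list(common_phi = phi, tagwise_phi = tag, prior_df = prior_df,
         common_lib = common_lib),
    class = "dispersion_estimate"
  )
}

.check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != n) stop("groups length must match sample count")
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group of size < 2: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  groups
}

#' Quantile-to-quantile NB adjustment of a count
#'
#' Maps counts observed at mean `mu_in` to the scale of mean `mu_out`,
#' preserving the cumulative probability under matched normal and gamma
#' approximations to the NB (the two are averaged). Variance follows the
#' NB mean-variance relation `mu + phi * mu^2`.
#'
#' @param x Counts (vector/matrix column).
#' @param mu_in,mu_out Input and output means (same length as `x`).
#' @param phi Dispersion (scalar or same length as `x`).
#' @keywords internal
.nb_quantile_map <- function(x, mu_in, mu_out, phi) {
  mu_in <- pmax(mu_in, 0.25)
  mu_out <- pmax(mu_out, 0.25)
  v_in <- mu_in * (1 + phi * mu_in)
  v_out <- mu_out * (1 + phi * mu_out)
  upper <- x >= mu_in
  lt <- !upper  # lower.tail per element

  p_n <- ifelse(upper,
                stats::pnorm(x, mu_in, sqrt(v_in), lower.tail = FALSE),
                stats::pnorm(x, mu_in, sqrt(v_in)))
  q_n <- ifelse(upper,
                stats::qnorm(p_n, mu_out, sqrt(v_out), lower.tail = FALSE),
                stats::qnorm(p_n, mu_out, sqrt(v_out)))

  shp_in <- mu_in^2 / v_in
  scl_in <- v_in / mu_in
  shp_out <- mu_out^2 / v_out
  scl_out <- v_out / mu_out
  p_g <- ifelse(upper,
                stats::pgamma(x, shape = shp_in, scale = scl_in, lower.tail = FALSE),
                stats::pgamma(x, shape = shp_in, scale = scl_in))
  q_g <- ifelse(upper,
                stats::qgamma(p_g, shape = shp_out, scale = scl_out, lower.tail = FALSE),
                stats::qgamma(p_g, shape = shp_out, scale = scl_out))
  pmax((q_n + q_g) / 2, 0)
}

# Fit a common log-proportion per window within one group:
# mu_j = exp(beta) * lib_j, NB score equation solved by Fisher scoring.
.nb_fit_group <- function(y, lib, phi) {
  beta <- log(pmax(rowSums(y), 0.5) / sum(lib))
  for (it in 1:25) {
    mu <- exp(beta) %o% lib
    denom <- 1 + phi * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

# Map all counts to the common library size, group by group.
.equalize_counts <- function(y, eff, groups, phi, common_lib) {
  pseudo <- y * NA_real_
  for (g in levels(groups)) {
    cols <- which(groups == g)
    beta <- .nb_fit_group(y[, cols, drop = FALSE], eff[cols], phi)
    mu_out <- exp(beta) * common_lib
    for (j in cols) {
      mu_in <- exp(beta) * eff[j]
      pseudo[, j] <- .nb_quantile_map(y[, j], mu_in, mu_out, phi)
    }
  }
  pseudo
}

# Conditional NB log-likelihood of equal-library counts given group sums,
# per window (terms free of phi dropped).
.cond_ll_by_window <- function(pseudo, groups, phi) {
  r <- 1 / phi
  tot <- numeric(nrow(pseudo))
  for (g in levels(groups)) {
    z <- pseudo[, groups == g, drop = FALSE]
    m <- ncol(z)
    tot <- tot + rowSums(lgamma(z + r)) - m * lgamma(r) +
      lgamma(m * r) - lgamma(rowSums(z) + m * r)
  }
  tot
}

.cond_ll_total <- function(pseudo, groups, phi) {
  sum(.cond_ll_by_window(pseudo, groups, phi))
}

#' Exact conditional NB test per window
#'
#' Counts are mapped to a common library size by the quantile-to-quantile
#' NB adjustment (using the tagwise dispersion when available, otherwise
#' the common one), then each window's rounded group sums are tested
#' conditionally on their total: under the null the reference-group sum
#' follows the NB-conditional (negative hypergeometric) distribution with
#' per-group sizes `n_g / phi` (binomial when phi = 0). The two-sided
#' p-value doubles the smaller tail, with the observed outcome's full
#' probability mass included in its tail, capped at 1.
#'
#' The log2 fold change is case vs control (second vs first group level;
#' positive = methylation gain in cases), computed from the adjusted group
#' means with a moderation prior count of 0.125 added to each mean (the
#' prior never enters the p-value).
#'
#' @param counts A `medip_counts` object (typically filtered).
#' @param groups Two-level factor; first level is the reference (control).
#' @param normalization A `norm_state` from [tmm_factors()].
#' @param dispersion A `dispersion_estimate` from [estimate_dispersion()].
#' @param prior_count Moderation prior for the fold-change only.
#' @return Data frame with one row per tested window: `chrom`, `start`,
#'   `end`, `index`, `log_fc`, `log_cpm`, `p_value`.
#' @export
exact_test <- function(counts, groups, normalization, dispersion,
                       prior_count = 0.125) {
  y <- counts$counts
  groups <- .check_groups(groups, ncol(y))
  eff <- normalization$effective_lib_sizes
  common_lib <- dispersion$common_lib
  phi_w <- if (!is.null(dispersion$tagwise_phi)) {
    dispersion$tagwise_phi
  } else {
    rep(dispersion$common_phi, nrow(y))
  }
  if (length(phi_w) != nrow(y)) stop("dispersion length does not match windows")

  pseudo <- .equalize_counts(y, eff, groups, phi_w, common_lib)
  ctrl <- groups == levels(groups)[1]
  n1 <- sum(ctrl)
  n2 <- sum(!ctrl)
  s1 <- round(rowSums(pseudo[, ctrl, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, !ctrl, drop = FALSE]))

  p <- vapply(seq_len(nrow(y)), function(w) {
    .exact_cond_p(s1[w], s2[w], n1, n2, phi_w[w])
  }, numeric(1))

  log_fc <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  log_cpm <- log2(((s1 + s2) / (n1 + n2) + 0.5) / common_lib * 1e6)

  data.frame(
    chrom = counts$windows$chrom,
    start = counts$windows$start,
    end = counts$windows$end,
    index = counts$windows$index,
    log_fc = log_fc,
    log_cpm = log_cpm,
    p_value = p,
    stringsAsFactors = FALSE
  )
}

# Two-sided exact conditional p-value for group sums s1 (n1 samples) vs
# s2 (n2 samples) given the total, NB dispersion phi.
.exact_cond_p <- function(s1, s2, n1, n2, phi) {
  N <- s1 + s2
  if (N == 0) return(1)
  x <- 0:N
  if (phi < 1e-8) {
    lp <- stats::dbinom(x, N, n1 / (n1 + n2), log = TRUE)
  } else {
    a <- n1 / phi
    b <- n2 / phi
    lp <- lgamma(x + a) - lgamma(x + 1) + lgamma(N - x + b) - lgamma(N - x + 1)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_lo <- sum(pr[x <= s1])
  p_hi <- sum(pr[x >= s1])
  min(1, 2 * min(p_lo, p_hi))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement, order-preserving
#' with the input vector.
#'
#' @param p_values Numeric vector in [0, 1].
#' @return Vector of q-values, same order as input.
#' @export
adjust_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Full per-window differential test
#'
#' Convenience wrapper: TMM normalization, dispersion estimation, exact
#' conditional test, and BH FDR, returning the complete per-window result
#' table consumed by the DMR caller.
#'
#' @inheritParams estimate_dispersion
#' @param tagwise Use tagwise dispersions (default TRUE).
#' @return Data frame `chrom start end index log_fc log_cpm p_value q_value`.
#' @export
diff_test <- function(counts, groups, prior_df = 10, tagwise = TRUE) {
  norm <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, groups, norm,
                              prior_df = prior_df, tagwise = tagwise)
  res <- exact_test(counts, groups, norm, disp)
  res$q_value <- adjust_fdr(res$p_value)
  attr(res, "normalization") <- norm
  attr(res, "dispersion") <- disp
  res
}

#' Write a per-window results table as TSV
#'
#' Full precision (no rounding) so downstream thresholding is exact.
#'
#' @param results Data frame from [diff_test()].
#' @param path Output path.
#' @export
write_results_tsv <- function(results, path) {
  data.table::fwrite(
    results[, c("chrom", "start", "end", "log_fc", "log_cpm",
                "p_value", "q_value")],
    path, sep = "\t"
  )
  invisible(path)
}
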