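#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-library scaling factors for count matrices. The reference library
#' is the one whose 75th-percentile-to-depth ratio is closest to the mean of
#' that statistic. For every library, gene-wise log2 expression ratios against
#' the reference (`M_g = log2((y_g/N)/(y_ref/N_ref))`, over genes positive in
#' both) are trimmed — the most extreme `trim_m` fraction at each end by M and
#' `trim_a` by average log expression A — and averaged with inverse
#' approximate-variance weights; the factor is `2^` that mean. Factors are
#' rescaled to geometric mean 1, so the product over libraries is 1.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param trim_m two-sided trim fraction on the M values.
#' @param trim_a two-sided trim fraction on the A values.
#' @return Named numeric vector of positive factors, one per sample; effective
#'   library size = column sum x factor.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- colSums(counts)
  if (any(N == 0)) {
    bad <- colnames(counts)[N == 0]
    if (is.null(bad)) bad <- which(N == 0)
    stop("library with zero total count: ", paste(bad, collapse = ", "))
  }
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / N
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(s) {
    if (s == ref) return(1)
    ys <- counts[, s]; yr <- counts[, ref]
    keep <- ys > 0 & yr > 0
    if (!any(keep)) return(1)
    ys <- ys[keep]; yr <- yr[keep]
    M <- log2((ys / N[s]) / (yr / N[ref]))
    A <- 0.5 * log2((ys / N[s]) * (yr / N[ref]))
    # delta-method variance of M under binomial sampling
    w <- 1 / ((N[s] - ys) / (N[s] * ys) + (N[ref] - yr) / (N[ref] * yr))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(use) || sum(w[use]) == 0) return(1)
    f <- 2^(sum(w[use] * M[use]) / sum(w[use]))
    if (!is.finite(f) || f <= 0) 1 else f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million
#'
#' Moderated log-scale expression used for correlation analysis:
#' `log2((count + prior_count) / (effective_libsize + 2 * prior_count) * 1e6)`,
#' where the effective library size is the column sum times its TMM factor.
#' The prior keeps zero counts finite.
#'
#' @param counts genes x samples count matrix.
#' @param factors normalization factors from [tmm_factors()] (default: computed).
#' @param prior_count non-negative pseudo-count.
#' @return Numeric matrix of the same dimension, finite everywhere.
#' @export
log_cpm <- function(counts, factors = tmm_factors(counts), prior_count = 2) {
  counts <- as.matrix(counts)
  if (prior_count < 0) stop("prior_count must be non-negative")
  if (length(factors) != ncol(counts)) {
    stop("factors must align with the sample columns")
  }
  if (!is.null(names(factors)) && !is.null(colnames(counts)) &&
      !identical(names(factors), colnames(counts))) {
    factors <- factors[colnames(counts)]
    if (anyNA(factors)) stop("factor names do not match sample columns")
  }
  eff <- colSums(counts) * factors
  out <- log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, `/`) * 1e6)
  stopifnot(all(is.finite(out)))
  out
}
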