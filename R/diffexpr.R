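#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with enforced monotonicity (a thin,
#' validated interface to `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]` (no NAs).
#' @return Vector of q-values, same order as `p`; `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Tagwise method-of-moments dispersion within replicate groups
#' (condition x timepoint cells), shrunk toward the common (median)
#' dispersion with prior weight `prior_weight`:
#' `phi_g = (w * phi_common + n_g * phi_hat_g) / (w + n_g)` where `n_g` is the
#' number of samples. Counts are first rescaled to a common effective library
#' size so depth differences do not inflate the estimates. Estimates are
#' floored at 1e-6.
#'
#' @param counts genes x samples count matrix.
#' @param design sample sheet aligned to the columns of `counts`.
#' @param factors TMM factors (default: computed from `counts`).
#' @param prior_weight weight of the common dispersion in the shrinkage.
#' @return Named numeric vector of dispersions phi (variance = mu + phi mu^2).
#' @export
estimate_dispersions <- function(counts, design, factors = tmm_factors(counts),
                                 prior_weight = 10) {
  counts <- as.matrix(counts)
  stopifnot(nrow(design) == ncol(counts))
  grp <- interaction(design$condition, design$timepoint, drop = TRUE)
  if (any(table(grp) < 2)) {
    stop("every condition x timepoint group needs at least 2 replicates")
  }
  eff <- colSums(counts) * factors
  z <- sweep(counts, 2, mean(eff) / eff, `*`)

  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in levels(grp)) {
    zz <- z[, grp == g, drop = FALSE]
    m <- rowMeans(zz)
    v <- apply(zz, 1, stats::var)
    # MoM for phi from E[s^2] = mu + phi mu^2; m^2 - v/n is the unbiased
    # estimate of mu^2 (plain m^2 biases phi downward at small n)
    mu2 <- pmax(m^2 - v / ncol(zz), m^2 * 0.1)
    ok <- m > 0
    df <- ncol(zz) - 1
    num[ok] <- num[ok] + df * (v[ok] - m[ok]) / mu2[ok]
    den[ok] <- den[ok] + df
  }
  phi_raw <- ifelse(den > 0, num / den, NA_real_)
  # common dispersion: median of the unclipped estimates (clipping first
  # would bias it low); tagwise estimates are clipped at 0 for shrinkage
  phi_common <- max(0, stats::median(phi_raw, na.rm = TRUE))
  if (!is.finite(phi_common)) phi_common <- 0.1
  phi_hat <- pmax(0, phi_raw)
  phi_hat[is.na(phi_hat)] <- phi_common
  n_g <- ncol(counts)
  phi <- (prior_weight * phi_common + n_g * phi_hat) / (prior_weight + n_g)
  phi <- pmax(phi, 1e-6)
  names(phi) <- rownames(counts)
  phi
}

#' Negative-binomial likelihood-ratio test for one contrast
#'
#' Per-gene differential expression between a treated and a control arm at one
#' timepoint. Each gene is fit with a negative-binomial generalized linear
#' model (log link, offset = log effective library size, mean model = group
#' indicator) by iteratively reweighted least squares, with the gene's
#' dispersion held fixed at its shrunken estimate. The statistic is the
#' likelihood ratio `2 (l_full - l_reduced)` against `chi^2(1)`; q-values are
#' Benjamini-Hochberg. Genes whose fits do not converge are reported with
#' `p = 1` and counted in a single warning.
#'
#' @param counts genes x samples count matrix.
#' @param design sample sheet aligned to the columns.
#' @param contrast named list or vector with `treat`, `control`, `timepoint`.
#' @param factors,dispersions optional normalization factors and per-gene
#'   dispersions computed on the contrast's samples; computed if missing.
#' @return A data.frame of class `de_table`: `gene_id`, `logFC` (log2,
#'   treated vs control), `pvalue`, `fdr`, `contrast`.
#' @export
de_test <- function(counts, design, contrast, factors = NULL, dispersions = NULL) {
  counts <- as.matrix(counts)
  contrast <- as.list(contrast)
  stopifnot(all(c("treat", "control", "timepoint") %in% names(contrast)))
  tp <- as.numeric(contrast$timepoint)
  sel <- design$timepoint == tp &
    as.character(design$condition) %in% c(contrast$treat, contrast$control)
  if (!any(as.character(design$condition[sel]) == contrast$treat) ||
      !any(as.character(design$condition[sel]) == contrast$control)) {
    stop("contrast does not name an existing (treated, control, timepoint) pair")
  }
  y <- counts[, sel, drop = FALSE]
  sub <- design[sel, , drop = FALSE]
  group <- as.integer(as.character(sub$condition) == contrast$treat)
  if (sum(group) < 2 || sum(1 - group) < 2) {
    stop("each arm of the contrast needs at least 2 replicates")
  }
  if (is.null(factors)) factors <- tmm_factors(y)
  if (is.null(dispersions)) {
    dsub <- sub
    dsub$timepoint <- tp  # single timepoint: groups are the two arms
    dispersions <- estimate_dispersions(y, dsub, factors = factors)
  }
  offset <- log(colSums(y) * factors)
  X_full <- cbind(intercept = 1, group = group)
  X_red <- X_full[, 1, drop = FALSE]

  n_fail <- 0L
  fit_gene <- function(g) {
    yy <- y[g, ]
    if (all(yy == 0)) return(c(0, 1))
    theta <- 1 / dispersions[g]
    fam <- MASS::negative.binomial(theta = theta, link = "log")
    ll <- function(mu) sum(stats::dnbinom(yy, size = theta, mu = mu, log = TRUE))
    full <- tryCatch(
      suppressWarnings(stats::glm.fit(X_full, yy, family = fam, offset = offset)),
      error = function(e) NULL)
    red <- tryCatch(
      suppressWarnings(stats::glm.fit(X_red, yy, family = fam, offset = offset)),
      error = function(e) NULL)
    if (is.null(full) || is.null(red) || !full$converged || !red$converged) {
      n_fail <<- n_fail + 1L
      lfc <- if (!is.null(full) && is.finite(full$coefficients[2])) {
        full$coefficients[2] / log(2)
      } else 0
      return(c(lfc, 1))
    }
    stat <- max(0, 2 * (ll(full$fitted.values) - ll(red$fitted.values)))
    c(full$coefficients[2] / log(2),
      stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  res <- vapply(seq_len(nrow(y)), fit_gene, numeric(2))
  if (n_fail > 0) {
    warning(sprintf("%d gene fit(s) did not converge; their p-values were set to 1",
                    n_fail))
  }
  out <- data.frame(
    gene_id = rownames(counts),
    logFC = res[1, ],
    pvalue = pmin(1, pmax(0, res[2, ])),
    stringsAsFactors = FALSE
  )
  out$fdr <- bh_adjust(out$pvalue)
  out$contrast <- sprintf("%s_vs_%s_%s", contrast$treat, contrast$control, tp)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Filter a differential-expression table into up/down gene sets
#'
#' Applies the strict cutoffs FDR < `fdr_max` together with
#' logFC > `lfc_min` (up) or logFC < `-lfc_min` (down).
#'
#' @param table a `de_table` from [de_test()].
#' @param fdr_max FDR cutoff (strict `<`).
#' @param lfc_min absolute log2-fold-change cutoff (strict `>`).
#' @return List with `up` and `down` [gene_set()]s.
#' @export
filter_de <- function(table, fdr_max = 0.001, lfc_min = 1.5) {
  if (fdr_max <= 0 || lfc_min <= 0) stop("thresholds must be positive")
  lab <- if (length(unique(table$contrast)) == 1) table$contrast[1] else ""
  up <- table$gene_id[table$fdr < fdr_max & table$logFC > lfc_min]
  down <- table$gene_id[table$fdr < fdr_max & table$logFC < -lfc_min]
  list(up = gene_set(up, label = lab, direction = "up"),
       down = gene_set(down, label = lab, direction = "down"))
}

#' Venn partition of two gene sets
#'
#' @param a,b gene sets (or character vectors) with matching direction labels.
#' @return List `only_a`, `shared`, `only_b` (character vectors) plus `sizes`.
#'   The sizes satisfy `|only_a| + |shared| = |a|`.
#' @export
venn_partition <- function(a, b) {
  da <- attr(a, "direction"); db <- attr(b, "direction")
  if (!is.null(da) && !is.null(db) && !is.na(da) && !is.na(db) && da != db) {
    stop("gene sets have different direction labels")
  }
  ga <- as_gene_ids(a); gb <- as_gene_ids(b)
  out <- list(only_a = setdiff(ga, gb), shared = intersect(ga, gb),
              only_b = setdiff(gb, ga))
  out$sizes <- lengths(out[1:3])
  out
}

#' Compare log-fold-change vectors between treatments
#'
#' Two-sided location comparison of matched or independent logFC vectors,
#' used to ask whether one fungal species modulates shared genes more strongly
#' than the other. `method = "t"` is Welch's t when unpaired and the paired t
#' otherwise; `method = "wilcoxon"` is the rank-sum (unpaired) or signed-rank
#' (paired) test.
#'
#' @param x,y numeric vectors (equal length when `paired`).
#' @param method `"t"` or `"wilcoxon"`.
#' @param paired logical.
#' @return List with `statistic`, `p.value`, `method`.
#' @export
compare_logfc <- function(x, y, method = c("t", "wilcoxon"), paired = FALSE) {
  method <- match.arg(method)
  if (paired && length(x) != length(y)) stop("paired vectors must match in length")
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3 per vector")
  if (method == "t") {
    if (paired) {
      d <- x - y
      if (stats::sd(d) == 0) {
        # degenerate: all differences identical
        if (mean(d) == 0) return(list(statistic = 0, p.value = 1, method = "paired t"))
        return(list(statistic = sign(mean(d)) * Inf, p.value = 0, method = "paired t"))
      }
      ht <- stats::t.test(x, y, paired = TRUE)
    } else {
      ht <- stats::t.test(x, y, var.equal = FALSE)
    }
  } else {
    if (paired && all(x == y)) {
      stop("signed-rank test undefined: all paired differences are zero")
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value, method = ht$method)
}
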