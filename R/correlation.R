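#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return rho_s in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a zero-variance vector")
  }
  stats::cor(x, y, method = "spearman")
}

# Exact two-sided null distribution of Spearman's rho for n distinct ranks:
# rho against 1:n over all n! permutations. Cached per n.
.spearman_null <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    perms <- function(v) {
      if (length(v) == 1) return(matrix(v, 1, 1))
      do.call(rbind, lapply(seq_along(v), function(i) {
        cbind(v[i], perms(v[-i]))
      }))
    }
    pm <- perms(seq_len(n))
    rhos <- apply(pm, 1, function(p) stats::cor(p, seq_len(n)))
    cache[[key]] <<- rhos
    rhos
  }
})

#' Significance of a Spearman correlation
#'
#' Two-sided p-value for `rho` observed over `n` samples. The default is the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` against Student's t
#' with `n - 2` degrees of freedom; `|rho| = 1` maps to `p = 0`. For small
#' samples without ties (`n <= 8`), `method = "exact"` enumerates all `n!`
#' rank permutations.
#'
#' @param rho correlation value(s) in `[-1, 1]` (vectorized for `"t"`).
#' @param n number of samples, >= 4.
#' @param method `"t"` (default) or `"exact"`.
#' @return p-value(s) in `[0, 1]`.
#' @export
corr_test <- function(rho, n, method = c("t", "exact")) {
  method <- match.arg(method)
  if (n < 4) stop("need n >= 4")
  if (any(abs(rho) > 1 + 1e-12)) stop("|rho| must be <= 1")
  rho <- pmin(1, pmax(-1, rho))
  if (method == "exact") {
    if (n > 8) stop("exact method limited to n <= 8")
    null <- .spearman_null(n)
    return(vapply(rho, function(r) mean(abs(null) >= abs(r) - 1e-12), numeric(1)))
  }
  p <- numeric(length(rho))
  one <- abs(rho) >= 1 - 1e-15
  p[one] <- 0
  tt <- rho[!one] * sqrt((n - 2) / (1 - rho[!one]^2))
  p[!one] <- 2 * stats::pt(-abs(tt), df = n - 2)
  pmin(1, p)
}

#' All-pairs Spearman correlation matrix with significance
#'
#' Computes the Spearman correlation between every pair of genes across
#' samples, the t-approximation p-value for each pair, and Benjamini-Hochberg
#' q-values over the off-diagonal upper triangle (each unordered pair tested
#' once). Genes with constant expression are dropped with a warning — their
#' correlations are undefined.
#'
#' @param expr numeric expression matrix, genes x samples (e.g. [log_cpm()]).
#' @param genes optional gene set restricting the matrix; all must be present.
#' @return A list of class `corr_matrix`: `genes`, `rho`, `p`, `q`
#'   (symmetric matrices; diagonal rho = 1, p = q = 0), `n_samples`.
#' @export
correlation_matrix <- function(expr, genes = NULL) {
  expr <- as.matrix(expr)
  if (!is.null(genes)) {
    ids <- as_gene_ids(genes)
    missing <- setdiff(ids, rownames(expr))
    if (length(missing) > 0) {
      stop("genes absent from the expression matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    expr <- expr[ids, , drop = FALSE]
  }
  if (ncol(expr) < 4) stop("need at least 4 samples")
  constant <- apply(expr, 1, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning(sprintf("dropping %d constant-expression gene(s): %s",
                    sum(constant),
                    paste(utils::head(rownames(expr)[constant], 5), collapse = ", ")))
    expr <- expr[!constant, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("fewer than 2 usable genes")
  n <- ncol(expr)
  rho <- stats::cor(t(expr), method = "spearman")
  ut <- upper.tri(rho)
  p <- matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  p[ut] <- corr_test(rho[ut], n)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  q <- matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  q[ut] <- bh_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(genes = rownames(rho), rho = rho, p = p, q = q, n_samples = n),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix: %d genes over %d samples>\n",
              length(x$genes), x$n_samples))
  invisible(x)
}
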