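#' Read a GMT annotation file
#'
#' Tab-separated format: `term_id <TAB> term_name <TAB> gene1 <TAB> gene2 ...`
#' per line. Gene sets are parsed with `fgsea::gmtPathways()`; term names are
#' taken from the second field.
#'
#' @param path GMT file.
#' @param universe population gene universe; defaults to the union of all
#'   annotated genes.
#' @return An [annotation()] object.
#' @export
read_gmt <- function(path, universe = NULL) {
  terms <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path), "\t")
  term_names <- stats::setNames(
    vapply(fields, function(f) f[2], character(1)),
    vapply(fields, function(f) f[1], character(1)))
  annotation(terms, term_names = term_names[names(terms)], universe = universe)
}

#' Construct a term-to-gene annotation
#'
#' @param terms named list: term_id -> character vector of gene IDs.
#' @param term_names optional named character vector of display names.
#' @param universe population gene universe; annotated genes outside it are
#'   dropped. Defaults to the union of annotated genes.
#' @return A list of class `annotation` with `terms`, `term_names`,
#'   `universe`; empty terms (after restriction to the universe) are removed
#'   with a message.
#' @export
annotation <- function(terms, term_names = NULL, universe = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)), !anyDuplicated(names(terms)))
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  universe <- unique(as.character(universe))
  terms <- lapply(terms, function(g) intersect(unique(as.character(g)), universe))
  empty <- lengths(terms) == 0
  if (any(empty)) {
    message(sprintf("dropping %d term(s) with no genes in the universe", sum(empty)))
    terms <- terms[!empty]
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms,
                 term_names = term_names[names(terms)],
                 universe = universe),
            class = "annotation")
}

#' Term overrepresentation by Fisher's exact test
#'
#' For every annotation term, tests whether the study set contains more term
#' members than expected under hypergeometric sampling from the universe. For
#' a term with `K` members in a universe of `N` genes and `k` hits in a study
#' set of `n` genes, the one-sided p-value is `P[X >= k]` with
#' `X ~ Hypergeometric(N, K, n)` (the upper tail of Fisher's exact test), and
#' the fold enrichment is `(k/n) / (K/N)`. q-values are Benjamini-Hochberg
#' over all tested terms.
#'
#' @param study gene set (or character vector); must lie within the universe.
#' @param annot an [annotation()] object.
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"` (Fisher's exact two-sided p).
#' @return A data.frame of class `enrichment_table`: `term_id`, `term_name`,
#'   `k`, `n`, `K`, `N`, `fold_enrichment`, `pvalue`, `fdr`, sorted by
#'   p-value.
#' @export
fisher_enrichment <- function(study, annot, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(annot, "annotation"))
  ids <- as_gene_ids(study)
  outside <- setdiff(ids, annot$universe)
  if (length(outside) > 0) {
    stop("study genes outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  }
  N <- length(annot$universe)
  n <- length(ids)
  if (n == 0 || n > N) stop("study set must be non-empty and within the universe")

  rows <- lapply(names(annot$terms), function(tid) {
    term <- annot$terms[[tid]]
    K <- length(term)
    k <- length(intersect(term, ids))
    p <- if (alternative == "greater") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(term_id = tid, term_name = unname(annot$term_names[tid]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               pvalue = min(1, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
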