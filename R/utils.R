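#' Construct a labelled gene set
#'
#' Lightweight container used throughout the pipeline for lists of gene IDs
#' carrying a label and, optionally, a regulation direction.
#'
#' @param genes character vector of gene IDs (de-duplicated, order preserved).
#' @param label single string naming the set.
#' @param direction `"up"`, `"down"`, or `NA` when direction is not meaningful.
#' @return An object of class `gene_set`: the character vector of IDs with
#'   `label` and `direction` attributes.
#' @export
gene_set <- function(genes, label = "", direction = NA_character_) {
  genes <- unique(as.character(genes))
  if (!is.na(direction) && !direction %in% c("up", "down")) {
    stop("direction must be 'up', 'down', or NA")
  }
  structure(genes, class = "gene_set", label = label, direction = direction)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'%s: %d genes>\n", attr(x, "label"),
              if (is.na(attr(x, "direction"))) "" else paste0(", ", attr(x, "direction")),
              length(x)))
  invisible(x)
}

# Accept either a gene_set or a plain character vector.
as_gene_ids <- function(x) {
  if (inherits(x, "gene_set")) as.character(x) else unique(as.character(x))
}

#' Edge density from node and edge counts
#'
#' Realized fraction of possible node pairs that are edges, `2m / (n (n - 1))`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param n_edges number of edges (>= 0).
#' @return Numeric density in `[0, 1]` for a simple graph.
#' @export
density_from_counts <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("density undefined for fewer than 2 nodes")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Atomic text write: write to a temp file in the same directory, then rename.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
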