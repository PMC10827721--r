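#' Read a gene-by-sample count matrix from TSV
#'
#' Expected layout: header row, first column `gene_id`, one column per
#' sample. Counts must be non-negative integers; duplicate gene IDs are
#' rejected. Rows and columns are canonicalized to lexicographic order so
#' downstream outputs are order-stable.
#'
#' @param path TSV file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene IDs: ",
         paste(utils::head(unique(df$gene_id[duplicated(df$gene_id)]), 5),
               collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count values")
  if (any(mat != round(mat))) stop("non-integer count")
  if (any(mat < 0)) stop("negative counts")
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$gene_id
  mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
}

#' Write a count matrix as TSV
#'
#' @param counts genes x samples matrix.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_atomic(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read a sample design table from CSV
#'
#' Requires columns `sample_id`, `condition`, `timepoint`, `replicate`;
#' rows are sorted by `sample_id`.
#'
#' @param path CSV file.
#' @param conditions optional condition level order; default: control first if
#'   present, then alphabetical.
#' @return A design data.frame as from [make_design()].
#' @export
read_design <- function(path, conditions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "timepoint", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("design lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in design")
  if (is.null(conditions)) {
    conds <- sort(unique(df$condition))
    conditions <- c(intersect("control", conds), setdiff(conds, "control"))
  }
  df <- df[order(df$sample_id), need]
  df$condition <- factor(df$condition, levels = conditions)
  df$replicate <- as.integer(df$replicate)
  rownames(df) <- NULL
  df
}

#' Write a sample design table as CSV
#' @param design design data.frame.
#' @param path output file.
#' @export
write_design <- function(design, path) {
  write_atomic(path, function(tmp) {
    utils::write.csv(design, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Match a count matrix against a design table
#'
#' Validates that every sample column has a design row and vice versa, and
#' returns the counts with columns ordered as the design rows.
#'
#' @param counts genes x samples matrix.
#' @param design design data.frame.
#' @return The reordered count matrix.
#' @export
align_counts <- function(counts, design) {
  missing_design <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_design) > 0) {
    stop("sample(s) absent from design: ", paste(missing_design, collapse = ", "))
  }
  missing_counts <- setdiff(design$sample_id, colnames(counts))
  if (length(missing_counts) > 0) {
    stop("design sample(s) absent from counts: ",
         paste(missing_counts, collapse = ", "))
  }
  counts[, design$sample_id, drop = FALSE]
}

#' Read / write one-ID-per-line gene sets
#' @param path text file, one gene ID per line.
#' @param label,direction passed to [gene_set()].
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, label = basename(path), direction = NA_character_) {
  gene_set(readLines(path), label = label, direction = direction)
}

#' @rdname read_gene_set
#' @param genes gene set (or character vector) to write.
#' @export
write_gene_set <- function(genes, path) {
  write_atomic(path, function(tmp) writeLines(as_gene_ids(genes), tmp))
}

# JSON report writer (atomic, deterministic key order as given)
write_json_report <- function(x, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  })
}
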