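#' Read a gene-expression matrix from CSV
#'
#' Expects the layout used by most GEO-style expression tables: gene names in
#' the first column, one column per sample with sample names in the header
#' row. Values must be non-negative numbers with a plain decimal point
#' (locale-independent parsing; thousands separators are rejected).
#'
#' @param path path to the CSV file.
#' @param delimiter field separator, comma by default (tab exports from GEO
#'   are accepted by passing `"\t"`).
#' @param is_raw_counts optional logical overriding the integer-valued
#'   heuristic of [expression_matrix()].
#' @return an [expression_matrix()] preserving the file's row and column
#'   order.
#' @export
read_expression_matrix <- function(path, delimiter = ",", is_raw_counts = NULL) {
  if (!file.exists(path)) tt_stop("file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) tt_stop("matrix file needs a gene column plus >= 1 sample column")
  genes <- trimws(df[[1]])
  samples <- trimws(colnames(df)[-1])
  vals <- vapply(seq_len(ncol(df) - 1L), function(j) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      tt_stop("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
              col[bad[1]], bad[1], genes[bad[1]], samples[j])
    num
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, samples))
  if (any(is.na(vals))) tt_stop("missing values are not allowed in the matrix")
  if (any(vals < 0)) {
    w <- which(vals < 0, arr.ind = TRUE)[1, ]
    tt_stop("negative value at gene '%s', sample '%s'",
            genes[w[1]], samples[w[2]])
  }
  expression_matrix(vals, is_raw_counts = is_raw_counts)
}

#' Read a two-column gene-length table
#'
#' Column 1: gene name; column 2: transcript length in base pairs. A header
#' row is accepted and detected by a non-numeric second field on the first
#' line.
#'
#' @inheritParams read_expression_matrix
#' @return named numeric vector of class `gene_length_table` mapping gene id
#'   to length (bp); all lengths strictly positive.
#' @export
read_gene_lengths <- function(path, delimiter = ",") {
  df <- read_support_csv(path, delimiter, n_cols = 2, numeric_col = 2)
  lens <- suppressWarnings(as.numeric(df[[2]]))
  genes <- trimws(df[[1]])
  if (any(is.na(lens))) tt_stop("non-numeric gene length for gene '%s'",
                                genes[which(is.na(lens))[1]])
  gene_length_table(stats::setNames(lens, genes))
}

#' @rdname read_gene_lengths
#' @param lengths named numeric vector (gene id -> length in bp).
#' @export
gene_length_table <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    tt_stop("gene lengths need unique gene names")
  if (any(!is.finite(lengths) | lengths <= 0))
    tt_stop("gene lengths must be positive (offender: '%s')",
            names(lengths)[which(!is.finite(lengths) | lengths <= 0)[1]])
  structure(lengths, class = "gene_length_table")
}

#' Read a one-column list of negative-control genes
#'
#' Negative controls are genes assumed stably expressed across all
#' experimental conditions; they anchor RUV normalization. Every line is
#' taken as a gene name (the format has no header).
#'
#' @inheritParams read_expression_matrix
#' @return character vector of class `control_gene_set`.
#' @export
read_control_genes <- function(path, delimiter = ",") {
  if (!file.exists(path)) tt_stop("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- lines[nzchar(lines)]
  control_gene_set(genes)
}

#' @rdname read_control_genes
#' @param genes character vector of control gene ids.
#' @export
control_gene_set <- function(genes) {
  genes <- trimws(as.character(genes))
  if (length(genes) == 0) tt_stop("control gene set is empty")
  if (anyDuplicated(genes))
    tt_stop("duplicate control genes: %s",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(genes, class = "control_gene_set")
}

#' Read sample metadata (sample, condition)
#'
#' Two columns mapping each sample column of the matrix to an experimental
#' condition label (e.g. Control, Treated). A header row reading
#' `sample,condition` (any case) is skipped.
#'
#' @inheritParams read_expression_matrix
#' @return named character vector of class `sample_metadata` (sample id ->
#'   condition).
#' @export
read_metadata <- function(path, delimiter = ",") {
  if (!file.exists(path)) tt_stop("file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != 2) tt_stop("metadata file must have exactly 2 columns")
  if (nrow(df) > 0 &&
      identical(tolower(trimws(unlist(df[1, ]))), c("sample", "condition")))
    df <- df[-1, , drop = FALSE]
  sample_metadata(stats::setNames(trimws(df[[2]]), trimws(df[[1]])))
}

#' @rdname read_metadata
#' @param conditions named character vector (sample id -> condition label).
#' @export
sample_metadata <- function(conditions) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    tt_stop("metadata needs unique sample names")
  if (length(conditions) == 0 || any(!nzchar(conditions)))
    tt_stop("every sample needs a non-empty condition label")
  structure(as.character(stats::setNames(conditions, names(conditions))),
            names = names(conditions), class = "sample_metadata")
}

#' Check that metadata covers a matrix exactly
#'
#' @param meta a `sample_metadata`.
#' @param m an `expression_matrix`.
#' @return `meta`, invisibly, reordered to the matrix sample order.
#' @export
validate_metadata <- function(meta, m) {
  sid <- sample_ids(m)
  missing <- setdiff(sid, names(meta))
  if (length(missing))
    tt_stop("metadata missing samples: %s", paste(missing, collapse = ", "),
            class = "transtat_metadata_coverage")
  invisible(sample_metadata(meta[sid]))
}

#' Read an externally produced differential-expression table
#'
#' Three columns: gene name, log2 fold change, p-value. A header row is
#' accepted and detected by a non-numeric second field on the first line.
#'
#' @inheritParams read_expression_matrix
#' @return data.frame of class `de_table` with columns `gene`, `log2fc`,
#'   `pvalue`.
#' @export
read_de_table <- function(path, delimiter = ",") {
  df <- read_support_csv(path, delimiter, n_cols = 3, numeric_col = 2)
  de_table(data.frame(gene = trimws(df[[1]]),
                      log2fc = suppressWarnings(as.numeric(df[[2]])),
                      pvalue = suppressWarnings(as.numeric(df[[3]])),
                      stringsAsFactors = FALSE))
}

#' @rdname read_de_table
#' @param df data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @export
de_table <- function(df) {
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(df))) tt_stop("DE table needs columns gene, log2fc, pvalue")
  df <- df[, need]
  if (anyDuplicated(df$gene))
    tt_stop("duplicate genes in DE table: %s",
            paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  if (any(!is.finite(df$log2fc))) tt_stop("log2 fold changes must be finite")
  if (any(is.na(df$pvalue) | df$pvalue < 0 | df$pvalue > 1))
    tt_stop("p-values must lie in [0, 1]")
  class(df) <- c("de_table", "data.frame")
  df
}

# shared reader for small support CSVs with optional header, detected by a
# non-numeric field in `numeric_col` of the first line
read_support_csv <- function(path, delimiter, n_cols, numeric_col) {
  if (!file.exists(path)) tt_stop("file not found: %s", path)
  df <- utils::read.table(path, sep = delimiter, header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != n_cols)
    tt_stop("expected %d columns in %s, found %d", n_cols, path, ncol(df))
  if (nrow(df) > 0 &&
      is.na(suppressWarnings(as.numeric(df[1, numeric_col]))))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) tt_stop("no data rows in %s", path)
  df
}

#' Write an expression matrix (or any table) back to CSV
#'
#' Round-trips: `read_expression_matrix(write_expression_matrix(m))`
#' reproduces `m` up to floating-point representation (15 significant
#' digits).
#'
#' @param m an `expression_matrix`.
#' @param path output path.
#' @param gene_column header of the gene-name column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, gene_column = "gene") {
  v <- expr_values(m)
  if (nrow(v) == 0 || ncol(v) == 0) tt_stop("refusing to write an empty matrix")
  df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_column
  write_table(df, path)
}

#' @rdname write_expression_matrix
#' @param df a data.frame.
#' @export
write_table <- function(df, path) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0)
    tt_stop("refusing to write an empty table")
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) tt_stop("could not write %s", path)
  invisible(path)
}
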