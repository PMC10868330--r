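#' Construct an expression dataset
#'
#' The universal carrier for single-cell expression input: a sparse
#' non-negative integer count matrix oriented cells x genes, together with
#' unique cell and gene identifiers and an optional per-cell metadata table.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers. Defaults to
#'   the row names of `counts`.
#' @param gene_ids Character vector of unique gene identifiers. Defaults to
#'   the column names of `counts`.
#' @param cell_meta Optional data frame keyed by `cell_id` with columns such
#'   as `sample_id`, `major_type`, `subtype_label`, `malignant_label`.
#'
#' @return An object of class `expr_dataset`: a list with elements `counts`
#'   (a `dgCMatrix`, cells x genes), `cell_ids`, `gene_ids`, `cell_meta`
#'   (a tibble) and `normalized` (`NULL` until [normalize_counts()] is
#'   called).
#' @seealso [read_expression_matrix()], [normalize_counts()]
#' @export
expression_dataset <- function(counts, cell_ids = rownames(counts),
                               gene_ids = colnames(counts),
                               cell_meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(cell_ids) || is.null(gene_ids)) {
    abort("`cell_ids` and `gene_ids` are required when `counts` is unnamed.")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids)) {
    abort(sprintf(
      "dimension mismatch: counts is %d x %d but %d cell ids and %d gene ids were given",
      nrow(counts), ncol(counts), length(cell_ids), length(gene_ids)
    ))
  }
  if (nrow(counts) == 0L) abort("dataset has no cells")
  if (ncol(counts) == 0L) abort("dataset has no genes")
  if (anyDuplicated(cell_ids)) abort("duplicate cell ids")
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    abort("counts must be non-negative integers")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(cell_meta)) {
    cell_meta <- tibble(cell_id = cell_ids)
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) {
      abort("`cell_meta` must have a `cell_id` column")
    }
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
    if (anyNA(cell_meta$cell_id)) abort("`cell_meta` is missing some cells")
  }
  structure(
    list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
         cell_meta = cell_meta, normalized = NULL),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d cells x %d genes (%s normalized)\n",
    length(x$cell_ids), length(x$gene_ids),
    if (is.null(x$normalized)) "not" else "library-size"
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$counts)

#' Read a sparse expression matrix with gene and barcode files
#'
#' Reads a MatrixMarket coordinate file plus one-entry-per-line gene and
#' barcode files (the common single-cell export triplet). By default the
#' matrix on disk is genes x cells and is transposed on read; set
#' `cells_as_rows = TRUE` if the file already stores cells in rows.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene id file (one symbol per line; a second
#'   tab-separated column, if present, is ignored).
#' @param barcodes_path Path to the cell barcode file (one per line).
#' @param cells_as_rows Logical; orientation of the file on disk.
#' @param uppercase_genes Normalize gene symbols to upper case.
#' @return An [expression_dataset()]. Duplicate gene symbols are
#'   disambiguated by suffixing an ordinal.
#' @export
read_expression_matrix <- function(matrix_path, genes_path, barcodes_path,
                                   cells_as_rows = FALSE,
                                   uppercase_genes = FALSE) {
  m <- readMM(matrix_path)
  genes <- read_id_file(genes_path)
  barcodes <- read_id_file(barcodes_path)
  if (uppercase_genes) genes <- toupper(genes)
  genes <- disambiguate(genes)
  if (!cells_as_rows) m <- Matrix::t(m)
  if (nrow(m) != length(barcodes) || ncol(m) != length(genes)) {
    abort(sprintf(
      "matrix is %d x %d after orientation but there are %d barcodes and %d genes",
      nrow(m), ncol(m), length(barcodes), length(genes)
    ))
  }
  expression_dataset(m, cell_ids = barcodes, gene_ids = genes)
}

read_id_file <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (!length(x)) abort(sprintf("id file '%s' is empty", path))
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

# suffix an ordinal onto repeated symbols: A, A -> A, A.2
disambiguate <- function(x) {
  if (!anyDuplicated(x)) return(x)
  ave_seq <- stats::ave(seq_along(x), x, FUN = seq_along)
  dup <- ave_seq > 1L
  x[dup] <- paste0(x[dup], ".", ave_seq[dup])
  x
}

#' Write an expression dataset as MatrixMarket + id files
#'
#' Inverse of [read_expression_matrix()]; the matrix is written genes x cells
#' unless `cells_as_rows = TRUE`.
#'
#' @inheritParams read_expression_matrix
#' @param dataset An [expression_dataset()].
#' @return Invisibly, `dataset`.
#' @export
write_expression_matrix <- function(dataset, matrix_path, genes_path,
                                    barcodes_path, cells_as_rows = FALSE) {
  m <- dataset$counts
  if (!cells_as_rows) m <- Matrix::t(m)
  writeMM(m, matrix_path)
  writeLines(dataset$gene_ids, genes_path)
  writeLines(dataset$cell_ids, barcodes_path)
  invisible(dataset)
}

#' Read a dense delimited expression table (cells as rows)
#'
#' Fallback reader for CSV/TSV exports: first column cell id, remaining
#' columns genes.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @inheritParams read_expression_matrix
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, sep = NULL, uppercase_genes = FALSE) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, row.names = 1L)
  genes <- colnames(df)
  if (uppercase_genes) genes <- toupper(genes)
  m <- as(as.matrix(df), "CsparseMatrix")
  expression_dataset(m, cell_ids = rownames(df), gene_ids = disambiguate(genes))
}

#' Library-size normalize an expression dataset
#'
#' Scales each cell to a fixed library size and applies `log(1 + x)`. This is
#' the normalization used by every downstream scoring step; multinomial
#' template fitting and likelihood classification stay on raw counts.
#'
#' @param dataset An [expression_dataset()] or `spot_grid`.
#' @param scale_factor Target library size per cell (default 10,000).
#' @return The input with its `normalized` slot filled (sparse, cells x
#'   genes). Cells with zero total counts stay all-zero.
#' @export
normalize_counts <- function(dataset, scale_factor = 1e4) {
  UseMethod("normalize_counts")
}

#' @export
normalize_counts.expr_dataset <- function(dataset, scale_factor = 1e4) {
  dataset$normalized <- lognormalize(dataset$counts, scale_factor)
  dataset
}

lognormalize <- function(counts, scale_factor = 1e4) {
  libsize <- Matrix::rowSums(counts)
  scale <- ifelse(libsize > 0, scale_factor / libsize, 0)
  norm <- Diagonal(x = scale) %*% counts
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  as(norm, "CsparseMatrix")
}

# normalized matrix, computing it on the fly if needed
norm_matrix <- function(dataset) {
  if (is.null(dataset$normalized)) lognormalize(dataset$counts) else dataset$normalized
}

#' Read a marker-gene reference
#'
#' Accepts either GMT (set name, description, then genes) or a two-column
#' table (subtype, gene; with or without a header line named
#' `subtype`/`gene`). Subtype order follows first appearance.
#'
#' @param path Path to the marker file.
#' @param uppercase_genes Normalize gene symbols to upper case.
#' @return A `marker_ref`: list with `subtypes` (ordered character) and
#'   `markers` (named list of character marker sets).
#' @export
read_marker_reference <- function(path, uppercase_genes = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("marker file '%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (all(n_fields == 2L)) {
    # two-column table; tolerate a header row
    subtype <- vapply(fields, `[[`, character(1), 1L)
    gene <- vapply(fields, `[[`, character(1), 2L)
    if (tolower(subtype[1]) %in% c("subtype", "celltype", "label") ||
        tolower(gene[1]) == "gene") {
      subtype <- subtype[-1]; gene <- gene[-1]
    }
    if (any(!nzchar(trimws(gene))) || any(!nzchar(trimws(subtype)))) {
      abort("marker table contains a blank subtype or gene field")
    }
    if (uppercase_genes) gene <- toupper(gene)
    markers <- split(gene, factor(subtype, levels = unique(subtype)))
    markers <- lapply(markers, unique)
  } else {
    # GMT: name, description, genes...
    nm <- vapply(fields, `[[`, character(1), 1L)
    markers <- lapply(fields, function(f) {
      g <- f[-(1:2)]
      g <- g[nzchar(trimws(g))]
      if (uppercase_genes) g <- toupper(g)
      unique(g)
    })
    names(markers) <- nm
  }
  marker_reference(markers)
}

#' Construct a marker reference from a named list
#'
#' @param markers Named list: subtype name -> character vector of marker
#'   genes. Marker sets may overlap between subtypes; each must be non-empty.
#' @return A `marker_ref` object.
#' @export
marker_reference <- function(markers) {
  if (!length(markers) || is.null(names(markers))) {
    abort("`markers` must be a non-empty named list")
  }
  if (any(!vapply(markers, length, 1L))) {
    bad <- names(markers)[!vapply(markers, length, 1L)]
    abort(sprintf("subtype(s) with zero marker genes: %s",
                  paste(bad, collapse = ", ")))
  }
  if (.UNKNOWN %in% names(markers)) {
    abort(sprintf("'%s' is a reserved label and cannot name a subtype", .UNKNOWN))
  }
  markers <- lapply(markers, function(g) unique(as.character(g)))
  structure(list(subtypes = names(markers), markers = markers),
            class = "marker_ref")
}

#' @export
print.marker_ref <- function(x, ...) {
  cat(sprintf("<marker_ref> %d subtypes: %s\n", length(x$subtypes),
              paste(x$subtypes, collapse = ", ")))
  invisible(x)
}

#' Write and re-read an annotation table
#'
#' Annotation results round-trip through a tab-separated file with columns
#' `cell_id`, `assigned_label` and, when the result came from a five-fold
#' ensemble, `vote_1` .. `vote_5`.
#'
#' @param result An `annotation_result` (see [classify_cells()]) or a tibble
#'   with at least `cell_id` and `assigned_label`.
#' @param path Output path.
#' @return Invisibly, the tibble written.
#' @export
write_annotation_table <- function(result, path) {
  df <- as_tibble(result)
  keep <- intersect(c("cell_id", "assigned_label",
                      paste0("vote_", 1:5)), names(df))
  df <- df[keep]
  chr <- vapply(df, function(col) any(grepl("\t", col, fixed = TRUE)), TRUE)
  if (any(chr)) abort("labels must not contain tab characters")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  as_tibble(read.delim(path, sep = "\t", check.names = FALSE,
                       colClasses = "character"))
}
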