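#' Construct an expression matrix
#'
#' An expression matrix is a dense numeric matrix oriented cells x features
#' with unique cell ids as row names and unique feature ids as column names.
#' Values are expected to be log-normalized (hence finite and non-negative).
#'
#' @param values Numeric matrix, cells x features.
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   existing row names).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to existing column names).
#' @return A validated numeric matrix of class `expr_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              feature_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(cell_ids) || is.null(feature_ids)) {
    stop("cell and feature ids are required")
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length of `cell_ids` (", length(cell_ids),
         ") does not match number of rows (", nrow(values), ")")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length of `feature_ids` (", length(feature_ids),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicated cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  dimnames(values) <- list(cell_ids, feature_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Cell metadata table
#'
#' Aligns a metadata table to an expression matrix by cell id (order
#' insensitive).  The batch column is mandatory unless `batch` is `NULL`,
#' in which case all cells are placed in a single batch `"all"`.
#'
#' @param cell_ids Character vector of cell ids (matrix order).
#' @param batch Factor/character of batch assignments per cell, or `NULL`.
#' @param label Optional factor/character of cell-type labels per cell.
#' @return A data.frame with columns `cell_id`, `batch` and optionally
#'   `label`, ordered as `cell_ids`.
#' @export
cell_metadata <- function(cell_ids, batch = NULL, label = NULL) {
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids in metadata")
  if (is.null(batch)) batch <- "all"
  if (length(batch) == 1L) batch <- rep(batch, length(cell_ids))
  if (length(batch) != length(cell_ids)) {
    stop("`batch` length does not match number of cells")
  }
  batch <- factor(as.character(batch))
  if (any(is.na(batch))) stop("missing batch assignments")
  out <- data.frame(cell_id = cell_ids, batch = batch,
                    stringsAsFactors = FALSE)
  if (!is.null(label)) {
    if (length(label) != length(cell_ids)) {
      stop("`label` length does not match number of cells")
    }
    out$label <- factor(as.character(label))
  }
  out
}

#' Read an expression matrix from disk
#'
#' Supports Matrix Market triplets with feature/cell-name sidecar files
#' (the 10x convention: the matrix is stored features x cells unless
#' `transposed = TRUE` says rows are already cells), and dense delimited
#' text with a header row of feature names and a first column of cell ids.
#' Gzip-compressed inputs are accepted everywhere.
#'
#' @param path Path to the `.mtx(.gz)` file or the delimited file.
#' @param fmt `"mtx"` or `"delimited"`.
#' @param features,barcodes Sidecar paths for `fmt = "mtx"`; default to
#'   `features.tsv` / `barcodes.tsv` next to `path`.
#' @param transposed For `"mtx"`: set `TRUE` if the file already stores
#'   cells in rows.  For `"delimited"`: set `TRUE` if rows are features.
#' @param sep Field separator for `"delimited"` (default tab).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, fmt = c("mtx", "delimited"),
                            features = NULL, barcodes = NULL,
                            transposed = FALSE, sep = "\t") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (fmt == "mtx") {
    dir <- dirname(path)
    if (is.null(features)) features <- .sidecar(dir, "features.tsv")
    if (is.null(barcodes)) barcodes <- .sidecar(dir, "barcodes.tsv")
    if (!file.exists(features)) stop("feature sidecar not found: ", features)
    if (!file.exists(barcodes)) stop("barcode sidecar not found: ", barcodes)
    m <- as.matrix(Matrix::readMM(path))
    feat <- readLines(.maybe_gz(features))
    feat <- vapply(strsplit(feat, "\t"), `[`, character(1), 1L)
    bc <- readLines(.maybe_gz(barcodes))
    if (!transposed) m <- t(m)
    if (nrow(m) != length(bc)) {
      stop("barcode file ", barcodes, " lists ", length(bc),
           " cells but matrix ", path, " has ", nrow(m))
    }
    if (ncol(m) != length(feat)) {
      stop("feature file ", features, " lists ", length(feat),
           " features but matrix ", path, " has ", ncol(m))
    }
    expression_matrix(m, bc, feat)
  } else {
    df <- utils::read.table(.maybe_gz(path), header = TRUE, sep = sep,
                            row.names = NULL, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric values in column ", colnames(df)[bad + 1L],
           " of ", path)
    }
    # data.frame subsetting de-duplicates names; restore the header so
    # duplicate feature ids are caught rather than silently renamed
    colnames(m) <- colnames(df)[-1L]
    rownames(m) <- ids
    if (transposed) m <- t(m)
    expression_matrix(m)
  }
}

.sidecar <- function(dir, base) {
  p <- file.path(dir, base)
  if (!file.exists(p) && file.exists(paste0(p, ".gz"))) p <- paste0(p, ".gz")
  p
}

.maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()].  `"mtx"` writes the matrix features x
#' cells (10x convention) plus `features.tsv` and `barcodes.tsv` sidecars.
#'
#' @param x An [expression_matrix()].
#' @param path Output path (for `"mtx"`, the matrix file; sidecars are
#'   written next to it).
#' @param fmt `"mtx"` or `"delimited"`.
#' @param sep Field separator for `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, fmt = c("mtx", "delimited"),
                             sep = "\t") {
  fmt <- match.arg(fmt)
  if (fmt == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(unclass(x)), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(colnames(x), file.path(dir, "features.tsv"))
    writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
  } else {
    df <- data.frame(cell_id = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell metadata table
#'
#' @param path Delimited file with a header; must contain `id_col` and
#'   `batch_col`; `label_col` is optional.
#' @param id_col,batch_col,label_col Column names.
#' @param sep Field separator.
#' @return A data.frame as returned by [cell_metadata()].
#' @export
read_metadata <- function(path, id_col = "cell_id", batch_col = "batch",
                          label_col = "label", sep = "\t") {
  df <- utils::read.table(.maybe_gz(path), header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% colnames(df)) {
    stop("metadata file ", path, " lacks id column '", id_col, "'")
  }
  if (!batch_col %in% colnames(df)) {
    stop("metadata file ", path, " lacks batch column '", batch_col, "'")
  }
  lab <- if (label_col %in% colnames(df)) df[[label_col]] else NULL
  cell_metadata(df[[id_col]], batch = df[[batch_col]], label = lab)
}

#' Align metadata to an expression matrix by cell id
#'
#' Join is by id string, never by position; a metadata table in a
#' different order is silently reordered, missing or unknown ids are
#' errors.
#'
#' @param x An [expression_matrix()].
#' @param meta A [cell_metadata()] data.frame.
#' @return `meta` reordered to match `rownames(x)`.
#' @export
align_metadata <- function(x, meta) {
  idx <- match(rownames(x), meta$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from metadata: ",
         paste(utils::head(rownames(x)[is.na(idx)], 5), collapse = ", "))
  }
  extra <- setdiff(meta$cell_id, rownames(x))
  if (length(extra)) {
    stop("metadata rows with no matching cell: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}

#' Log-normalize a count matrix
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale_factor`, and natural-log transformed with a pseudocount of 1:
#' `out[i,g] = ln(1 + counts[i,g] * scale_factor / total_i)`.
#'
#' @param counts Non-negative numeric matrix, cells x features.
#' @param scale_factor Positive scaling constant (default 10000).
#' @return An [expression_matrix()] of the same dimensions.
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (scale_factor <= 0) stop("`scale_factor` must be positive")
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("cells with zero total counts: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- log1p(counts * (scale_factor / totals))
  expression_matrix(as.matrix(out))
}

#' Drop features expressed in no cell
#'
#' Removes all-zero feature columns, preserving the order of survivors.
#'
#' @param x An [expression_matrix()].
#' @return The filtered [expression_matrix()].
#' @export
filter_unexpressed <- function(x) {
  keep <- colSums(abs(unclass(x))) > 0
  if (!any(keep)) stop("all features are unexpressed")
  expression_matrix(unclass(x)[, keep, drop = FALSE])
}

# Serialized model archives -------------------------------------------------

.ARCHIVE_FORMAT <- "divicp-archive"
.ARCHIVE_VERSION <- 1L

#' Save a fitted model to a versioned archive
#'
#' Works for any of the package's fitted objects (multi-run ICP results,
#' reference models, embeddings).  The archive is a single file carrying a
#' format tag and schema version so that incompatible files are refused,
#' not misread.
#'
#' @param obj Object to serialize.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(obj, path) {
  saveRDS(list(format = .ARCHIVE_FORMAT, version = .ARCHIVE_VERSION,
               class = class(obj)[1L], payload = obj),
          path)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path Archive file.
#' @return The deserialized object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  arch <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read archive ", path, " (corrupted or not an archive): ",
         conditionMessage(e))
  })
  if (!is.list(arch) || !identical(arch$format, .ARCHIVE_FORMAT)) {
    stop("file ", path, " is not a model archive")
  }
  if (arch$version > .ARCHIVE_VERSION) {
    stop("archive ", path, " has schema version ", arch$version,
         " but this build reads at most ", .ARCHIVE_VERSION)
  }
  arch$payload
}
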