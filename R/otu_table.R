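#' Construct an OTU count table
#'
#' The universal input container of the package: a samples-by-OTUs matrix of
#' non-negative integer read counts, plus optional per-sample metadata
#' (developmental stage, treatment, time point).
#'
#' @param counts A samples x OTUs numeric matrix of non-negative integers with
#'   unique row names (sample ids) and column names (OTU ids), or a data frame
#'   in the same wide layout with a leading `sample_id` column.
#' @param metadata Optional data frame of per-sample covariates; must contain a
#'   `sample_id` column matching the rows of `counts`. A `stage` column, when
#'   present, is used by stage-aware downstream steps.
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix), `otu_ids`, `sample_ids`, and `metadata` (tibble or
#'   `NULL`).
#'
#' @details Samples whose row sums are zero are rejected: relative abundances
#'   (and hence log-ratio statistics) are undefined for them.
#'
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'   dimnames = list(paste0("S", 1:4), paste0("OTU_", 1:5)))
#' tab <- otu_table(m)
#' tab
#' @export
otu_table <- function(counts, metadata = NULL) {
  if (is.data.frame(counts)) {
    if (!"sample_id" %in% names(counts)) {
      stop("data-frame input needs a 'sample_id' column", call. = FALSE)
    }
    ids <- as.character(counts$sample_id)
    counts <- as.matrix(counts[setdiff(names(counts), "sample_id")])
    rownames(counts) <- ids
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("OTU_", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("OTU ids must be unique", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0)) {
    stop("samples with zero total reads are not allowed", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (!"sample_id" %in% names(metadata)) {
      stop("metadata needs a 'sample_id' column", call. = FALSE)
    }
    if (!all(rownames(counts) %in% metadata$sample_id)) {
      stop("metadata is missing some samples", call. = FALSE)
    }
    metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  }
  structure(
    list(
      counts = counts,
      otu_ids = colnames(counts),
      sample_ids = rownames(counts),
      metadata = metadata
    ),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "<otu_table> %d samples x %d OTUs, median depth %s\n",
    nrow(x$counts), ncol(x$counts),
    format(stats::median(rowSums(x$counts)), big.mark = ",")
  ))
  if (!is.null(x$metadata) && "stage" %in% names(x$metadata)) {
    tb <- table(x$metadata$stage)
    cat("stages:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Long tidy view of an OTU table
#'
#' @param x An [otu_table()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `otu_id`, `count`, joined with
#'   the sample metadata when present.
#' @export
as_tibble.otu_table <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(x$sample_ids, times = length(x$otu_ids)),
    otu_id = rep(x$otu_ids, each = length(x$sample_ids)),
    count = as.vector(x$counts)
  )
  if (!is.null(x$metadata)) out <- dplyr::left_join(out, x$metadata, by = "sample_id")
  out
}

#' Read / write a classic tab-separated OTU table
#'
#' The classic dialect stores OTUs as rows and samples as columns, with a
#' leading `#OTU ID` header cell (QIIME's "classic" OTU-table layout). The
#' in-memory orientation is samples x OTUs.
#'
#' @param path File path.
#' @param metadata Optional sample metadata passed to [otu_table()].
#' @return `read_otu_table()` returns an [otu_table()]; `write_otu_table()`
#'   returns `path` invisibly.
#' @export
read_otu_table <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  otu_ids <- as.character(df[[1]])
  m <- t(as.matrix(df[-1]))
  colnames(m) <- otu_ids
  otu_table(m, metadata = metadata)
}

#' @rdname read_otu_table
#' @param table An [otu_table()].
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(`#OTU ID` = table$otu_ids, t(table$counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared guard used by inference entry points
assert_otu_table <- function(table) {
  if (!inherits(table, "otu_table")) stop("expected an 'otu_table'", call. = FALSE)
  invisible(table)
}
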