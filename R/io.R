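#' Write an expression matrix and its sample sheet to TSV
#'
#' Matrix file: columns `gene_id`, `is_coding`, then one column per sample
#' (header row of sample ids). Sample sheet: `sample`, `bpa`, `rad`.
#'
#' @param mat An [expr_matrix()].
#' @param matrix_path,sheet_path Output paths.
#' @return Invisibly, the matrix path.
#' @export
write_expression <- function(mat, matrix_path, sheet_path) {
  stopifnot(inherits(mat, "expr_matrix"))
  df <- data.frame(gene_id = mat$gene_ids,
                   is_coding = as.integer(mat$is_coding),
                   mat$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mat$sample_info, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read an expression matrix and sample sheet from TSV
#'
#' Validates on read: unique gene ids, numeric cells (a non-numeric cell
#' is reported with its row and column), and a one-to-one match between
#' matrix columns and sheet samples. Samples are reordered to sheet order.
#' A missing `is_coding` column defaults to all coding.
#'
#' @param matrix_path,sheet_path Input paths.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(matrix_path, sheet_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(sheet_path)) stop("sample sheet not found: ", sheet_path)
  df <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  sheet <- utils::read.table(sheet_path, sep = "\t", header = TRUE,
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
  gene_ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  if ("is_coding" %in% names(df)) {
    is_coding <- as.integer(df[["is_coding"]]) == 1L
    df <- df[, setdiff(names(df), "is_coding"), drop = FALSE]
  } else {
    is_coding <- rep(TRUE, length(gene_ids))
  }
  extra <- setdiff(colnames(df), sheet$sample)
  miss <- setdiff(sheet$sample, colnames(df))
  if (length(extra) || length(miss))
    stop("sample ids mismatch between matrix and sheet; ",
         "matrix-only: [", paste(extra, collapse = ", "), "] ",
         "sheet-only: [", paste(miss, collapse = ", "), "]")
  df <- df[, sheet$sample, drop = FALSE]
  values <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = length(gene_ids),
           dimnames = list(NULL, colnames(df))))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at row ", bad[1], " (gene ",
         gene_ids[bad[1]], "), column '", colnames(df)[bad[2]], "'")
  }
  expr_matrix(values, gene_ids, sheet, is_coding)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member ids. Duplicate members within a set are collapsed with a
#' warning.
#'
#' @param path GMT file path.
#' @return Named list of gene sets, each a list with `name`, `description`,
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set '", f[1], "' (line ", i,
              "): duplicate members collapsed")
      members <- unique(members)
    }
    list(name = f[1], description = f[2], members = members)
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene sets (`name`, `description`, `members`)
#'   or a single such list.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  if (!is.null(sets$members)) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (is.null(s$description)) "" else s$description,
            s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format endpoint table from TSV
#'
#' Expects columns `value`, `factor_bpa`, `factor_rad` (and optionally
#' `subject`).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_endpoint_table <- function(path) {
  if (!file.exists(path)) stop("endpoint table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("value", "factor_bpa", "factor_rad")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("endpoint table missing column(s): ", paste(miss, collapse = ", "))
  df
}
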