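#' Group labels of the 2x2 factorial design
#'
#' The four exposure groups, in canonical order: control, chemical agent
#' alone (BPA), physical agent alone (RAD), and combined exposure.
#'
#' @return Character vector `c("CTL", "BPA", "RAD", "BPA_RAD")`.
#' @export
group_levels <- function() c("CTL", "BPA", "RAD", "BPA_RAD")

#' Construct a factorial expression matrix
#'
#' Container for a genes x samples matrix of log2-normalized intensities
#' together with the 2x2 design (each sample carries a pair of 0/1 exposure
#' indicators) and a per-gene protein-coding flag.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. No
#'   missing values allowed.
#' @param gene_ids Character vector of unique gene/transcript identifiers,
#'   one per row.
#' @param sample_info Data frame with columns `sample`, `bpa`, `rad`
#'   (`bpa`, `rad` in 0/1), one row per column of `values`, in column order.
#' @param is_coding Logical vector, one flag per gene; `TRUE` marks
#'   protein-coding transcripts. Defaults to all `TRUE`.
#'
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values`, `gene_ids`, `sample_info`, `is_coding` and a per-sample
#'   `group` factor with levels [group_levels()].
#' @export
expr_matrix <- function(values, gene_ids, sample_info, is_coding = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("expression values contain missing entries")
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 5), collapse = ", "))
  if (is.null(is_coding)) is_coding <- rep(TRUE, length(gene_ids))
  if (length(is_coding) != length(gene_ids))
    stop("is_coding length does not match gene_ids")
  if (!all(c("sample", "bpa", "rad") %in% names(sample_info)))
    stop("sample_info must have columns sample, bpa, rad")
  if (nrow(sample_info) != ncol(values))
    stop("sample_info rows do not match number of samples")
  if (!all(sample_info$bpa %in% c(0, 1)) || !all(sample_info$rad %in% c(0, 1)))
    stop("bpa and rad indicators must be 0 or 1")
  group <- factor(sample_group(sample_info$bpa, sample_info$rad),
                  levels = group_levels())
  tab <- table(group)
  if (any(tab < 2))
    stop("every exposure group needs >= 2 samples; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  rownames(values) <- gene_ids
  colnames(values) <- sample_info$sample
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         sample_info = sample_info, is_coding = as.logical(is_coding),
         group = group),
    class = "expr_matrix")
}

#' Map 0/1 exposure indicators to group labels
#'
#' @param bpa,rad Vectors of 0/1 indicators.
#' @return Character vector of group labels.
#' @export
sample_group <- function(bpa, rad) {
  out <- character(length(bpa))
  out[bpa == 0 & rad == 0] <- "CTL"
  out[bpa == 1 & rad == 0] <- "BPA"
  out[bpa == 0 & rad == 1] <- "RAD"
  out[bpa == 1 & rad == 1] <- "BPA_RAD"
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$group)),
                                 table(x$group)), collapse = " "), "\n")
  cat("  protein-coding:", sum(x$is_coding), "genes\n")
  invisible(x)
}
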