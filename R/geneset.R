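#' Draw random gene sets of fixed size from the unfiltered gene list
#'
#' Each set is a simple random sample without replacement from the
#' universe (the full measured gene list, DEGs or not); sets are drawn
#' independently of each other.
#'
#' @param universe Character vector of gene ids.
#' @param set_size Genes per set (default 200).
#' @param n_sets Number of sets (default 1000).
#' @param seed Integer seed; same seed reproduces the same sets.
#' @return List of `n_sets` character vectors of length `set_size`.
#' @export
sample_random_sets <- function(universe, set_size = 200, n_sets = 1000,
                               seed = 1L) {
  if (length(universe) < set_size)
    stop("universe (", length(universe),
         ") smaller than requested set size (", set_size, ")")
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  })
}

#' Random-sampling median-shift test for a gene set
#'
#' Tests whether a gene set's log2 fold changes are shifted relative to
#' sets of the same size drawn at random from the unfiltered gene list.
#' The observed statistic is the median logFC over the set's measured
#' members; the null distribution is the medians of `n_sets` random sets.
#' Following the published procedure, a one-sample t-test of the null
#' medians against the observed median (as the reference constant) gives
#' the headline p-value. Because that t-test's sample size is the number
#' of random sets, an empirical rank p-value,
#' (number of null medians at least as extreme + 1) / (n_sets + 1),
#' is reported alongside as the calibrated alternative.
#'
#' @param logfc Named numeric vector of per-gene log2 fold changes for one
#'   contrast (names are gene ids; this is the unfiltered list).
#' @param gene_set Character vector of member gene ids (unmeasured members
#'   are dropped with a message; >= 3 measured members required).
#' @param set_size Size of the random comparison sets; defaults to the
#'   number of measured set members.
#' @param n_sets Number of random sets (default 1000; >= 2 required).
#' @param seed Integer seed for the random sets.
#' @param alpha Significance level used to call a direction (default 0.05).
#' @param set_name Label carried into the result.
#' @param contrast Label carried into the result.
#' @return List of class `"geneset_shift"`: `observed_median`,
#'   `null_medians`, `t_stat`, `p` (t-based), `p_rank` (empirical),
#'   `direction` (`"down"`, `"up"` or `"none"`), `n_sets`, `set_size`,
#'   `n_dropped`, `seed`, `set_name`, `contrast`.
#' @export
geneset_shift_test <- function(logfc, gene_set, set_size = NULL,
                               n_sets = 1000, seed = 1L, alpha = 0.05,
                               set_name = "gene_set", contrast = "") {
  if (is.null(names(logfc))) stop("logfc must be named by gene id")
  if (n_sets < 2) stop("need at least 2 random sets")
  members <- unique(gene_set)
  measured <- intersect(members, names(logfc))
  n_dropped <- length(members) - length(measured)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " unmeasured gene-set member(s)")
  if (length(measured) < 3)
    stop("fewer than 3 measured gene-set members")
  if (is.null(set_size)) set_size <- length(measured)
  observed <- stats::median(logfc[measured])
  sets <- sample_random_sets(names(logfc), set_size, n_sets, seed)
  null_medians <- vapply(sets, function(s) stats::median(logfc[s]),
                         numeric(1))
  null_mean <- mean(null_medians)
  if (stats::sd(null_medians) == 0) {
    warning("zero-variance null: all random-set medians identical")
    t_stat <- if (null_medians[1] == observed) 0 else
      sign(null_mean - observed) * Inf
    p <- if (null_medians[1] == observed) 1 else 0
  } else {
    tt <- stats::t.test(null_medians, mu = observed)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  p_rank <- (sum(abs(null_medians - null_mean) >=
                   abs(observed - null_mean)) + 1) / (n_sets + 1)
  direction <- "none"
  if (p < alpha && null_mean != observed)
    direction <- if (observed < null_mean) "down" else "up"
  structure(list(observed_median = observed, null_medians = null_medians,
                 t_stat = t_stat, p = p, p_rank = p_rank,
                 direction = direction, n_sets = as.integer(n_sets),
                 set_size = as.integer(set_size),
                 n_dropped = as.integer(n_dropped), seed = as.integer(seed),
                 set_name = set_name, contrast = contrast),
            class = "geneset_shift")
}

#' @export
print.geneset_shift <- function(x, ...) {
  cat(sprintf("gene-set shift test: %s (%s)\n", x$set_name, x$contrast))
  cat(sprintf("  observed median logFC = %.4f over %d genes\n",
              x$observed_median, x$set_size))
  cat(sprintf("  null: %d random sets, mean median = %.4f\n",
              x$n_sets, mean(x$null_medians)))
  cat(sprintf("  t = %.2f, p = %.3g (rank p = %.3g), direction = %s\n",
              x$t_stat, x$p, x$p_rank, x$direction))
  invisible(x)
}
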