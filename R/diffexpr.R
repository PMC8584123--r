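#' Fit the four-group factorial model gene by gene
#'
#' The group-means parameterization of the 2x2 design: per gene, the
#' arithmetic mean of each exposure group and the pooled within-group
#' residual variance with N - 4 degrees of freedom. Equivalent fitted
#' means to the two-factor-with-interaction parameterization.
#'
#' @param mat An [expr_matrix()].
#' @return List of class `"group_fit"`: `means` (genes x 4 matrix, columns
#'   [group_levels()]), `s2` (pooled residual variance per gene), `df`
#'   (residual degrees of freedom, scalar), `n` (named group sizes),
#'   `gene_ids`, `is_coding`.
#' @export
fit_groups <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  groups <- group_levels()
  idx <- lapply(groups, function(g) which(mat$group == g))
  names(idx) <- groups
  if (any(lengths(idx) < 1)) stop("every group needs at least one sample")
  N <- ncol(mat$values)
  df <- N - 4L
  if (df <= 0) stop("residual df N - 4 must be positive; have N = ", N)
  means <- do.call(cbind, lapply(idx, function(i)
    rowMeans(mat$values[, i, drop = FALSE])))
  ss <- 0
  for (g in groups) {
    dev <- mat$values[, idx[[g]], drop = FALSE] - means[, g]
    ss <- ss + rowSums(dev^2)
  }
  structure(list(means = means, s2 = ss / df, df = df,
                 n = lengths(idx), gene_ids = mat$gene_ids,
                 is_coding = mat$is_coding),
            class = "group_fit")
}

#' Estimate the variance prior by the method of moments on log variances
#'
#' Fits the scaled-F hierarchical model behind variance moderation: given
#' gene-wise residual variances s2 with common residual df d and prior
#' sigma^2 ~ s0_sq * d0 / chisq(d0), log(s2) has known mean and variance in
#' terms of digamma/trigamma functions. Matching the first two empirical
#' moments of log(s2) yields (d0, s0_sq). When the empirical spread of
#' log(s2) does not exceed what sampling alone (trigamma(d/2)) explains,
#' the prior df is infinite: every gene shares one variance and no
#' moderation beyond pooling is possible.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar, > 0).
#' @return List with `d0` (positive, possibly `Inf`) and `s0_sq`.
#'   Deterministic. Genes with `s2 == 0` are excluded from the moments (at
#'   least 50 positive variances required).
#' @export
estimate_prior <- function(s2, df) {
  stopifnot(length(df) == 1, df > 0)
  s2 <- s2[is.finite(s2)]
  pos <- s2[s2 > 0]
  if (length(pos) == 0) stop("degenerate variance field: all variances zero")
  if (length(pos) < 50)
    stop("need >= 50 genes with positive residual variance; have ",
         length(pos))
  z <- log(pos)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling: one shared variance
    d0 <- Inf
    s0_sq <- mean(pos)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Invert the trigamma function
#'
#' Solves trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma,
#' which is nearly linear; used by the method-of-moments prior estimator.
#'
#' @param x Positive value(s).
#' @return y with trigamma(y) = x (elementwise).
#' @export
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  y
}

#' Shrink residual variances toward the prior
#'
#' Posterior (moderated) variance s2_tilde = (d0 * s0_sq + d * s2) /
#' (d0 + d); with d0 = Inf every gene gets s0_sq.
#'
#' @param fit A `"group_fit"` from [fit_groups()].
#' @param prior List with `d0`, `s0_sq` (e.g. from [estimate_prior()]);
#'   `d0 = 0` disables moderation (ordinary pooled variances).
#' @return The fit, augmented with `s2_tilde`, `d0`, `s0_sq`.
#' @export
moderate_variances <- function(fit, prior) {
  stopifnot(inherits(fit, "group_fit"))
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (d0 < 0) stop("prior df must be >= 0")
  fit$s2_tilde <- if (is.infinite(d0)) rep(s0, length(fit$s2)) else
    (d0 * s0 + fit$df * fit$s2) / (d0 + fit$df)
  fit$d0 <- d0
  fit$s0_sq <- s0
  class(fit) <- c("moderated_fit", class(fit))
  fit
}

#' Moderated t-test of one exposure contrast against control
#'
#' logFC = mean(exposed) - mean(CTL); t = logFC / sqrt(s2_tilde *
#' (1/n_t + 1/n_c)); two-sided p from the t distribution on d + d0 total
#' degrees of freedom (standard normal in the d0 = Inf limit). Negative
#' logFC means downregulation under exposure.
#'
#' @param fit A `"moderated_fit"` from [moderate_variances()].
#' @param contrast One of `"BPA"`, `"RAD"`, `"BPA_RAD"`.
#' @param lfc_cutoff,p_cutoff DEG thresholds applied inclusively to set the
#'   `significant` flag (defaults 0.5 and 0.05).
#' @return Data frame: `gene_id`, `logFC`, `t`, `p`, `p_adj` (BH-adjusted,
#'   informational only — never used for filtering), `significant`,
#'   `is_coding`.
#' @export
moderated_contrast <- function(fit, contrast = c("BPA", "RAD", "BPA_RAD"),
                               lfc_cutoff = 0.5, p_cutoff = 0.05) {
  stopifnot(inherits(fit, "moderated_fit"))
  contrast <- match.arg(contrast)
  logFC <- fit$means[, contrast] - fit$means[, "CTL"]
  se2 <- fit$s2_tilde * (1 / fit$n[[contrast]] + 1 / fit$n[["CTL"]])
  df_total <- fit$df + fit$d0
  tstat <- p <- numeric(length(logFC))
  zero <- se2 == 0
  if (any(zero & logFC != 0))
    warning(sum(zero & logFC != 0),
            " gene(s) with zero posterior variance but nonzero logFC: p set to 0")
  tstat[!zero] <- logFC[!zero] / sqrt(se2[!zero])
  tstat[zero] <- ifelse(logFC[zero] == 0, 0, sign(logFC[zero]) * Inf)
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  p[zero & logFC == 0] <- 1
  p[zero & logFC != 0] <- 0
  data.frame(gene_id = fit$gene_ids, logFC = unname(logFC),
             t = unname(tstat), p = unname(p),
             p_adj = stats::p.adjust(p, method = "BH"),
             significant = p <= p_cutoff & abs(logFC) >= lfc_cutoff,
             is_coding = fit$is_coding,
             stringsAsFactors = FALSE)
}

#' Moderated F-test across the four exposure groups
#'
#' One-way moderated F over the group means (between-group mean square
#' over the posterior variance), on (3, d + d0) degrees of freedom.
#' Exposed for completeness; DEG calls use the per-contrast t-tests.
#'
#' @param fit A `"moderated_fit"`.
#' @return Data frame with `gene_id`, `F`, `p`.
#' @export
moderated_ftest <- function(fit) {
  stopifnot(inherits(fit, "moderated_fit"))
  grand <- as.vector(fit$means %*% fit$n) / sum(fit$n)
  msb <- rowSums(sweep((fit$means - grand)^2, 2, fit$n, "*")) / 3
  Fstat <- ifelse(fit$s2_tilde > 0, msb / fit$s2_tilde,
                  ifelse(msb == 0, 0, Inf))
  p <- stats::pf(Fstat, 3, fit$df + fit$d0, lower.tail = FALSE)
  p[Fstat == 0] <- 1
  data.frame(gene_id = fit$gene_ids, F = unname(Fstat), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Run the full moderated DE analysis for the three exposure contrasts
#'
#' Convenience wrapper: [fit_groups()], [estimate_prior()],
#' [moderate_variances()], then [moderated_contrast()] for BPA, RAD and
#' BPA_RAD vs control.
#'
#' @param mat An [expr_matrix()].
#' @param lfc_cutoff,p_cutoff DEG thresholds (inclusive), defaults 0.5 and
#'   0.05.
#' @param prior Optional list `(d0, s0_sq)` to override the estimated
#'   prior (e.g. `d0 = 0` for an unmoderated analysis).
#' @return List of class `"de_result"`: `tables` (named list of the three
#'   contrast data frames), `prior`, `fit`.
#' @export
run_de <- function(mat, lfc_cutoff = 0.5, p_cutoff = 0.05, prior = NULL) {
  fit <- fit_groups(mat)
  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df)
  mfit <- moderate_variances(fit, prior)
  tables <- lapply(c(BPA = "BPA", RAD = "RAD", BPA_RAD = "BPA_RAD"),
                   moderated_contrast, fit = mfit,
                   lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff)
  structure(list(tables = tables, prior = prior, fit = mfit,
                 lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff),
            class = "de_result")
}

#' Filter a contrast table to its differentially expressed genes
#'
#' Inclusive thresholds exactly as printed in the headline analysis:
#' |logFC| >= lfc_cutoff AND p <= p_cutoff (raw p; no multiplicity
#' correction enters the call).
#'
#' @param de_table A contrast data frame from [moderated_contrast()].
#' @param lfc_cutoff,p_cutoff Thresholds (defaults 0.5, 0.05).
#' @return Data frame of the passing rows (`gene_id`, `logFC`, `p`, ...).
#'   May be empty.
#' @export
filter_degs <- function(de_table, lfc_cutoff = 0.5, p_cutoff = 0.05) {
  stopifnot(all(c("gene_id", "logFC", "p") %in% names(de_table)))
  de_table[abs(de_table$logFC) >= lfc_cutoff & de_table$p <= p_cutoff, ,
           drop = FALSE]
}

#' Venn-region counts of DEG lists
#'
#' Counts genes in every membership region of the Venn diagram over the
#' given lists (region "BPA&RAD" = in both those lists and no other).
#' Region counts sum to the size of the union.
#'
#' @param lists Named list (>= 2 entries) of gene-id character vectors;
#'   ids must be unique within each list.
#' @return Data frame with `region` (list names joined by "&") and
#'   `count`, one row per nonempty membership pattern plus all empty
#'   regions with count 0.
#' @export
deg_overlap <- function(lists) {
  if (length(lists) < 2) stop("need at least two DEG lists")
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named")
  for (nm in names(lists)) {
    if (anyDuplicated(lists[[nm]]))
      stop("duplicate gene ids within list '", nm, "'")
  }
  universe <- unique(unlist(lists, use.names = FALSE))
  member <- vapply(lists, function(l) universe %in% l,
                   logical(length(universe)))
  if (length(universe) == 0)
    member <- matrix(logical(0), 0, length(lists),
                     dimnames = list(NULL, names(lists)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(lists)))
  names(patterns) <- names(lists)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  region <- apply(patterns, 1, function(r)
    paste(names(lists)[as.logical(r)], collapse = "&"))
  count <- apply(patterns, 1, function(r)
    sum(colSums(t(member) == as.logical(r)) == length(lists)))
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}
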