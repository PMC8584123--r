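#' Abercrombie correction for double-counted nuclei
#'
#' Profile counts in tissue sections overestimate cell numbers because a
#' nucleus split across adjacent sections is counted in both. The classic
#' thickness correction N = n * T / (T + H), with T the section thickness
#' and H the mean nuclear height (same units), removes the bias.
#'
#' @param raw_counts Nonnegative per-section counts.
#' @param thickness Section thickness T, micrometers (> 0).
#' @param nuclear_height Mean nuclear height H, micrometers (>= 0).
#' @return Corrected per-section counts (correction factor in (0, 1]).
#' @export
abercrombie_correct <- function(raw_counts, thickness, nuclear_height) {
  if (any(raw_counts < 0)) stop("raw counts must be nonnegative")
  if (!(thickness > 0)) stop("section thickness must be positive")
  if (nuclear_height < 0) stop("nuclear height must be nonnegative")
  if (thickness + nuclear_height == 0) stop("T + H must be positive")
  raw_counts * thickness / (thickness + nuclear_height)
}

#' Extrapolate a whole-organ count from systematically sampled sections
#'
#' With equidistant 1-in-k section sampling, the organ total is the sum of
#' the (corrected) counts times the sampling interval k.
#'
#' @param corrected_counts Per-section corrected counts (non-empty).
#' @param sampling_interval k >= 1: every k-th section was counted.
#' @return Estimated whole-organ count.
#' @export
extrapolate_total <- function(corrected_counts, sampling_interval) {
  if (length(corrected_counts) == 0) stop("no section counts supplied")
  if (sampling_interval < 1) stop("sampling interval must be >= 1")
  sum(corrected_counts) * sampling_interval
}

#' Cells per unit reference area
#'
#' @param count Cell count(s).
#' @param area Reference area(s), mm^2 (> 0).
#' @return count / area, cells per mm^2 (vectorized).
#' @export
density_per_area <- function(count, area) {
  if (any(area <= 0)) stop("area must be positive")
  count / area
}

#' Partner-preference score
#'
#' (a - b) / (a + b) for the times spent investigating the two stimulus
#' arms; +1 is exclusive preference for arm A, -1 for arm B, 0 no
#' preference. Antisymmetric in its arguments.
#'
#' @param time_arm_a,time_arm_b Investigation times, seconds (>= 0, not
#'   both zero; vectorized).
#' @return Score(s) in [-1, 1].
#' @export
preference_score <- function(time_arm_a, time_arm_b) {
  if (any(time_arm_a < 0) || any(time_arm_b < 0))
    stop("investigation times must be nonnegative")
  if (any(time_arm_a + time_arm_b == 0)) stop("no investigation time")
  (time_arm_a - time_arm_b) / (time_arm_a + time_arm_b)
}

#' Two-way factorial ANOVA with Tukey HSD and compact letter display
#'
#' Fits value ~ bpa * rad with type-II sums of squares (appropriate for
#' balanced or near-balanced 2x2 designs), then Tukey's HSD over the four
#' cell means (the studentized range with the pooled error df), and a
#' compact letter display in which groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param table Data frame with columns `value`, `factor_bpa`,
#'   `factor_rad` (0/1). All four cells must be occupied with >= 2
#'   replicates.
#' @param alpha Significance level for the Tukey letters (default 0.05).
#' @return List of class `"anova_tukey"`: `anova` (data frame with `term`,
#'   `F`, `p` for BPA, RAD, interaction), `tukey` (data frame of the six
#'   pairwise comparisons with `diff` and `p_adj`), `letters` (named
#'   character vector group -> letters), `group_means`, `alpha`.
#' @export
two_way_anova_tukey <- function(table, alpha = 0.05) {
  stopifnot(all(c("value", "factor_bpa", "factor_rad") %in% names(table)))
  if (!all(is.finite(table$value))) stop("endpoint values must be finite")
  grp <- factor(sample_group(table$factor_bpa, table$factor_rad),
                levels = group_levels())
  tab <- table(grp)
  if (any(tab == 0))
    stop("empty design cell: ", paste(names(tab)[tab == 0], collapse = ", "))
  if (any(tab < 2))
    stop("cell(s) with < 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  bpa <- factor(table$factor_bpa)
  rad <- factor(table$factor_rad)
  means <- tapply(table$value, grp, mean)

  if (stats::var(table$value) == 0) {
    # all observations identical: no variance to test; everything ties
    anova_df <- data.frame(term = c("BPA", "RAD", "BPA:RAD"),
                           F = NA_real_, p = 1, stringsAsFactors = FALSE)
    pairs <- t(utils::combn(group_levels(), 2))
    tukey <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                        diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    letters <- stats::setNames(rep("a", 4), group_levels())
    return(structure(list(anova = anova_df, tukey = tukey,
                          letters = letters, group_means = means,
                          alpha = alpha),
                     class = "anova_tukey"))
  }

  fit <- stats::lm(value ~ bpa * rad, data = data.frame(value = table$value,
                                                        bpa = bpa, rad = rad))
  a2 <- car::Anova(fit, type = "II")
  anova_df <- data.frame(term = c("BPA", "RAD", "BPA:RAD"),
                         F = a2[c("bpa", "rad", "bpa:rad"), "F value"],
                         p = a2[c("bpa", "rad", "bpa:rad"), "Pr(>F)"],
                         stringsAsFactors = FALSE, row.names = NULL)

  aovfit <- stats::aov(value ~ grp,
                       data = data.frame(value = table$value, grp = grp))
  th <- stats::TukeyHSD(aovfit, conf.level = 1 - alpha)$grp
  cmp <- strsplit(rownames(th), "-", fixed = TRUE)
  tukey <- data.frame(group1 = vapply(cmp, `[`, "", 1),
                      group2 = vapply(cmp, `[`, "", 2),
                      diff = unname(th[, "diff"]),
                      p_adj = unname(th[, "p adj"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  sig_pairs <- tukey[tukey$p_adj < alpha, c("group1", "group2"),
                     drop = FALSE]
  letters <- compact_letter_display(group_levels(), sig_pairs)

  structure(list(anova = anova_df, tukey = tukey, letters = letters,
                 group_means = means, alpha = alpha),
            class = "anova_tukey")
}

#' Compact letter display by insert-and-absorb
#'
#' Assigns letter strings to groups so that two groups share at least one
#' letter if and only if they are NOT in the significant-difference list.
#' Implements the insert-and-absorb algorithm: start from one letter
#' covering all groups; for each significant pair, split every letter
#' containing both into two (each missing one member of the pair); absorb
#' letters that are subsets of others.
#'
#' @param groups Character vector of group names.
#' @param sig_pairs Data frame (or 2-column matrix) of significantly
#'   different pairs (`group1`, `group2`).
#' @return Named character vector: group -> concatenated letters.
#' @export
compact_letter_display <- function(groups, sig_pairs) {
  cols <- list(groups)
  sig_pairs <- as.data.frame(sig_pairs, stringsAsFactors = FALSE)
  if (nrow(sig_pairs)) {
    for (k in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs[k, 1]
      g2 <- sig_pairs[k, 2]
      new_cols <- list()
      for (col in cols) {
        if (g1 %in% col && g2 %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, g1)),
                        list(setdiff(col, g2)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
      cols <- cols[lengths(cols) > 0]
    }
  }
  labs <- vapply(seq_along(groups), function(i) {
    paste(letters[which(vapply(cols, function(col) groups[i] %in% col,
                               logical(1)))], collapse = "")
  }, character(1))
  stats::setNames(labs, groups)
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("two-way ANOVA (type II):\n")
  print(x$anova, row.names = FALSE)
  cat("group means with Tukey letters (alpha =", x$alpha, "):\n")
  for (g in names(x$letters))
    cat(sprintf("  %-8s %8.3f  %s\n", g, x$group_means[[g]], x$letters[[g]]))
  invisible(x)
}
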