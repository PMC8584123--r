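#' Simulate a factorial expression matrix with known ground truth
#'
#' Generates log2 intensities under the hierarchical model that makes
#' empirical-Bayes moderated statistics exact: per-gene variances
#' sigma_g^2 ~ s0_sq * d0 / chisq(d0) (a scaled inverse-chi-square prior),
#' and sample values Normal(baseline_g + group effect, sigma_g). Group
#' effects are the planted log2 fold changes vs control recorded in the
#' truth table; the combined-exposure effect of each non-null gene is
#' constructed from its single-exposure effects according to its drawn
#' interaction class (additive: sum; potentiation/antagonism: sum scaled by
#' the configured factor; unexpected: sign-reversed sum). A planted gene
#' set of coherently downregulated genes (all with the same
#' combined-exposure shift) emulates a coordinated pathway signature.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `matrix` (an [expr_matrix()]) and `truth`,
#'   a data frame with one row per gene: `gene_id`, `beta_bpa`, `beta_rad`,
#'   `beta_combo`, `true_class` (one of null/additive/potentiation/
#'   antagonism/unexpected), `sigma_sq`, `set_membership`, `is_coding`.
#'   Identical config (including seed) gives bit-identical output.
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_genes
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("G%05d", seq_len(n))
    is_coding <- rep(FALSE, n)
    is_coding[sample.int(n, round(n * config$coding_fraction))] <- TRUE

    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    sigma_sq <- if (is.finite(config$d0)) {
      config$s0_sq * config$d0 / stats::rchisq(n, config$d0)
    } else rep(config$s0_sq, n)

    rng <- config$effect_size_range
    draw_beta <- function(active) {
      mag <- stats::runif(n, rng[1], rng[2])
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      ifelse(active, sgn * mag, 0)
    }
    de_bpa <- stats::runif(n) < config$frac_de_bpa
    de_rad <- stats::runif(n) < config$frac_de_rad
    beta_bpa <- draw_beta(de_bpa)
    beta_rad <- draw_beta(de_rad)

    true_class <- rep("null", n)
    beta_combo <- numeric(n)
    nonnull <- which(de_bpa | de_rad)
    if (length(nonnull)) {
      klass <- sample(names(config$interaction_mix), length(nonnull),
                      replace = TRUE, prob = config$interaction_mix)
      s <- beta_bpa[nonnull] + beta_rad[nonnull]
      fac <- c(additive = 1,
               potentiation = config$potentiation_factor,
               antagonism = config$antagonism_factor,
               unexpected = -1)[klass]
      beta_combo[nonnull] <- fac * s
      true_class[nonnull] <- klass
    }

    # planted coherent set: identical combined-exposure shift so its true
    # median equals planted_set_shift exactly; single effects split evenly
    # (additive by construction)
    set_membership <- rep(FALSE, n)
    if (config$planted_set_size > 0) {
      planted <- sample.int(n, config$planted_set_size)
      set_membership[planted] <- TRUE
      beta_bpa[planted] <- config$planted_set_shift / 2
      beta_rad[planted] <- config$planted_set_shift / 2
      beta_combo[planted] <- config$planted_set_shift
      true_class[planted] <- if (config$planted_set_shift == 0) "null" else "additive"
    }

    effects <- cbind(CTL = 0, BPA = beta_bpa, RAD = beta_rad,
                     BPA_RAD = beta_combo)
    k <- config$n_reps_per_group
    groups <- rep(group_levels(), each = k)
    samples <- paste(groups, rep(seq_len(k), times = 4), sep = "_")
    mu <- baseline + effects[, groups, drop = FALSE]
    values <- mu + matrix(stats::rnorm(n * length(groups), 0,
                                       sqrt(sigma_sq)),
                          nrow = n)
    colnames(values) <- samples

    sheet <- data.frame(sample = samples,
                        bpa = as.integer(groups %in% c("BPA", "BPA_RAD")),
                        rad = as.integer(groups %in% c("RAD", "BPA_RAD")),
                        stringsAsFactors = FALSE)
    mat <- expr_matrix(values, gene_ids, sheet, is_coding)
    truth <- data.frame(gene_id = gene_ids, beta_bpa = beta_bpa,
                        beta_rad = beta_rad, beta_combo = beta_combo,
                        true_class = true_class, sigma_sq = sigma_sq,
                        set_membership = set_membership,
                        is_coding = is_coding, stringsAsFactors = FALSE)
    list(matrix = mat, truth = truth)
  })
}

#' Simulate a long-format endpoint table
#'
#' Draws normal measurements for the four exposure groups of the 2x2
#' design, e.g. cell densities or call counts, for exercising the factorial
#' ANOVA machinery.
#'
#' @param n_per_group Replicates per group (>= 2: the ANOVA needs residual
#'   degrees of freedom).
#' @param group_means Numeric length 4, in [group_levels()] order (a named
#'   vector is reordered by name).
#' @param group_sd Common within-group standard deviation (>= 0; 0 gives
#'   noise-free values).
#' @param seed Integer seed.
#' @return Data frame with columns `value`, `factor_bpa`, `factor_rad`
#'   (0/1), `subject`.
#' @export
simulate_endpoint_table <- function(n_per_group, group_means, group_sd, seed) {
  if (n_per_group < 2) stop("n_per_group must be >= 2 (ANOVA residual df)")
  if (length(group_means) != 4) stop("group_means must have length 4")
  if (!is.null(names(group_means))) {
    if (!setequal(names(group_means), group_levels()))
      stop("named group_means must use: ", paste(group_levels(), collapse = ", "))
    group_means <- group_means[group_levels()]
  }
  if (group_sd < 0) stop("group_sd must be >= 0")
  withr::with_seed(seed, {
    groups <- rep(group_levels(), each = n_per_group)
    value <- rep(unname(group_means), each = n_per_group) +
      stats::rnorm(4 * n_per_group, 0, group_sd)
    data.frame(value = value,
               factor_bpa = as.integer(groups %in% c("BPA", "BPA_RAD")),
               factor_rad = as.integer(groups %in% c("RAD", "BPA_RAD")),
               subject = paste(groups, rep(seq_len(n_per_group), 4), sep = "_"),
               stringsAsFactors = FALSE)
  })
}
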