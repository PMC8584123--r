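#' Simulation configuration for factorial expression data
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the statistical structure of a pooled-replicate 2x2
#' fetal-testis microarray design: two pooled replicates per condition,
#' gene-wise variances from a scaled inverse-chi-square prior, planted
#' treatment effects with |log2FC| in [0.5, 2], and a coordinated
#' downregulated 200-gene set.
#'
#' @param n_genes Number of transcripts to simulate.
#' @param coding_fraction Fraction of transcripts flagged protein-coding.
#' @param n_reps_per_group Samples per exposure group (pools are treated as
#'   independent samples).
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline
#'   log2 intensities.
#' @param d0 Prior degrees of freedom of the variance prior (may be `Inf`).
#' @param s0_sq Prior variance (log2-intensity scale).
#' @param frac_de_bpa,frac_de_rad Fractions of genes given a nonzero effect
#'   under each single exposure; drawn independently so overlap arises by
#'   chance.
#' @param effect_size_range Length-2 numeric: |log2FC| magnitudes are drawn
#'   uniformly from this interval. The lower bound must be at least the DEG
#'   cutoff (0.5) so planted effects are detectable.
#' @param interaction_mix Named numeric proportions over
#'   `c(additive, potentiation, antagonism, unexpected)`, summing to 1;
#'   class assignment for genes with a nonzero single-exposure effect.
#' @param potentiation_factor Ratio |combo| / |sum of singles| planted for
#'   potentiation genes; must exceed 1.2.
#' @param antagonism_factor Same ratio for antagonism genes; in (0, 0.8).
#' @param planted_set_size Size of the coherently shifted gene set (0
#'   disables planting).
#' @param planted_set_shift Common combined-exposure log2FC of the planted
#'   set (negative = coordinated downregulation).
#' @param seed Integer seed; the single source of randomness.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000,
                       coding_fraction = 0.6,
                       n_reps_per_group = 2,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       d0 = 4,
                       s0_sq = 0.01,
                       frac_de_bpa = 0.05,
                       frac_de_rad = 0.05,
                       effect_size_range = c(0.5, 2),
                       interaction_mix = c(additive = 0.25, potentiation = 0.25,
                                           antagonism = 0.25, unexpected = 0.25),
                       potentiation_factor = 2,
                       antagonism_factor = 0.4,
                       planted_set_size = 200,
                       planted_set_shift = -0.5,
                       seed = 1L) {
  stopifnot(length(n_genes) == 1, n_genes >= 1,
            length(n_reps_per_group) == 1)
  if (n_reps_per_group < 1) stop("n_reps_per_group must be >= 1")
  props <- c(coding_fraction, frac_de_bpa, frac_de_rad)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  if (!(d0 > 0)) stop("prior df d0 must be positive (Inf allowed)")
  if (!(s0_sq > 0)) stop("prior variance s0_sq must be positive")
  if (length(effect_size_range) != 2 || diff(effect_size_range) < 0)
    stop("effect_size_range must be an increasing pair")
  if (effect_size_range[1] < 0.5)
    stop("effect_size_range lower bound must be >= the DEG logFC cutoff (0.5) ",
         "so planted effects are detectable")
  classes <- c("additive", "potentiation", "antagonism", "unexpected")
  if (!setequal(names(interaction_mix), classes))
    stop("interaction_mix must be named over: ", paste(classes, collapse = ", "))
  interaction_mix <- interaction_mix[classes]
  if (any(interaction_mix < 0) || abs(sum(interaction_mix) - 1) > 1e-9)
    stop("interaction_mix must be nonnegative and sum to 1 (tolerance 1e-9)")
  if (!(potentiation_factor > 1.2))
    stop("potentiation_factor must exceed 1.2")
  if (!(antagonism_factor > 0 && antagonism_factor < 0.8))
    stop("antagonism_factor must lie in (0, 0.8)")
  if (planted_set_size < 0 || planted_set_size > n_genes)
    stop("planted_set_size must be in [0, n_genes]")
  structure(
    list(n_genes = as.integer(n_genes),
         coding_fraction = coding_fraction,
         n_reps_per_group = as.integer(n_reps_per_group),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         d0 = d0, s0_sq = s0_sq,
         frac_de_bpa = frac_de_bpa, frac_de_rad = frac_de_rad,
         effect_size_range = effect_size_range,
         interaction_mix = interaction_mix,
         potentiation_factor = potentiation_factor,
         antagonism_factor = antagonism_factor,
         planted_set_size = as.integer(planted_set_size),
         planted_set_shift = planted_set_shift,
         seed = as.integer(seed)),
    class = "sim_config")
}
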