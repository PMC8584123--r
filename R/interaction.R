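#' Interaction ratio of a combined exposure over the sum of single agents
#'
#' r = |logFC(combined)| / |logFC(agent A) + logFC(agent B)|, the signed
#' sum in the denominator. Under additivity of effects on the log2 scale
#' r is close to 1. Undefined (NA) when the predicted sum is numerically
#' zero (|sum| < eps).
#'
#' @param lfc_bpa,lfc_rad,lfc_combo Log2 fold changes vs control
#'   (vectorized; must be finite).
#' @param eps Zero-denominator guard, default 1e-8 (far below any
#'   meaningful logFC resolution).
#' @return Nonnegative numeric vector, NA where undefined.
#' @export
interaction_ratio <- function(lfc_bpa, lfc_rad, lfc_combo, eps = 1e-8) {
  if (!all(is.finite(lfc_bpa), is.finite(lfc_rad), is.finite(lfc_combo)))
    stop("log fold changes must be finite")
  pred <- lfc_bpa + lfc_rad
  r <- abs(lfc_combo) / abs(pred)
  r[abs(pred) < eps] <- NA_real_
  r
}

#' Classify the combined-exposure effect of each transcript
#'
#' Total classification of the BPA x RAD combined response from the three
#' log2 fold changes vs control:
#' \itemize{
#'   \item \strong{unexpected} — the combined response goes in the
#'     opposite direction to the predicted sum of single-agent effects
#'     (a zero combined logFC counts as sign-concordant), or the
#'     predicted sum is numerically zero so the ratio is undefined;
#'   \item \strong{additive} — ratio r in the closed interval [lo, hi];
#'   \item \strong{potentiation} — r > hi (combined effect stronger than
#'     the sum of the single effects);
#'   \item \strong{antagonism} — r < lo (combined effect weaker).
#' }
#' The additive class owns the closed interval, so the printed boundary
#' values 0.8 and 1.2 are additive. Classification is invariant to scaling
#' all three logFCs by a common positive constant.
#'
#' @param lfc_bpa,lfc_rad,lfc_combo Log2 fold changes vs control
#'   (vectorized, finite).
#' @param lo,hi Additivity window bounds (defaults 0.8 and 1.2; `lo < hi`
#'   required).
#' @param eps Zero-denominator guard for the ratio.
#' @return Character vector over
#'   `c("additive", "potentiation", "antagonism", "unexpected")`; every
#'   input gets exactly one class.
#' @export
classify_interaction <- function(lfc_bpa, lfc_rad, lfc_combo,
                                 lo = 0.8, hi = 1.2, eps = 1e-8) {
  if (lo >= hi) stop("additivity bounds require lo < hi")
  r <- interaction_ratio(lfc_bpa, lfc_rad, lfc_combo, eps = eps)
  pred <- lfc_bpa + lfc_rad
  discordant <- lfc_combo != 0 & sign(lfc_combo) != sign(pred)
  out <- character(length(r))
  out[is.na(r) | discordant] <- "unexpected"
  todo <- out == ""
  out[todo & r >= lo & r <= hi] <- "additive"
  out[todo & r > hi] <- "potentiation"
  out[todo & r < lo] <- "antagonism"
  out
}

#' Assemble the misregulated-transcript universe from the DE tables
#'
#' The transcripts entering the interaction study: by default the union of
#' significant DEGs across all three contrasts (BPA, RAD, combined);
#' `mode = "bpa_rad_only"` restricts to transcripts significant under
#' either single exposure. `scope = "protein_coding"` further restricts by
#' the coding flag.
#'
#' @param de A `"de_result"` from [run_de()] or a named list of the three
#'   contrast tables (`BPA`, `RAD`, `BPA_RAD`) sharing one gene index.
#' @param mode `"union"` (default) or `"bpa_rad_only"`.
#' @param scope `"all"` (default) or `"protein_coding"`.
#' @return Character vector of gene ids (may be empty, with a warning).
#' @export
build_universe <- function(de, mode = c("union", "bpa_rad_only"),
                           scope = c("all", "protein_coding")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  tables <- if (inherits(de, "de_result")) de$tables else de
  stopifnot(all(c("BPA", "RAD", "BPA_RAD") %in% names(tables)))
  ids <- tables$BPA$gene_id
  if (!identical(ids, tables$RAD$gene_id) ||
      !identical(ids, tables$BPA_RAD$gene_id))
    stop("contrast tables must share one gene index")
  sig <- tables$BPA$significant | tables$RAD$significant
  if (mode == "union") sig <- sig | tables$BPA_RAD$significant
  if (scope == "protein_coding") sig <- sig & tables$BPA$is_coding
  out <- ids[sig]
  if (length(out) == 0) warning("empty interaction universe")
  out
}

#' Per-transcript interaction records for a universe
#'
#' Joins the three contrast tables on the universe and classifies each
#' transcript's combined-exposure response.
#'
#' @param de A `"de_result"` or named list of contrast tables.
#' @param universe Gene ids to classify (e.g. from [build_universe()]).
#' @param lo,hi,eps Passed to [classify_interaction()].
#' @return Data frame: `gene_id`, `lfc_bpa`, `lfc_rad`, `lfc_combo`,
#'   `predicted_sum`, `r`, `class`.
#' @export
interaction_records <- function(de, universe, lo = 0.8, hi = 1.2,
                                eps = 1e-8) {
  tables <- if (inherits(de, "de_result")) de$tables else de
  ids <- tables$BPA$gene_id
  miss <- setdiff(universe, ids)
  if (length(miss))
    stop("universe transcripts absent from DE tables: ",
         paste(utils::head(miss, 5), collapse = ", "))
  i <- match(universe, ids)
  b <- tables$BPA$logFC[i]
  r_ <- tables$RAD$logFC[i]
  cmb <- tables$BPA_RAD$logFC[i]
  data.frame(gene_id = universe, lfc_bpa = b, lfc_rad = r_,
             lfc_combo = cmb, predicted_sum = b + r_,
             r = interaction_ratio(b, r_, cmb, eps = eps),
             class = classify_interaction(b, r_, cmb, lo, hi, eps),
             stringsAsFactors = FALSE)
}

#' Summarize interaction classes over a universe
#'
#' Counts and percentages per interaction class, in the shape of the
#' published interaction tables (one row block per scope). Percentages are
#' taken over the universe size.
#'
#' @param records Data frame from [interaction_records()]; must classify
#'   exactly the universe.
#' @param universe The gene-id universe the records cover.
#' @param scope Label recorded in the output (`"all"` or
#'   `"protein_coding"`).
#' @return Data frame of class `"interaction_summary"`: one row per class
#'   with `scope`, `class`, `count`, `percent`, plus attribute
#'   `universe_size`.
#' @export
summarize_interactions <- function(records, universe,
                                   scope = c("all", "protein_coding")) {
  scope <- match.arg(scope)
  extra <- setdiff(records$gene_id, universe)
  if (length(extra))
    stop("records outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (!setequal(records$gene_id, universe) ||
      nrow(records) != length(universe))
    stop("every universe transcript must be classified exactly once")
  classes <- c("potentiation", "additive", "antagonism", "unexpected")
  count <- vapply(classes, function(k) sum(records$class == k), integer(1))
  n <- length(universe)
  out <- data.frame(scope = scope, class = classes,
                    count = as.integer(count),
                    percent = if (n > 0) 100 * count / n else rep(0, 4),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "universe_size") <- n
  class(out) <- c("interaction_summary", class(out))
  out
}
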