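#' Pipeline configuration
#'
#' Paths, thresholds and resampling settings for one end-to-end run. The
#' threshold defaults are the study's printed constants: DEG cutoffs
#' |logFC| >= 0.5 and p <= 0.05, additivity window [0.8, 1.2], 1000 random
#' sets of 200 genes, alpha 0.05.
#'
#' @param matrix_path,sheet_path Expression matrix and sample-sheet TSVs.
#' @param gmt_path Optional GMT file of gene sets for the shift test.
#' @param out_dir Output directory (created if absent).
#' @param lfc_cutoff,p_cutoff DEG thresholds.
#' @param additive_lo,additive_hi Additivity window bounds.
#' @param alpha Significance level for shift-test direction calls.
#' @param set_size,n_sets Random-set size and count for the shift test.
#' @param universe_mode `"union"` or `"bpa_rad_only"` (see
#'   [build_universe()]).
#' @param seed Integer seed governing all resampling.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(matrix_path, sheet_path, gmt_path = NULL,
                            out_dir = "coexpose_out",
                            lfc_cutoff = 0.5, p_cutoff = 0.05,
                            additive_lo = 0.8, additive_hi = 1.2,
                            alpha = 0.05, set_size = 200, n_sets = 1000,
                            universe_mode = c("union", "bpa_rad_only"),
                            seed = 1L) {
  universe_mode <- match.arg(universe_mode)
  if (any(c(lfc_cutoff, p_cutoff, additive_lo, additive_hi, alpha) <= 0))
    stop("thresholds must be positive")
  if (additive_lo >= additive_hi) stop("additive_lo must be < additive_hi")
  structure(list(matrix_path = matrix_path, sheet_path = sheet_path,
                 gmt_path = gmt_path, out_dir = out_dir,
                 lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff,
                 additive_lo = additive_lo, additive_hi = additive_hi,
                 alpha = alpha, set_size = set_size, n_sets = n_sets,
                 universe_mode = universe_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Reads the expression matrix, runs moderated differential expression for
#' the three exposure contrasts, filters DEGs and writes per-contrast
#' tables, computes Venn-region overlaps, classifies combined-exposure
#' interactions for both scopes (all transcripts, protein coding), and —
#' when a GMT file is supplied — runs the random-sampling median-shift
#' test for every gene set against every contrast. All outputs are TSV
#' (plus a JSON Venn report and a JSON run manifest echoing the applied
#' configuration). Identical config + seed produces byte-identical output.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`de`, `degs`,
#'   `overlap`, `interaction`, `geneset`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[coexpose] ", ...)
  out <- config$out_dir
  ok <- FALSE
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character(0)
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(df, name) {
    path <- file.path(out, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mat <- stage("read", read_expression(config$matrix_path, config$sheet_path))
  say("read ", length(mat$gene_ids), " genes x ", ncol(mat$values),
      " samples")

  de <- stage("de", run_de(mat, config$lfc_cutoff, config$p_cutoff))
  degs <- lapply(de$tables, filter_degs, lfc_cutoff = config$lfc_cutoff,
                 p_cutoff = config$p_cutoff)
  for (ctr in names(de$tables)) {
    emit(de$tables[[ctr]], paste0("de_", ctr, ".tsv"))
    say("contrast ", ctr, ": ", nrow(degs[[ctr]]), " DEGs (|logFC| >= ",
        config$lfc_cutoff, ", p <= ", config$p_cutoff, ")")
  }

  overlap <- stage("overlap",
                   deg_overlap(lapply(degs, `[[`, "gene_id")))
  venn_path <- file.path(out, "venn_regions.json")
  jsonlite::write_json(stats::setNames(as.list(overlap$count),
                                       overlap$region),
                       venn_path, auto_unbox = TRUE)
  written <- c(written, venn_path)

  interaction <- list()
  for (scope in c("all", "protein_coding")) {
    uni <- stage("interaction",
                 withCallingHandlers(
                   build_universe(de, mode = config$universe_mode,
                                  scope = scope),
                   warning = function(w) {
                     say("universe (", scope, "): ", conditionMessage(w))
                     invokeRestart("muffleWarning")
                   }))
    rec <- stage("interaction",
                 interaction_records(de, uni, config$additive_lo,
                                     config$additive_hi))
    summ <- stage("interaction",
                  summarize_interactions(rec, uni, scope = scope))
    emit(rec, paste0("interaction_records_", scope, ".tsv"))
    emit(as.data.frame(summ), paste0("interaction_summary_", scope, ".tsv"))
    say("interaction (", scope, "): universe ", length(uni), " transcripts")
    interaction[[scope]] <- list(universe = uni, records = rec,
                                 summary = summ)
  }

  geneset <- list()
  if (!is.null(config$gmt_path)) {
    sets <- stage("geneset", read_gmt(config$gmt_path))
    rows <- list()
    nulls <- list()
    for (s in sets) {
      for (ctr in names(de$tables)) {
        lfc <- stats::setNames(de$tables[[ctr]]$logFC,
                               de$tables[[ctr]]$gene_id)
        res <- stage("geneset",
                     geneset_shift_test(lfc, s$members,
                                        set_size = config$set_size,
                                        n_sets = config$n_sets,
                                        seed = config$seed,
                                        alpha = config$alpha,
                                        set_name = s$name, contrast = ctr))
        geneset[[paste(s$name, ctr, sep = ".")]] <- res
        rows[[length(rows) + 1]] <- data.frame(
          set = s$name, contrast = ctr,
          observed_median = res$observed_median,
          null_mean = mean(res$null_medians), t = res$t_stat,
          p = res$p, p_rank = res$p_rank, direction = res$direction,
          n_sets = res$n_sets, set_size = res$set_size,
          stringsAsFactors = FALSE)
        nulls[[length(nulls) + 1]] <- data.frame(
          set = s$name, contrast = ctr, null_median = res$null_medians,
          stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, rows), "geneset_shift.tsv")
    emit(do.call(rbind, nulls), "geneset_null_medians.tsv")
    say("gene-set shift: ", length(rows), " set x contrast tests")
  }

  manifest <- list(
    config = unclass(config),
    n_genes = length(mat$gene_ids), n_samples = ncol(mat$values),
    prior = de$prior,
    deg_counts = lapply(degs, nrow),
    universe_sizes = lapply(interaction, function(x) length(x$universe)))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  written <- c(written, manifest_path)
  ok <- TRUE
  say("done; outputs in ", out)
  invisible(list(de = de, degs = degs, overlap = overlap,
                 interaction = interaction, geneset = geneset,
                 manifest = manifest))
}
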