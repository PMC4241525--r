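# Pipeline drivers: validated end-to-end runs that write their outputs and
# a reproducibility manifest into an output directory. The analysis/
# scripts are thin wrappers over these.

prepare_out_dir <- function(out_dir, overwrite, expected) {
  existing <- file.path(out_dir, expected)
  if (!overwrite && any(file.exists(existing)))
    stop("output(s) already present in ", out_dir,
         "; use overwrite = TRUE to replace them", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

write_manifest <- function(out_dir, stage, params) {
  manifest <- list(stage = stage,
                   package = "rbpregulon",
                   package_version = as.character(utils::packageVersion("rbpregulon")),
                   params = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the RBP-target co-expression pipeline
#'
#' End-to-end driver: load the expression matrix and target map,
#' log-transform, apply the target filter, summarize each regulon per
#' condition, correlate each regulator with its regulon's mean/SD/CD, and
#' classify regulators into the four regulatory relationships. Outputs
#' (`target_summaries.tsv`, `correlations.tsv`, `classifications.tsv`,
#' `summary.json`, `manifest.json`) are written to `out_dir`. Inputs are
#' validated before anything is written, so a failing run leaves no
#' partial outputs; reruns with the same inputs and parameters are
#' byte-identical.
#'
#' @param expr Path to an expression TSV (see [read_expression_matrix()])
#'   or an `expr_matrix` (raw or log scale).
#' @param targets Path to a target-map TSV or a `target_map`.
#' @param out_dir Output directory (created if needed).
#' @param log_base,pseudocount Log-transform settings (applied when the
#'   matrix is raw).
#' @param q_cutoff,min_targets Target-filter settings (defaults: q < 0.001
#'   and regulon size >= 11, i.e. "more than 10 targets").
#' @param method Correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @param overwrite Refuse to clobber existing outputs unless `TRUE`.
#' @return Invisibly, a list with `summaries`, `correlations`,
#'   `classification`, `out_dir`.
#' @export
run_coexpression_pipeline <- function(expr, targets, out_dir,
                                      log_base = 10, pseudocount = 1,
                                      q_cutoff = 0.001, min_targets = 11,
                                      method = "spearman", overwrite = FALSE) {
  m <- if (inherits(expr, "expr_matrix")) expr else read_expression_matrix(expr)
  tm <- if (inherits(targets, "target_map")) targets else read_target_map(targets)
  if (m$scale == "raw") m <- log_transform(m, base = log_base, pseudocount = pseudocount)
  tm <- filter_targets(tm, q_cutoff = q_cutoff, min_targets = min_targets,
                       universe = gene_ids(m))
  summaries <- summarize_targets(m, tm)
  correlations <- correlate_all_rbps(summaries, method = method)
  classification <- classify_rbps(correlations)

  prepare_out_dir(out_dir, overwrite,
                  c("target_summaries.tsv", "correlations.tsv",
                    "classifications.tsv", "summary.json", "manifest.json"))
  write_tsv(summaries, file.path(out_dir, "target_summaries.tsv"))
  write_tsv(correlations, file.path(out_dir, "correlations.tsv"))
  write_tsv(classification$classifications, file.path(out_dir, "classifications.tsv"))
  jsonlite::write_json(list(fraction_buffering = classification$fraction_buffering,
                            n_rbps = classification$n_rbps),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "coexpress",
                 list(log_base = log_base, pseudocount = pseudocount,
                      q_cutoff = q_cutoff, min_targets = min_targets,
                      method = method))
  invisible(list(summaries = summaries, correlations = correlations,
                 classification = classification, out_dir = out_dir))
}

#' Run the wild-type vs knockout degradation pipeline
#'
#' End-to-end driver for the deletion-strain analysis: build the
#' [knockout_pair()] from two single-condition expression profiles and a
#' target list, compute per-target degradation efficiencies, correlate
#' efficiency with deletion-strain expression level, and compare target
#' CDs between strains with the variance-ratio F-test. Writes
#' `degradation.tsv`, `knockout_summary.json` and `manifest.json`.
#'
#' @param wt,ko Paths to single-condition expression TSVs, or
#'   `expr_matrix` objects (raw scale), for the wild-type and deletion
#'   strains.
#' @param targets Path to a one-gene-id-per-line file, or a character
#'   vector of target ids.
#' @param out_dir Output directory.
#' @param rbp_id Id of the deleted RBP (annotation only).
#' @param log_base Log base for `ko_level` and the CD comparison.
#' @param eff_pseudocount Pseudocount for the efficiency ratio (default
#'   0).
#' @param cd_pseudocount Pseudocount for the CD comparison logs (default
#'   1).
#' @param method Correlation method for efficiency vs expression.
#' @param overwrite Refuse to clobber existing outputs unless `TRUE`.
#' @return Invisibly, a list with `records`, `correlation`, `cd`,
#'   `out_dir`.
#' @export
run_knockout_pipeline <- function(wt, ko, targets, out_dir, rbp_id = "RBP",
                                  log_base = 2, eff_pseudocount = 0,
                                  cd_pseudocount = 1, method = "spearman",
                                  overwrite = FALSE) {
  wt_m <- if (inherits(wt, "expr_matrix")) wt else read_expression_matrix(wt)
  ko_m <- if (inherits(ko, "expr_matrix")) ko else read_expression_matrix(ko)
  if (ncol(wt_m$values) != 1 || ncol(ko_m$values) != 1)
    stop("wt and ko must each be single-condition profiles", call. = FALSE)
  tg <- if (is.character(targets) && length(targets) == 1 && file.exists(targets))
    readLines(targets) else as.character(targets)
  tg <- tg[nzchar(trimws(tg))]
  common <- intersect(gene_ids(wt_m), gene_ids(ko_m))
  if (length(common) < 3) stop("profiles share fewer than 3 genes", call. = FALSE)
  pair <- knockout_pair(gene_ids = common,
                        wt_expr = wt_m$values[common, 1],
                        ko_expr = ko_m$values[common, 1],
                        rbp_id = rbp_id, target_ids = intersect(tg, common))
  records <- degradation_efficiency(pair, pseudocount = eff_pseudocount,
                                    log_base = log_base)
  correlation <- efficiency_vs_expression(records, method = method)
  cd <- cd_comparison(pair, log_base = log_base, pseudocount = cd_pseudocount)

  prepare_out_dir(out_dir, overwrite,
                  c("degradation.tsv", "knockout_summary.json", "manifest.json"))
  write_tsv(records, file.path(out_dir, "degradation.tsv"))
  jsonlite::write_json(list(rbp_id = rbp_id,
                            rho = correlation$rho, p = correlation$p_value,
                            method = method, n_targets = cd$n_targets,
                            n_upregulated = attr(records, "n_upregulated"),
                            cd_wt = cd$cd_wt, cd_ko = cd$cd_ko,
                            F = cd$f_statistic, p_F = cd$p_value),
                       file.path(out_dir, "knockout_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "knockout",
                 list(rbp_id = rbp_id, log_base = log_base,
                      eff_pseudocount = eff_pseudocount,
                      cd_pseudocount = cd_pseudocount, method = method))
  invisible(list(records = records, correlation = correlation, cd = cd,
                 out_dir = out_dir))
}

#' Run the regulation-model phase-diagram sweep
#'
#' End-to-end driver for the Monte-Carlo (m, j) sweep (see
#' [sweep_phase_diagram()]). Writes `phase_grid.tsv` and `manifest.json`
#' (which records the seed, so the grid reproduces bit-for-bit).
#'
#' @inheritParams sweep_phase_diagram
#' @param out_dir Output directory.
#' @param overwrite Refuse to clobber existing outputs unless `TRUE`.
#' @return Invisibly, a list with `grid` and `out_dir`.
#' @export
run_model_pipeline <- function(grid_m, grid_j, out_dir, n_genes = 100,
                               n_reps = 200, n_rbp_levels = 200, seed = 1,
                               method = "pearson", t_obs = 0.5,
                               overwrite = FALSE) {
  grid <- sweep_phase_diagram(grid_m, grid_j, n_genes = n_genes,
                              n_reps = n_reps, n_rbp_levels = n_rbp_levels,
                              seed = seed, method = method, t_obs = t_obs)
  prepare_out_dir(out_dir, overwrite, c("phase_grid.tsv", "manifest.json"))
  write_tsv(grid, file.path(out_dir, "phase_grid.tsv"))
  write_manifest(out_dir, "model",
                 list(grid_m = grid_m, grid_j = grid_j, n_genes = n_genes,
                      n_reps = n_reps, n_rbp_levels = n_rbp_levels,
                      seed = seed, method = method, t_obs = t_obs))
  invisible(list(grid = grid, out_dir = out_dir))
}
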