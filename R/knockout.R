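#' Paired wild-type / deletion-strain expression profiles
#'
#' Bundles one expression profile from the wild-type strain and one from
#' the RBP-deletion strain, aligned on gene ids, together with the set of
#' the deleted RBP's target genes. The deletion-strain expression of a
#' target approximates its level before the RBP acts; the wild-type level
#' reflects expression after RBP-mediated decay.
#'
#' @param gene_ids Character vector of gene ids.
#' @param wt_expr,ko_expr Non-negative expression (RPKM) aligned to
#'   `gene_ids`.
#' @param rbp_id Id of the deleted RBP.
#' @param target_ids Subset of `gene_ids` bound by the RBP.
#' @return A list of class `knockout_pair`.
#' @export
knockout_pair <- function(gene_ids, wt_expr, ko_expr, rbp_id, target_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(wt_expr) != length(gene_ids) || length(ko_expr) != length(gene_ids))
    stop("wt_expr and ko_expr must align with gene_ids", call. = FALSE)
  if (anyNA(wt_expr) || anyNA(ko_expr) || any(wt_expr < 0) || any(ko_expr < 0))
    stop("expression values must be non-negative and complete", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids in knockout pair", call. = FALSE)
  missing <- setdiff(target_ids, gene_ids)
  if (length(missing)) {
    warning(length(missing), " target(s) absent from the profiles dropped",
            call. = FALSE)
    target_ids <- intersect(target_ids, gene_ids)
  }
  structure(list(gene_ids = gene_ids,
                 wt_expr = stats::setNames(as.numeric(wt_expr), gene_ids),
                 ko_expr = stats::setNames(as.numeric(ko_expr), gene_ids),
                 rbp_id = as.character(rbp_id),
                 target_ids = as.character(target_ids)),
            class = "knockout_pair")
}

#' Per-target degradation efficiency
#'
#' The degradation efficiency of a target is the fraction of its
#' deletion-strain (KO) expression lost in the wild type:
#' `(ko - wt) / (ko + pseudocount)`, computed on raw RPKM. Efficiency is
#' bounded above by 1 (complete loss) and may be negative for targets
#' up-regulated in the wild type; such targets are retained and flagged,
#' and their count is reported in the `n_upregulated` attribute, because
#' discarding them would bias the efficiency-expression correlation.
#' `ko_level` is the target's log expression in the deletion strain (the
#' ordinate of the efficiency-versus-expression analysis).
#'
#' @param pair A `knockout_pair`.
#' @param pseudocount Non-negative offset guarding against zero KO
#'   expression; `ko + pseudocount` must be positive for every target.
#' @param log_base Base of the log used for `ko_level` (default 2).
#' @return Data frame with columns `gene_id`, `efficiency`, `ko_level`,
#'   `upregulated`; attribute `n_upregulated`.
#' @export
degradation_efficiency <- function(pair, pseudocount = 0, log_base = 2) {
  stopifnot(inherits(pair, "knockout_pair"))
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  ko <- pair$ko_expr[pair$target_ids]
  wt <- pair$wt_expr[pair$target_ids]
  if (any(ko + pseudocount <= 0))
    stop("ko + pseudocount must be positive for every target; ",
         "use a positive pseudocount", call. = FALSE)
  eff <- (ko - wt) / (ko + pseudocount)
  res <- data.frame(gene_id = pair$target_ids,
                    efficiency = unname(eff),
                    ko_level = unname(log(ko + pseudocount) / log(log_base)),
                    upregulated = unname(eff < 0),
                    stringsAsFactors = FALSE)
  attr(res, "n_upregulated") <- sum(res$upregulated)
  res
}

#' Correlate degradation efficiency with expression level
#'
#' Tests whether RBP-mediated decay preferentially removes highly
#' expressed targets: the correlation (two-sided p-value) between each
#' target's degradation efficiency and its log expression in the deletion
#' strain.
#'
#' @param records Output of [degradation_efficiency()]; at least 3 rows.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row data frame: `rho`, `p_value`, `method`, `n`,
#'   `degenerate`.
#' @export
efficiency_vs_expression <- function(records, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(records) < 3) stop("need at least 3 targets", call. = FALSE)
  ct <- cor_flagged(records$efficiency, records$ko_level, method)
  data.frame(rho = ct$rho, p_value = ct$p_value, method = method,
             n = ct$n, degenerate = ct$degenerate, stringsAsFactors = FALSE)
}

#' Compare target-expression dispersion between strains
#'
#' Computes the coefficient of deviation (SD / mean of log expression
#' across the RBP's targets) in the wild type and the deletion strain, and
#' tests the dispersion difference with a variance-ratio F-test on the log
#' expression values: `F = var(KO targets) / var(WT targets)` with a
#' two-sided p-value from the F distribution on (n - 1, n - 1) degrees of
#' freedom. An F above 1 with a small p indicates that deleting the RBP
#' inflates expression variation among its targets. (The F-test compares
#' variances; the two CDs are reported alongside so the dispersion is also
#' seen relative to the mean.)
#'
#' Zero wild-type variance yields a flagged infinite F with the limiting
#' p-value 0.
#'
#' @param pair A `knockout_pair` with at least 3 targets.
#' @param log_base Log base applied to expression before CD and variance
#'   (default 2).
#' @param pseudocount Offset added before the log (default 1).
#' @return A list: `cd_wt`, `cd_ko`, `f_statistic`, `p_value`, `df1`,
#'   `df2`, `n_targets`, `degenerate`.
#' @export
cd_comparison <- function(pair, log_base = 2, pseudocount = 1) {
  stopifnot(inherits(pair, "knockout_pair"))
  if (length(pair$target_ids) < 3) stop("need at least 3 targets", call. = FALSE)
  lwt <- log(pair$wt_expr[pair$target_ids] + pseudocount) / log(log_base)
  lko <- log(pair$ko_expr[pair$target_ids] + pseudocount) / log(log_base)
  n <- length(lwt)
  cd_wt <- coef_deviation(lwt)
  cd_ko <- coef_deviation(lko)
  if (stats::var(lwt) == 0) {
    return(list(cd_wt = cd_wt, cd_ko = cd_ko, f_statistic = Inf, p_value = 0,
                df1 = n - 1L, df2 = n - 1L, n_targets = n, degenerate = TRUE))
  }
  vt <- stats::var.test(lko, lwt, alternative = "two.sided")
  list(cd_wt = cd_wt, cd_ko = cd_ko,
       f_statistic = unname(vt$statistic), p_value = vt$p.value,
       df1 = unname(vt$parameter[1]), df2 = unname(vt$parameter[2]),
       n_targets = n, degenerate = FALSE)
}
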