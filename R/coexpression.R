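#' Per-condition summary statistics of each RBP's target regulon
#'
#' For every regulator in the target map and every condition of the log
#' expression matrix, computes the mean, the sample standard deviation
#' (n - 1 denominator) and the coefficient of deviation (CD = SD / mean) of
#' the regulator's targets' log expression, alongside the regulator's own
#' log expression in that condition.
#'
#' Targets absent from the expression matrix are dropped with a warning;
#' regulators left with fewer than two targets are excluded with a warning
#' (SD is undefined below n = 2). A regulator itself must have an
#' expression row. Conditions where |mean| falls below `cd_guard` get an
#' undefined CD (`cd_defined = FALSE`) rather than an exploding ratio, and
#' are excluded from downstream CD correlations.
#'
#' @param m An `expr_matrix` on the log scale (see [log_transform()]).
#' @param tm A `target_map`, typically after [filter_targets()].
#' @param cd_guard Threshold on |mean| below which CD is flagged undefined.
#' @return A data frame with one row per (regulator, condition):
#'   `rbp_id`, `condition_id`, `rbp_expr`, `n_targets`, `target_mean`,
#'   `target_sd`, `target_cd`, `cd_defined`.
#' @export
summarize_targets <- function(m, tm, cd_guard = 1e-8) {
  stopifnot(inherits(m, "expr_matrix"), inherits(tm, "target_map"))
  if (m$scale != "log")
    stop("expression matrix must be log-transformed first", call. = FALSE)
  rbps <- unique(tm$rbp_id)
  missing_rbp <- setdiff(rbps, gene_ids(m))
  if (length(missing_rbp))
    stop("regulator(s) without an expression row: ",
         paste(missing_rbp, collapse = ", "), call. = FALSE)
  missing_tg <- setdiff(unique(tm$target_id), gene_ids(m))
  if (length(missing_tg))
    warning(length(missing_tg), " target(s) absent from the expression matrix dropped",
            call. = FALSE)
  conds <- condition_ids(m)
  out <- vector("list", length(rbps))
  skipped <- character(0)
  for (i in seq_along(rbps)) {
    r <- rbps[i]
    tgs <- setdiff(intersect(tm$target_id[tm$rbp_id == r], gene_ids(m)), r)
    if (length(tgs) < 2) {
      skipped <- c(skipped, r)
      next
    }
    sub <- m$values[tgs, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    defined <- abs(mu) >= cd_guard
    cd <- ifelse(defined, sdv / mu, NA_real_)
    out[[i]] <- data.frame(
      rbp_id = r, condition_id = conds,
      rbp_expr = unname(m$values[r, ]),
      n_targets = length(tgs),
      target_mean = unname(mu), target_sd = unname(sdv),
      target_cd = unname(cd), cd_defined = unname(defined),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(skipped))
    warning("regulator(s) with < 2 usable targets excluded: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(rbp_id = character(0), condition_id = character(0),
                      rbp_expr = numeric(0), n_targets = integer(0),
                      target_mean = numeric(0), target_sd = numeric(0),
                      target_cd = numeric(0), cd_defined = logical(0))
  res
}

#' Correlate one RBP's expression with a regulon summary statistic
#'
#' Across conditions, correlates the regulator's log expression with the
#' chosen summary of its targets (mean, SD or CD) and reports the
#' correlation coefficient with a two-sided p-value. Spearman (the
#' default) uses average ranks for ties. A constant vector on either side
#' yields a flagged (`degenerate = TRUE`) result with `NA` rho rather than
#' propagating NaN.
#'
#' @param summaries Rows of [summarize_targets()] for a single regulator.
#' @param statistic One of `"mean"`, `"sd"`, `"cd"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row data frame: `rbp_id`, `statistic`, `method`, `rho`,
#'   `p_value`, `n_conditions`, `degenerate`.
#' @export
correlate_rbp <- function(summaries, statistic = c("mean", "sd", "cd"),
                          method = c("spearman", "pearson")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  r <- unique(summaries$rbp_id)
  if (length(r) != 1)
    stop("`summaries` must contain exactly one regulator", call. = FALSE)
  col <- switch(statistic, mean = "target_mean", sd = "target_sd", cd = "target_cd")
  rows <- if (statistic == "cd") summaries[summaries$cd_defined, , drop = FALSE]
          else summaries
  if (nrow(rows) < 3)
    stop("need at least 3 conditions to correlate (regulator ", r, ")", call. = FALSE)
  ct <- cor_flagged(rows$rbp_expr, rows[[col]], method)
  data.frame(rbp_id = r, statistic = statistic, method = method,
             rho = ct$rho, p_value = ct$p_value,
             n_conditions = ct$n, degenerate = ct$degenerate,
             stringsAsFactors = FALSE)
}

#' Correlate every RBP with its regulon summaries
#'
#' Convenience wrapper applying [correlate_rbp()] to each regulator and
#' each requested statistic, with optional Benjamini-Hochberg adjusted
#' p-values (off by default; raw per-regulator p-values are reported
#' either way).
#'
#' @param summaries Output of [summarize_targets()].
#' @param statistics Subset of `c("mean", "sd", "cd")`.
#' @param method `"spearman"` or `"pearson"`.
#' @param adjust If `TRUE`, add a `p_adjusted` column (BH within each
#'   statistic).
#' @return Data frame of correlation rows.
#' @export
correlate_all_rbps <- function(summaries, statistics = c("mean", "sd", "cd"),
                               method = "spearman", adjust = FALSE) {
  statistics <- match.arg(statistics, c("mean", "sd", "cd"), several.ok = TRUE)
  rbps <- unique(summaries$rbp_id)
  res <- do.call(rbind, lapply(rbps, function(r) {
    sub <- summaries[summaries$rbp_id == r, , drop = FALSE]
    do.call(rbind, lapply(statistics, function(s) correlate_rbp(sub, s, method)))
  }))
  if (isTRUE(adjust)) {
    res$p_adjusted <- NA_real_
    for (s in statistics) {
      sel <- res$statistic == s & !res$degenerate
      res$p_adjusted[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
    }
  }
  rownames(res) <- NULL
  res
}

#' Classify each RBP into one of four regulator-target relationships
#'
#' The sign pair (rho with the regulon mean, rho with the regulon CD)
#' places each regulator into one of four classes:
#' `pos_mean_pos_cd` (co-expressed, amplifies variation),
#' `pos_mean_neg_cd` (co-expressed, buffers variation - the regime most
#' RBPs occupy), `neg_mean_pos_cd`, and `neg_mean_neg_cd`. The fraction of
#' regulators in `pos_mean_neg_cd` is reported as `fraction_buffering`.
#'
#' A rho of exactly zero on either axis falls on the negative side of that
#' axis and flags the regulator as degenerate.
#'
#' @param correlations Output of [correlate_all_rbps()] containing both a
#'   `mean` and a `cd` row per regulator.
#' @return A list with `classifications` (data frame: `rbp_id`,
#'   `rho_mean`, `rho_cd`, `region`, `degenerate`), `fraction_buffering`
#'   and `n_rbps`.
#' @export
classify_rbps <- function(correlations) {
  cm <- correlations[correlations$statistic == "mean", , drop = FALSE]
  cc <- correlations[correlations$statistic == "cd", , drop = FALSE]
  rbps <- sort(unique(correlations$rbp_id))
  if (!all(rbps %in% cm$rbp_id) || !all(rbps %in% cc$rbp_id))
    stop("every regulator needs both a mean- and a cd-correlation", call. = FALSE)
  rho_mean <- cm$rho[match(rbps, cm$rbp_id)]
  rho_cd <- cc$rho[match(rbps, cc$rbp_id)]
  deg <- cm$degenerate[match(rbps, cm$rbp_id)] |
         cc$degenerate[match(rbps, cc$rbp_id)] |
         (!is.na(rho_mean) & rho_mean == 0) | (!is.na(rho_cd) & rho_cd == 0)
  usable <- !is.na(rho_mean) & !is.na(rho_cd)
  cls <- data.frame(rbp_id = rbps[usable],
                    rho_mean = rho_mean[usable], rho_cd = rho_cd[usable],
                    region = classify_region(rho_mean[usable], rho_cd[usable]),
                    degenerate = deg[usable],
                    stringsAsFactors = FALSE)
  list(classifications = cls,
       fraction_buffering = mean(cls$region == "pos_mean_neg_cd"),
       n_rbps = nrow(cls))
}
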