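#' Construct a regulator-target map
#'
#' A `target_map` records which mRNAs each RNA-binding protein binds,
#' together with the q-value of the association (as in genome-wide RBP
#' target compendia).
#'
#' @param rbp_id,target_id Character vectors (recycled to common length).
#' @param q_value Numeric q-values in \[0, 1\].
#' @return A data frame of class `target_map` with columns `rbp_id`,
#'   `target_id`, `q_value`.
#' @export
target_map <- function(rbp_id, target_id, q_value) {
  df <- data.frame(rbp_id = as.character(rbp_id),
                   target_id = as.character(target_id),
                   q_value = as.numeric(q_value),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("target map contains missing values", call. = FALSE)
  if (any(df$q_value < 0 | df$q_value > 1))
    stop("q-values must lie in [0, 1]", call. = FALSE)
  class(df) <- c("target_map", "data.frame")
  df
}

#' Read / write a target map (TSV)
#'
#' Three tab-separated columns `rbp_id  target_id  q_value` with a header
#' row.
#'
#' @param path File path.
#' @return `read_target_map()` returns a `target_map`;
#'   `write_target_map()` returns `path` invisibly.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"),
                          quote = "", comment.char = "")
  if (!identical(colnames(df), c("rbp_id", "target_id", "q_value")))
    stop("target map must have columns rbp_id, target_id, q_value", call. = FALSE)
  target_map(df$rbp_id, df$target_id, df$q_value)
}

#' @rdname read_target_map
#' @param tm A `target_map`.
#' @export
write_target_map <- function(tm, path) {
  stopifnot(inherits(tm, "target_map"))
  utils::write.table(tm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a target map to confidently bound, well-populated regulons
#'
#' Applies the target-selection rule used throughout the analysis: keep
#' (target, q) pairs with `q < q_cutoff` whose target lies in `universe`
#' (when given), drop self-targeting entries, and then keep only regulators
#' whose surviving regulon has at least `min_targets` members. The
#' compendium rule "more than 10 target genes" corresponds to the default
#' `min_targets = 11`.
#'
#' Self-targets (an RBP listed as its own target) are removed before
#' counting, with a message, so that a regulator's co-expression with its
#' regulon is never trivially self-induced. The operation is idempotent.
#'
#' @param tm A `target_map`.
#' @param q_cutoff Keep associations with q-value strictly below this.
#' @param min_targets Minimum surviving regulon size to retain a regulator.
#' @param universe Optional character vector of admissible target ids
#'   (e.g. the genes present in an expression matrix).
#' @return A filtered `target_map`. An empty result raises a warning, not
#'   an error.
#' @export
filter_targets <- function(tm, q_cutoff = 0.001, min_targets = 11, universe = NULL) {
  stopifnot(inherits(tm, "target_map"))
  if (q_cutoff <= 0 || q_cutoff > 1) stop("`q_cutoff` must be in (0, 1]", call. = FALSE)
  if (min_targets < 1) stop("`min_targets` must be >= 1", call. = FALSE)
  self <- tm$rbp_id == tm$target_id
  if (any(self))
    message(sum(self), " self-targeting entr",
            if (sum(self) == 1) "y" else "ies", " removed")
  keep <- !self & tm$q_value < q_cutoff
  if (!is.null(universe)) keep <- keep & tm$target_id %in% universe
  out <- tm[keep, , drop = FALSE]
  counts <- table(out$rbp_id)
  survivors <- names(counts)[counts >= min_targets]
  out <- out[out$rbp_id %in% survivors, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no regulators survive the target filter", call. = FALSE)
  class(out) <- c("target_map", "data.frame")
  out
}
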