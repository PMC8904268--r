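#' Gene-inclusion and differential-expression filter settings
#'
#' Two read-count dialects are supported and must be chosen explicitly:
#' `"all"` keeps a gene only when every sample has at least `min_reads`
#' reads, `"kofn"` keeps a gene when at least `k` samples do. Fold-change
#' gates are inclusive (FC >= threshold, or <= 1/threshold for
#' down-regulation); the adjusted-p gate is strict (p < alpha).
#'
#' @param min_reads Integer read-count threshold (>= 0), default 5.
#' @param min_samples_mode "kofn" or "all".
#' @param k Number of samples required at `min_reads` in "kofn" mode,
#'   default 3.
#' @param fc_threshold Linear fold-change threshold (>= 1), applied
#'   symmetrically; default 2.
#' @param alpha Adjusted-p bound in (0, 1]; default 0.1.
#' @export
filter_spec <- function(min_reads = 5, min_samples_mode = c("kofn", "all"),
                        k = 3, fc_threshold = 2, alpha = 0.1) {
  min_samples_mode <- match.arg(min_samples_mode)
  if (min_reads < 0) stop("min_reads must be >= 0")
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (min_samples_mode == "kofn" && (!is.numeric(k) || k < 1)) {
    stop("k must be a positive integer in kofn mode")
  }
  structure(list(min_reads = min_reads, min_samples_mode = min_samples_mode,
                 k = k, fc_threshold = fc_threshold, alpha = alpha),
            class = "filter_spec")
}

#' Read-count gene-inclusion filter
#'
#' @param counts Non-negative integer matrix, genes x samples, with gene
#'   rownames.
#' @param spec A `filter_spec`.
#' @return List with `genes` (retained, in input order) and `n`.
#' @export
apply_read_count_filter <- function(counts, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("`counts` must have gene rownames")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  n_ok <- rowSums(counts >= spec$min_reads)
  keep <- if (spec$min_samples_mode == "all") {
    n_ok == ncol(counts)
  } else {
    if (spec$k > ncol(counts)) {
      stop(sprintf("k = %d exceeds the number of samples (%d)",
                   spec$k, ncol(counts)))
    }
    n_ok >= spec$k
  }
  list(genes = rownames(counts)[keep], n = sum(keep))
}

#' Construct a differential-expression results table
#'
#' @param gene Gene identifiers.
#' @param fold_change Linear fold change test/control (> 0), or log2
#'   fold change when `fc_scale = "log2"` (converted internally to the
#'   linear canonical form).
#' @param adjusted_p Adjusted p-values in [0, 1].
#' @param p Optional raw p-values.
#' @param fc_scale "linear" (default) or "log2".
#' @export
deg_table <- function(gene, fold_change, adjusted_p, p = NULL,
                      fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (fc_scale == "log2") fold_change <- 2^fold_change
  if (length(gene) != length(fold_change) ||
      length(gene) != length(adjusted_p)) {
    stop("gene, fold_change and adjusted_p must have equal length")
  }
  bad <- which(!is.finite(fold_change) | fold_change <= 0)
  if (length(bad) > 0) {
    stop("non-positive fold change for gene(s): ",
         paste(gene[bad], collapse = ", "))
  }
  if (anyNA(adjusted_p) || any(adjusted_p < 0 | adjusted_p > 1)) {
    stop("adjusted_p must lie in [0, 1]")
  }
  df <- data.frame(gene = as.character(gene), fold_change = fold_change,
                   adjusted_p = adjusted_p, stringsAsFactors = FALSE)
  if (!is.null(p)) df$p <- p
  structure(df, class = c("deg_table", "data.frame"))
}

#' Differential-expression gate
#'
#' A gene passes when adjusted_p < alpha (strict) and its fold change
#' clears the symmetric threshold in the requested direction;
#' `direction = "both"` is the union of up and down. `alpha = 1`
#' disables the p gate entirely so that a vacuous filter passes every
#' gene.
#'
#' @param table A `deg_table`.
#' @param spec A `filter_spec` (uses `fc_threshold` and `alpha`).
#' @param direction "up", "down" or "both".
#' @return List with `table` (the passing subset), `n`, `n_up`, `n_down`.
#' @export
apply_deg_filter <- function(table, spec = filter_spec(),
                             direction = c("both", "up", "down")) {
  stopifnot(inherits(table, "deg_table"), inherits(spec, "filter_spec"))
  direction <- match.arg(direction)
  # strict p gate; alpha = 1 disables it (otherwise padj = 1 rows could
  # never pass a nominally vacuous filter)
  sig <- table$adjusted_p < spec$alpha | spec$alpha >= 1
  up <- sig & table$fold_change >= spec$fc_threshold
  down <- sig & table$fold_change <= 1 / spec$fc_threshold
  keep <- switch(direction, up = up, down = down, both = up | down)
  list(table = table[keep, , drop = FALSE],
       n = sum(keep), n_up = sum(up & keep), n_down = sum(down & keep))
}
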