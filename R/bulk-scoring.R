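#' Construct an expression matrix
#'
#' FPKM-like non-negative values, genes in rows, samples in columns.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (anyNA(values) || any(values < 0)) {
    stop("expression values must be non-negative and non-missing")
  }
  structure(list(values = values, genes = rownames(values),
                 samples = colnames(values)),
            class = "expression_matrix")
}

#' Construct a group design
#'
#' @param assignment Named character vector mapping sample -> group.
#' @param control_group The reference group label.
#' @export
group_design <- function(assignment, control_group) {
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("`assignment` must be a named vector (names = samples)")
  }
  assignment <- vapply(assignment, as.character, character(1))
  if (anyDuplicated(names(assignment))) stop("duplicate sample in design")
  groups <- unique(unname(assignment))
  if (length(groups) < 2) stop("design must contain at least 2 groups")
  if (!control_group %in% groups) {
    stop("control group '", control_group, "' has no samples in the design")
  }
  structure(list(assignment = assignment, control_group = control_group,
                 groups = groups),
            class = "group_design")
}

#' Per-group gene medians
#'
#' Entry (g, k) is the sample median of gene g over group k's samples;
#' for even group sizes this is the midpoint of the two central order
#' statistics.
#'
#' @param expr An `expression_matrix`.
#' @param design A `group_design`; all of its samples must exist in `expr`.
#' @return Numeric matrix, genes x groups.
#' @export
group_medians <- function(expr, design) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(design, "group_design"))
  missing <- setdiff(names(design$assignment), expr$samples)
  if (length(missing) > 0) {
    stop("design sample(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  out <- vapply(design$groups, function(g) {
    s <- names(design$assignment)[design$assignment == g]
    apply(expr$values[, s, drop = FALSE], 1, median)
  }, numeric(length(expr$genes)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = 1, dimnames = list(expr$genes, design$groups))
  }
  out
}

#' Relative expression versus the control group
#'
#' ratio(g, k) = median(g, k) / median(g, control). Genes whose control
#' median falls below `epsilon` have an undefined ratio and are moved to
#' `dropped_genes` rather than imputed. For every retained gene the
#' control column is exactly 1.
#'
#' @param medians Gene x group median matrix from [group_medians()].
#' @param control_group Column of `medians` to normalize against.
#' @param epsilon Control-median guard (default 1e-6, FPKM-like units).
#' @return A `relative_expression_table` with fields `ratio` (matrix),
#'   `genes`, `groups`, `control_group`, `dropped_genes`.
#' @export
relative_expression <- function(medians, control_group, epsilon = 1e-6) {
  if (!control_group %in% colnames(medians)) {
    stop("control group '", control_group, "' is not a column of `medians`")
  }
  ctrl <- medians[, control_group]
  drop <- ctrl < epsilon
  if (all(drop)) stop("all genes dropped: control medians all below epsilon")
  kept <- medians[!drop, , drop = FALSE]
  ratio <- sweep(kept, 1, kept[, control_group], "/")
  ratio[, control_group] <- 1  # exact, not up to floating-point division
  structure(
    list(ratio = ratio, genes = rownames(ratio), groups = colnames(ratio),
         control_group = control_group,
         dropped_genes = rownames(medians)[drop]),
    class = "relative_expression_table"
  )
}

#' Score cell types from marker-gene relative expression
#'
#' For each cell type, collects the relative-expression values of its
#' marker genes (those present among retained genes) in every group and
#' summarizes each group by the median ratio. This reproduces the
#' one-point-per-gene-per-group panel construction used for figure-style
#' group comparisons. Cell types with no marker present are reported as
#' absent with a warning.
#'
#' @param rel A `relative_expression_table`.
#' @param sigs A `signature_set`.
#' @return A `cell_type_score_panel`: per cell type a list with
#'   `genes`, `ratios` (gene x group matrix), `summary` (per-group
#'   median), `n_genes`; plus `absent_cell_types`.
#' @export
score_cell_types <- function(rel, sigs) {
  stopifnot(inherits(rel, "relative_expression_table"),
            inherits(sigs, "signature_set"))
  panels <- list()
  absent <- character(0)
  for (ct in names(sigs$sets)) {
    genes <- intersect(sigs$sets[[ct]], rel$genes)
    if (length(genes) == 0) {
      absent <- c(absent, ct)
      next
    }
    ratios <- rel$ratio[genes, , drop = FALSE]
    panels[[ct]] <- list(
      genes = genes,
      ratios = ratios,
      summary = apply(ratios, 2, median),
      n_genes = length(genes)
    )
  }
  if (length(panels) == 0) {
    stop("no signature gene of any cell type is present in the matrix")
  }
  if (length(absent) > 0) {
    warning("cell type(s) with no marker present: ",
            paste(absent, collapse = ", "))
  }
  structure(
    list(cell_types = panels, groups = rel$groups,
         control_group = rel$control_group, absent_cell_types = absent),
    class = "cell_type_score_panel"
  )
}

#' Attach group-comparison tests to a score panel
#'
#' Per cell type: a Kruskal-Wallis omnibus test over the groups'
#' marker-ratio vectors, then pairwise tests of each group against the
#' control. With three or more groups the pairwise tests are Dunn's
#' post-hoc; with exactly two groups the Wilcoxon rank-sum test is used
#' instead (exact at small n without ties), matching the source
#' experiments' two-group convention and avoiding the poor normal
#' approximation of a two-group Dunn test at n of 3-6. Set
#' `two_group_test = "dunn"` to force Dunn throughout. Following the
#' source experiments' convention, the Bonferroni adjustment is applied
#' across the pairwise contrasts only when the number of groups exceeds
#' `bonferroni_threshold`; pass `bonferroni_threshold = 0` to always
#' adjust. Cell types whose ratio vectors are shorter than 2 are
#' flagged untestable.
#'
#' @param panel A `cell_type_score_panel`.
#' @param alpha Significance level for the flags (default 0.05).
#' @param adjust Multiplicity scheme for the pairwise contrasts:
#'   "bonferroni", "holm_sidak" or "none".
#' @param bonferroni_threshold Apply the adjustment only when the number
#'   of groups exceeds this (default 4).
#' @param two_group_test Pairwise test used when there are exactly two
#'   groups: "wilcoxon" (default) or "dunn".
#' @return The panel with, per cell type, `omnibus` (an
#'   `occ_test_result`) and `pairwise` (a data.frame with columns group,
#'   statistic, p, p_adj, significant), plus `untestable` flags.
#' @export
compare_panel <- function(panel, alpha = 0.05, adjust = "bonferroni",
                          bonferroni_threshold = 4,
                          two_group_test = c("wilcoxon", "dunn")) {
  stopifnot(inherits(panel, "cell_type_score_panel"))
  adjust <- match.arg(adjust, c("bonferroni", "holm_sidak", "none"))
  two_group_test <- match.arg(two_group_test)
  groups <- panel$groups
  ctrl_idx <- match(panel$control_group, groups)
  do_adjust <- length(groups) > bonferroni_threshold
  eff_adjust <- if (do_adjust) adjust else "none"
  use_ranksum <- length(groups) == 2 && two_group_test == "wilcoxon"
  for (ct in names(panel$cell_types)) {
    p <- panel$cell_types[[ct]]
    vecs <- lapply(groups, function(g) p$ratios[, g])
    if (any(lengths(vecs) < 2)) {
      panel$cell_types[[ct]]$untestable <- TRUE
      next
    }
    omni <- suppressWarnings(kruskal_wallis(vecs))
    if (use_ranksum) {
      other <- setdiff(seq_along(groups), ctrl_idx)
      rs <- wilcoxon_rank_sum(vecs[[other]], vecs[[ctrl_idx]])
      pw <- data.frame(
        group = groups[other],
        statistic = rs$statistic,
        p = rs$p_value,
        p_adj = rs$p_value,  # single contrast: m = 1
        stringsAsFactors = FALSE
      )
    } else {
      dunn <- dunn_posthoc(vecs, control_index = ctrl_idx,
                           adjust = eff_adjust)
      pw <- data.frame(
        group = groups[vapply(dunn, function(d) d$comparison[["group"]],
                              numeric(1))],
        statistic = vapply(dunn, `[[`, numeric(1), "statistic"),
        p = vapply(dunn, `[[`, numeric(1), "p_value"),
        p_adj = vapply(dunn, `[[`, numeric(1), "p_adjusted"),
        stringsAsFactors = FALSE
      )
    }
    pw$significant <- pw$p_adj < alpha
    panel$cell_types[[ct]]$untestable <- FALSE
    panel$cell_types[[ct]]$omnibus <- omni
    panel$cell_types[[ct]]$pairwise <- pw
  }
  panel$alpha <- alpha
  panel$adjust <- adjust
  panel$adjust_applied <- do_adjust
  panel
}

#' Flatten a score panel to tidy data frames
#'
#' @param panel A `cell_type_score_panel`, optionally after
#'   [compare_panel()].
#' @return List of two data.frames: `ratios` (cell_type, group, gene,
#'   ratio) and `summary` (cell_type, group, summary, n_genes and test
#'   columns when present).
#' @export
panel_as_data_frames <- function(panel) {
  stopifnot(inherits(panel, "cell_type_score_panel"))
  rat <- do.call(rbind, lapply(names(panel$cell_types), function(ct) {
    p <- panel$cell_types[[ct]]
    expand <- expand.grid(gene = p$genes, group = panel$groups,
                          stringsAsFactors = FALSE)
    expand$cell_type <- ct
    expand$ratio <- p$ratios[cbind(expand$gene, expand$group)]
    expand[, c("cell_type", "group", "gene", "ratio")]
  }))
  summ <- do.call(rbind, lapply(names(panel$cell_types), function(ct) {
    p <- panel$cell_types[[ct]]
    df <- data.frame(cell_type = ct, group = panel$groups,
                     summary = unname(p$summary[panel$groups]),
                     n_genes = p$n_genes, stringsAsFactors = FALSE)
    if (!is.null(p$pairwise)) {
      df$p_omnibus <- p$omnibus$p_value
      m <- match(df$group, p$pairwise$group)
      df$p_pairwise_adj <- p$pairwise$p_adj[m]
      df$significant <- p$pairwise$significant[m]
    }
    df
  }))
  list(ratios = rat, summary = summ)
}

#' @export
print.cell_type_score_panel <- function(x, ...) {
  cat(sprintf("cell_type_score_panel: %d cell types x %d groups (control = %s)\n",
              length(x$cell_types), length(x$groups), x$control_group))
  for (ct in names(x$cell_types)) {
    p <- x$cell_types[[ct]]
    s <- paste(sprintf("%s=%.3g", x$groups, p$summary[x$groups]),
               collapse = ", ")
    extra <- if (!is.null(p$pairwise)) {
      sig <- p$pairwise$group[p$pairwise$significant]
      sprintf("  [KW p=%.3g%s]", p$omnibus$p_value,
              if (length(sig)) paste0("; sig vs control: ",
                                      paste(sig, collapse = ",")) else "")
    } else ""
    cat(sprintf("  %-18s (%d genes) %s%s\n", ct, p$n_genes, s, extra))
  }
  invisible(x)
}
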