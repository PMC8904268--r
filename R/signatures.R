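#' Default lung cell-type vocabulary
#'
#' Cell populations tracked by the bulk scoring workflow: airway
#' epithelial types (basal, club, ciliated, goblet), alveolar types
#' (AT1, AT2), fibroblast lineages, a generic epithelial set, and
#' myeloid cells.
#'
#' @export
lung_cell_types <- function() {
  c("basal", "club", "ciliated", "goblet", "AT1", "AT2",
    "lipofibroblast", "matrix_fibroblast", "myofibroblast",
    "epithelial", "myeloid")
}

#' Construct a reference expression-profile table
#'
#' A gene x (cell type, timepoint) table of non-negative mean
#' expression values, the raw material marker sets are derived from.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids).
#' @param cell_types Character vector, one entry per column of `expr`.
#' @param timepoints Character vector, one entry per column of `expr`.
#' @return A `ref_profile_table` object.
#' @export
ref_profile_table <- function(expr, cell_types, timepoints) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("`expr` must have gene rownames")
  if (length(cell_types) != ncol(expr) || length(timepoints) != ncol(expr)) {
    stop("cell_types and timepoints must each have one entry per column")
  }
  if (anyNA(expr) || any(expr < 0)) {
    stop("reference profile contains negative or missing expression values")
  }
  if (anyDuplicated(rownames(expr))) {
    dup <- unique(rownames(expr)[duplicated(rownames(expr))])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(paste(cell_types, timepoints))) {
    stop("duplicate (cell type, timepoint) columns")
  }
  structure(
    list(expr = expr,
         genes = rownames(expr),
         cell_types = as.character(cell_types),
         timepoints = as.character(timepoints)),
    class = "ref_profile_table"
  )
}

#' Read/write a reference profile table
#'
#' TSV with gene rows; column names are `<celltype>|<timepoint>`.
#'
#' @param path File path.
#' @return `load_reference_profiles()` returns a `ref_profile_table`.
#' @export
load_reference_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed reference table: need gene column plus data")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- genes
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    bad <- colnames(m)[lengths(parts) != 2]
    stop("malformed header; expected <celltype>|<timepoint>, got: ",
         paste(bad, collapse = ", "))
  }
  ref_profile_table(m,
                    cell_types = vapply(parts, `[`, character(1), 1),
                    timepoints = vapply(parts, `[`, character(1), 2))
}

#' @rdname load_reference_profiles
#' @param ref A `ref_profile_table`.
#' @export
write_reference_profiles <- function(ref, path) {
  stopifnot(inherits(ref, "ref_profile_table"))
  m <- ref$expr
  colnames(m) <- paste(ref$cell_types, ref$timepoints, sep = "|")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker-specificity parameters
#'
#' A gene is assigned to a cell type when its aggregated expression
#' there is at least `min_expr` and at least `fold_margin` times its
#' aggregated expression in every other cell type. The margin-over-
#' second-best rule guarantees disjoint marker sets by construction.
#'
#' @param fold_margin Required ratio over the runner-up cell type (> 1).
#' @param min_expr Minimum aggregated expression in the top cell type.
#' @param aggregation How timepoints are collapsed: "mean" or "max".
#' @export
specificity_params <- function(fold_margin = 5, min_expr = 1,
                               aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  if (!is.numeric(fold_margin) || fold_margin <= 1) {
    stop("fold_margin must be > 1")
  }
  if (!is.numeric(min_expr) || min_expr < 0) stop("min_expr must be >= 0")
  structure(list(fold_margin = fold_margin, min_expr = min_expr,
                 aggregation = aggregation),
            class = "specificity_params")
}

#' Construct a signature (marker gene) set
#'
#' @param sets Named list mapping cell-type name to a non-empty
#'   character vector of gene identifiers; sets must be disjoint.
#' @param provenance Free-text description of how the sets were derived.
#' @export
signature_set <- function(sets, provenance = "user-supplied") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list")
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(lengths(sets) == 0)) {
    stop("empty marker set: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    stop("gene(s) assigned to more than one cell type: ",
         paste(dup, collapse = ", "))
  }
  structure(list(sets = sets, provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d cell types, %d genes (%s)\n",
              length(x$sets), length(unlist(x$sets)), x$provenance))
  for (nm in names(x$sets)) {
    cat(sprintf("  %-18s %d genes\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}

# collapse timepoints into a gene x cell-type matrix
aggregate_profiles <- function(ref, aggregation) {
  fun <- switch(aggregation, mean = rowMeans,
                max = function(m) apply(m, 1, max))
  types <- unique(ref$cell_types)
  out <- vapply(types, function(ct) {
    fun(ref$expr[, ref$cell_types == ct, drop = FALSE])
  }, numeric(nrow(ref$expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(ref$genes, types))
  out
}

#' Derive disjoint cell-type marker sets from reference profiles
#'
#' Timepoints are collapsed per `params$aggregation`, then each gene is
#' tested against the specificity rule (see [specificity_params()]).
#' Genes specific to no cell type are dropped. A gene whose aggregated
#' expression ties across several top cell types cannot exceed the
#' margin against them and is therefore unassigned.
#'
#' @param ref A `ref_profile_table`.
#' @param params A `specificity_params`.
#' @return A `signature_set`.
#' @export
derive_signatures <- function(ref, params = specificity_params()) {
  stopifnot(inherits(ref, "ref_profile_table"),
            inherits(params, "specificity_params"))
  agg <- aggregate_profiles(ref, params$aggregation)
  types <- colnames(agg)
  sets <- stats::setNames(vector("list", length(types)), types)
  for (g in seq_len(nrow(agg))) {
    v <- agg[g, ]
    top <- which.max(v)
    if (v[top] <= 0) next  # all-zero genes are informationless
    others <- v[-top]
    if (v[top] >= params$min_expr &&
        all(v[top] >= params$fold_margin * others)) {
      sets[[top]] <- c(sets[[top]], rownames(agg)[g])
    }
  }
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) {
    stop(sprintf(paste0("no gene qualifies as a marker for any cell type ",
                        "(fold_margin = %g, min_expr = %g, aggregation = %s)"),
                 params$fold_margin, params$min_expr, params$aggregation))
  }
  signature_set(sets, provenance = sprintf(
    "derived: fold_margin=%g, min_expr=%g, aggregation=%s",
    params$fold_margin, params$min_expr, params$aggregation))
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name TAB description TAB gene TAB gene ...
#'
#' @param sigs A `signature_set`.
#' @param path File path.
#' @export
write_gmt <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  lines <- vapply(names(sigs$sets), function(nm) {
    paste(c(nm, sigs$provenance, sigs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop("malformed GMT line (need name, description, >= 1 gene)")
  }
  nms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nms)) stop("duplicate set names in ", path)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nms)
  signature_set(sets, provenance = fields[[1]][2])
}
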