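#' Read and write expression matrices as TSV
#'
#' Gene rows, sample columns, header row, first column `gene`; UTF-8,
#' decimal point.
#'
#' @param path File path.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m)
}

#' @rdname read_expression_tsv
#' @param expr An `expression_matrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a group design from CSV
#'
#' Expects columns `sample` and `group`.
#'
#' @param path File path.
#' @param control_group Control group label.
#' @export
read_design_csv <- function(path, control_group) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("design CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  group_design(stats::setNames(df$group, df$sample), control_group)
}

#' @rdname read_design_csv
#' @param design A `group_design`.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  write.csv(data.frame(sample = names(design$assignment),
                       group = unname(design$assignment)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count matrix (TSV) for the read-count filter
#'
#' @param path File path; gene rows, integer sample columns.
#' @export
read_counts_tsv <- function(path) {
  e <- read_expression_tsv(path)
  m <- e$values
  if (any(m != floor(m))) stop("counts TSV contains non-integer values")
  storage.mode(m) <- "integer"
  m
}

#' Read a differential-expression table from CSV
#'
#' Requires columns `gene`, `padj`, and one of `fold_change` (linear) or
#' `log2fc`; the scale flag must match the column supplied.
#'
#' @param path File path.
#' @param fc_scale "linear" or "log2".
#' @export
read_deg_csv <- function(path, fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  fc_col <- if (fc_scale == "linear") "fold_change" else "log2fc"
  missing <- setdiff(c("gene", fc_col, "padj"), names(df))
  if (length(missing) > 0) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "))
  }
  deg_table(df$gene, df[[fc_col]], df$padj,
            p = if ("p" %in% names(df)) df$p else NULL,
            fc_scale = fc_scale)
}

#' Write a tidy results data frame as CSV
#'
#' @param obj A data.frame.
#' @param path File path.
#' @export
write_results_csv <- function(obj, path) {
  write.csv(obj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write grayscale rasters as plain (ASCII) PGM
#'
#' Portable graymap P2: text header `P2`, width height, maxval, then
#' row-major pixel values. Comments (`#`) are skipped. This text format
#' stands in for TIFF/PNG so that fixtures stay plain text.
#'
#' @param path File path.
#' @return `read_pgm()` returns a numeric matrix.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  tok <- scan(text = paste(lines, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (length(tok) < 4 || tok[1] != "P2") stop("not a plain PGM (P2): ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) {
    stop(sprintf("PGM %s: expected %d pixels, found %d", path, w * h,
                 length(vals)))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param img Numeric matrix of non-negative intensities.
#' @param maxval Stated maximum value (default 65535, 16-bit range);
#'   values are rounded to integers on write.
#' @export
write_pgm <- function(img, path, maxval = 65535) {
  img <- round(as.matrix(img))
  if (any(img < 0) || any(img > maxval)) {
    stop("intensities out of [0, maxval] range")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected with a nearest-match suggestion so that a
#' typo like `thresold` fails loudly instead of silently using a
#' default.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param allowed_keys Character vector of permitted top-level keys;
#'   NULL skips the check.
#' @export
load_config <- function(path, allowed_keys = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext))
  if (!is.list(cfg)) stop("config must be a mapping of key: value")
  if (!is.null(allowed_keys)) {
    unknown <- setdiff(names(cfg), allowed_keys)
    if (length(unknown) > 0) {
      hints <- vapply(unknown, function(u) {
        d <- utils::adist(u, allowed_keys)
        if (min(d) <= 3) {
          sprintf("'%s' (did you mean '%s'?)", u, allowed_keys[which.min(d)])
        } else sprintf("'%s'", u)
      }, character(1))
      stop("unknown config key(s): ", paste(hints, collapse = ", "))
    }
  }
  cfg
}

#' Write a JSON provenance record for a run
#'
#' Records parameters, seed, package version and input-file checksums;
#' a run is reproducible from this record alone.
#'
#' @param path Output path for the JSON record.
#' @param parameters Named list of run parameters.
#' @param seed Integer seed used (or NULL).
#' @param inputs Character vector of input file paths to checksum.
#' @export
write_provenance <- function(path, parameters, seed = NULL,
                             inputs = character(0)) {
  inputs <- inputs[file.exists(inputs)]
  rec <- list(
    package = "occuscore",
    version = as.character(utils::packageVersion("occuscore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = parameters,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
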