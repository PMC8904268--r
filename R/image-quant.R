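#' Bundle fluorescence image channels
#'
#' @param nuclei Numeric matrix: nuclear-stain intensity raster.
#' @param marker Numeric matrix, same shape: marker-channel raster.
#' @param exclusion_mask Optional logical matrix, same shape; TRUE marks
#'   pixels excluded from all analysis (non-lung material).
#' @param pixel_size Optional physical length per pixel, for reporting.
#' @export
image_channel_set <- function(nuclei, marker, exclusion_mask = NULL,
                              pixel_size = NULL) {
  nuclei <- as.matrix(nuclei); marker <- as.matrix(marker)
  if (!all(dim(nuclei) == dim(marker))) {
    stop("nuclei and marker channels must share shape")
  }
  if (anyNA(nuclei) || anyNA(marker) || any(nuclei < 0) || any(marker < 0)) {
    stop("channel intensities must be non-negative and non-missing")
  }
  if (!is.null(exclusion_mask)) {
    exclusion_mask <- matrix(as.logical(exclusion_mask), nrow(nuclei))
    if (!all(dim(exclusion_mask) == dim(nuclei))) {
      stop("exclusion mask must share the channel shape")
    }
  }
  structure(list(nuclei = nuclei, marker = marker,
                 exclusion_mask = exclusion_mask, pixel_size = pixel_size),
            class = "image_channel_set")
}

#' Otsu's automatic intensity threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' supplied intensities. Returns a threshold on the original intensity
#' scale; pixels strictly above it are foreground.
#'
#' @param values Numeric vector of intensities.
#' @param n_bins Histogram resolution (default 256).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite intensities")
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  best <- which.max(sigma_b[-n_bins])
  breaks[best + 1]
}

# fill interior holes: background components (4-connected) not touching
# the raster border become foreground
fill_holes <- function(mask) {
  bg <- .cc_label(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

#' Nucleus segmentation parameters
#'
#' @param size_min,size_max Connected-component area bounds in pixels;
#'   defaults bracket disks of radius ~3-13 px.
#' @export
nucleus_seg_params <- function(size_min = 30, size_max = 500) {
  if (size_min > size_max) stop("size_min must be <= size_max")
  structure(list(size_min = size_min, size_max = size_max),
            class = "nucleus_seg_params")
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Otsu threshold computed over non-excluded pixels, hole filling,
#' 8-connected component labelling and an area gate. Touching nuclei
#' are not split (no watershed); fields are assumed sparse enough that
#' nuclei rarely merge.
#'
#' @param img An `image_channel_set`.
#' @param params A `nucleus_seg_params`.
#' @return A `nucleus_set`: `labels` (integer raster, 0 = background),
#'   `ids`, `areas`, `centroids` (id x (row, col)), `empty_field` flag.
#' @export
segment_nuclei <- function(img, params = nucleus_seg_params()) {
  stopifnot(inherits(img, "image_channel_set"),
            inherits(params, "nucleus_seg_params"))
  excl <- img$exclusion_mask
  ok <- if (is.null(excl)) rep(TRUE, length(img$nuclei)) else !excl
  if (!any(ok)) stop("all pixels excluded; nothing to segment")
  vals <- img$nuclei[ok]
  empty <- diff(range(vals)) == 0
  if (empty) {
    labels <- matrix(0L, nrow(img$nuclei), ncol(img$nuclei))
    return(structure(list(labels = labels, ids = integer(0),
                          areas = integer(0),
                          centroids = matrix(numeric(0), 0, 2),
                          empty_field = TRUE, params = params),
                     class = "nucleus_set"))
  }
  thr <- otsu_threshold(vals)
  mask <- img$nuclei > thr
  if (!is.null(excl)) mask[excl] <- FALSE
  mask <- fill_holes(mask)
  if (!is.null(excl)) mask[excl] <- FALSE  # holes may not cross the mask
  lab <- .cc_label(mask, 8L)
  filtered <- filter_labels_by_size(lab, params$size_min, params$size_max)
  structure(c(filtered, list(empty_field = length(filtered$ids) == 0,
                             params = params)),
            class = "nucleus_set")
}

# drop components with area outside [size_min, size_max] and relabel
# contiguously; returns labels, ids, areas, centroids
filter_labels_by_size <- function(lab, size_min, size_max) {
  if (max(lab) == 0) {
    return(list(labels = lab, ids = integer(0), areas = integer(0),
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col")))))
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= size_min & areas <= size_max)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  new_lab <- lab
  new_lab[lab > 0] <- remap[lab[lab > 0]]
  ids <- seq_along(keep)
  cent <- matrix(NA_real_, length(keep), 2,
                 dimnames = list(NULL, c("row", "col")))
  if (length(keep) > 0) {
    pix <- which(new_lab > 0, arr.ind = TRUE)
    l <- new_lab[new_lab > 0]
    cent[, 1] <- tapply(pix[, 1], l, mean)
    cent[, 2] <- tapply(pix[, 2], l, mean)
  }
  list(labels = new_lab, ids = ids, areas = areas[keep], centroids = cent)
}

#' Calibrate the marker-intensity threshold from a negative control
#'
#' The threshold is an upper quantile (default 0.999) of the negative
#' control's marker-channel intensities over non-excluded pixels, so
#' that at most ~0.1% of pure-background pixels exceed it. Size bounds
#' and the localization class travel with the calibration.
#'
#' @param negative_control An `image_channel_set` imaged without primary
#'   signal; needs >= 1e4 non-excluded pixels.
#' @param quantile Upper quantile used as the threshold.
#' @param size_min,size_max Marker-object area bounds in pixels.
#' @param localization One of "nuclear", "cytoplasmic", "apical".
#' @return A `threshold_calibration`.
#' @export
calibrate_marker_threshold <- function(negative_control, quantile = 0.999,
                                       size_min = 20, size_max = 1e6,
                                       localization = c("nuclear",
                                                        "cytoplasmic",
                                                        "apical")) {
  stopifnot(inherits(negative_control, "image_channel_set"))
  localization <- match.arg(localization)
  if (size_min > size_max) stop("size_min must be <= size_max")
  excl <- negative_control$exclusion_mask
  vals <- if (is.null(excl)) negative_control$marker else {
    negative_control$marker[!excl]
  }
  if (length(vals) < 1e4) {
    stop("negative control must provide >= 1e4 non-excluded pixels")
  }
  thr <- unname(stats::quantile(vals, quantile, type = 7))
  if (thr >= max(vals)) {
    if (diff(range(vals)) == 0) {
      warning("constant negative control; bumping threshold above it")
      thr <- thr + max(.Machine$double.eps * abs(thr), .Machine$double.xmin)
    }
  }
  structure(list(marker_threshold = thr, size_min = size_min,
                 size_max = size_max, localization = localization,
                 quantile = quantile),
            class = "threshold_calibration")
}

#' Detect marker objects
#'
#' Pixels strictly above the calibrated threshold (after applying any
#' exclusion mask) are labelled by 8-connectivity and filtered to the
#' calibration's size bounds. An empty mask is a valid result.
#'
#' @param img An `image_channel_set`.
#' @param cal A `threshold_calibration`.
#' @return List: `labels` (integer raster), `ids`, `areas`, `centroids`.
#' @export
marker_objects <- function(img, cal) {
  stopifnot(inherits(img, "image_channel_set"),
            inherits(cal, "threshold_calibration"))
  mask <- img$marker > cal$marker_threshold
  if (!is.null(img$exclusion_mask)) mask[img$exclusion_mask] <- FALSE
  lab <- .cc_label(mask, 8L)
  filter_labels_by_size(lab, cal$size_min, cal$size_max)
}

#' Associate marker signal with nuclei
#'
#' Localization-aware positivity rules. Nuclear: marker pixels must
#' cover at least `f_nuc` of the nucleus footprint. Cytoplasmic: marker
#' pixels must occupy at least `f_cyt` of a ring of width `ring_width`
#' dilated around the nucleus, excluding the nucleus itself and all
#' other nuclei. Apical: any marker pixel within `apical_distance` of
#' the nucleus footprint counts. One marker object may flag several
#' nuclei.
#'
#' @param nuclei A `nucleus_set`.
#' @param marker_mask Logical raster of marker-positive pixels (e.g.
#'   `marker_objects(...)$labels > 0`), same shape as the labels.
#' @param cal A `threshold_calibration` (provides the localization).
#' @param f_nuc,f_cyt Coverage fractions for the nuclear and
#'   cytoplasmic rules.
#' @param ring_width Cytoplasmic ring width in pixels.
#' @param apical_distance Apical capture distance in pixels.
#' @return Logical vector of per-nucleus positivity flags.
#' @export
associate_nuclei <- function(nuclei, marker_mask, cal, f_nuc = 0.3,
                             f_cyt = 0.1, ring_width = 4,
                             apical_distance = 6) {
  stopifnot(inherits(nuclei, "nucleus_set"),
            inherits(cal, "threshold_calibration"))
  marker_mask <- matrix(as.logical(marker_mask), nrow(nuclei$labels))
  if (!all(dim(marker_mask) == dim(nuclei$labels))) {
    stop("marker mask and nucleus labels must share shape")
  }
  n <- length(nuclei$ids)
  if (n == 0) return(logical(0))
  lab <- nuclei$labels
  pad <- ceiling(max(ring_width, apical_distance)) + 1
  nr <- nrow(lab); nc <- ncol(lab)
  pix <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  flags <- logical(n)
  for (i in seq_len(n)) {
    sel <- l == i
    r0 <- max(1, min(pix[sel, 1]) - pad); r1 <- min(nr, max(pix[sel, 1]) + pad)
    c0 <- max(1, min(pix[sel, 2]) - pad); c1 <- min(nc, max(pix[sel, 2]) + pad)
    lab_c <- lab[r0:r1, c0:c1, drop = FALSE]
    mk_c <- marker_mask[r0:r1, c0:c1, drop = FALSE]
    nuc_c <- lab_c == i
    flags[i] <- switch(cal$localization,
      nuclear = {
        sum(mk_c & nuc_c) / sum(nuc_c) >= f_nuc
      },
      cytoplasmic = {
        ring <- .binary_dilate(nuc_c, ring_width) & lab_c == 0
        sum(ring) > 0 && sum(mk_c & ring) / sum(ring) >= f_cyt
      },
      apical = {
        reach <- .binary_dilate(nuc_c, apical_distance)
        any(mk_c & reach)
      })
  }
  flags
}

#' Summarize per-nucleus flags as a percent-positive result
#'
#' @param flags Logical vector from [associate_nuclei()].
#' @param parameters Optional list echoed into the result (threshold,
#'   localization, association settings) for provenance.
#' @return A `quant_result` with `n_nuclei`, `n_positive`, `fraction`
#'   (0 with `flagged_empty = TRUE` when there are no nuclei).
#' @export
percent_positive <- function(flags, parameters = list()) {
  n <- length(flags)
  np <- sum(flags)
  structure(list(n_nuclei = n, n_positive = np,
                 fraction = if (n == 0) 0 else np / n,
                 flagged_empty = n == 0, parameters = parameters),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result: %d/%d nuclei positive (%.1f%%)%s\n",
              x$n_positive, x$n_nuclei, 100 * x$fraction,
              if (x$flagged_empty) " [empty field]" else ""))
  invisible(x)
}

#' Full single-image quantification
#'
#' Convenience wrapper: segment nuclei, detect marker objects with a
#' supplied calibration, associate, and summarize.
#'
#' @param img An `image_channel_set`.
#' @param cal A `threshold_calibration`.
#' @param seg_params A `nucleus_seg_params`.
#' @param ... Association parameters passed to [associate_nuclei()].
#' @return A `quant_result`.
#' @export
quantify_image <- function(img, cal, seg_params = nucleus_seg_params(), ...) {
  nuc <- segment_nuclei(img, seg_params)
  mk <- marker_objects(img, cal)
  flags <- associate_nuclei(nuc, mk$labels > 0, cal, ...)
  percent_positive(flags, parameters = list(
    marker_threshold = cal$marker_threshold, localization = cal$localization,
    size_min = cal$size_min, size_max = cal$size_max,
    nucleus_size_min = seg_params$size_min,
    nucleus_size_max = seg_params$size_max, dots = list(...)))
}

#' Compare per-image positive fractions between groups
#'
#' Two groups are compared with the rank-sum test; three or more with
#' Kruskal-Wallis plus Dunn's post-hoc versus the control group.
#'
#' @param fractions Named list: group -> numeric vector of per-image
#'   fractions.
#' @param control_group Name of the control group in `fractions`.
#' @param alpha Significance level.
#' @return List with `omnibus` and (for >= 3 groups) `pairwise`; NULL
#'   with a warning when only one group is supplied.
#' @export
compare_image_groups <- function(fractions, control_group, alpha = 0.05) {
  if (!is.list(fractions) || is.null(names(fractions))) {
    stop("`fractions` must be a named list of per-image fraction vectors")
  }
  if (length(fractions) < 2) {
    warning("single group supplied; comparison skipped")
    return(NULL)
  }
  if (!control_group %in% names(fractions)) {
    stop("control group '", control_group, "' not found")
  }
  if (length(fractions) == 2) {
    other <- setdiff(names(fractions), control_group)
    res <- wilcoxon_rank_sum(fractions[[other]], fractions[[control_group]])
    return(list(omnibus = res, pairwise = NULL,
                significant = res$p_value < alpha))
  }
  ci <- match(control_group, names(fractions))
  omni <- kruskal_wallis(fractions)
  dunn <- dunn_posthoc(fractions, control_index = ci)
  list(omnibus = omni, pairwise = dunn,
       significant = vapply(dunn, function(d) d$p_adjusted < alpha,
                            logical(1)))
}
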