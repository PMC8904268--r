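#' Microscopy-field simulation parameters
#'
#' Disk-shaped nuclei with Gaussian intensity noise over Gaussian
#' background; marker signal rendered in a chosen subcellular
#' localization for a ground-truth subset of nuclei. Nuclei are
#' non-overlapping by default (the segmenter does not split touching
#' nuclei).
#'
#' @param field Raster size, c(rows, cols); default 512 x 512.
#' @param n_nuclei Number of nuclei (default 50).
#' @param radius_range Nucleus radius bounds in pixels (default 5-8).
#' @param positive_fraction Fraction of nuclei carrying marker signal.
#' @param localization "nuclear", "cytoplasmic" or "apical".
#' @param bg_mean,bg_sd Background intensity (default 100 +/- 10), both
#'   channels.
#' @param fg_mean,fg_sd Foreground (stain) intensity (default
#'   1000 +/- 20), both channels.
#' @param ring_width Cytoplasmic ring width in pixels (default 4).
#' @param apical_span Angular span of the apical arc in degrees
#'   (default 120).
#' @param apical_width Radial width of the apical arc in pixels
#'   (default 3).
#' @param min_gap Minimum empty gap between nucleus borders (default 2).
#' @param seed Integer seed.
#' @export
image_sim_params <- function(field = c(512, 512), n_nuclei = 50,
                             radius_range = c(5, 8),
                             positive_fraction = 0.2,
                             localization = c("nuclear", "cytoplasmic",
                                              "apical"),
                             bg_mean = 100, bg_sd = 10,
                             fg_mean = 1000, fg_sd = 20,
                             ring_width = 4, apical_span = 120,
                             apical_width = 3, min_gap = 2, seed = 1) {
  localization <- match.arg(localization)
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("positive_fraction must be in [0, 1]")
  }
  if (radius_range[1] > radius_range[2] || radius_range[1] <= 0) {
    stop("invalid radius_range")
  }
  structure(list(field = field, n_nuclei = n_nuclei,
                 radius_range = radius_range,
                 positive_fraction = positive_fraction,
                 localization = localization, bg_mean = bg_mean,
                 bg_sd = bg_sd, fg_mean = fg_mean, fg_sd = fg_sd,
                 ring_width = ring_width, apical_span = apical_span,
                 apical_width = apical_width, min_gap = min_gap,
                 seed = seed),
            class = "image_sim_params")
}

# paint value(s) onto pixels of `img` selected by predicate on squared
# distance/angle within a bounding box around (cr, cc)
disk_pixels <- function(dim, cr, cc, rmax) {
  r0 <- max(1, floor(cr - rmax)); r1 <- min(dim[1], ceiling(cr + rmax))
  c0 <- max(1, floor(cc - rmax)); c1 <- min(dim[2], ceiling(cc + rmax))
  rows <- r0:r1; cols <- c0:c1
  gr <- matrix(rows, length(rows), length(cols))
  gc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  list(rows = gr, cols = gc, d2 = (gr - cr)^2 + (gc - cc)^2)
}

#' Simulate a fluorescence field with matched negative control
#'
#' Nuclei are placed by rejection sampling (at most 1e4 attempts; an
#' error suggests reducing `n_nuclei` if packing fails). The number of
#' marker-positive nuclei is round(positive_fraction * n_nuclei), half
#' away from zero, and the positive subset is drawn uniformly. The
#' negative control shares the nucleus layout (fresh intensity noise)
#' and has pure background in its marker channel.
#'
#' @param params An `image_sim_params`.
#' @return List: `image` (an `image_channel_set`), `negative_control`
#'   (an `image_channel_set`), `truth` (centers, radii, positive
#'   indices, `n_positive`, params).
#' @export
simulate_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  dim <- params$field
  set.seed(derive_seed(params$seed, 1))
  margin <- params$radius_range[2] + params$ring_width +
    params$apical_width + 2
  centers <- matrix(NA_real_, params$n_nuclei, 2)
  radii <- numeric(params$n_nuclei)
  placed <- 0
  attempts <- 0
  while (placed < params$n_nuclei) {
    attempts <- attempts + 1
    if (attempts > 1e4) {
      stop(sprintf(paste0("could not place %d non-overlapping nuclei in a ",
                          "%dx%d field; reduce n_nuclei"),
                   params$n_nuclei, dim[1], dim[2]))
    }
    r <- runif(1, params$radius_range[1], params$radius_range[2])
    cr <- runif(1, margin, dim[1] - margin)
    cc <- runif(1, margin, dim[2] - margin)
    if (placed > 0) {
      d <- sqrt((centers[seq_len(placed), 1] - cr)^2 +
                  (centers[seq_len(placed), 2] - cc)^2)
      # rings/arcs of neighbouring nuclei must not touch either
      if (any(d < radii[seq_len(placed)] + r + params$min_gap +
                2 * max(params$ring_width, params$apical_width))) next
    }
    placed <- placed + 1
    centers[placed, ] <- c(cr, cc)
    radii[placed] <- r
  }

  n_pos <- round_half_away(params$positive_fraction * params$n_nuclei)
  positive <- if (n_pos > 0) sort(sample.int(params$n_nuclei, n_pos))
    else integer(0)
  apical_dir <- runif(params$n_nuclei, 0, 2 * pi)

  render_channel <- function(stream, paint) {
    set.seed(derive_seed(params$seed, stream))
    img <- matrix(rnorm(prod(dim), params$bg_mean, params$bg_sd),
                  dim[1], dim[2])
    img <- paint(img)
    pmax(img, 0)
  }

  paint_nuclei <- function(img) {
    for (i in seq_len(params$n_nuclei)) {
      px <- disk_pixels(dim, centers[i, 1], centers[i, 2], radii[i])
      sel <- px$d2 <= radii[i]^2
      idx <- cbind(px$rows[sel], px$cols[sel])
      img[idx] <- rnorm(nrow(idx), params$fg_mean, params$fg_sd)
    }
    img
  }

  paint_marker <- function(img) {
    for (i in positive) {
      r <- radii[i]
      reach <- switch(params$localization,
        nuclear = r,
        cytoplasmic = r + params$ring_width,
        apical = r + params$apical_width)
      px <- disk_pixels(dim, centers[i, 1], centers[i, 2], reach)
      sel <- switch(params$localization,
        nuclear = px$d2 <= r^2,
        cytoplasmic = px$d2 > r^2 & px$d2 <= (r + params$ring_width)^2,
        apical = {
          ang <- atan2(px$rows - centers[i, 1], px$cols - centers[i, 2])
          dang <- abs(((ang - apical_dir[i] + pi) %% (2 * pi)) - pi)
          px$d2 > r^2 & px$d2 <= (r + params$apical_width)^2 &
            dang <= pi * params$apical_span / 360
        })
      idx <- cbind(px$rows[sel], px$cols[sel])
      img[idx] <- rnorm(nrow(idx), params$fg_mean, params$fg_sd)
    }
    img
  }

  image <- image_channel_set(
    nuclei = render_channel(2, paint_nuclei),
    marker = render_channel(3, paint_marker))
  negative_control <- image_channel_set(
    nuclei = render_channel(4, paint_nuclei),
    marker = render_channel(5, identity))

  list(image = image, negative_control = negative_control,
       truth = list(centers = centers, radii = radii, positive = positive,
                    n_positive = n_pos, apical_dir = apical_dir,
                    params = params))
}
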