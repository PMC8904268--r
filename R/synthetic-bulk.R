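# deterministic sub-seed for per-object random streams: adding samples
# never perturbs the draws of earlier objects
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index) %% 2147483647)
}

# round half away from zero (documented truth-count rounding rule)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Mixing proportions for a two-group focal-expansion scenario
#'
#' Control and test groups share the same composition except for the
#' focal cell type, whose proportion changes from `control_prop` to
#' `test_prop` (defaults 1.5% to 2.5%, the basal-cell shift measured by
#' flow cytometry after tracheal occlusion); the remaining mass is
#' split equally over the other cell types.
#'
#' @param cell_types Character vector of cell-type names.
#' @param focal The expanding/contracting cell type.
#' @param control_prop,test_prop Focal proportions in the two groups.
#' @param groups Names of the two groups (control first).
#' @return Named list: group -> named proportion vector summing to 1.
#' @export
two_group_mixing <- function(cell_types = lung_cell_types(),
                             focal = "basal", control_prop = 0.015,
                             test_prop = 0.025,
                             groups = c("control", "TO")) {
  if (!focal %in% cell_types) stop("focal type not in cell_types")
  out <- lapply(c(control_prop, test_prop), function(p) {
    v <- stats::setNames(rep((1 - p) / (length(cell_types) - 1),
                             length(cell_types)), cell_types)
    v[focal] <- p
    v
  })
  stats::setNames(out, groups)
}

#' Bulk-mixture simulation parameters
#'
#' The generator draws each sample as a noisy linear mixture of
#' cell-type expression profiles: value(g, s) =
#' \[sum_c pi_c(s) P(g, c)\] * exp(e), e ~ N(0, noise_sigma^2).
#' Marker genes express `base_expr` in their own cell type and
#' `base_expr / marker_fold` elsewhere (`marker_fold = Inf` gives pure
#' markers); filler genes share a common profile across cell types.
#'
#' @param n_genes Total genes including markers (default 1000).
#' @param cell_types Cell-type names.
#' @param markers_per_type Markers simulated per cell type (default 20).
#' @param marker_fold Own-type/other-type expression ratio of a marker
#'   (default 1000; strongly specific, as for canonical markers).
#' @param base_expr Marker expression in its own cell type, FPKM-like.
#' @param proportions Named list group -> mixing vector over
#'   `cell_types`, each summing to 1 (default: the two-group basal
#'   expansion of [two_group_mixing()]).
#' @param n_samples Samples per group (default 6).
#' @param noise_sigma SD of the multiplicative lognormal noise on the
#'   log scale (default 0.2).
#' @param seed Integer seed.
#' @export
bulk_sim_params <- function(n_genes = 1000, cell_types = lung_cell_types(),
                            markers_per_type = 20, marker_fold = 1000,
                            base_expr = 100,
                            proportions = two_group_mixing(cell_types),
                            n_samples = 6, noise_sigma = 0.2, seed = 1) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (marker_fold <= 1) stop("marker_fold must be > 1")
  if (n_genes < length(cell_types) * markers_per_type) {
    stop("n_genes smaller than the number of marker genes")
  }
  for (g in names(proportions)) {
    v <- proportions[[g]]
    if (is.null(names(v)) || !setequal(names(v), cell_types)) {
      stop("proportions for group '", g,
           "' must be named over all cell types")
    }
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("proportions for group '", g, "' must be >= 0 and sum to 1")
    }
  }
  if (length(proportions) < 2) stop("need at least 2 groups")
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 markers_per_type = markers_per_type,
                 marker_fold = marker_fold, base_expr = base_expr,
                 proportions = proportions, n_samples = n_samples,
                 noise_sigma = noise_sigma, seed = seed),
            class = "bulk_sim_params")
}

#' Simulate a bulk expression matrix from cell-type mixtures
#'
#' @param params A `bulk_sim_params`.
#' @return List: `expr` (an `expression_matrix`), `design` (a
#'   `group_design`, control = first group in `params$proportions`),
#'   and `truth` with the profile matrix `P`, per-sample proportions,
#'   the true `signature_set`, and the parameters.
#' @export
simulate_bulk <- function(params = bulk_sim_params()) {
  stopifnot(inherits(params, "bulk_sim_params"))
  k <- length(params$cell_types)
  n_markers <- k * params$markers_per_type
  marker_names <- unlist(lapply(params$cell_types, function(ct) {
    sprintf("%s_m%02d", ct, seq_len(params$markers_per_type))
  }))
  n_filler <- params$n_genes - n_markers
  filler_names <- if (n_filler > 0) sprintf("filler_%04d", seq_len(n_filler))
    else character(0)

  off <- if (is.finite(params$marker_fold)) {
    params$base_expr / params$marker_fold
  } else 0
  P <- matrix(off, nrow = n_markers, ncol = k,
              dimnames = list(marker_names, params$cell_types))
  for (j in seq_len(k)) {
    rows <- (j - 1) * params$markers_per_type + seq_len(params$markers_per_type)
    P[rows, j] <- params$base_expr
  }
  if (n_filler > 0) {
    set.seed(derive_seed(params$seed, 0))
    # nonspecific genes: one lognormal level shared by all cell types
    lvl <- exp(rnorm(n_filler, mean = log(50), sd = 1))
    P <- rbind(P, matrix(lvl, nrow = n_filler, ncol = k,
                         dimnames = list(filler_names, params$cell_types)))
  }

  groups <- names(params$proportions)
  sample_names <- unlist(lapply(groups, function(g) {
    sprintf("%s_s%d", g, seq_len(params$n_samples))
  }))
  assignment <- stats::setNames(rep(groups, each = params$n_samples),
                                sample_names)
  props <- matrix(NA_real_, nrow = length(sample_names), ncol = k,
                  dimnames = list(sample_names, params$cell_types))
  values <- matrix(NA_real_, nrow = nrow(P), ncol = length(sample_names),
                   dimnames = list(rownames(P), sample_names))
  for (si in seq_along(sample_names)) {
    g <- assignment[[sample_names[si]]]
    pi_s <- params$proportions[[g]][params$cell_types]
    props[si, ] <- pi_s
    clean <- as.numeric(P %*% pi_s)
    set.seed(derive_seed(params$seed, si))
    noise <- if (params$noise_sigma > 0) {
      exp(rnorm(nrow(P), 0, params$noise_sigma))
    } else rep(1, nrow(P))
    values[, si] <- clean * noise
  }

  sigs <- signature_set(
    stats::setNames(lapply(seq_len(k), function(j) {
      marker_names[(j - 1) * params$markers_per_type +
                     seq_len(params$markers_per_type)]
    }), params$cell_types),
    provenance = "simulated ground truth")

  list(expr = expression_matrix(values),
       design = group_design(assignment, control_group = groups[1]),
       truth = list(P = P, proportions = props, signatures = sigs,
                    params = params))
}

#' Simulate a differential-expression results table
#'
#' Null genes receive fold changes centered at 1 (log2 FC ~
#' N(0, `null_lfc_sd`)) and uniform adjusted p-values; alternative
#' genes receive log2 FCs of random sign drawn from
#' N(`lfc_mean`, `lfc_sd`) and Beta(`alt_p_shape1`, `alt_p_shape2`)
#' adjusted p-values concentrated near zero. The number of alternative
#' genes is `round(prop_alt * n_genes)` (half away from zero).
#'
#' @param n_genes Number of genes.
#' @param prop_alt Proportion of genes drawn from the alternative.
#' @param lfc_mean,lfc_sd Alternative effect-size distribution (log2).
#' @param null_lfc_sd Null fold-change jitter (log2), default 0.2.
#' @param alt_p_shape1,alt_p_shape2 Beta parameters of alternative
#'   adjusted p-values (defaults 0.25, 25).
#' @param seed Integer seed.
#' @return List: `table` (a `deg_table`) and `truth` (`is_alt` logical
#'   vector plus parameters).
#' @export
simulate_deg_table <- function(n_genes = 1000, prop_alt = 0.1,
                               lfc_mean = 2, lfc_sd = 0.5,
                               null_lfc_sd = 0.2,
                               alt_p_shape1 = 0.25, alt_p_shape2 = 25,
                               seed = 1) {
  if (prop_alt < 0 || prop_alt > 1) stop("prop_alt must be in [0, 1]")
  set.seed(derive_seed(seed, 0))
  n_alt <- round_half_away(prop_alt * n_genes)
  is_alt <- rep(FALSE, n_genes)
  if (n_alt > 0) is_alt[sample.int(n_genes, n_alt)] <- TRUE
  lfc <- rnorm(n_genes, 0, null_lfc_sd)
  padj <- runif(n_genes)
  if (n_alt > 0) {
    sgn <- sample(c(-1, 1), n_alt, replace = TRUE)
    lfc[is_alt] <- sgn * rnorm(n_alt, lfc_mean, lfc_sd)
    padj[is_alt] <- rbeta(n_alt, alt_p_shape1, alt_p_shape2)
  }
  tab <- deg_table(gene = sprintf("gene_%05d", seq_len(n_genes)),
                   fold_change = lfc, adjusted_p = padj, fc_scale = "log2")
  list(table = tab,
       truth = list(is_alt = is_alt, n_alt = n_alt,
                    params = list(n_genes = n_genes, prop_alt = prop_alt,
                                  lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                                  null_lfc_sd = null_lfc_sd,
                                  alt_p_shape1 = alt_p_shape1,
                                  alt_p_shape2 = alt_p_shape2, seed = seed)))
}

#' Expected null pass rate of the DE gate under the generator
#'
#' Closed form for the probability that a null gene of
#' [simulate_deg_table()] passes [apply_deg_filter()] in direction
#' "both": alpha * P(|N(0, null_lfc_sd)| >= log2(fc_threshold)).
#'
#' @param spec A `filter_spec`.
#' @param null_lfc_sd The generator's null log2-FC standard deviation.
#' @export
deg_null_pass_prob <- function(spec, null_lfc_sd = 0.2) {
  stopifnot(inherits(spec, "filter_spec"))
  spec$alpha * 2 * pnorm(-log2(spec$fc_threshold) / null_lfc_sd)
}
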