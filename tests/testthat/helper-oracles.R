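# Independent brute-force / permutation oracles used by the unit and
# acceptance tests. Deliberately naive implementations that share no code
# with the package internals.

# two-sided Monte-Carlo permutation p for the rank-sum test:
# statistic = sum of pooled ranks of x, centred at its permutation mean
perm_p_ranksum <- function(x, y, B = 1e5) {
  n1 <- length(x)
  r <- rank(c(x, y))
  n <- length(r)
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n + 1) / 2)
  stat <- vapply(seq_len(B), function(i) {
    abs(sum(r[sample.int(n, n1)]) - n1 * (n + 1) / 2)
  }, numeric(1))
  mean(stat >= obs - 1e-12)
}

# permutation p for Kruskal-Wallis via the (divisor-free) weighted sum of
# squared mean ranks, which is a monotone transform of H for fixed data
perm_p_kw <- function(groups, B = 1e5) {
  ns <- lengths(groups)
  r <- rank(unlist(groups, use.names = FALSE))
  idx <- rep(seq_along(groups), ns)
  stat_of <- function(rr) sum(tapply(rr, idx, mean)^2 * ns)
  obs <- stat_of(r)
  perm <- vapply(seq_len(B), function(i) stat_of(sample(r)), numeric(1))
  mean(perm >= obs - 1e-9)
}

# permutation p for a single Dunn contrast: |mean rank difference| between
# group i and the control group under full relabelling
perm_p_dunn <- function(groups, i, control, B = 1e5) {
  ns <- lengths(groups)
  r <- rank(unlist(groups, use.names = FALSE))
  idx <- rep(seq_along(groups), ns)
  stat_of <- function(rr) {
    m <- tapply(rr, idx, mean)
    abs(m[[i]] - m[[control]])
  }
  obs <- stat_of(r)
  perm <- vapply(seq_len(B), function(j) stat_of(sample(r)), numeric(1))
  mean(perm >= obs - 1e-12)
}

# literal double-loop marker assignment scan
brute_force_signatures <- function(agg, fold_margin, min_expr) {
  sets <- list()
  for (g in rownames(agg)) {
    for (ct in colnames(agg)) {
      v <- agg[g, ct]
      ok <- v > 0 && v >= min_expr
      if (ok) {
        for (other in setdiff(colnames(agg), ct)) {
          if (v < fold_margin * agg[g, other]) ok <- FALSE
        }
      }
      if (ok) sets[[ct]] <- c(sets[[ct]], g)
    }
  }
  sets
}

# double-loop read-count filter
brute_force_count_filter <- function(counts, min_reads, mode, k = NULL) {
  kept <- character(0)
  for (g in rownames(counts)) {
    n_ok <- 0
    for (s in colnames(counts)) {
      if (counts[g, s] >= min_reads) n_ok <- n_ok + 1
    }
    pass <- if (mode == "all") n_ok == ncol(counts) else n_ok >= k
    if (pass) kept <- c(kept, g)
  }
  kept
}

# row-by-row DEG gate
brute_force_deg_filter <- function(tab, fc, alpha, direction) {
  kept <- character(0)
  for (i in seq_len(nrow(tab))) {
    sig <- tab$adjusted_p[i] < alpha || alpha >= 1
    up <- sig && tab$fold_change[i] >= fc
    down <- sig && tab$fold_change[i] <= 1 / fc
    pass <- switch(direction, up = up, down = down, both = up || down)
    if (pass) kept <- c(kept, tab$gene[i])
  }
  kept
}

# paint a filled disk into a matrix (used to build tiny image fixtures)
paint_disk <- function(img, cr, cc, radius, value) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((r - cr)^2 + (c - cc)^2 <= radius^2) img[r, c] <- value
    }
  }
  img
}

# a quick deterministic toy reference table
toy_reference <- function() {
  expr <- matrix(
    c(100, 0, 0,
      0, 80, 0,
      5, 5, 5),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Krt5", "Scgb1a1", "Actb"), NULL))
  ref_profile_table(expr, cell_types = c("basal", "club", "ciliated"),
                    timepoints = rep("E18.5", 3))
}
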