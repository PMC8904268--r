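#' @useDynLib occuscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pnorm pchisq pwilcox pf quantile rnorm runif rbeta
#' @importFrom utils read.delim write.csv read.csv
"_PACKAGE"

new_test_result <- function(statistic, p_value, method, n_per_group,
                            ties_corrected = FALSE) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n_per_group = n_per_group, ties_corrected = ties_corrected),
    class = "occ_test_result"
  )
}

#' @export
print.occ_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = ", "),
              if (isTRUE(x$ties_corrected)) ", tie-corrected" else ""))
  invisible(x)
}

# Sum over tie groups of (t^3 - t), used by the rank-test variance corrections.
tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration is used when both samples have at most `exact_max_n`
#' observations and the pooled data contain no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' The small-sample exact switch matters here because group sizes in the
#' experiments this models are typically 4-6, where the normal
#' approximation is unreliable.
#'
#' @param x,y Numeric sample vectors, each of length >= 1.
#' @param exact_max_n Largest per-group n for which the exact null
#'   distribution is used (default 8).
#' @return An `occ_test_result` with the Mann-Whitney U statistic.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (anyNA(c(x, y))) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  has_ties <- anyDuplicated(pooled) > 0
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (!has_ties && n1 <= exact_max_n && n2 <= exact_max_n) {
    mu <- n1 * n2 / 2
    p <- if (u <= mu) {
      2 * pwilcox(u, n1, n2)
    } else {
      2 * (1 - pwilcox(u - 1, n1, n2))
    }
    p <- min(1, p)
    return(new_test_result(u, p, "Wilcoxon rank-sum (exact)", c(n1, n2)))
  }

  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term(pooled) / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all observations tied: no evidence against the null
    return(new_test_result(0, 1, "Wilcoxon rank-sum (normal approx.)",
                           c(n1, n2), ties_corrected = TRUE))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  new_test_result(z, p, "Wilcoxon rank-sum (normal approx.)", c(n1, n2),
                  ties_corrected = has_ties)
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus test that k independent samples come from the same
#' distribution, with the standard tie-correction divisor and a
#' chi-square reference distribution on k - 1 degrees of freedom.
#' Degenerate all-tied input returns H = 0, p = 1 with a warning rather
#' than an error so that batch pipelines keep running.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 1,
#'   total length >= 3.
#' @return An `occ_test_result` carrying the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 sample vectors")
  }
  ns <- lengths(groups)
  if (any(ns < 1)) stop("every group must contain at least one observation")
  n <- sum(ns)
  if (n < 3) stop("need at least 3 observations in total")
  pooled <- as.numeric(unlist(groups, use.names = FALSE))
  if (anyNA(pooled)) stop("samples must not contain NA")
  r <- rank(pooled)
  idx <- rep(seq_along(groups), ns)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(ns * rbar^2) - 3 * (n + 1)
  tt <- tie_term(pooled)
  divisor <- 1 - tt / (n^3 - n)
  if (divisor <= 0) {
    warning("all observations identical; returning H = 0, p = 1")
    return(new_test_result(0, 1, "Kruskal-Wallis", ns, ties_corrected = TRUE))
  }
  h <- h / divisor
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_test_result(h, p, "Kruskal-Wallis", ns, ties_corrected = tt > 0)
}

#' Dunn's post-hoc test of each group against a control group
#'
#' Pairwise z statistics from pooled ranks across all groups with tie
#' correction, following a Kruskal-Wallis omnibus test. Only the
#' (group, control) contrasts are computed, matching the
#' each-treatment-versus-control structure of the experiments this
#' package models; the number of reported pairs m is used for the
#' Bonferroni adjustment min(1, m * p).
#'
#' @param groups List of numeric sample vectors.
#' @param control_index Index of the control group within `groups`.
#' @param adjust One of "bonferroni", "holm_sidak", "none".
#' @return A list of `occ_test_result`, one per non-control group, each
#'   with extra fields `comparison`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, control_index = 1, adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 sample vectors")
  }
  k <- length(groups)
  if (control_index < 1 || control_index > k) {
    stop(sprintf("control_index %d out of range [1, %d]", control_index, k))
  }
  adjust <- match.arg(adjust, c("bonferroni", "holm_sidak", "none"))
  ns <- lengths(groups)
  n <- sum(ns)
  pooled <- as.numeric(unlist(groups, use.names = FALSE))
  r <- rank(pooled)
  idx <- rep(seq_along(groups), ns)
  rbar <- tapply(r, idx, mean)
  tt <- tie_term(pooled)
  sigma2 <- n * (n + 1) / 12 - tt / (12 * (n - 1))
  others <- setdiff(seq_len(k), control_index)
  res <- lapply(others, function(i) {
    v <- sigma2 * (1 / ns[i] + 1 / ns[control_index])
    if (v <= 0) {
      z <- 0; p <- 1
    } else {
      z <- (rbar[[i]] - rbar[[control_index]]) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    out <- new_test_result(z, p, "Dunn post-hoc",
                           c(ns[i], ns[control_index]),
                           ties_corrected = tt > 0)
    out$comparison <- c(group = i, control = control_index)
    out
  })
  praw <- vapply(res, `[[`, numeric(1), "p_value")
  padj <- switch(adjust,
    bonferroni = bonferroni_adjust(praw),
    holm_sidak = holm_sidak_adjust(praw),
    none = praw
  )
  for (j in seq_along(res)) res[[j]]$p_adjusted <- padj[j]
  res
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test of equality of group means assuming a
#' common variance.
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return An `occ_test_result` carrying the F statistic.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 sample vectors")
  }
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group must have at least 2 observations")
  k <- length(groups)
  n <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / n
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) {
    sum((groups[[i]] - means[i])^2)
  }, numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  if (ss_within <= 0) {
    # zero within-group variance: any between-group difference is infinite
    # evidence; identical groups are no evidence at all
    p <- if (ss_between > 0) 0 else 1
    return(new_test_result(0, p, "One-way ANOVA", ns))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  new_test_result(f, p, "One-way ANOVA", ns)
}

#' Multiplicity adjustments
#'
#' `bonferroni_adjust()` returns min(1, m * p). `holm_sidak_adjust()`
#' applies the step-down Sidak procedure, 1 - (1 - p_(i))^(m - i + 1)
#' on the ascending p-values with running-maximum enforcement of
#' monotonicity. Both are order-preserving and map into [0, 1].
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bonferroni_adjust <- function(pvals) {
  check_pvals(pvals)
  pmin(1, length(pvals) * pvals)
}

#' @rdname bonferroni_adjust
#' @export
holm_sidak_adjust <- function(pvals) {
  check_pvals(pvals)
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- 1 - (1 - pvals[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

check_pvals <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  invisible(TRUE)
}
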