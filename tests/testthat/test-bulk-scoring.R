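make_expr <- function(values, genes, samples) {
  expression_matrix(matrix(values, nrow = length(genes), byrow = TRUE,
                           dimnames = list(genes, samples)))
}

test_that("group medians: odd, even and singleton groups", {
  expr <- make_expr(c(2, 4, 6, 10, 7, 1, 3, 5, 9, 2),
                    c("g1", "g2"), sprintf("s%d", 1:5))
  design <- group_design(
    c(s1 = "ctrl", s2 = "ctrl", s3 = "ctrl", s4 = "ctrl", s5 = "TO"),
    control_group = "ctrl")
  med <- group_medians(expr, design)
  expect_equal(med["g1", "ctrl"], 5)   # midpoint of 4 and 6
  expect_equal(med["g2", "ctrl"], 4)   # midpoint of 3 and 5
  expect_equal(med["g1", "TO"], 7)     # singleton
  med3 <- group_medians(
    make_expr(c(2, 4, 6, 1), "g1", sprintf("s%d", 1:4)),
    group_design(c(s1 = "a", s2 = "a", s3 = "a", s4 = "b"), "a"))
  expect_equal(med3["g1", "a"], 4)     # odd count

  bad <- group_design(c(s1 = "ctrl", missing_one = "TO"), "ctrl")
  expect_error(group_medians(expr, bad), "missing_one")
})

test_that("relative expression normalizes to control and guards zeros", {
  med <- matrix(c(4, 10, 0, 3), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("ctrl", "TO")))
  rel <- relative_expression(med, "ctrl", epsilon = 1e-6)
  expect_equal(rel$ratio["g1", "TO"], 2.5)
  expect_identical(rel$ratio["g1", "ctrl"], 1)
  expect_identical(rel$dropped_genes, "g2")

  med0 <- matrix(0, 1, 2, dimnames = list("g1", c("ctrl", "TO")))
  expect_error(relative_expression(med0, "ctrl"), "all genes dropped")
})

test_that("score_cell_types takes marker medians and reports absences", {
  med <- matrix(c(1, 1, 1, 2, 1, 4), nrow = 3, byrow = TRUE,
                dimnames = list(c("m1", "m2", "m3"), c("ctrl", "TO")))
  rel <- relative_expression(med, "ctrl")
  sigs <- signature_set(list(basal = c("m1", "m2", "m3", "not_measured"),
                             club = "also_missing"))
  expect_warning(panel <- score_cell_types(rel, sigs), "club")
  expect_equal(unname(panel$cell_types$basal$summary["TO"]), 2)  # med{1,2,4}
  expect_equal(unname(panel$cell_types$basal$summary["ctrl"]), 1)
  expect_equal(panel$cell_types$basal$n_genes, 3)  # absent gene dropped
  expect_identical(panel$absent_cell_types, "club")

  none <- signature_set(list(basal = "nothing_here"))
  expect_error(suppressWarnings(score_cell_types(rel, none)), "no signature")
})

test_that("compare_panel: exchangeable null and permutation-accurate pairs", {
  # identical ratio vectors in all groups -> nothing significant
  med <- matrix(rep(c(1, 2, 3), 3), nrow = 3,
                dimnames = list(c("m1", "m2", "m3"), c("ctrl", "TO", "CDH")))
  rel <- relative_expression(med, "ctrl")
  rel$ratio[, ] <- rep(c(1, 1.3, 0.7), 3)  # same vector per group
  panel <- compare_panel(score_cell_types(
    rel, signature_set(list(basal = c("m1", "m2", "m3")))))
  expect_gt(panel$cell_types$basal$omnibus$p_value, 0.5)
  expect_false(any(panel$cell_types$basal$pairwise$significant))

  # two separated triples: exact two-group p equals the permutation value
  med2 <- matrix(c(1, 1, 1, 10, 11, 12), nrow = 3,
                 dimnames = list(c("m1", "m2", "m3"), c("ctrl", "TO")))
  rel2 <- relative_expression(med2, "ctrl")
  rel2$ratio[, "ctrl"] <- c(1, 2, 3)
  rel2$ratio[, "TO"] <- c(10, 11, 12)
  panel2 <- compare_panel(score_cell_types(
    rel2, signature_set(list(basal = c("m1", "m2", "m3")))))
  p <- panel2$cell_types$basal$pairwise$p
  set.seed(1)
  expect_lt(abs(p - perm_p_ranksum(c(10, 11, 12), c(1, 2, 3), B = 2e4)),
            0.02)
  expect_equal(p, 0.1)  # exact enumeration value

  # too-short vectors are flagged untestable
  med3 <- matrix(c(1, 2), nrow = 1, dimnames = list("m1", c("ctrl", "TO")))
  rel3 <- relative_expression(med3, "ctrl")
  panel3 <- compare_panel(score_cell_types(
    rel3, signature_set(list(basal = "m1"))))
  expect_true(panel3$cell_types$basal$untestable)
})

test_that("scoring is scale-equivariant and sample-permutation invariant", {
  sim <- simulate_bulk(bulk_sim_params(n_genes = 240, seed = 7))
  expr <- sim$expr; design <- sim$design
  rel1 <- relative_expression(group_medians(expr, design), "control")

  # multiply one gene's values by a constant: its ratios are unchanged
  v2 <- expr$values
  v2["basal_m01", ] <- v2["basal_m01", ] * 37
  rel2 <- relative_expression(group_medians(expression_matrix(v2), design),
                              "control")
  expect_equal(rel2$ratio["basal_m01", ], rel1$ratio["basal_m01", ])

  # shuffle sample columns (labels travel along)
  set.seed(8)
  perm <- sample(ncol(expr$values))
  expr_p <- expression_matrix(expr$values[, perm])
  rel3 <- relative_expression(group_medians(expr_p, design), "control")
  expect_equal(rel3$ratio, rel1$ratio)
})

test_that("summary ratio rises monotonically with the focal proportion", {
  props <- c(0.015, 0.025, 0.045)
  summaries <- vapply(props, function(p) {
    mix <- two_group_mixing(control_prop = 0.015, test_prop = p)
    reps <- vapply(1:5, function(r) {
      sim <- simulate_bulk(bulk_sim_params(
        n_genes = 240, proportions = mix, noise_sigma = 0.2,
        seed = 900 + r))
      rel <- relative_expression(group_medians(sim$expr, sim$design),
                                 "control")
      panel <- score_cell_types(rel, sim$truth$signatures)
      unname(panel$cell_types$basal$summary["TO"])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_gte(summaries[1], 0.85)  # null-ish: near 1
  expect_true(all(diff(summaries) > 0))
})
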