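test_that("reference tables validate, round-trip, and reject bad input", {
  ref <- toy_reference()
  expect_s3_class(ref, "ref_profile_table")
  expect_length(ref$genes, 3)
  expect_length(unique(ref$cell_types), 3)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_profiles(ref, path)
  back <- load_reference_profiles(path)
  expect_equal(back$expr, ref$expr, ignore_attr = TRUE)
  expect_identical(back$cell_types, ref$cell_types)
  expect_identical(back$timepoints, ref$timepoints)

  bad <- ref$expr; bad[1, 1] <- -1
  expect_error(ref_profile_table(bad, ref$cell_types, ref$timepoints),
               "negative")
  dup <- ref$expr; rownames(dup) <- c("Krt5", "Krt5", "Actb")
  expect_error(ref_profile_table(dup, ref$cell_types, ref$timepoints),
               "duplicate gene")

  # malformed header rejected on load
  writeLines("gene\tbasal\n g1\t1", path)
  expect_error(load_reference_profiles(path), "celltype")
})

test_that("derive_signatures applies the margin-over-second-best rule", {
  # sole expressor is assigned; insufficient margin leaves unassigned
  expr <- matrix(c(100, 0, 100, 30), nrow = 2, byrow = TRUE,
                 dimnames = list(c("Trp63", "Krt14"), NULL))
  ref <- ref_profile_table(expr, cell_types = c("basal", "club"),
                           timepoints = rep("PND1", 2))
  sigs <- derive_signatures(ref, specificity_params(fold_margin = 5,
                                                    min_expr = 1))
  expect_identical(sigs$sets, list(basal = "Trp63"))  # 100 < 5 * 30

  # no qualifying gene errors, naming the parameters
  expr2 <- matrix(c(10, 9), nrow = 1,
                  dimnames = list("Gapdh", NULL))
  ref2 <- ref_profile_table(expr2, cell_types = c("basal", "club"),
                            timepoints = rep("PND1", 2))
  expect_error(derive_signatures(ref2, specificity_params(fold_margin = 5)),
               "fold_margin = 5")
})

test_that("derivation matches the brute-force oracle on random tables", {
  set.seed(101)
  for (rep in 1:30) {
    n_genes <- sample(20:50, 1)
    n_types <- sample(2:5, 1)
    n_tp <- sample(1:3, 1)
    expr <- matrix(rexp(n_genes * n_types * n_tp, rate = 0.05),
                   nrow = n_genes)
    # sprinkle exact zeros to hit the all-zero / zero-runner-up branches
    expr[sample(length(expr), length(expr) %/% 10)] <- 0
    rownames(expr) <- sprintf("g%03d", seq_len(n_genes))
    ref <- ref_profile_table(
      expr,
      cell_types = rep(sprintf("ct%d", seq_len(n_types)), each = n_tp),
      timepoints = rep(sprintf("t%d", seq_len(n_tp)), n_types))
    params <- specificity_params(fold_margin = sample(c(2, 5, 10), 1),
                                 min_expr = sample(c(0, 1, 10), 1))
    agg <- vapply(unique(ref$cell_types), function(ct) {
      rowMeans(ref$expr[, ref$cell_types == ct, drop = FALSE])
    }, numeric(n_genes))
    expected <- brute_force_signatures(agg, params$fold_margin,
                                       params$min_expr)
    got <- tryCatch(derive_signatures(ref, params)$sets,
                    error = function(e) list())
    expect_identical(got[sort(names(got))], expected[sort(names(expected))])
    # disjointness
    expect_false(anyDuplicated(unlist(got)) > 0)
  }
})

test_that("raising fold_margin never adds a marker (monotonicity)", {
  set.seed(202)
  expr <- matrix(rexp(40 * 4, 0.05), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  ref <- ref_profile_table(expr, cell_types = paste0("ct", 1:4),
                           timepoints = rep("t1", 4))
  margins <- c(1.5, 2, 3, 5, 10, 50)
  sets <- lapply(margins, function(m) {
    tryCatch(derive_signatures(ref, specificity_params(fold_margin = m))$sets,
             error = function(e) list())
  })
  for (i in seq_len(length(margins) - 1)) {
    for (ct in names(sets[[i + 1]])) {
      expect_true(all(sets[[i + 1]][[ct]] %in% sets[[i]][[ct]]))
    }
  }
})

test_that("GMT write/read round-trips and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".gmt")
  sigs <- signature_set(list(basal = c("Trp63", "Krt5")),
                        provenance = "derived")
  write_gmt(sigs, path)
  expect_identical(readLines(path), "basal\tderived\tTrp63\tKrt5")

  many <- signature_set(
    stats::setNames(lapply(1:10, function(i) sprintf("g%d_%d", i, 1:3)),
                    sprintf("set%02d", 1:10)),
    provenance = "round-trip")
  write_gmt(many, path)
  expect_identical(read_gmt(path)$sets, many$sets)

  writeLines(c("a\td\tg1\tg2", "b\td\tg2"), path)
  expect_error(read_gmt(path), "more than one")
  writeLines(c("a\td\tg1", "a\td\tg2"), path)
  expect_error(read_gmt(path), "duplicate")
  expect_error(signature_set(list(basal = character(0))), "empty")
})
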