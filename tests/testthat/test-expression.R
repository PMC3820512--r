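test_that("fold changes follow the log2 pseudocount rule", {
  # large abundances make the default pseudocount negligible
  expr <- tibble::tibble(gene = "a", `0` = 1e6, `1` = 2e6, `2` = 1e6)
  st <- gene_stats(expr)
  expect_equal(st$max_abs_lfc, 1, tolerance = 1e-5)  # doubling = 1 log2 unit

  flat <- tibble::tibble(gene = "a", `0` = 10, `1` = 10, `2` = 10)
  expect_equal(gene_stats(flat)$max_abs_lfc, 0)

  # zero baseline stays finite through the pseudocount
  z <- tibble::tibble(gene = "a", `0` = 0, `1` = 31)
  fc <- fold_changes(z, pseudocount = 1)
  expect_equal(fc$abs_lfc, 5)  # |log2(32/1)|

  # down-regulation counts through the absolute value
  dn <- tibble::tibble(gene = "a", `0` = 4e6, `1` = 1e6)
  expect_equal(gene_stats(dn)$max_abs_lfc, 2, tolerance = 1e-5)
})

test_that("expression validation rejects malformed matrices", {
  expect_error(validate_expression(tibble::tibble(gene = "a", `1` = 5, `2` = 6)),
               "time-0", class = "tempoflow_input_error")
  expect_error(
    validate_expression(tibble::tibble(gene = c("a", "a"), `0` = 1, `1` = 2)),
    "duplicate", class = "tempoflow_input_error"
  )
  expect_error(
    validate_expression(tibble::tibble(gene = "a", `0` = -1, `1` = 2)),
    "non-negative", class = "tempoflow_input_error"
  )
})

test_that("the three expression filters match hand-computed outcomes", {
  st <- gene_stats(make_filter_expr())
  by_gene <- split(st, st$gene)
  # steady 15 fpkm with one 64 fpkm spike passes everything
  expect_true(by_gene$induced$passes_filters)
  # all values 1 fpkm: fails both abundance filters
  expect_false(by_gene$low$pass_min2)
  expect_false(by_gene$low$pass_min10)
  # constant 12 fpkm: only the fold-change filter fails
  expect_true(by_gene$flat$pass_min2 && by_gene$flat$pass_min10)
  expect_false(by_gene$flat$pass_fc)
  expect_identical(filter_genes(st)$gene %in% c("low", "flat"),
                   rep(FALSE, nrow(filter_genes(st))))
})

test_that("filtering is monotone in its thresholds", {
  fx <- simulate_cascade_data(n_nodes = 80, n_cascades = 5, seed = 11)
  base <- filter_genes(gene_stats(fx$expression))$gene
  relaxed <- filter_genes(gene_stats(fx$expression, min_abund_low = 1,
                                     min_abund_high = 5,
                                     fold_change_min = 1.5))$gene
  expect_true(all(base %in% relaxed))
})

test_that("stage assignment follows the argmax window with earliest-tie rule", {
  expr <- tibble::tibble(
    gene = c("mid", "early", "tied"),
    `0` = c(10, 10, 10), `0.5` = c(10, 80, 10), `1` = c(10, 40, 60),
    `2` = c(10, 10, 10), `3` = c(80, 10, 10), `4` = c(10, 10, 10),
    `6` = c(10, 10, 10), `8` = c(10, 10, 60)
  )
  st <- stage_genes(expr)
  stage <- setNames(as.character(st$stage), st$gene)
  expect_equal(stage[["mid"]], "T2")    # peak at 3 h
  expect_equal(stage[["early"]], "T1")  # peak at 0.5 h
  expect_equal(stage[["tied"]], "T1")   # 1 h and 8 h tie -> earliest
})

test_that("staged genes partition the filtered set", {
  fx <- simulate_cascade_data(n_nodes = 120, n_cascades = 8, seed = 3)
  st <- gene_stats(fx$expression)
  staged <- st |> filter_genes() |> assign_stages()
  expect_false(anyNA(staged$stage))
  expect_equal(sum(stage_counts(stage_genes(fx$expression))),
               nrow(filter_genes(st)))
})

test_that("fold change is invariant to global rescaling (pseudocount limit)", {
  fx <- simulate_cascade_data(n_nodes = 40, n_cascades = 3, seed = 5)
  expr <- fx$expression
  scaled <- expr |> mutate(across(-gene, ~ .x * 1000))
  f1 <- gene_stats(expr, pseudocount = 1e-9)$max_abs_lfc
  f2 <- gene_stats(scaled, pseudocount = 1e-9)$max_abs_lfc
  expect_equal(f1, f2, tolerance = 1e-6)
  # with the default pseudocount, abundances >> 1 fpkm change negligibly
  f3 <- gene_stats(scaled)$max_abs_lfc
  expect_equal(f2, f3, tolerance = 1e-3)
})

test_that("mean abundance averages over used time points plus baseline", {
  expr <- tibble::tibble(gene = "a", `0` = 10, `1` = 20, `2` = 60)
  expect_equal(gene_stats(expr)$mean_abund, 30)
  expect_equal(gene_stats(expr, used_times = 1)$mean_abund, 15)
})
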