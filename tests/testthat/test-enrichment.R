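test_that("hypergeometric tail reproduces direct combinatorial counts", {
  expect_equal(hypergeometric_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeometric_tail(2, 4, 5, 10), 186 / 252, tolerance = 1e-12)
  expect_equal(
    hypergeometric_tail(4, 5, 4, 20), 5 / 4845,
    tolerance = 1e-12
  )
  expect_equal(hypergeometric_tail(4, 5, 4, 20), 1.0320e-3, tolerance = 1e-4)
  expect_error(hypergeometric_tail(5, 4, 5, 10), "impossible")
  expect_error(hypergeometric_tail(2, 4, 5, 4), "impossible")
})

test_that("hypergeometric tail agrees with enumeration over a small grid", {
  for (N in c(5, 12, 19)) {
    for (K in 0:N) {
      for (n in c(1, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(
            hypergeometric_tail(k, K, n, N),
            hyper_tail_enum(k, K, n, N),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  withr::with_seed(13, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_reference(p), tolerance = 1e-12)
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("module enrichment handles degenerate and disjoint terms", {
  part <- tibble::tibble(
    gene = c("a", "b", "c"),
    module = "M1"
  )
  class(part) <- c("module_partition", class(part))
  coll <- gene_set_collection(list(T1 = c("a", "b", "c")))
  rows <- enrich_module(part, coll,
    p_cutoff = 1, q_cutoff = 1,
    term_size_range = c(1, 500)
  )
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$p_value, 1)
  expect_equal(rows$k, 3L)

  disjoint <- gene_set_collection(list(T1 = c("x", "y", "z")))
  expect_error(
    enrich_module(part, disjoint, term_size_range = c(1, 500)),
    "empty universe"
  )

  mixed <- gene_set_collection(list(T1 = c("a", "x"), T2 = c("x", "y")))
  rows2 <- enrich_module(part, mixed,
    p_cutoff = 1, q_cutoff = 1,
    term_size_range = c(1, 500)
  )
  expect_equal(rows2$term, "T1") # T2 has zero overlap: untested
})

test_that("a planted term ranks first for its module with q below cutoff", {
  sim <- simulate_study(small_config(seed = 61))
  fit <- suppressWarnings(detect_modules(sim$study))
  suppressMessages(
    rows <- enrich_module(fit$partition, sim$gene_sets)
  )
  expect_gt(nrow(rows), 0)
  expect_true(all(rows$q_value <= 0.01))
  # each detected module's best term is one of the module-matched terms
  best <- rows |>
    dplyr::group_by(module) |>
    dplyr::slice_min(p_value, n = 1, with_ties = FALSE)
  expect_true(all(grepl("^T_M", best$term)))
  # p-values recompute through the oracle
  for (i in seq_len(nrow(rows))) {
    expect_equal(
      rows$p_value[i],
      hyper_tail_enum(rows$k[i], rows$term_size[i], rows$module_size[i],
        rows$universe_size[i]),
      tolerance = 1e-10
    )
  }
})

test_that("enrichment is invariant under gene relabeling", {
  sim <- simulate_study(small_config(seed = 62))
  fit <- suppressWarnings(detect_modules(sim$study))
  suppressMessages(rows <- enrich_module(fit$partition, sim$gene_sets))

  relabel <- setNames(
    sprintf("x%04d", seq_along(fit$partition$gene)), fit$partition$gene
  )
  part2 <- tibble::tibble(
    gene = unname(relabel[fit$partition$gene]),
    module = fit$partition$module
  )
  class(part2) <- c("module_partition", class(part2))
  sets2 <- lapply(sim$gene_sets$sets, function(s) unname(relabel[s]))
  suppressMessages(
    rows2 <- enrich_module(part2, gene_set_collection(sets2))
  )
  expect_equal(rows$p_value, rows2$p_value, tolerance = 1e-12)
  expect_equal(rows$term, rows2$term)
})

test_that("cross-module term counts deduplicate and sort", {
  rows <- tibble::tibble(
    module = c("M1", "M3", "M1", "M2"),
    term = c("T1", "T1", "T2", "T1")
  )
  counts <- cross_module_term_counts(rows)
  expect_equal(counts$term, c("T1", "T2"))
  expect_equal(counts$n_modules, c(3L, 1L))
  expect_equal(counts, cross_module_term_counts(rows[c(3, 1, 4, 2), ]))
  expect_equal(nrow(cross_module_term_counts(rows[0, ])), 0L)
})
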