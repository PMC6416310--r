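test_that("correlation matrix reproduces hand-computed Pearson values", {
  m <- rbind(
    x = c(1, 2, 3),
    y = c(1, 2, 4),
    x2 = c(1, 2, 3),
    neg = c(-1, -2, -3)
  )
  r <- correlation_matrix(m)
  expect_equal(r["x", "y"], 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(r["x", "y"], 0.9819805, tolerance = 1e-7)
  expect_equal(r["x", "x2"], 1)
  expect_equal(r["x", "neg"], -1)
  expect_true(isSymmetric(r))

  m_const <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(correlation_matrix(m_const), "a")
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
})

test_that("adjacency applies unsigned and signed soft thresholds", {
  r <- matrix(c(1, -0.8, -0.8, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  a6 <- adjacency(r, 6)
  expect_equal(a6["a", "b"], 0.8^6, tolerance = 1e-12)
  expect_equal(a6["a", "b"], 0.262144, tolerance = 1e-9)
  expect_equal(unname(diag(a6)), c(0, 0))

  a1 <- adjacency(r, 1)
  expect_equal(a1["a", "b"], 0.8)

  r_neg <- matrix(c(1, -1, -1, 1), 2, dimnames = dimnames(r))
  for (p in c(1, 3, 7)) {
    expect_equal(adjacency(r_neg, p, signed = TRUE)["a", "b"], 0)
  }
  expect_error(adjacency(r, 0), "positive integer")
})

test_that("unsigned adjacency is invariant to flipping a gene's sign", {
  sim <- simulate_expression(small_config(seed = 21))
  v <- sim$study$values[1:30, ]
  v_flipped <- v
  v_flipped[c(3, 17), ] <- -v_flipped[c(3, 17), ]
  a <- adjacency(correlation_matrix(v), 6)
  b <- adjacency(correlation_matrix(v_flipped), 6)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("scale-free fit recovers an exact power law and signs its R^2", {
  # connectivities at 1, 2, 4, 8 with counts proportional to k^-2
  k <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  fit <- suppressWarnings(scale_free_fit(k, n_bins = 10))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-12)

  increasing <- rep(c(1, 2, 4, 8), times = c(1, 4, 16, 64))
  expect_lte(suppressWarnings(scale_free_fit(increasing, n_bins = 10))$r2, 0)

  expect_error(scale_free_fit(rep(3, 10)), "degenerate")
})

test_that("scale-free fit equals an independent least-squares recomputation", {
  withr::with_seed(404, {
    a <- matrix(runif(40 * 40), 40)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    fit <- scale_free_fit(a, n_bins = 10)
    k <- rowSums(a)
    breaks <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, breaks, include.lowest = TRUE, labels = FALSE)
    mk <- tapply(k, bin, mean)
    fr <- tapply(k, bin, length) / length(k)
    x <- log10(mk)
    y <- log10(fr)
    beta <- cov(x, y) / var(x)
    r2 <- cor(x, y)^2
    expect_equal(abs(fit$r2), r2, tolerance = 1e-10)
    expect_equal(fit$slope, beta, tolerance = 1e-10)
  })
})

test_that("soft power selection follows the smallest-qualifying rule", {
  sim <- simulate_expression(small_config(seed = 31))
  corr <- correlation_matrix(center_by_group(sim$study))
  scan <- suppressWarnings(select_soft_power(corr, n_samples = 20))
  chosen <- attr(scan, "chosen_power")
  expect_true(chosen %in% scan$power)
  qualifying <- scan$power[scan$scale_free_r2 >= 0.85]
  if (length(qualifying) > 0L) {
    expect_equal(chosen, qualifying[1L])
  } else {
    # fallback: the sample-size default (8 at 20 samples, unsigned)
    expect_equal(chosen, 8L)
    expect_warning(select_soft_power(corr, n_samples = 20), "sample-size")
  }
  # mean connectivity must shrink as the power grows
  expect_true(all(diff(scan$mean_connectivity) <= 0))

  scan2 <- suppressWarnings(select_soft_power(corr, n_samples = 20))
  expect_identical(attr(scan2, "chosen_power"), chosen)
})

test_that("TOM matches hand-evaluated cases and the brute-force oracle", {
  triangle <- matrix(1, 3, 3) - diag(3)
  tom <- tom_similarity(triangle)
  expect_equal(tom[1, 2], (1 + 1) / (2 + 1 - 1))
  expect_equal(diag(tom), rep(1, 3))

  isolated <- matrix(0, 2, 2)
  expect_equal(tom_similarity(isolated)[1, 2], 0)

  withr::with_seed(77, {
    for (n in c(5, 20, 50)) {
      a <- matrix(runif(n * n), n)
      a <- (a + t(a)) / 2
      diag(a) <- 0
      expect_equal(tom_similarity(a), tom_reference(a), tolerance = 1e-10)
    }
  })

  expect_error(tom_similarity(matrix(c(0, 2, 2, 0), 2)), "\\[0, 1\\]")
})

test_that("average-linkage dendrogram is monotone and matches a naive oracle", {
  withr::with_seed(5, {
    sim <- matrix(runif(36, 0, 0.9), 6)
    sim <- (sim + t(sim)) / 2
  })
  diag(sim) <- 1
  dimnames(sim) <- list(paste0("g", 1:6), paste0("g", 1:6))
  dend <- cluster_dendrogram(sim)
  expect_true(all(diff(dend$height) >= -1e-12))
  expect_equal(
    sort(dend$height),
    sort(average_linkage_heights(1 - sim)),
    tolerance = 1e-12
  )

  twin <- rbind(c(1, 1, 0.1), c(1, 1, 0.1), c(0.1, 0.1, 1))
  dimnames(twin) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(cluster_dendrogram(twin)$height[1L], 0)
  expect_error(cluster_dendrogram(sim[1, 1, drop = FALSE]), "at least 2")
})

test_that("module cut labels by size and respects the minimum size", {
  sim <- simulate_expression(small_config(seed = 41))
  tom <- tom_similarity(
    adjacency(correlation_matrix(center_by_group(sim$study)), 8)
  )
  dend <- cluster_dendrogram(tom)

  part <- cut_modules(dend, cut_height = 1, min_module_size = 1)
  expect_equal(unique(part$module), "M1")

  part_none <- cut_modules(dend, 0.95, min_module_size = nrow(tom) + 1)
  expect_equal(unique(part_none$module), "unassigned")

  part_def <- cut_modules(dend, 0.95, 30)
  sizes <- module_sizes(part_def)
  assigned <- sizes[sizes$module != "unassigned", ]
  expect_true(all(diff(assigned$size) <= 0))
  expect_true(all(assigned$size >= 30))
  expect_equal(sum(sizes$size), nrow(part_def))
})

test_that("oversized-module filter drops blocks at the size threshold", {
  part <- tibble::tibble(
    gene = sprintf("g%03d", 1:700),
    module = rep(c("M1", "M2", "M3"), c(600, 60, 40))
  )
  class(part) <- c("module_partition", class(part))
  suppressMessages(filtered <- filter_modules(part, max_module_size = 500))
  sizes <- module_sizes(filtered)
  expect_equal(sizes$size[sizes$module == "unassigned"], 600L)
  expect_setequal(
    sizes$module[sizes$module != "unassigned"], c("M1", "M2")
  )
  expect_equal(max(sizes$size[sizes$module != "unassigned"]), 60L)

  identity <- filter_modules(part, max_module_size = Inf)
  expect_equal(identity$module, part$module)
})

test_that("a 22-module partition with one oversized block keeps 21", {
  sizes <- c(600L, seq(150, 50, length.out = 21))
  part <- tibble::tibble(
    gene = sprintf("g%04d", seq_len(sum(sizes))),
    module = rep(paste0("M", seq_along(sizes)), sizes)
  )
  class(part) <- c("module_partition", class(part))
  suppressMessages(filtered <- filter_modules(part, 500))
  kept <- setdiff(unique(filtered$module), "unassigned")
  expect_length(kept, 21L)
})

test_that("module detection is deterministic on identical input", {
  sim <- simulate_expression(small_config(seed = 51))
  f1 <- suppressWarnings(detect_modules(sim$study))
  f2 <- suppressWarnings(detect_modules(sim$study))
  expect_identical(f1$partition, f2$partition)
  expect_identical(f1$power, f2$power)
})

test_that("dendrogram exports as readable Newick text", {
  sim <- simulate_expression(small_config(seed = 52))
  tom <- tom_similarity(
    adjacency(correlation_matrix(center_by_group(sim$study)), 8)
  )
  dend <- cluster_dendrogram(tom)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(dend, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, sim$study$genes)
})
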