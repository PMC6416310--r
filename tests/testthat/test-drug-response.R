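test_that("differential expression calls planted shifts and spares nulls", {
  sim <- simulate_expression(small_config(seed = 81))
  de <- differential_expression(sim$study, "model", "healthy")
  planted <- c(sim$truth$true_disease_up, sim$truth$true_disease_down)
  called <- de$feature[de$direction != "ns"]
  expect_gte(mean(planted %in% called), 0.8)
  # planted direction is respected
  up_rows <- de[de$feature %in% sim$truth$true_disease_up, ]
  expect_true(all(up_rows$direction %in% c("up", "ns")))
  # null features rarely called
  nulls <- setdiff(de$feature, planted)
  expect_lte(mean(nulls %in% called), 0.05)
})

test_that("a feature identical across groups is never called", {
  sim <- simulate_expression(small_config(seed = 82))
  v <- sim$study$values
  v["g0001", ] <- 5
  v["g0002", ] <- seq_len(ncol(v)) # varies but identically per sample order
  study <- expression_study(v, sim$study$design)
  suppressMessages(
    de <- differential_expression(study, "model", "healthy", method = "welch")
  )
  expect_equal(de$direction[de$feature == "g0001"], "ns")
  expect_equal(de$p_value[de$feature == "g0001"], 1)
})

test_that("welch and moderated tests agree on strong effects", {
  sim <- simulate_expression(small_config(seed = 83, disease_log2fc = 4))
  w <- differential_expression(sim$study, "model", "healthy", method = "welch")
  m <- differential_expression(sim$study, "model", "healthy")
  planted <- c(sim$truth$true_disease_up, sim$truth$true_disease_down)
  expect_gte(mean(planted %in% w$feature[w$direction != "ns"]), 0.8)
  expect_gte(mean(planted %in% m$feature[m$direction != "ns"]), 0.8)
  expect_equal(w$log2_fold_change, m$log2_fold_change, tolerance = 1e-12)
})

test_that("reversal target sets follow the directional intersections", {
  mk <- function(features, dirs) {
    tibble::tibble(
      feature = features, log2_fold_change = 0, t_statistic = 0,
      p_value = 0.5, q_value = 0.5, direction = dirs
    )
  }
  disease <- mk(c("A", "B", "C", "D", "E"),
    c("up", "up", "up", "down", "down"))
  treatment <- mk(c("A", "B", "C", "D", "E"),
    c("down", "down", "ns", "up", "down"))
  ts <- reversal_targets(disease, treatment, "drugX")
  expect_equal(ts$inhibited, c("A", "B"))
  expect_equal(ts$promoted, "D")
  expect_length(intersect(ts$inhibited, ts$promoted), 0L)

  none <- reversal_targets(disease, mk("Z", "up"), "drugY")
  expect_length(none$inhibited, 0L)
  expect_length(none$promoted, 0L)

  g <- glance(ts)
  expect_equal(g$n_targets, g$n_inhibited + g$n_promoted)
})

test_that("reversal is symmetric under negating all fold changes", {
  sim <- simulate_expression(small_config(seed = 84))
  de_d <- differential_expression(sim$study, "model", "healthy")
  de_t <- differential_expression(sim$study, "drug_A", "model")
  flip <- function(rows) {
    rows$log2_fold_change <- -rows$log2_fold_change
    rows$direction <- c(up = "down", down = "up", ns = "ns")[rows$direction]
    rows
  }
  ts <- reversal_targets(de_d, de_t, "d")
  ts_flipped <- reversal_targets(flip(de_d), flip(de_t), "d")
  expect_equal(ts$inhibited, ts_flipped$promoted)
  expect_equal(ts$promoted, ts_flipped$inhibited)
})

test_that("targets map onto modules and overlap reported pivots", {
  part <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    module = c("M1", "M1", "M2", "unassigned")
  )
  class(part) <- c("module_partition", class(part))
  ts <- structure(
    list(drug = "d", inhibited = c("A", "D"), promoted = "C"),
    class = "target_sets"
  )
  pivots <- tibble::tibble(
    regulator = c("C", "r9"), regulator_class = "TF",
    module = "M1", k = 2L, n_reg = 3L, K_mod = 4L, N_bg = 10L,
    p_value = 1e-4
  )
  report <- map_targets_to_modules(ts, part, pivots)
  expect_equal(report$modules_hit, 2L)
  expect_equal(report$targets_in_modules$M1, "A")
  expect_equal(report$targets_in_modules$M2, "C")
  expect_equal(report$pivot_overlap, "C")

  off <- structure(
    list(drug = "d", inhibited = "zz", promoted = character(0)),
    class = "target_sets"
  )
  expect_equal(map_targets_to_modules(off, part)$modules_hit, 0L)

  all_m1 <- structure(
    list(drug = "d", inhibited = c("A", "B"), promoted = character(0)),
    class = "target_sets"
  )
  rep2 <- map_targets_to_modules(all_m1, part)
  expect_equal(rep2$modules_hit, 1L)
  expect_equal(rep2$targets_in_modules$M1, c("A", "B"))
})

test_that("groups with fewer than two samples are rejected", {
  sim <- simulate_expression(small_config(seed = 85))
  design <- sim$study$design
  design$group[design$group == "healthy"][-1L] <- "spare"
  study <- expression_study(sim$study$values, design)
  expect_error(
    differential_expression(study, "model", "healthy"),
    "at least 2 samples"
  )
})
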