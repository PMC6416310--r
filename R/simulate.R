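#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study generator.
#' The defaults describe the reference study used throughout the test suite:
#' five planted 100-gene co-expression modules at within-module Pearson
#' correlation 0.7 plus 100 unstructured background genes, four sample groups
#' (healthy control, disease model, and two simulated treatments) of five
#' samples each, 50 disease genes shifted by +/- 2 log2 units in every
#' non-healthy group, with 60% of the disease shift exactly cancelled in each
#' treatment group; 30 module-specific regulators (80% of targets inside the
#' assigned module) against 200 null regulators; and a 300-protein network
#' with 5 planted hubs over a sparse random background.
#'
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per planted module (`n_modules * module_size`
#'   must not exceed `n_genes`; the remainder are background genes).
#' @param within_module_correlation Target expected pairwise Pearson
#'   correlation between genes of the same module, in (0, 1).
#' @param n_samples_per_group Samples per group.
#' @param groups Group labels; the first is the healthy reference, the second
#'   the disease model, any further labels are treatments.
#' @param n_disease_genes Number of module genes receiving a disease shift
#'   (half up, half down).
#' @param disease_log2fc Magnitude of the disease shift on the log2-like scale.
#' @param reversal_fraction Fraction of disease genes whose shift is exactly
#'   cancelled in each treatment group.
#' @param noise_sd Marginal per-gene standard deviation around the group
#'   mean, shared by all genes; module genes split it into a shared factor
#'   part and residual noise (see [simulate_expression()]).
#' @param n_regulators Number of module-specific ("true pivot") regulators.
#' @param n_null_regulators Number of regulators drawing targets uniformly.
#' @param targets_per_regulator Distinct targets drawn per regulator.
#' @param regulator_module_specificity Fraction of a true regulator's targets
#'   drawn from its assigned module, in \[0, 1\].
#' @param n_random_sets,random_set_size,module_set_extra Gene-set collection
#'   shape: decoy terms, their size, and the number of off-module genes mixed
#'   into each module-derived term.
#' @param ppi_n_nodes Number of proteins in the interaction network.
#' @param ppi_n_hubs Number of planted hub proteins.
#' @param hub_degree Neighbours wired to each hub.
#' @param ppi_mean_degree Mean background degree of the random graph.
#' @param baseline Baseline abundance added to every value.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600,
                       n_modules = 5,
                       module_size = 100,
                       within_module_correlation = 0.7,
                       n_samples_per_group = 5,
                       groups = c("healthy", "model", "drug_A", "drug_B"),
                       n_disease_genes = 50,
                       disease_log2fc = 2,
                       reversal_fraction = 0.6,
                       noise_sd = 0.5,
                       n_regulators = 30,
                       n_null_regulators = 200,
                       targets_per_regulator = 20,
                       regulator_module_specificity = 0.8,
                       n_random_sets = 20,
                       random_set_size = 50,
                       module_set_extra = 20,
                       ppi_n_nodes = 300,
                       ppi_n_hubs = 5,
                       hub_degree = 50,
                       ppi_mean_degree = 4,
                       baseline = 8,
                       seed = 1L) {
  cfg <- as.list(environment())
  errors <- character()
  chk <- function(ok, msg) {
    if (!ok) errors <<- c(errors, msg)
  }
  for (f in c(
    "n_genes", "n_modules", "module_size", "n_samples_per_group",
    "n_disease_genes", "targets_per_regulator", "ppi_n_nodes"
  )) {
    chk(is_count(cfg[[f]]), sprintf("`%s` must be a positive integer", f))
  }
  for (f in c("n_regulators", "n_null_regulators", "ppi_n_hubs", "hub_degree",
              "n_random_sets")) {
    chk(
      length(cfg[[f]]) == 1L && is.numeric(cfg[[f]]) && cfg[[f]] >= 0 &&
        cfg[[f]] == floor(cfg[[f]]),
      sprintf("`%s` must be a non-negative integer", f)
    )
  }
  chk(
    is.numeric(cfg$within_module_correlation) &&
      cfg$within_module_correlation > 0 && cfg$within_module_correlation < 1,
    "`within_module_correlation` must lie in (0, 1)"
  )
  chk(is_prob(cfg$reversal_fraction), "`reversal_fraction` must lie in [0, 1]")
  chk(
    is_prob(cfg$regulator_module_specificity),
    "`regulator_module_specificity` must lie in [0, 1]"
  )
  chk(
    is.numeric(cfg$noise_sd) && cfg$noise_sd > 0,
    "`noise_sd` must be positive"
  )
  chk(
    length(cfg$groups) >= 2L && !anyDuplicated(cfg$groups),
    "`groups` needs at least healthy and model labels, without duplicates"
  )
  if (is_count(cfg$n_modules) && is_count(cfg$module_size) &&
    is_count(cfg$n_genes)) {
    chk(
      cfg$n_modules * cfg$module_size <= cfg$n_genes,
      "n_modules * module_size must not exceed n_genes"
    )
  }
  if (is_count(cfg$n_disease_genes) && is_count(cfg$n_genes)) {
    chk(
      cfg$n_disease_genes <= cfg$n_modules * cfg$module_size,
      "n_disease_genes must not exceed the number of module genes"
    )
  }
  chk(
    length(cfg$seed) == 1L && is.numeric(cfg$seed) &&
      cfg$seed == floor(cfg$seed),
    "`seed` must be an integer"
  )
  if (length(errors) > 0L) {
    stop_mp("invalid simulation config:\n- %s", paste(errors, collapse = "\n- "))
  }
  structure(cfg, class = "sim_config")
}

pad_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}

#' Simulate an expression study with planted structure
#'
#' Genes of module *m* share a latent factor: `value = baseline +
#' loading * factor_m + noise`. `noise_sd` is every gene's marginal standard
#' deviation around its group mean; for module genes it splits into the
#' shared factor component (`loading = noise_sd * sqrt(r)`) and residual
#' noise (`sd = noise_sd * sqrt(1 - r)`), so the expected within-module
#' Pearson correlation `loading^2 / (loading^2 + resid_sd^2)` equals
#' `within_module_correlation` exactly.
#' Background genes are pure noise with the same marginal variance. Disease
#' genes (drawn from module genes, half up, half down) receive a
#' `+/- disease_log2fc` shift in every non-healthy group; in each treatment
#' group a `reversal_fraction` of them has that shift exactly cancelled.
#'
#' @param config A [sim_config()].
#' @return A list with elements `study` (an [expression_study()]) and `truth`
#'   (list with `true_module_of`, `true_disease_up`, `true_disease_down`,
#'   `true_reversed`, a per-treatment list of reversed gene sets).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    genes <- pad_ids("g", config$n_genes)
    n_mod_genes <- config$n_modules * config$module_size
    module_of <- rep("unassigned", config$n_genes)
    module_of[seq_len(n_mod_genes)] <-
      rep(paste0("M", seq_len(config$n_modules)), each = config$module_size)
    names(module_of) <- genes

    groups <- rep(config$groups, each = config$n_samples_per_group)
    samples <- sprintf(
      "%s_%d", groups,
      rep(seq_len(config$n_samples_per_group), times = length(config$groups))
    )
    n_samples <- length(samples)

    # noise_sd is the marginal per-gene sd around the group mean; for module
    # genes it splits into a shared factor component (variance r * sd^2) and
    # residual noise ((1 - r) * sd^2), so the expected within-module
    # correlation is exactly r = loading^2 / (loading^2 + resid_sd^2).
    r <- config$within_module_correlation
    loading <- config$noise_sd * sqrt(r)
    resid_sd <- config$noise_sd * sqrt(1 - r)
    gene_sd <- config$noise_sd

    # Factor realizations are orthogonalized against the group-indicator
    # space and against each other, then scaled to unit sample variance:
    # planted modules are distinct expression patterns by construction and
    # carry no group-mean component (group contrasts are planted separately
    # through the disease shift).
    group_design <- stats::model.matrix(~ factor(groups))
    if (n_samples < ncol(group_design) + config$n_modules) {
      stop_mp(
        "need at least %d samples for %d orthogonal module factors over %d groups",
        ncol(group_design) + config$n_modules, config$n_modules,
        length(config$groups)
      )
    }
    raw <- matrix(rnorm(config$n_modules * n_samples), nrow = n_samples)
    resid <- stats::lm.fit(group_design, raw)$residuals
    factors <- t(qr.Q(qr(resid))) * sqrt(n_samples - 1)
    values <- matrix(
      rnorm(config$n_genes * n_samples, sd = resid_sd),
      nrow = config$n_genes,
      dimnames = list(genes, samples)
    )
    for (m in seq_len(config$n_modules)) {
      idx <- which(module_of == paste0("M", m))
      values[idx, ] <- values[idx, ] +
        matrix(loading * factors[m, ], length(idx), n_samples, byrow = TRUE)
    }
    bg <- which(module_of == "unassigned")
    if (length(bg) > 0L) {
      values[bg, ] <- matrix(
        rnorm(length(bg) * n_samples, sd = gene_sd),
        length(bg), n_samples, dimnames = list(genes[bg], samples)
      )
    }
    values <- values + config$baseline

    disease <- sample(genes[seq_len(n_mod_genes)], config$n_disease_genes)
    n_up <- ceiling(config$n_disease_genes / 2)
    up <- disease[seq_len(n_up)]
    down <- setdiff(disease, up)
    shift <- stats::setNames(numeric(config$n_genes), genes)
    shift[up] <- config$disease_log2fc
    shift[down] <- -config$disease_log2fc

    treatments <- config$groups[-(1:2)]
    reversed <- lapply(stats::setNames(treatments, treatments), function(d) {
      sort(sample(disease, round(config$reversal_fraction * length(disease))))
    })
    for (g in config$groups[-1L]) {
      cols <- which(groups == g)
      s <- shift
      if (g %in% treatments) {
        s[reversed[[g]]] <- 0
      }
      values[, cols] <- values[, cols] + s
    }

    study <- expression_study(
      values,
      tibble::tibble(sample = samples, group = groups)
    )
    truth <- list(
      true_module_of = module_of,
      true_disease_up = sort(up),
      true_disease_down = sort(down),
      true_reversed = reversed
    )
    list(study = study, truth = truth)
  })
}

#' Simulate a regulator-to-target interaction table
#'
#' True pivot regulators are assigned to planted modules round-robin and draw
#' `regulator_module_specificity * targets_per_regulator` of their targets
#' from the assigned module, the rest uniformly from all other genes; null
#' regulators draw all targets uniformly. Classes alternate between ncRNA and
#' TF so both scans are exercised. Scores are drawn in \[0.5, 1\] so the
#' default inclusive score filter keeps every row.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_expression()] (supplies the planted
#'   module memberships).
#' @return List with `interactions` (tibble: regulator, target, score,
#'   regulator_class) and `truth` (list with `true_pivot_regulators`, a named
#'   regulator -> module map, and `true_null_regulators`).
#' @export
simulate_interactions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  module_of <- truth$true_module_of
  genes <- names(module_of)
  n_specific <- round(config$regulator_module_specificity *
    config$targets_per_regulator)
  if (n_specific > config$module_size) {
    stop_mp(
      "module size %d smaller than requested %d module-specific targets",
      config$module_size, n_specific
    )
  }
  withr::with_seed(derive_seed(config$seed, 2L), {
    n_total <- config$n_regulators + config$n_null_regulators
    regs <- pad_ids("R", n_total)
    classes <- rep(c("ncRNA", "TF"), length.out = n_total)
    true_regs <- utils::head(regs, config$n_regulators)
    null_regs <- setdiff(regs, true_regs)
    module_labels <- paste0("M", seq_len(config$n_modules))
    assigned <- stats::setNames(
      rep(module_labels, length.out = length(true_regs)), true_regs
    )
    draw_targets <- function(reg) {
      if (reg %in% true_regs) {
        own <- genes[module_of == assigned[[reg]]]
        spec <- sample(own, n_specific)
        rest <- sample(
          setdiff(genes, spec),
          config$targets_per_regulator - n_specific
        )
        c(spec, rest)
      } else {
        sample(genes, config$targets_per_regulator)
      }
    }
    tab <- purrr::map2_dfr(regs, classes, function(reg, cls) {
      tibble::tibble(
        regulator = reg,
        target = draw_targets(reg),
        score = round(runif(config$targets_per_regulator, 0.5, 1), 4),
        regulator_class = cls
      )
    })
    list(
      interactions = tibble::as_tibble(stable_arrange(tab)),
      truth = list(
        true_pivot_regulators = assigned,
        true_null_regulators = null_regs
      )
    )
  })
}

#' Simulate a protein-protein interaction edge table with planted hubs
#'
#' Background edges form an Erdos-Renyi graph with mean degree
#' `ppi_mean_degree`; each of the first `ppi_n_hubs` proteins is additionally
#' wired to `hub_degree` random neighbours. Scores are drawn in (950, 1000)
#' so the strict default score threshold keeps every edge.
#'
#' @param config A [sim_config()].
#' @return List with `edges` (tibble: protein_a, protein_b, score), `nodes`
#'   (all protein identifiers) and `truth` (list with `true_hubs`).
#' @export
simulate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 3L), {
    nodes <- pad_ids("P", config$ppi_n_nodes)
    hubs <- utils::head(nodes, config$ppi_n_hubs)
    p_bg <- min(1, config$ppi_mean_degree / (config$ppi_n_nodes - 1))
    pairs <- utils::combn(nodes, 2L)
    keep <- runif(ncol(pairs)) < p_bg
    edges <- tibble::tibble(
      protein_a = pairs[1L, keep],
      protein_b = pairs[2L, keep]
    )
    hub_edges <- purrr::map_dfr(hubs, function(h) {
      nb <- sample(setdiff(nodes, h), config$hub_degree)
      tibble::tibble(protein_a = h, protein_b = nb)
    })
    edges <- dplyr::bind_rows(edges, hub_edges)
    edges$score <- round(runif(nrow(edges), 951, 999), 1)
    list(
      edges = ppi_edge_table(edges),
      nodes = nodes,
      truth = list(true_hubs = hubs)
    )
  })
}

#' Simulate a gene-set collection aligned with the planted modules
#'
#' One term per planted module (its genes diluted with `module_set_extra`
#' random off-module genes) plus `n_random_sets` decoy terms of
#' `random_set_size` random genes.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return A `gene_set_collection`.
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  module_of <- truth$true_module_of
  genes <- names(module_of)
  withr::with_seed(derive_seed(config$seed, 4L), {
    sets <- list()
    descriptions <- character()
    for (m in paste0("M", seq_len(config$n_modules))) {
      own <- genes[module_of == m]
      extra <- sample(setdiff(genes, own), config$module_set_extra)
      term <- paste0("T_", m)
      sets[[term]] <- c(own, extra)
      descriptions[[term]] <- sprintf("term matched to planted module %s", m)
    }
    for (i in seq_len(config$n_random_sets)) {
      term <- sprintf("T_rand%02d", i)
      sets[[term]] <- sample(genes, config$random_set_size)
      descriptions[[term]] <- "random decoy term"
    }
    gene_set_collection(sets, descriptions)
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator under one seed and optionally writes the expression
#' TSV, design TSV, interaction TSV, PPI TSV, GMT and a truth YAML to a
#' directory, mirroring the flat-file inputs of the analysis stages.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return A list with `study`, `interactions`, `ppi` (edges), `gene_sets`,
#'   `truth` (all truth elements merged) and, when `out_dir` is given,
#'   `paths`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  expr <- simulate_expression(config)
  inter <- simulate_interactions(config, expr$truth)
  ppi <- simulate_ppi(config)
  sets <- simulate_gene_sets(config, expr$truth)
  truth <- c(expr$truth, inter$truth, ppi$truth)
  out <- list(
    study = expr$study,
    interactions = inter$interactions,
    ppi = ppi$edges,
    ppi_nodes = ppi$nodes,
    gene_sets = sets,
    truth = truth,
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      expression = file.path(out_dir, "expression.tsv"),
      design = file.path(out_dir, "design.tsv"),
      interactions = file.path(out_dir, "interactions.tsv"),
      ppi = file.path(out_dir, "ppi.tsv"),
      gmt = file.path(out_dir, "gene_sets.gmt"),
      truth = file.path(out_dir, "truth.yaml")
    )
    write_expression(expr$study, paths$expression, paths$design)
    write_table(inter$interactions, paths$interactions)
    write_table(ppi$edges, paths$ppi)
    write_gmt(sets, paths$gmt)
    yaml::write_yaml(
      list(
        true_module_of = as.list(truth$true_module_of),
        true_disease_up = truth$true_disease_up,
        true_disease_down = truth$true_disease_down,
        true_reversed = truth$true_reversed,
        true_pivot_regulators = as.list(truth$true_pivot_regulators),
        true_null_regulators = truth$true_null_regulators,
        true_hubs = truth$true_hubs
      ),
      paths$truth
    )
    out$paths <- paths
  }
  out
}
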