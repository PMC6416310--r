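pipeline_defaults <- function() {
  list(
    expression = NULL,
    design = NULL,
    interactions = NULL,
    ppi = NULL,
    gmt = NULL,
    out_dir = NULL,
    ppi_nodes = NULL,
    power = "auto",
    signed = FALSE,
    r2_cutoff = 0.85,
    cut_height = 0.95,
    min_module_size = 30,
    max_module_size = 500,
    enrich_p = 0.01,
    enrich_q = 0.01,
    term_size_min = 10,
    term_size_max = 500,
    pivot_p = 0.01,
    min_pairs = 2,
    fc_cut = 1,
    q_cut = 0.05,
    de_method = "moderated",
    interaction_min_score = 0.5,
    ppi_min_score = 950,
    healthy_group = "healthy",
    disease_group = "model",
    treatment_groups = NULL,
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (suggesting the nearest known key),
#' and checks every parameter range, reporting all violations at once. The
#' defaults encode the pipeline's conventions: GO-style enrichment cutoffs
#' p = q = 0.01, pivot raw p < 0.01 with at least 2 interacting pairs,
#' interaction scores kept at >= 0.5 (inclusive), PPI scores kept at > 950
#' (strict), and oversized co-expression modules dropped at 500 genes.
#'
#' @param config Named list of overrides, or a path to a YAML file.
#' @return The completed config list, invisibly classed `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  for (key in unknown) {
    d <- utils::adist(key, names(defaults))
    suggestion <- names(defaults)[which.min(d)]
    errors <- c(errors, sprintf(
      "unknown key '%s'%s", key,
      if (min(d) <= 5) sprintf(" (did you mean '%s'?)", suggestion) else ""
    ))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  for (f in c("enrich_p", "enrich_q", "pivot_p", "q_cut")) {
    chk(is_prob(cfg[[f]]) && cfg[[f]] > 0,
      sprintf("`%s` out of range (0, 1]", f))
  }
  chk(is.numeric(cfg$cut_height) && cfg$cut_height > 0 && cfg$cut_height <= 1,
    "`cut_height` out of range (0, 1]")
  chk(is.numeric(cfg$r2_cutoff) && cfg$r2_cutoff <= 1,
    "`r2_cutoff` must be <= 1")
  for (f in c("min_module_size", "max_module_size", "min_pairs")) {
    chk(is_count(cfg[[f]]), sprintf("`%s` must be a positive integer", f))
  }
  chk(identical(cfg$power, "auto") || is_count(cfg$power),
    "`power` must be \"auto\" or a positive integer")
  chk(is.numeric(cfg$fc_cut) && cfg$fc_cut >= 0, "`fc_cut` must be >= 0")
  chk(cfg$de_method %in% c("moderated", "welch"),
    "`de_method` must be \"moderated\" or \"welch\"")
  for (f in c("interaction_min_score", "ppi_min_score")) {
    chk(is.numeric(cfg[[f]]) && is.finite(cfg[[f]]) && cfg[[f]] >= 0,
      sprintf("`%s` must be a finite non-negative number", f))
  }
  if (length(errors) > 0L) {
    stop_mp("invalid pipeline config:\n- %s", paste(errors, collapse = "\n- "))
  }
  invisible(structure(cfg, class = c("pipeline_config", "list")))
}

flatten_list_col <- function(df, col) {
  df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
  df
}

#' Run the full dysfunction-module pipeline
#'
#' Executes the five analytic stages in order — co-expression modules,
#' per-module gene-set enrichment, ncRNA/TF pivot scan, drug-reversal
#' targets for every treatment group, and the PPI hub/cluster stage — from
#' one configuration, writing every result table, a serialized copy of the
#' config, a deterministic run log and a manifest with MD5 content hashes to
#' `out_dir`. A rerun with identical config and inputs is byte-identical. A
#' stage failure aborts with the stage name and cause.
#'
#' @param config Named list or YAML path accepted by [validate_config()];
#'   must provide `expression`, `design`, `interactions`, `ppi`, `gmt` and
#'   `out_dir`.
#' @return Invisibly, a list with `manifest` (tibble: file, md5, n_rows),
#'   `results` (in-memory stage outputs) and `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  for (f in c("expression", "design", "interactions", "ppi", "gmt", "out_dir")) {
    if (is.null(cfg[[f]])) {
      stop_mp("pipeline config must set `%s`", f)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    mp_log("%s", line)
    log_lines <<- c(log_lines, line)
  }
  written <- character()
  emit <- function(rows, name) {
    path <- file.path(cfg$out_dir, name)
    write_table(rows, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mp("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  results <- list()

  stage("modules", {
    study <- read_expression(cfg$expression, cfg$design)
    note("modules: %d genes x %d samples", length(study$genes),
      length(study$samples))
    fit <- detect_modules(study,
      power = cfg$power, signed = cfg$signed,
      cut_height = cfg$cut_height, min_module_size = cfg$min_module_size,
      max_module_size = cfg$max_module_size, r2_cutoff = cfg$r2_cutoff
    )
    note("modules: soft power %d, %d modules retained", fit$power,
      glance(fit$partition)$n_modules)
    emit(tibble::as_tibble(fit$partition), "partition.tsv")
    if (!is.null(fit$scan)) {
      emit(tibble::as_tibble(fit$scan), "soft_threshold_scan.tsv")
    }
    write_dendrogram(fit$dendrogram, file.path(cfg$out_dir, "dendrogram.nwk"))
    written <- c(written, file.path(cfg$out_dir, "dendrogram.nwk"))
    results$study <- study
    results$fit <- fit
  })
  partition <- results$fit$partition

  stage("enrich", {
    collection <- read_gmt(cfg$gmt)
    rows <- enrich_module(partition, collection,
      p_cutoff = cfg$enrich_p, q_cutoff = cfg$enrich_q,
      term_size_range = c(cfg$term_size_min, cfg$term_size_max)
    )
    note("enrich: %d significant (module, term) rows", nrow(rows))
    emit(flatten_list_col(rows, "overlap_genes"), "enrichment.tsv")
    emit(cross_module_term_counts(rows), "term_counts.tsv")
    results$enrichment <- rows
  })

  stage("pivots", {
    interactions <- read_interactions(cfg$interactions,
      min_score = cfg$interaction_min_score
    )
    rows <- pivot_scan(interactions, partition,
      p_cutoff = cfg$pivot_p, min_pairs = cfg$min_pairs
    )
    note("pivots: %d significant (regulator, module) pairs from %d regulators",
      nrow(rows), length(unique(rows$regulator)))
    emit(rows, "pivots.tsv")
    emit(flatten_list_col(core_regulators(rows), "modules"),
      "core_regulators.tsv")
    results$pivots <- rows
  })

  stage("targets", {
    study <- results$study
    groups <- unique(study$design$group)
    treatments <- cfg$treatment_groups %||%
      setdiff(groups, c(cfg$healthy_group, cfg$disease_group))
    disease_de <- differential_expression(study, cfg$disease_group,
      cfg$healthy_group, fc_cut = cfg$fc_cut, q_cut = cfg$q_cut,
      method = cfg$de_method
    )
    emit(disease_de, "de_disease.tsv")
    target_rows <- list()
    report_rows <- list()
    for (drug in treatments) {
      treat_de <- differential_expression(study, drug, cfg$disease_group,
        fc_cut = cfg$fc_cut, q_cut = cfg$q_cut, method = cfg$de_method
      )
      emit(treat_de, sprintf("de_%s.tsv", drug))
      ts <- reversal_targets(disease_de, treat_de, drug)
      note("targets: %s has %d inhibited + %d promoted",
        drug, length(ts$inhibited), length(ts$promoted))
      report <- map_targets_to_modules(ts, partition, results$pivots)
      target_rows[[drug]] <- tidy(ts)
      report_rows[[drug]] <- tidy(report)
      results$targets[[drug]] <- ts
      results$module_reports[[drug]] <- report
    }
    emit(dplyr::bind_rows(target_rows), "targets.tsv")
    emit(dplyr::bind_rows(report_rows), "target_modules.tsv")
  })

  stage("ppi", {
    edges <- read_ppi(cfg$ppi)
    subset <- if (!is.null(cfg$ppi_nodes)) {
      readr::read_lines(cfg$ppi_nodes, progress = FALSE)
    } else {
      NULL
    }
    graph <- build_graph(edges, node_subset = subset,
      min_score = cfg$ppi_min_score)
    note("ppi: %d nodes, %d edges above score %s", length(graph$nodes),
      nrow(graph$edges), format(cfg$ppi_min_score))
    emit(hub_ranking(graph), "ppi_degrees.tsv")
    clusters <- connected_clusters(graph)
    emit(
      tibble::tibble(
        cluster = rep(seq_along(clusters), lengths(clusters)),
        node = unlist(clusters) %||% character(0)
      ),
      "ppi_clusters.tsv"
    )
    write_sif(graph$edges, file.path(cfg$out_dir, "ppi_network.sif"))
    written <- c(written, file.path(cfg$out_dir, "ppi_network.sif"))
    results$graph <- graph
  })

  config_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), config_path)
  log_path <- file.path(cfg$out_dir, "run.log")
  readr::write_lines(log_lines, log_path)
  written <- c(written, config_path, log_path)

  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  ) |>
    dplyr::arrange(.data$file)
  write_table(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  results$manifest <- manifest
  invisible(list(manifest = manifest, results = results, config = cfg))
}
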