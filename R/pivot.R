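#' Pivot scan: regulators significantly wired into modules
#'
#' For each regulator class present in the interaction table, the background
#' is the set of distinct targets of that class's table; each
#' (regulator, module) pair is then tested by [hypergeometric_tail()] with
#' `k` = regulator targets inside the module, `K` = module genes in the
#' background, `n` = regulator targets in the background, `N` = background
#' size. A pair is reported when it has at least `min_pairs` interacting
#' pairs into the module and raw `p < p_cutoff` (no multiple-testing
#' correction by default, matching the raw-p convention of pivot analysis;
#' set `bh = TRUE` to add a BH-adjusted column and filter on it instead).
#' Self-targeting rows are dropped and `"unassigned"` genes are never a
#' module.
#'
#' @param interactions Tibble with columns `regulator`, `target`,
#'   `regulator_class` (from [read_interactions()] or
#'   [simulate_interactions()]).
#' @param partition A `module_partition`.
#' @param p_cutoff Raw p-value cutoff. Default 0.01.
#' @param min_pairs Minimum interacting pairs into the module. Default 2.
#' @param bh Filter on BH-adjusted q-values instead of raw p.
#' @return Tibble with columns `regulator`, `regulator_class`, `module`,
#'   `k`, `n_reg`, `K_mod`, `N_bg`, `p_value` (and `q_value` when
#'   `bh = TRUE`), sorted by p-value.
#' @export
pivot_scan <- function(interactions, partition, p_cutoff = 0.01,
                       min_pairs = 2, bh = FALSE) {
  if (nrow(interactions) == 0L) {
    stop_mp("interaction table is empty")
  }
  modules <- setdiff(unique(partition$module), "unassigned")
  if (length(modules) == 0L) {
    stop_mp("partition contains no module")
  }
  interactions <- dplyr::filter(
    interactions, .data$regulator != .data$target
  )
  module_of <- stats::setNames(partition$module, partition$gene)
  out <- interactions |>
    dplyr::group_split(.data$regulator_class) |>
    purrr::map_dfr(function(tab) {
      background <- unique(tab$target)
      mappable <- intersect(background, partition$gene)
      if (length(mappable) == 0L) {
        stop_mp(
          "no mappable targets: class '%s' background is disjoint from the partition",
          tab$regulator_class[[1L]]
        )
      }
      n_bg <- length(background)
      k_mod <- table(factor(
        module_of[intersect(background, names(module_of))],
        levels = modules
      ))
      targets_of <- split(tab$target, tab$regulator)
      purrr::imap_dfr(targets_of, function(targets, reg) {
        targets <- unique(targets)
        mods <- module_of[intersect(targets, names(module_of))]
        hits <- table(factor(mods[mods %in% modules], levels = modules))
        keep <- names(hits)[hits >= min_pairs]
        if (length(keep) == 0L) {
          return(NULL)
        }
        tibble::tibble(
          regulator = reg,
          regulator_class = tab$regulator_class[[1L]],
          module = keep,
          k = as.integer(hits[keep]),
          n_reg = length(targets),
          K_mod = as.integer(k_mod[keep]),
          N_bg = n_bg,
          p_value = hypergeometric_tail(
            as.integer(hits[keep]), as.integer(k_mod[keep]),
            length(targets), n_bg
          )
        )
      })
    })
  if (nrow(out) == 0L) {
    return(empty_pivot(bh))
  }
  if (bh) {
    out$q_value <- bh_adjust(out$p_value)
    out <- dplyr::filter(out, .data$q_value < .env$p_cutoff)
  } else {
    out <- dplyr::filter(out, .data$p_value < .env$p_cutoff)
  }
  dplyr::arrange(out, .data$p_value, .data$regulator, .data$module)
}

empty_pivot <- function(bh = FALSE) {
  out <- tibble::tibble(
    regulator = character(), regulator_class = character(),
    module = character(), k = integer(), n_reg = integer(),
    K_mod = integer(), N_bg = integer(), p_value = numeric()
  )
  if (bh) out$q_value <- numeric()
  out
}

#' Rank core regulators by modules driven
#'
#' @param rows Output of [pivot_scan()].
#' @param top_n Number of regulators to return (default all).
#' @return Tibble with columns `regulator`, `regulator_class`,
#'   `modules_driven`, `modules` (list column of deduplicated module
#'   labels), sorted by descending `modules_driven`, ties by regulator.
#' @export
core_regulators <- function(rows, top_n = Inf) {
  if (nrow(rows) == 0L) {
    return(tibble::tibble(
      regulator = character(), regulator_class = character(),
      modules_driven = integer(), modules = list()
    ))
  }
  rows |>
    dplyr::distinct(.data$regulator, .data$regulator_class, .data$module) |>
    dplyr::group_by(.data$regulator, .data$regulator_class) |>
    dplyr::summarise(
      modules_driven = dplyr::n(),
      modules = list(sort(.data$module)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$modules_driven), .data$regulator) |>
    utils::head(n = top_n)
}
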