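#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items without
#' replacement from a universe of `N` containing `K` marked items. This is
#' the over-representation p-value shared by the module enrichment and pivot
#' stages.
#'
#' @param k Observed overlap.
#' @param K Marked items in the universe (term size / module targets).
#' @param n Draws (module size / regulator targets).
#' @param N Universe size.
#' @return The exact upper-tail probability.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  bad <- !(k >= 0 & K >= 0 & n >= 0 & N >= 0 & K <= N & n <= N &
    k <= pmin(K, n))
  if (any(bad)) {
    stop_mp("impossible hypergeometric counts (need 0 <= k <= min(K, n) <= N)")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)` on the sorted
#' p-values, mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return Vector of BH-adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) {
    return(numeric(0))
  }
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop_mp("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-module gene-set over-representation
#'
#' Tests every (module, term) pair with overlap `k >= 1` by
#' [hypergeometric_tail()], adjusts p-values by BH within each module's
#' family of tested terms, and keeps rows with `p <= p_cutoff` and
#' `q <= q_cutoff`. The `"unassigned"` label is never tested. The default
#' universe is the partition's genes intersected with the genes annotated
#' anywhere in the collection; pass `universe` for an explicit background.
#' Terms outside `term_size_range` (after intersection with the universe)
#' are skipped.
#'
#' @param partition A `module_partition`.
#' @param collection A `gene_set_collection`.
#' @param p_cutoff,q_cutoff Row-retention cutoffs (GO-style defaults 0.01;
#'   use 0.05 / 0.2 for pathway-style screens).
#' @param universe Optional explicit background gene vector.
#' @param term_size_range Length-2 numeric: minimum and maximum universe-
#'   intersected term size tested.
#' @param keep_all Return all tested rows, ignoring the cutoffs.
#' @return Tibble with columns `module`, `term`, `description`, `k`,
#'   `term_size`, `module_size`, `universe_size`, `p_value`, `q_value`,
#'   `overlap_genes` (list column), sorted by module then p-value.
#' @export
enrich_module <- function(partition, collection, p_cutoff = 0.01,
                          q_cutoff = 0.01, universe = NULL,
                          term_size_range = c(10, 500), keep_all = FALSE) {
  if (nrow(partition) == 0L || length(collection$sets) == 0L) {
    stop_mp("partition and collection must be non-empty")
  }
  annotated <- unique(unlist(collection$sets, use.names = FALSE))
  universe <- if (is.null(universe)) {
    intersect(partition$gene, annotated)
  } else {
    unique(as.character(universe))
  }
  if (length(universe) == 0L) {
    stop_mp("empty universe: no partition gene is annotated in the collection")
  }
  sets <- lapply(collection$sets, intersect, y = universe)
  sizes <- lengths(sets)
  in_range <- sizes >= term_size_range[1L] & sizes <= term_size_range[2L]
  if (any(!in_range)) {
    mp_log(
      "enrichment: skipped %d term(s) outside size range [%d, %d]",
      sum(!in_range), term_size_range[1L], term_size_range[2L]
    )
  }
  sets <- sets[in_range]
  n_universe <- length(universe)
  modules <- setdiff(unique(partition$module), "unassigned")
  modules <- modules[order(as.integer(sub("^M", "", modules)))]
  rows <- purrr::map_dfr(modules, function(m) {
    mod_genes <- intersect(module_genes(partition, m), universe)
    if (length(mod_genes) == 0L) {
      return(NULL)
    }
    tested <- purrr::map_dfr(names(sets), function(term) {
      overlap <- intersect(mod_genes, sets[[term]])
      if (length(overlap) == 0L) {
        return(NULL)
      }
      tibble::tibble(
        module = m,
        term = term,
        description = unname(collection$description[term]),
        k = length(overlap),
        term_size = length(sets[[term]]),
        module_size = length(mod_genes),
        universe_size = n_universe,
        p_value = hypergeometric_tail(
          length(overlap), length(sets[[term]]), length(mod_genes), n_universe
        ),
        overlap_genes = list(sort(overlap))
      )
    })
    if (nrow(tested) == 0L) {
      return(NULL)
    }
    tested$q_value <- bh_adjust(tested$p_value)
    tested
  })
  if (nrow(rows) == 0L) {
    return(empty_enrichment())
  }
  rows <- dplyr::relocate(rows, "q_value", .after = "p_value")
  if (!keep_all) {
    rows <- dplyr::filter(
      rows,
      .data$p_value <= .env$p_cutoff, .data$q_value <= .env$q_cutoff
    )
  }
  dplyr::arrange(rows, .data$module, .data$p_value, .data$term)
}

empty_enrichment <- function() {
  tibble::tibble(
    module = character(), term = character(), description = character(),
    k = integer(), term_size = integer(), module_size = integer(),
    universe_size = integer(), p_value = numeric(), q_value = numeric(),
    overlap_genes = list()
  )
}

#' Count modules enriched per term
#'
#' @param rows Output of [enrich_module()].
#' @return Tibble with columns `term` and `n_modules`, sorted by descending
#'   count, ties by term.
#' @export
cross_module_term_counts <- function(rows) {
  if (nrow(rows) == 0L) {
    return(tibble::tibble(term = character(), n_modules = integer()))
  }
  rows |>
    dplyr::distinct(.data$term, .data$module) |>
    dplyr::count(.data$term, name = "n_modules") |>
    dplyr::arrange(dplyr::desc(.data$n_modules), .data$term)
}
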