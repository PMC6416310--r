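#' Gene-gene Pearson correlation matrix
#'
#' @param study An [expression_study()] or a numeric gene-by-sample matrix
#'   with row names.
#' @return Symmetric correlation matrix with unit diagonal, genes in rows and
#'   columns.
#' @export
correlation_matrix <- function(study) {
  values <- if (inherits(study, "expression_study")) study$values else study
  if (!is.matrix(values) || is.null(rownames(values))) {
    stop_mp("expected an expression_study or a named numeric matrix")
  }
  if (ncol(values) < 3L) {
    stop_mp("correlation needs at least 3 samples")
  }
  v <- apply(values, 1L, var)
  if (any(v == 0)) {
    stop_mp(
      "zero-variance gene: '%s' (remove constant genes first)",
      rownames(values)[which(v == 0)[1L]]
    )
  }
  r <- cor(t(values))
  diag(r) <- 1
  r
}

#' Centre an expression study within sample groups
#'
#' Subtracts each gene's per-group mean, so correlations computed afterwards
#' reflect co-variation within groups rather than group-mean differences.
#' Recommended whenever samples span disease/treatment groups: without it,
#' genes sharing a group response (e.g. the disease signature) correlate
#' regardless of co-regulation and can contaminate module detection.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] with group-centred values.
#' @export
center_by_group <- function(study) {
  values <- study$values
  groups <- group_of(study)
  for (g in unique(groups)) {
    cols <- names(groups)[groups == g]
    values[, cols] <- values[, cols] - rowMeans(values[, cols, drop = FALSE])
  }
  expression_study(values, study$design)
}

#' Soft-thresholded adjacency
#'
#' Raises correlations to a power so network connectivity approximates a
#' scale-free (power-law) degree distribution. Unsigned mode uses
#' `|r|^power`; signed mode uses `((1 + r) / 2)^power`, which sends perfect
#' negative correlation to zero. The diagonal is zeroed so row sums are node
#' connectivities.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param power Positive integer soft-thresholding power.
#' @param signed Use the signed transformation. Default unsigned.
#' @return Symmetric adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency <- function(corr, power, signed = FALSE) {
  if (!is_count(power)) {
    stop_mp("`power` must be a positive integer")
  }
  a <- if (signed) ((1 + corr) / 2)^power else abs(corr)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a network's connectivity distribution
#'
#' Bins node connectivities `k = rowSums(adjacency)` into `n_bins`
#' equal-width bins and regresses `log10` of the per-bin frequency on
#' `log10` of the per-bin mean connectivity over occupied bins. The returned
#' `r2` is signed: negated when the fitted slope is positive, so only
#' decreasing (power-law-like) relations score near 1.
#'
#' @param adjacency Adjacency matrix with zero diagonal, or a numeric vector
#'   of node connectivities.
#' @param n_bins Number of equal-width connectivity bins.
#' @return List with `r2` (signed) and `slope`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- if (is.matrix(adjacency)) rowSums(adjacency) else as.numeric(adjacency)
  if (length(unique(k)) == 1L) {
    stop_mp("degenerate connectivity: all nodes have identical k")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE, labels = FALSE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- is.finite(mean_k) & freq > 0 & mean_k > 0
  if (sum(ok) < 2L) {
    stop_mp("need at least 2 occupied connectivity bins")
  }
  fit <- lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  slope <- unname(coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r2 = if (slope > 0) -r2 else r2, slope = slope)
}

#' Scan candidate soft powers and pick one by scale-free fit
#'
#' Chooses the smallest candidate power whose signed scale-free fit reaches
#' `r2_cutoff`. When none qualifies the fit curve carries no usable
#' optimum (it typically keeps rising as the power shrinks all
#' connectivities), so the fallback is the field's sample-size-based default
#' power when `n_samples` is supplied (unsigned: 9 below 20 samples, 8 for
#' 20-29, 7 for 30-39, 6 from 40; doubled for signed networks), otherwise
#' the power maximising the fit; both fallbacks warn.
#'
#' @param corr Correlation matrix.
#' @param candidate_powers Sorted positive integer powers to scan.
#' @param r2_cutoff Signed R-squared required to accept a power.
#' @param signed Passed to [adjacency()].
#' @param n_bins Passed to [scale_free_fit()].
#' @param n_samples Number of samples behind `corr`; enables the
#'   sample-size-based fallback.
#' @return A `soft_threshold_scan`: tibble with columns `power`,
#'   `scale_free_r2`, `slope`, `mean_connectivity`; the selected power is in
#'   attribute `chosen_power` (also reported by [glance()]).
#' @export
select_soft_power <- function(corr, candidate_powers = 1:20, r2_cutoff = 0.85,
                              signed = FALSE, n_bins = 10, n_samples = NULL) {
  if (length(candidate_powers) == 0L || is.unsorted(candidate_powers)) {
    stop_mp("`candidate_powers` must be non-empty and sorted")
  }
  rows <- purrr::map_dfr(candidate_powers, function(p) {
    a <- adjacency(corr, p, signed = signed)
    fit <- scale_free_fit(a, n_bins = n_bins)
    tibble::tibble(
      power = as.integer(p),
      scale_free_r2 = fit$r2,
      slope = fit$slope,
      mean_connectivity = mean(rowSums(a))
    )
  })
  hit <- which(rows$scale_free_r2 >= r2_cutoff)
  if (length(hit) > 0L) {
    chosen <- rows$power[hit[1L]]
  } else if (!is.null(n_samples)) {
    default <- if (n_samples < 20) 9L else if (n_samples < 30) 8L
    else if (n_samples < 40) 7L else 6L
    if (signed) default <- 2L * default
    chosen <- rows$power[which.min(abs(rows$power - default))]
    warning(sprintf(
      "no candidate power reached scale-free R^2 >= %s; using the sample-size default power %d",
      format(r2_cutoff), chosen
    ), call. = FALSE)
  } else {
    chosen <- rows$power[which.max(rows$scale_free_r2)]
    warning(sprintf(
      "no candidate power reached scale-free R^2 >= %s; using power %d (max R^2 = %.3f)",
      format(r2_cutoff), chosen, max(rows$scale_free_r2)
    ), call. = FALSE)
  }
  structure(
    rows,
    chosen_power = chosen,
    r2_cutoff = r2_cutoff,
    class = c("soft_threshold_scan", class(rows))
  )
}

#' @export
glance.soft_threshold_scan <- function(x, ...) {
  chosen <- attr(x, "chosen_power")
  row <- x[x$power == chosen, , drop = FALSE]
  tibble::tibble(
    chosen_power = chosen,
    scale_free_r2 = row$scale_free_r2,
    slope = row$slope,
    mean_connectivity = row$mean_connectivity,
    r2_cutoff = attr(x, "r2_cutoff")
  )
}

#' Topological overlap similarity
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is set to 1
#' by convention. Two genes score high when they are directly connected
#' and/or share neighbours.
#'
#' @param adjacency Symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  if (any(adjacency < 0 | adjacency > 1)) {
    stop_mp("adjacency values must lie in [0, 1]")
  }
  if (any(diag(adjacency) != 0)) {
    stop_mp("adjacency diagonal must be zero")
  }
  l <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  min_k <- outer(k, k, pmin)
  tom <- (l + adjacency) / (min_k + 1 - adjacency)
  diag(tom) <- 1
  tom
}

#' Average-linkage dendrogram on topological-overlap dissimilarity
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @return An [stats::hclust] tree built on `1 - TOM` with average linkage.
#' @export
cluster_dendrogram <- function(tom) {
  if (nrow(tom) < 2L) {
    stop_mp("need at least 2 genes to cluster")
  }
  hclust(stats::as.dist(1 - tom), method = "average")
}

#' Export a gene dendrogram as Newick text
#'
#' @param dendrogram Tree from [cluster_dendrogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}

new_module_partition <- function(gene, module) {
  out <- tibble::tibble(gene = gene, module = module)
  class(out) <- c("module_partition", class(out))
  out
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- module_sizes(x)
  cat(sprintf(
    "<module_partition> %d genes, %d modules (+ %d unassigned)\n",
    nrow(x), sum(sizes$module != "unassigned"),
    sum(x$module == "unassigned")
  ))
  NextMethod()
}

#' Module sizes of a partition
#'
#' @param partition A `module_partition`.
#' @return Tibble with columns `module` and `size`, modules first in label
#'   order, `unassigned` last.
#' @export
module_sizes <- function(partition) {
  counts <- dplyr::count(tibble::as_tibble(partition), .data$module,
    name = "size"
  )
  assigned <- counts[counts$module != "unassigned", , drop = FALSE]
  assigned <- assigned[order(as.integer(sub("^M", "", assigned$module))), ]
  dplyr::bind_rows(assigned, counts[counts$module == "unassigned", ])
}

#' Genes of one module
#'
#' @param partition A `module_partition`.
#' @param label Module label.
#' @return Character vector of gene identifiers.
#' @export
module_genes <- function(partition, label) {
  partition$gene[partition$module == label]
}

#' @export
tidy.module_partition <- function(x, ...) {
  module_sizes(x)
}

#' @export
glance.module_partition <- function(x, ...) {
  sizes <- module_sizes(x)
  tibble::tibble(
    n_genes = nrow(x),
    n_modules = sum(sizes$module != "unassigned"),
    n_unassigned = sum(x$module == "unassigned"),
    largest_module = max(c(sizes$size[sizes$module != "unassigned"], 0L))
  )
}

#' Cut a dendrogram into modules
#'
#' Cuts the tree at `cut_height` on the `1 - TOM` scale; clusters smaller
#' than `min_module_size` become `"unassigned"`. Surviving modules are
#' labelled `M1, M2, ...` in decreasing size order, ties broken by the
#' lexicographically smallest member gene.
#'
#' @param dendrogram Tree from [cluster_dendrogram()].
#' @param cut_height Static cut height in (0, 1\].
#' @param min_module_size Minimum genes per retained module.
#' @return A `module_partition`: tibble with columns `gene`, `module`.
#' @export
cut_modules <- function(dendrogram, cut_height = 0.95, min_module_size = 30) {
  if (!is.numeric(cut_height) || cut_height <= 0 || cut_height > 1) {
    stop_mp("`cut_height` must lie in (0, 1]")
  }
  if (!is_count(min_module_size)) {
    stop_mp("`min_module_size` must be a positive integer")
  }
  cl <- cutree(dendrogram, h = cut_height)
  genes <- dendrogram$labels
  tab <- split(genes, cl)
  keep <- tab[lengths(tab) >= min_module_size]
  ord <- order(
    -lengths(keep),
    vapply(keep, function(g) min(sort(g, method = "radix")), character(1)),
    method = "radix"
  )
  keep <- keep[ord]
  module <- stats::setNames(rep("unassigned", length(genes)), genes)
  for (i in seq_along(keep)) {
    module[keep[[i]]] <- paste0("M", i)
  }
  new_module_partition(genes, unname(module[genes]))
}

#' Drop oversized modules
#'
#' Modules with at least `max_module_size` genes are relabelled
#' `"unassigned"`; surviving modules are renumbered `M1, M2, ...` preserving
#' their original order. The removed modules are logged.
#'
#' @param partition A `module_partition`.
#' @param max_module_size Size at and above which a module is dropped.
#' @return A `module_partition`.
#' @export
filter_modules <- function(partition, max_module_size = 500) {
  sizes <- module_sizes(partition)
  over <- sizes$module[sizes$module != "unassigned" &
    sizes$size >= max_module_size]
  if (length(over) > 0L) {
    mp_log(
      "removed %d oversized module(s) (>= %d genes): %s",
      length(over), max_module_size, paste(over, collapse = ", ")
    )
  }
  keep <- sizes$module[sizes$module != "unassigned" &
    sizes$size < max_module_size]
  relabel <- stats::setNames(paste0("M", seq_along(keep)), keep)
  module <- ifelse(
    partition$module %in% keep,
    unname(relabel[partition$module]),
    "unassigned"
  )
  new_module_partition(partition$gene, module)
}

#' Detect co-expression modules end to end
#'
#' Correlation, soft-power selection (unless `power` is given), adjacency,
#' topological overlap, average-linkage clustering, static cut, and the
#' oversized-module filter, in one call.
#'
#' @param study An [expression_study()].
#' @param power `"auto"` (select by scale-free fit) or a positive integer.
#' @param signed Signed adjacency.
#' @param center_groups Centre the matrix within sample groups before
#'   correlating (see [center_by_group()]). Default `TRUE`.
#' @param cut_height,min_module_size Passed to [cut_modules()].
#' @param max_module_size Passed to [filter_modules()].
#' @param candidate_powers,r2_cutoff Passed to [select_soft_power()].
#' @return List of class `coexpression_fit` with `partition`
#'   (`module_partition`), `scan` (`soft_threshold_scan` or `NULL`), `power`,
#'   `dendrogram`.
#' @export
detect_modules <- function(study, power = "auto", signed = FALSE,
                           center_groups = TRUE,
                           cut_height = 0.95, min_module_size = 30,
                           max_module_size = 500,
                           candidate_powers = 1:20, r2_cutoff = 0.85) {
  if (center_groups && inherits(study, "expression_study")) {
    study <- center_by_group(study)
  }
  corr <- correlation_matrix(study)
  scan <- NULL
  if (identical(power, "auto")) {
    n_samples <- if (inherits(study, "expression_study")) {
      length(study$samples)
    } else {
      ncol(study)
    }
    scan <- select_soft_power(corr, candidate_powers, r2_cutoff,
      signed = signed, n_samples = n_samples
    )
    power <- attr(scan, "chosen_power")
  }
  adj <- adjacency(corr, power, signed = signed)
  tom <- tom_similarity(adj)
  dend <- cluster_dendrogram(tom)
  partition <- cut_modules(dend, cut_height, min_module_size) |>
    filter_modules(max_module_size)
  structure(
    list(partition = partition, scan = scan, power = power, dendrogram = dend),
    class = "coexpression_fit"
  )
}

#' @export
print.coexpression_fit <- function(x, ...) {
  cat(sprintf("<coexpression_fit> soft power %d\n", x$power))
  print(x$partition)
  invisible(x)
}

#' @export
tidy.coexpression_fit <- function(x, ...) {
  tibble::as_tibble(x$partition)
}

#' @export
glance.coexpression_fit <- function(x, ...) {
  dplyr::mutate(glance(x$partition), power = x$power, .before = 1L)
}
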