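#' Per-feature differential expression between two groups
#'
#' Tests every feature on the stored (log2-like) scale with
#' `log2_fold_change = mean(group_a) - mean(group_b)` and BH adjustment
#' within the contrast. The default `"moderated"` method is the
#' empirical-Bayes moderated t-test (limma), which borrows variance
#' information across features — the standard choice at the few-samples-per-
#' group sizes these studies run at; `"welch"` gives the plain Welch
#' two-sample t-test. A feature is called `up` when `q <= q_cut` and
#' `log2_fold_change >= fc_cut`, `down` symmetrically, otherwise `ns`.
#' Under `"welch"`, features with zero variance in both groups get `p = 1`
#' when the means are equal and `p = 0` otherwise, with a logged count.
#' Applies identically to transcript and protein abundance tables.
#'
#' @param study An [expression_study()] (genes or proteins in rows).
#' @param group_a Contrast group (e.g. `"model"`, or a treatment).
#' @param group_b Reference group (e.g. `"healthy"`, or `"model"`).
#' @param fc_cut Absolute log2 fold-change cutoff. Default 1.
#' @param q_cut BH q-value cutoff. Default 0.05.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Tibble with columns `feature`, `log2_fold_change`, `t_statistic`,
#'   `p_value`, `q_value`, `direction`.
#' @export
differential_expression <- function(study, group_a, group_b,
                                    fc_cut = 1, q_cut = 0.05,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  groups <- group_of(study)
  cols_a <- names(groups)[groups == group_a]
  cols_b <- names(groups)[groups == group_b]
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    stop_mp(
      "each group needs at least 2 samples (got %d '%s', %d '%s')",
      length(cols_a), group_a, length(cols_b), group_b
    )
  }
  xa <- study$values[, cols_a, drop = FALSE]
  xb <- study$values[, cols_b, drop = FALSE]
  lfc <- rowMeans(xa) - rowMeans(xb)
  if (method == "moderated") {
    x <- cbind(xa, xb)
    design <- cbind(
      intercept = 1,
      contrast = rep(c(1, 0), c(ncol(xa), ncol(xb)))
    )
    fit <- limma::eBayes(limma::lmFit(x, design))
    tt <- fit$t[, "contrast"]
    p <- fit$p.value[, "contrast"]
  } else {
    na <- ncol(xa)
    nb <- ncol(xb)
    va <- apply(xa, 1L, var)
    vb <- apply(xb, 1L, var)
    se2 <- va / na + vb / nb
    tt <- lfc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(tt), df)
    degenerate <- se2 == 0
    if (any(degenerate)) {
      p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
      tt[degenerate] <-
        ifelse(lfc[degenerate] == 0, 0, Inf * sign(lfc[degenerate]))
      mp_log(
        "differential expression: %d feature(s) with zero variance in both groups",
        sum(degenerate)
      )
    }
  }
  q <- bh_adjust(p)
  tibble::tibble(
    feature = rownames(study$values),
    log2_fold_change = unname(lfc),
    t_statistic = unname(tt),
    p_value = unname(p),
    q_value = unname(q),
    direction = dplyr::case_when(
      q <= q_cut & lfc >= fc_cut ~ "up",
      q <= q_cut & lfc <= -fc_cut ~ "down",
      .default = "ns"
    )
  )
}

#' Directional drug-reversal target sets
#'
#' Inhibited targets are up-regulated in disease (model vs healthy) and
#' down-regulated by treatment (treated vs model); promoted targets are the
#' mirror case. The two sets are disjoint by construction: a feature cannot
#' be both up and down in the treatment contrast.
#'
#' @param disease_rows [differential_expression()] rows for model vs healthy.
#' @param treatment_rows [differential_expression()] rows for treated vs
#'   model.
#' @param drug_label Label attached to the result.
#' @return A list of class `target_sets` with elements `drug`, `inhibited`,
#'   `promoted` (sorted feature vectors).
#' @export
reversal_targets <- function(disease_rows, treatment_rows, drug_label) {
  dir_of <- function(rows, d) rows$feature[rows$direction == d]
  out <- list(
    drug = drug_label,
    inhibited = sort(intersect(
      dir_of(disease_rows, "up"), dir_of(treatment_rows, "down")
    )),
    promoted = sort(intersect(
      dir_of(disease_rows, "down"), dir_of(treatment_rows, "up")
    ))
  )
  stopifnot(length(intersect(out$inhibited, out$promoted)) == 0L)
  structure(out, class = "target_sets")
}

#' @export
print.target_sets <- function(x, ...) {
  cat(sprintf(
    "<target_sets> %s: %d inhibited + %d promoted = %d targets\n",
    x$drug, length(x$inhibited), length(x$promoted),
    length(x$inhibited) + length(x$promoted)
  ))
  invisible(x)
}

#' @export
tidy.target_sets <- function(x, ...) {
  tibble::tibble(
    drug = x$drug,
    feature = c(x$inhibited, x$promoted),
    class = rep(c("inhibited", "promoted"),
      c(length(x$inhibited), length(x$promoted))
    )
  )
}

#' @export
glance.target_sets <- function(x, ...) {
  tibble::tibble(
    drug = x$drug,
    n_inhibited = length(x$inhibited),
    n_promoted = length(x$promoted),
    n_targets = length(x$inhibited) + length(x$promoted)
  )
}

#' Place drug targets onto modules and pivots
#'
#' @param targets A `target_sets` from [reversal_targets()].
#' @param partition A `module_partition`.
#' @param pivots Optional [pivot_scan()] rows; targets that are themselves
#'   reported pivot regulators are collected in `pivot_overlap`.
#' @return A list of class `target_module_report` with `drug`,
#'   `targets_in_modules` (module -> sorted target vector, non-empty entries
#'   only, `"unassigned"` excluded), `modules_hit`, `pivot_overlap`.
#' @export
map_targets_to_modules <- function(targets, partition, pivots = NULL) {
  all_targets <- c(targets$inhibited, targets$promoted)
  hit <- partition[
    partition$gene %in% all_targets & partition$module != "unassigned", ,
    drop = FALSE
  ]
  by_module <- lapply(split(hit$gene, hit$module), sort)
  by_module <- by_module[order(as.integer(sub("^M", "", names(by_module))))]
  pivot_overlap <- if (is.null(pivots) || nrow(pivots) == 0L) {
    character(0)
  } else {
    sort(intersect(all_targets, unique(pivots$regulator)))
  }
  structure(
    list(
      drug = targets$drug,
      targets_in_modules = by_module,
      modules_hit = length(by_module),
      pivot_overlap = pivot_overlap
    ),
    class = "target_module_report"
  )
}

#' @export
print.target_module_report <- function(x, ...) {
  cat(sprintf(
    "<target_module_report> %s: %d target(s) in %d module(s); %d pivot overlap(s)\n",
    x$drug, sum(lengths(x$targets_in_modules)), x$modules_hit,
    length(x$pivot_overlap)
  ))
  invisible(x)
}

#' @export
tidy.target_module_report <- function(x, ...) {
  if (x$modules_hit == 0L) {
    return(tibble::tibble(
      drug = character(), module = character(), feature = character()
    ))
  }
  tibble::tibble(
    drug = x$drug,
    module = rep(names(x$targets_in_modules), lengths(x$targets_in_modules)),
    feature = unlist(x$targets_in_modules, use.names = FALSE)
  )
}
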