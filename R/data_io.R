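#' Construct an expression study
#'
#' Bundles a gene-by-sample abundance matrix (assumed to be on a log-like
#' scale already; no normalisation is performed) with its sample design.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with row
#'   and column names.
#' @param design Data frame with columns `sample` and `group`; every column of
#'   `values` must appear exactly once in `sample`.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (the matrix), `genes`, `samples`, and `design` (a tibble).
#' @export
expression_study <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_mp("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_mp("`values` must carry gene rownames and sample colnames")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop_mp("duplicate gene identifier: '%s'", dup[[1L]])
  }
  dup <- samples[duplicated(samples)]
  if (length(dup) > 0L) {
    stop_mp("duplicate sample identifier: '%s'", dup[[1L]])
  }
  design <- tibble::as_tibble(design)
  if (!all(c("sample", "group") %in% names(design))) {
    stop_mp("design must have columns `sample` and `group`")
  }
  missing <- setdiff(samples, design$sample)
  if (length(missing) > 0L) {
    stop_mp("sample '%s' present in matrix but absent from design", missing[[1L]])
  }
  design <- design[match(samples, design$sample), c("sample", "group")]
  if (!all(is.finite(values))) {
    bad <- rowSums(!is.finite(values)) > 0L
    mp_log("dropped %d gene(s) with missing values", sum(bad))
    values <- values[!bad, , drop = FALSE]
    genes <- rownames(values)
  }
  structure(
    list(values = values, genes = genes, samples = samples, design = design),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d genes x %d samples; groups: %s\n",
    length(x$genes), length(x$samples),
    paste(unique(x$design$group), collapse = ", ")
  ))
  invisible(x)
}

#' Group labels of an expression study
#'
#' @param study An [expression_study()].
#' @return Named character vector, sample -> group.
#' @export
group_of <- function(study) {
  stats::setNames(study$design$group, study$design$sample)
}

#' @export
tidy.expression_study <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    dplyr::left_join(x$design, by = "sample")
}

#' Read an expression matrix and its sample design
#'
#' The matrix file is a TSV whose header row names the samples and whose
#' first column names the genes. The design file is a TSV with columns
#' `sample` and `group`. Genes containing any missing value are dropped with
#' a logged count; duplicate identifiers and samples missing from the design
#' are hard errors.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(path, design_path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(expr) < 2L) {
    stop_mp("expression file needs a gene column plus at least one sample")
  }
  genes <- as.character(expr[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop_mp("duplicate gene identifier: '%s'", dup[[1L]])
  }
  values <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  expression_study(values, design)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term <TAB> description <TAB> member...`.
#' Duplicate members within a line are collapsed; a duplicated term
#' identifier or a line with fewer than three fields is an error.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of unique
#'   member vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_mp("GMT line %d has fewer than 3 fields", i)
    }
    term <- fields[[1L]]
    if (term %in% names(sets)) {
      stop_mp("duplicate term identifier '%s' at GMT line %d", term, i)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop_mp("GMT line %d defines an empty set", i)
    }
    sets[[term]] <- members
    descriptions[[term]] <- fields[[2L]]
  }
  gene_set_collection(sets, descriptions)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (term -> members).
#' @param description Optional named character vector of term descriptions.
#' @param universe Optional explicit background gene set.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL, universe = NULL) {
  if (length(sets) > 0L && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop_mp("all sets must be named")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) {
    stop_mp("empty gene sets are not allowed")
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(
    list(sets = sets, description = description, universe = universe),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d sets, median size %s\n",
    length(x$sets),
    if (length(x$sets)) stats::median(lengths(x$sets)) else "NA"
  ))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(term) {
    paste(c(term, collection$description[[term]], collection$sets[[term]]),
      collapse = "\t"
    )
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a scored regulator-to-target interaction table
#'
#' Rows with `score < min_score` are removed (inclusive threshold: a row at
#' exactly `min_score` is kept). Scores are taken on the file's native scale,
#' so the same reader serves 0-1 style interaction scores and 0-1000 style
#' database scores. Exact duplicate (regulator, target) pairs keep the
#' highest score.
#'
#' @param path TSV with columns `regulator`, `target`, `score`, and
#'   optionally `regulator_class`.
#' @param min_score Minimum score to keep (inclusive). Default 0.5.
#' @param regulator_class Class label (`"ncRNA"` or `"TF"`) applied to all
#'   rows when the file carries no `regulator_class` column.
#' @return A tibble with columns `regulator`, `target`, `score`,
#'   `regulator_class`.
#' @export
read_interactions <- function(path, min_score = 0.5, regulator_class = NULL) {
  raw <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("regulator", "target", "score") %in% names(raw))) {
    stop_mp("interaction file needs columns regulator, target, score")
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(!is.finite(score))
  if (length(bad) > 0L) {
    stop_mp("non-numeric score at line %d", bad[[1L]] + 1L)
  }
  tab <- tibble::tibble(
    regulator = raw$regulator,
    target = raw$target,
    score = score,
    regulator_class = if ("regulator_class" %in% names(raw)) {
      raw$regulator_class
    } else {
      regulator_class %||% NA_character_
    }
  )
  n0 <- nrow(tab)
  tab <- dplyr::filter(tab, .data$score >= .env$min_score)
  mp_log(
    "interactions: kept %d of %d rows at min_score >= %s",
    nrow(tab), n0, format(min_score)
  )
  tab |>
    dplyr::group_by(.data$regulator, .data$target) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    stable_arrange() |>
    tibble::as_tibble()
}

#' Read a scored protein-protein interaction edge table
#'
#' Self-loops are dropped; each undirected pair is stored once with its
#' endpoints in sorted order, keeping the maximum score across duplicates.
#' No score filter is applied at load time (see [build_graph()] for the
#' strict threshold).
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `score`.
#' @return Tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
read_ppi <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("protein_a", "protein_b", "score") %in% names(raw))) {
    stop_mp("PPI file needs columns protein_a, protein_b, score")
  }
  ppi_edge_table(raw)
}

#' Canonicalise a PPI edge table
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `score`.
#' @return Tibble with self-loops removed and undirected duplicates collapsed
#'   keeping the maximum score.
#' @export
ppi_edge_table <- function(edges) {
  edges <- tibble::as_tibble(edges)
  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  tab <- tibble::tibble(
    protein_a = pmin(a, b),
    protein_b = pmax(a, b),
    score = as.numeric(edges$score)
  )
  if (any(!is.finite(tab$score))) {
    stop_mp("non-finite PPI score")
  }
  tab |>
    dplyr::filter(.data$protein_a != .data$protein_b) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    stable_arrange() |>
    tibble::as_tibble()
}

#' Write a result table deterministically
#'
#' Rows are sorted by every column left to right with a locale-independent
#' radix sort, then written as UTF-8 TSV with `\n` line endings, so the same
#' rows always produce byte-identical files.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- stable_arrange(as.data.frame(rows, stringsAsFactors = FALSE))
  readr::write_tsv(tibble::as_tibble(rows), path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Write an expression study to disk
#'
#' @param study An [expression_study()].
#' @param path Path for the expression TSV.
#' @param design_path Path for the design TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(study, path, design_path) {
  tab <- tibble::as_tibble(study$values, rownames = "gene")
  readr::write_tsv(tab, path, eol = "\n", progress = FALSE)
  readr::write_tsv(study$design, design_path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Export an undirected network in SIF format
#'
#' @param edges Data frame whose first two columns are node identifiers.
#' @param path Output path.
#' @param relation Relation label placed in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, relation = "pp") {
  rows <- tibble::tibble(
    a = as.character(edges[[1L]]),
    rel = relation,
    b = as.character(edges[[2L]])
  )
  rows <- stable_arrange(rows)
  readr::write_lines(paste(rows$a, rows$rel, rows$b, sep = "\t"), path)
  invisible(path)
}
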