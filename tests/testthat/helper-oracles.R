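# Independent oracles used across the suite. Each reimplements the quantity
# from first principles (enumeration, explicit loops) and never calls the
# package path it checks.

# Upper-tail hypergeometric by direct combinatorial enumeration.
hyper_tail_enum <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Quadratic-time BH step-up reference.
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Explicit O(n^3) TOM recomputation.
tom_reference <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        out[i, j] <- 1
      } else {
        l <- 0
        for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
        out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      }
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# Naive average-linkage agglomeration; returns the sorted merge heights.
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Flood-fill connected components over an undirected edge list.
flood_fill_components <- function(nodes, edges_a, edges_b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_a)) {
    adj[[edges_a[i]]] <- c(adj[[edges_a[i]]], edges_b[i])
    adj[[edges_b[i]]] <- c(adj[[edges_b[i]]], edges_a[i])
  }
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Small, fast simulation used where full reference-study scale is unneeded.
small_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(
      n_genes = 150, n_modules = 3, module_size = 40,
      n_disease_genes = 20, n_regulators = 6, n_null_regulators = 20,
      ppi_n_nodes = 60, ppi_n_hubs = 2, hub_degree = 20,
      n_random_sets = 5, random_set_size = 20, module_set_extra = 10,
      seed = seed
    ),
    list(...)
  )
  do.call(sim_config, args)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
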