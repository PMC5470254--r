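#' Ontology term levels
#'
#' Level of each term in a DAG supplied as child-parent edges: the root has
#' level 1 and every other term has level `1 + min(level of parents)`
#' (shortest path to the root). Cycles are an error; terms with no path to
#' the root are dropped with a warning.
#'
#' @param edges Tibble with columns `term` and `parent`.
#' @param root Root term id; autodetected (the unique term appearing only as
#'   a parent) when `NULL`.
#' @return Tibble: `term`, `level`.
#' @export
term_levels <- function(edges, root = NULL) {
  if (!all(c("term", "parent") %in% names(edges))) {
    abort("edges need columns term and parent")
  }
  terms <- unique(c(edges$term, edges$parent))
  if (is.null(root)) {
    cand <- setdiff(edges$parent, edges$term)
    if (length(unique(cand)) != 1) {
      abort("cannot autodetect a single root; pass `root`")
    }
    root <- unique(cand)
  }
  detect_dag_cycle(edges)
  children <- split(edges$term, edges$parent)
  level <- setNames(rep(NA_integer_, length(terms)), terms)
  level[root] <- 1L
  frontier <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (p in frontier) {
      for (ch in children[[p]]) {
        if (is.na(level[ch])) {
          level[ch] <- level[p] + 1L
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  orphan <- names(level)[is.na(level)]
  if (length(orphan)) {
    warn(paste0(length(orphan), " orphan term(s) without a path to the root excluded"))
  }
  tibble(term = names(level), level = as.integer(level)) |>
    dplyr::filter(!is.na(.data$level))
}

detect_dag_cycle <- function(edges) {
  # Kahn-style leaf stripping on the term -> parent graph
  e <- unique(edges[, c("term", "parent")])
  repeat {
    sinks <- setdiff(e$parent, e$term)
    keep <- !(e$parent %in% sinks)
    if (all(keep)) break
    e <- e[keep, ]
  }
  if (nrow(e)) abort("cycle detected in term DAG")
  invisible(TRUE)
}

# A gene annotated to a term is annotated to all its ancestors.
propagate_annotations <- function(gene2term, edges) {
  if (!all(c("gene_id", "term") %in% names(gene2term))) {
    abort("gene2term needs columns gene_id and term")
  }
  parents <- split(edges$parent, edges$term)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    ps <- parents[[t]]
    out <- if (is.null(ps)) character(0) else {
      unique(c(ps, unlist(lapply(ps, ancestors))))
    }
    anc_cache[[t]] <- out
    out
  }
  expanded <- lapply(seq_len(nrow(gene2term)), function(i) {
    t <- gene2term$term[i]
    tibble(gene_id = gene2term$gene_id[i], term = c(t, ancestors(t)))
  })
  dplyr::distinct(dplyr::bind_rows(expanded))
}

#' GO-style term enrichment with a filtered Fisher test
#'
#' Annotations are propagated to ancestor terms, terms are filtered to those
#' of sufficient ontology level with an informative number of annotated genes
#' (by default level >= 5 and more than 10 but fewer than 1000 universe
#' genes), and each eligible term is tested for over-representation in the
#' gene set with a one-sided Fisher exact test (equivalently the
#' hypergeometric upper tail), followed by Benjamini-Hochberg adjustment.
#'
#' @param gene_set Character vector of genes of interest (subset of the
#'   universe).
#' @param universe Character vector of all considered genes.
#' @param gene2term Tibble `gene_id`, `term` (direct annotations).
#' @param edges Term DAG edges (`term`, `parent`).
#' @param config A [run_config()] (`go_min_level`, `go_min_genes`,
#'   `go_max_genes` are used).
#' @param root Optional DAG root (see [term_levels()]).
#' @return Tibble sorted by p-value: `term`, `level`, `k` (set genes with
#'   term), `n` (set size), `K` (universe genes with term), `N` (universe
#'   size), `p_value`, `p_adjust`.
#' @export
go_fisher <- function(gene_set, universe, gene2term, edges,
                      config = run_config(), root = NULL) {
  if (!length(universe)) abort("empty universe")
  universe <- unique(universe)
  gene_set <- unique(intersect(gene_set, universe))
  levels <- term_levels(edges, root = root)
  ann <- propagate_annotations(gene2term, edges) |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::semi_join(levels, by = "term")

  counts <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     k = dplyr::n_distinct(.data$gene_id[.data$gene_id %in% gene_set]),
                     .groups = "drop") |>
    dplyr::left_join(levels, by = "term") |>
    dplyr::filter(.data$level >= config$go_min_level,
                  .data$K > config$go_min_genes,
                  .data$K < config$go_max_genes)

  n <- length(gene_set)
  N <- length(universe)
  counts |>
    dplyr::mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      p_adjust = bh_fdr(.data$p_value)
    ) |>
    dplyr::select("term", "level", "k", "n", "K", "N", "p_value", "p_adjust") |>
    dplyr::arrange(.data$p_value, .data$term)
}

#' Physical clustering index of a gene set
#'
#' Within each genomic region, genes are sorted by start coordinate and
#' consecutive neighbours closer than `distance_bp` (start-to-start) are
#' counted; the index is that count divided by `n - 1` (or `n`, see
#' `denominator`), clamped to [0, 1]. An index of 1 means every gene lies
#' within the distance of its next nearest gene in the same region; 0 means
#' none does.
#'
#' @param genes Tibble with `start` and a region grouping column.
#' @param distance_bp Clustering distance (default 500 kb).
#' @param region_col Name of the grouping column (default `"region"`; a
#'   chromosome column works equally).
#' @param denominator `"n_minus_1"` (default) or `"n"`.
#' @return One-row tibble: `n_genes`, `n_linked`, `index` (`NA` when fewer
#'   than 2 genes).
#' @examples
#' g <- tibble::tibble(region = "r1", start = c(0, 1e5, 2e5))
#' clustering_index(g)  # index 1
#' @export
clustering_index <- function(genes, distance_bp = 5e5, region_col = "region",
                             denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  if (distance_bp <= 0) abort("distance_bp must be positive")
  if (!region_col %in% names(genes)) {
    abort(paste0("genes lack region column ", region_col))
  }
  n <- nrow(genes)
  if (n < 2) {
    return(tibble(n_genes = n, n_linked = NA_integer_, index = NA_real_))
  }
  linked <- genes |>
    dplyr::group_by(.data[[region_col]]) |>
    dplyr::summarise(
      pairs = sum(diff(sort(.data$start)) <= distance_bp),
      .groups = "drop"
    ) |>
    dplyr::pull(.data$pairs) |>
    sum()
  den <- if (denominator == "n_minus_1") n - 1 else n
  tibble(n_genes = n, n_linked = as.integer(linked),
         index = max(0, min(1, linked / den)))
}
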