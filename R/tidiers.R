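#' Tidy a gene-tree classification batch
#'
#' @param x A `redip_classification`.
#' @param ... Unused.
#' @return Tibble, one row per tree: `locus_id`, `class`, `n_events`,
#'   `event_branches` (semicolon-joined), `lineage_status`
#'   (semicolon-joined `lineage=status`), `notes`.
#' @export
tidy.redip_classification <- function(x, ...) {
  x$classifications |>
    dplyr::mutate(
      event_branches = purrr::map_chr(
        .data$events, ~ paste(.x$branch_id, collapse = ";")),
      lineage_status = purrr::map_chr(
        .data$lineage_status,
        ~ paste(paste0(names(.x), "=", .x), collapse = ";"))
    ) |>
    dplyr::select("locus_id", "class", "n_events", "event_branches",
                  "lineage_status", "notes")
}

#' @rdname tidy.redip_classification
#' @return `glance()` returns a one-row tibble with per-class counts, the
#'   decisive (LORe + AORe) fraction and the LORe share of decisive trees.
#' @export
glance.redip_classification <- function(x, ...) {
  n <- setNames(x$summary$n, x$summary$class)
  total <- sum(n)
  decisive <- n[["LORe"]] + n[["AORe"]]
  tibble(
    n_trees = total, n_lore = n[["LORe"]], n_aore = n[["AORe"]],
    n_ambiguous = n[["ambiguous"]], n_uninformative = n[["uninformative"]],
    n_error = n[["error"]],
    decisive_fraction = decisive / total,
    lore_fraction_decisive = if (decisive > 0) n[["LORe"]] / decisive else NA_real_
  )
}

#' Tidy a LORe/AORe group comparison
#'
#' @param x A `redip_grouptest` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `direction`,
#'   group medians and sizes.
#' @export
tidy.redip_grouptest <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value,
    method = if (x$exact) "wilcoxon_exact" else "wilcoxon_normal_approx",
    direction = x$direction,
    median_lore = x$median_lore, median_aore = x$median_aore,
    n_lore = x$n_lore, n_aore = x$n_aore, n_excluded = x$n_excluded
  )
}

#' @rdname tidy.redip_grouptest
#' @export
glance.redip_grouptest <- function(x, ...) {
  tidy.redip_grouptest(x)
}
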