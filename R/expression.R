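#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization factors correcting for sample
#' composition bias (reference sample chosen by upper quartile closest to the
#' mean upper quartile; 30% of extreme M-values and 5% of extreme A-values
#' trimmed; factors renormalized to geometric mean 1). Computed with
#' [edgeR::calcNormFactors()], whose defaults are exactly this procedure.
#'
#' @param counts Numeric count matrix (genes x samples), >= 2 samples, no
#'   all-zero sample.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort("need at least two samples")
  if (any(colSums(counts) == 0)) abort("all-zero sample in count matrix")
  if (any(counts < 0)) abort("negative counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / (libsize_s * factor_s) * 1e6`. With unit
#' factors this is plain library-size scaling; pass [tmm_factors()] output
#' for composition-corrected values.
#'
#' @param counts Count matrix (genes x samples).
#' @param factors Per-sample scaling factors (default all 1).
#' @return CPM matrix with the same dimnames.
#' @export
cpm_matrix <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs == 0)) abort("all-zero sample in count matrix")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (length(factors) != ncol(counts)) {
    abort("one scaling factor per sample required")
  }
  sweep(counts, 2, libs * factors, "/") * 1e6
}

#' Per-tissue expression profiles
#'
#' Pools replicates by the arithmetic mean of CPM within each tissue.
#'
#' @param cpm CPM matrix (genes x samples).
#' @param samples Sample metadata with `sample_id`, `tissue`; optional
#'   `condition` used by `condition_filter`.
#' @param condition_filter Optional condition to restrict samples to.
#' @return Tibble: `gene_id` plus one column per tissue.
#' @export
tissue_profile <- function(cpm, samples, condition_filter = NULL) {
  missing_meta <- setdiff(colnames(cpm), samples$sample_id)
  if (length(missing_meta)) {
    abort(paste0("sample(s) without metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  meta <- samples[match(colnames(cpm), samples$sample_id), ]
  keep <- rep(TRUE, ncol(cpm))
  if (!is.null(condition_filter) && "condition" %in% names(meta)) {
    keep <- meta$condition == condition_filter
  }
  tis <- unique(meta$tissue[keep])
  prof <- vapply(tis, function(t) {
    rowMeans(cpm[, keep & meta$tissue == t, drop = FALSE])
  }, numeric(nrow(cpm)))
  if (!is.matrix(prof)) {
    prof <- matrix(prof, nrow = 1, dimnames = list(NULL, tis))
  }
  as_tibble(prof) |>
    dplyr::mutate(gene_id = rownames(cpm), .before = 1)
}

profile_vector <- function(profiles, gene) {
  i <- match(gene, profiles$gene_id)
  if (is.na(i)) return(NULL)
  as.numeric(profiles[i, -1])
}

#' Pearson correlation between two expression profiles
#'
#' Standard product-moment correlation; returns `NA` (with the pair flagged
#' undefined downstream) when either vector is constant.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or `NA_real_`.
#' @examples
#' pair_correlation(c(1, 2, 3), c(1, 3, 2))
#' @export
pair_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("profiles differ in length")
  if (length(a) < 3) abort("need at least 3 shared dimensions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b, method = "pearson")
}

#' Per-tissue log2 fold-change between conditions
#'
#' `log2((mean CPM in 'treatment' + pc) / (mean CPM in 'reference' + pc))`
#' per tissue and gene; tissues missing either condition are skipped with a
#' warning.
#'
#' @param cpm CPM matrix.
#' @param samples Metadata with `sample_id`, `tissue`, `condition`.
#' @param treatment,reference Condition labels contrasted.
#' @param pseudocount Positive pseudo-count (default 0.5).
#' @return Tibble: `gene_id` plus one logFC column per usable tissue.
#' @export
response_logfc <- function(cpm, samples, treatment = "saltwater",
                           reference = "freshwater", pseudocount = 0.5) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (!"condition" %in% names(samples)) abort("samples lack a condition column")
  meta <- samples[match(colnames(cpm), samples$sample_id), ]
  out <- list(gene_id = rownames(cpm))
  for (t in unique(meta$tissue)) {
    trt <- meta$tissue == t & meta$condition == treatment
    ref <- meta$tissue == t & meta$condition == reference
    if (!any(trt) || !any(ref)) {
      warn(paste0("tissue ", t, " lacks a condition; skipped"))
      next
    }
    out[[t]] <- unname(
      log2((rowMeans(cpm[, trt, drop = FALSE]) + pseudocount) /
             (rowMeans(cpm[, ref, drop = FALSE]) + pseudocount)))
  }
  if (length(out) == 1) abort("no tissue has both conditions")
  as_tibble(out)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment ([stats::p.adjust()] with
#' `method = "BH"`).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values, monotone in rank order and never below raw p.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Compare correlation distributions between LORe and AORe pairs
#'
#' Two-sided Wilcoxon rank-sum test; exact enumeration when the smaller
#' group has at most 8 values and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections. Undefined correlations
#' are removed (and counted) before testing.
#'
#' @param r_lore,r_aore Numeric vectors of pair correlations.
#' @return Object of class `redip_grouptest` supporting [tidy()], [glance()]
#'   and [autoplot()]; elements include `statistic`, `p_value`, `direction`
#'   (sign of median(LORe) - median(AORe)) and the retained group values.
#' @export
compare_groups <- function(r_lore, r_aore) {
  n_excluded <- sum(is.na(r_lore)) + sum(is.na(r_aore))
  r_lore <- r_lore[!is.na(r_lore)]
  r_aore <- r_aore[!is.na(r_aore)]
  if (!length(r_lore) || !length(r_aore)) {
    abort("both groups must be non-empty after removing undefined correlations")
  }
  ties <- anyDuplicated(c(r_lore, r_aore)) > 0
  exact <- min(length(r_lore), length(r_aore)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(r_lore, r_aore, alternative = "two.sided",
                exact = exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         exact = exact,
         direction = sign(median(r_lore) - median(r_aore)),
         median_lore = median(r_lore), median_aore = median(r_aore),
         n_lore = length(r_lore), n_aore = length(r_aore),
         n_excluded = n_excluded,
         groups = list(LORe = r_lore, AORe = r_aore)),
    class = "redip_grouptest"
  )
}

#' @export
print.redip_grouptest <- function(x, ...) {
  cat("Wilcoxon rank-sum (", if (x$exact) "exact" else "normal approximation",
      "): W = ", x$statistic, ", P = ", format(x$p_value, digits = 3),
      "\nmedians: LORe ", round(x$median_lore, 3), " vs AORe ",
      round(x$median_aore, 3), " (", x$n_lore, "/", x$n_aore, " pairs, ",
      x$n_excluded, " undefined excluded)\n", sep = "")
  invisible(x)
}

#' Classify regulatory neofunctionalization of an ohnologue pair
#'
#' Compares each copy's tissue profile to the outgroup singleton (the proxy
#' for the ancestral expression pattern). If exactly one copy correlates with
#' the outgroup at or above the threshold, the other copy has acquired a new
#' pattern: regulatory neofunctionalization. Both above: conserved; both
#' below: both diverged; any undefined correlation: unclassifiable.
#'
#' @param copy1,copy2,outgroup Equal-length expression profiles.
#' @param threshold Correlation threshold (default 0.6).
#' @return One of `"conserved"`, `"neofunctionalized_copy1"`,
#'   `"neofunctionalized_copy2"`, `"both_diverged"`, `"unclassifiable"`.
#' @export
classify_neofunctionalization <- function(copy1, copy2, outgroup,
                                          threshold = 0.6) {
  if (length(copy1) != length(copy2) || length(copy1) != length(outgroup)) {
    abort("profiles differ in length")
  }
  r1 <- pair_correlation(copy1, outgroup)
  r2 <- pair_correlation(copy2, outgroup)
  if (is.na(r1) || is.na(r2)) return("unclassifiable")
  keep1 <- r1 >= threshold
  keep2 <- r2 >= threshold
  if (keep1 && keep2) "conserved"
  else if (keep1 && !keep2) "neofunctionalized_copy2"
  else if (!keep1 && keep2) "neofunctionalized_copy1"
  else "both_diverged"
}

#' Hypergeometric enrichment of neofunctionalized pairs in AORe regions
#'
#' Upper-tail hypergeometric probability that at least `k_aore_neo` of the
#' `n_neo` neofunctionalized pairs fall in AORe regions, given `K_aore_pairs`
#' AORe pairs among `N_pairs` classified pairs. Computed in log space via
#' [stats::phyper()].
#'
#' @param k_aore_neo Neofunctionalized pairs located in AORe regions.
#' @param n_neo Total neofunctionalized pairs (draws).
#' @param K_aore_pairs Total AORe pairs (successes in the population).
#' @param N_pairs Total classified pairs (population).
#' @return One-row tibble with the counts, background and observed AORe
#'   fractions, and the one-sided `p_value`.
#' @export
neofunct_enrichment <- function(k_aore_neo, n_neo, K_aore_pairs, N_pairs) {
  ok <- k_aore_neo >= 0 && n_neo <= N_pairs && K_aore_pairs <= N_pairs &&
    k_aore_neo <= min(n_neo, K_aore_pairs) &&
    n_neo - k_aore_neo <= N_pairs - K_aore_pairs
  if (!ok) abort("inconsistent hypergeometric counts")
  p <- phyper(k_aore_neo - 1, K_aore_pairs, N_pairs - K_aore_pairs, n_neo,
              lower.tail = FALSE)
  tibble(
    k_aore_neo = k_aore_neo, n_neo = n_neo,
    K_aore_pairs = K_aore_pairs, N_pairs = N_pairs,
    background_fraction = K_aore_pairs / N_pairs,
    observed_fraction = k_aore_neo / n_neo,
    p_value = p
  )
}

#' Mean pair correlation in genome windows
#'
#' Tiles each chromosome with non-overlapping windows and averages the
#' defined pair correlations whose first-copy midpoint falls inside each
#' window; windows containing no pairs are omitted.
#'
#' @param pair_div Tibble with `chrom`, `start`, `end` (first-copy
#'   coordinates) and a correlation column.
#' @param window_bp Window width in bp.
#' @param r_col Name of the correlation column (default `r_tissue`).
#' @param threshold Flagging threshold for `high_cor`.
#' @return Tibble: `chrom`, `window_start`, `window_end`, `n_pairs`,
#'   `mean_r`, `high_cor`.
#' @export
window_correlation <- function(pair_div, window_bp = 4e6, r_col = "r_tissue",
                               threshold = 0.6) {
  if (window_bp <= 0) abort("window_bp must be positive")
  df <- pair_div[!is.na(pair_div[[r_col]]) & !is.na(pair_div$start), ]
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), window_start = double(),
                  window_end = double(), n_pairs = integer(),
                  mean_r = double(), high_cor = logical()))
  }
  mid <- (df$start + df$end) %/% 2
  df |>
    dplyr::mutate(window_start = (mid %/% window_bp) * window_bp) |>
    dplyr::group_by(.data$chrom, .data$window_start) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_r = mean(.data[[r_col]]), .groups = "drop") |>
    dplyr::mutate(window_end = .data$window_start + window_bp,
                  high_cor = .data$mean_r >= threshold) |>
    dplyr::select("chrom", "window_start", "window_end", "n_pairs",
                  "mean_r", "high_cor")
}

#' Ohnologue pair divergence from count data
#'
#' End-to-end driver: TMM-normalizes counts, computes per-tissue profiles on
#' the log2(CPM + 1) scale, then per pair the tissue-profile correlation, the
#' regulatory-neofunctionalization status against the outgroup singleton,
#' and - when a condition design is supplied - the correlation of per-tissue
#' log2 fold-change responses.
#'
#' @param atlas_counts Tissue-atlas count matrix.
#' @param atlas_samples Its sample metadata.
#' @param pairs Tibble: `pair_id`, `copy1`, `copy2`, `outgroup` (gene ids),
#'   optional `region_class`, `chrom`, `start`, `end`.
#' @param smolt_counts,smolt_samples Optional condition-design counts and
#'   metadata (freshwater/saltwater).
#' @param config A [run_config()] (uses `correlation_threshold`,
#'   `pseudocount`).
#' @return Tibble, one row per pair: `pair_id`, `region_class`, `r_tissue`,
#'   `r_response`, `neofunct_status`, plus coordinates when given.
#' @export
pair_divergence <- function(atlas_counts, atlas_samples, pairs,
                            smolt_counts = NULL, smolt_samples = NULL,
                            config = run_config()) {
  f <- tmm_factors(atlas_counts)
  lcpm <- log2(cpm_matrix(atlas_counts, f) + 1)
  prof <- tissue_profile(lcpm, atlas_samples)

  lfc <- NULL
  if (!is.null(smolt_counts)) {
    fs <- tmm_factors(smolt_counts)
    scpm <- cpm_matrix(smolt_counts, fs)
    lfc <- response_logfc(scpm, smolt_samples, pseudocount = config$pseudocount)
  }

  res <- purrr::pmap(
    list(pairs$pair_id, pairs$copy1, pairs$copy2, pairs$outgroup),
    function(id, g1, g2, go) {
      p1 <- profile_vector(prof, g1)
      p2 <- profile_vector(prof, g2)
      po <- profile_vector(prof, go)
      if (is.null(p1) || is.null(p2)) {
        return(tibble(pair_id = id, r_tissue = NA_real_,
                      r_response = NA_real_,
                      neofunct_status = "unclassifiable"))
      }
      rt <- pair_correlation(p1, p2)
      status <- if (is.null(po)) "unclassifiable" else {
        classify_neofunctionalization(p1, p2, po,
                                      config$correlation_threshold)
      }
      rr <- NA_real_
      if (!is.null(lfc)) {
        l1 <- profile_vector(lfc, g1)
        l2 <- profile_vector(lfc, g2)
        if (!is.null(l1) && !is.null(l2)) rr <- response_correlation(l1, l2)
      }
      tibble(pair_id = id, r_tissue = rt, r_response = rr,
             neofunct_status = status)
    }
  ) |> dplyr::bind_rows()

  extra <- intersect(c("region_class", "chrom", "start", "end"), names(pairs))
  dplyr::left_join(res, pairs[, c("pair_id", extra)], by = "pair_id") |>
    dplyr::relocate(dplyr::any_of("region_class"), .after = "pair_id")
}

#' @rdname pair_correlation
#' @export
response_correlation <- function(a, b) {
  pair_correlation(a, b)
}
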