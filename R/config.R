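#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline in one validated list.
#' Defaults follow the conventions of the genome-wide ohnologue analyses the
#' package implements: node supports treated as posterior probabilities with a
#' 0.95 cut-off, an expression-correlation convention of 0.6, 4-Mb genome
#' windows, a 500-kb tandem-clustering distance, a 5% false-discovery rate,
#' and GO-term filters (level at least 5, more than 10 but fewer than 1000
#' annotated genes).
#'
#' @param support_threshold Minimum node support kept during tree
#'   classification; supports below it are collapsed into polytomies.
#' @param correlation_threshold Pearson correlation above which an ohnologue
#'   copy is considered to retain the ancestral expression pattern.
#' @param window_bp Width (bp) of the non-overlapping genome windows used to
#'   summarise pair correlations.
#' @param cluster_distance_bp Distance (bp) under which two neighbouring genes
#'   count as physically clustered.
#' @param fdr_alpha Benjamini-Hochberg adjusted significance level.
#' @param rng_seed Integer seed recorded with the run.
#' @param go_min_genes,go_max_genes Exclusive bounds on the number of
#'   universe genes a GO term may have to be tested.
#' @param go_min_level Minimum ontology level (root = 1) of testable terms.
#' @param species_sep Separator between the species code and the gene id in
#'   gene-tree tip labels.
#' @param pseudocount Pseudo-count added to mean CPM before log fold-changes.
#'
#' @return A named list of class `redip_config`.
#' @examples
#' cfg <- run_config(support_threshold = 0.9)
#' cfg$window_bp
#' @export
run_config <- function(support_threshold = 0.95,
                       correlation_threshold = 0.6,
                       window_bp = 4e6,
                       cluster_distance_bp = 5e5,
                       fdr_alpha = 0.05,
                       rng_seed = 1L,
                       go_min_genes = 10L,
                       go_max_genes = 1000L,
                       go_min_level = 5L,
                       species_sep = "|",
                       pseudocount = 0.5) {
  cfg <- list(
    support_threshold = support_threshold,
    correlation_threshold = correlation_threshold,
    window_bp = as.integer(window_bp),
    cluster_distance_bp = as.integer(cluster_distance_bp),
    fdr_alpha = fdr_alpha,
    rng_seed = as.integer(rng_seed),
    go_min_genes = as.integer(go_min_genes),
    go_max_genes = as.integer(go_max_genes),
    go_min_level = as.integer(go_min_level),
    species_sep = species_sep,
    pseudocount = pseudocount
  )
  validate_config(cfg)
  structure(cfg, class = c("redip_config", "list"))
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(cfg$support_threshold)) abort("support_threshold must be in [0,1]")
  if (!is.numeric(cfg$correlation_threshold) ||
      cfg$correlation_threshold < -1 || cfg$correlation_threshold > 1) {
    abort("correlation_threshold must be in [-1,1]")
  }
  if (cfg$window_bp <= 0) abort("window_bp must be positive")
  if (cfg$cluster_distance_bp <= 0) abort("cluster_distance_bp must be positive")
  if (!in01(cfg$fdr_alpha)) abort("fdr_alpha must be in [0,1]")
  if (cfg$go_min_genes < 0 || cfg$go_max_genes <= cfg$go_min_genes) {
    abort("go gene-count bounds must satisfy 0 <= min < max")
  }
  if (cfg$go_min_level < 1) abort("go_min_level must be >= 1")
  if (cfg$pseudocount <= 0) abort("pseudocount must be positive")
  invisible(cfg)
}

#' Read / write a run configuration (YAML)
#'
#' The on-disk format is a flat YAML mapping; unknown keys are rejected so a
#' typo cannot silently fall back to a default. `write_run_config()` followed
#' by `read_run_config()` is the identity.
#'
#' @param path File path.
#' @return `read_run_config()` returns a `redip_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `redip_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
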