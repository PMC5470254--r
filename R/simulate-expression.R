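#' Derive ohnologue pairs (with divergence times) from a simulation truth table
#'
#' Each locus contributes one ohnologue pair. The time since the onset of
#' independent divergence (`tau`, Myr) is the ancestral rediploidization time
#' for AORe loci and the focal lineage's rediploidization time for LORe loci
#' (Atlantic salmon, hence Salmoninae, in the default setting).
#'
#' @param truth Truth tibble from [simulate_gene_trees()].
#' @param focal_lineage Lineage whose genome the expression data represent.
#' @return Tibble: `pair_id`, `region_class`, `tau`.
#' @export
sim_pairs_from_truth <- function(truth, focal_lineage = "Salmoninae") {
  tau_col <- paste0("tau_", focal_lineage)
  if (!tau_col %in% names(truth)) {
    abort(paste0("truth table lacks column ", tau_col))
  }
  tibble(
    pair_id = truth$locus_id,
    region_class = truth$true_class,
    tau = ifelse(truth$true_class == "AORe",
                 truth$tau_ancestral, truth[[tau_col]])
  ) |>
    dplyr::filter(!is.na(.data$tau))
}

#' Simulate ohnologue expression with drift and regulatory neofunctionalization
#'
#' For each pair an ancestral per-tissue log-expression profile is drawn
#' (Normal(mu, sigma^2)). Each copy equals the ancestral profile plus
#' independent per-tissue drift Normal(0, drift_sd^2 * tau), so pair
#' correlation decays with time since rediploidization. With probability
#' `1 - exp(-neo_hazard * tau)` one copy (fair coin) is replaced by an
#' independent fresh profile - regulatory neofunctionalization, recorded in
#' the truth. The outgroup singleton keeps the ancestral profile plus small
#' noise. Counts are drawn negative-binomially (Poisson when `dispersion` is
#' 0) around the exponentiated profiles. A second design simulates per-tissue
#' freshwater/saltwater responses on the log2 fold-change scale with the same
#' drift/neofunctionalization structure.
#'
#' @param pairs Tibble from [sim_pairs_from_truth()] (needs `pair_id`, `tau`;
#'   `tau` must be non-negative).
#' @param params A [sim_params()] list (`params$expression` is used).
#' @param seed Optional override of `params$rng_seed`.
#' @return List: `atlas_counts`, `atlas_samples` (tissue atlas, genes
#'   `<pair>_1`, `<pair>_2`, `<pair>_out`), `smolt_counts`, `smolt_samples`
#'   (two conditions across the response tissues), and `pair_truth`
#'   (`pair_id`, `tau`, `neofunctionalized`, `neo_copy`).
#' @export
simulate_expression <- function(pairs, params = sim_params(), seed = NULL) {
  ex <- params$expression
  if (any(pairs$tau < 0, na.rm = TRUE)) abort("tau must be non-negative")
  set.seed(seed %||% params$rng_seed)

  n_pair <- nrow(pairs)
  nt <- ex$n_tissues
  nr <- ex$n_response_tissues
  if (nr > nt) abort("n_response_tissues cannot exceed n_tissues")

  tissues <- sprintf("tissue%02d", seq_len(nt))
  atlas_samples <- tidyr::expand_grid(tissue = tissues,
                                      replicate = seq_len(ex$n_reps)) |>
    dplyr::mutate(sample_id = paste0(.data$tissue, "_r", .data$replicate),
                  condition = "control") |>
    dplyr::select("sample_id", "tissue", "condition", "replicate")

  smolt_samples <- tidyr::expand_grid(tissue = tissues[seq_len(nr)],
                                      condition = c("freshwater", "saltwater"),
                                      replicate = seq_len(ex$n_reps)) |>
    dplyr::mutate(sample_id = paste0(.data$tissue, "_",
                                     substr(.data$condition, 1, 4), "_r",
                                     .data$replicate)) |>
    dplyr::select("sample_id", "tissue", "condition", "replicate")

  draw_counts <- function(log_mean) {
    mu <- ex$lib_scale * exp(log_mean)
    if (ex$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / ex$dispersion)
    } else {
      rpois(length(mu), mu)
    }
  }

  gene_ids <- as.vector(t(outer(pairs$pair_id, c("_1", "_2", "_out"), paste0)))
  atlas_counts <- matrix(0L, nrow = 3 * n_pair, ncol = nrow(atlas_samples),
                         dimnames = list(gene_ids, atlas_samples$sample_id))
  smolt_counts <- matrix(0L, nrow = 3 * n_pair, ncol = nrow(smolt_samples),
                         dimnames = list(gene_ids, smolt_samples$sample_id))

  neo <- logical(n_pair)
  neo_copy <- rep(NA_integer_, n_pair)

  for (i in seq_len(n_pair)) {
    tau <- pairs$tau[i]
    anc <- rnorm(nt, ex$mu, ex$sigma)
    prof <- list(
      anc + rnorm(nt, 0, ex$drift_sd * sqrt(tau)),
      anc + rnorm(nt, 0, ex$drift_sd * sqrt(tau)),
      anc + rnorm(nt, 0, ex$outgroup_sd)
    )
    neo[i] <- runif(1) < 1 - exp(-ex$neo_hazard * tau)
    anc_resp <- rnorm(nr, 0, ex$response_sd)
    resp <- list(
      anc_resp + rnorm(nr, 0, ex$response_drift_sd * sqrt(tau)),
      anc_resp + rnorm(nr, 0, ex$response_drift_sd * sqrt(tau)),
      anc_resp + rnorm(nr, 0, ex$outgroup_sd)
    )
    if (neo[i]) {
      neo_copy[i] <- sample(1:2, 1)
      prof[[neo_copy[i]]] <- rnorm(nt, ex$mu, ex$sigma)
      resp[[neo_copy[i]]] <- rnorm(nr, 0, ex$response_sd)
    }
    for (k in 1:3) {
      row <- (i - 1L) * 3L + k
      tis_idx <- match(atlas_samples$tissue, tissues)
      atlas_counts[row, ] <- draw_counts(prof[[k]][tis_idx])
      base <- prof[[k]][match(smolt_samples$tissue, tissues)]
      lfc <- resp[[k]][match(smolt_samples$tissue, tissues[seq_len(nr)])]
      logm <- base + ifelse(smolt_samples$condition == "saltwater",
                            lfc * log(2), 0)
      smolt_counts[row, ] <- draw_counts(logm)
    }
  }

  list(
    atlas_counts = atlas_counts, atlas_samples = atlas_samples,
    smolt_counts = smolt_counts, smolt_samples = smolt_samples,
    pair_truth = tibble(pair_id = pairs$pair_id,
                        region_class = pairs$region_class,
                        tau = pairs$tau,
                        neofunctionalized = neo, neo_copy = neo_copy)
  )
}
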