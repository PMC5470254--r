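#' Simulation parameters
#'
#' Parameters of the synthetic-data generator. Defaults encode the study
#' conditions of the salmonid Ss4R system: WGD ~95 Ma, subfamily divergence
#' 52/50 Ma, Salmoninae crown 32.5 Ma, Coregonus-Stenodus split 4.2 Ma, a
#' genome-wide LORe gene fraction of 27.1%, and one third of sampled loci
#' showing assembly collapse of the grayling/whitefish copies.
#'
#' @param t_wgd Age of the whole-genome duplication, Ma.
#' @param esox_split Age of the outgroup (pike) divergence, Ma; must predate
#'   the WGD.
#' @param ages Named list of species-tree node ages (Ma):
#'   `ingroup_root` (Salmoninae vs. rest), `thy_cor`
#'   (Thymallinae-Coregoninae), `salmoninae`, `thymallinae`, `coregoninae`
#'   (Prosopium split) and `whitefish` (Coregonus-Stenodus) crowns.
#' @param lore_fraction Probability a locus evolves under lineage-specific
#'   ohnologue resolution (LORe); the complement is AORe.
#' @param aore_redip_range Uniform bounds (Ma) for the single ancestral
#'   rediploidization time of an AORe locus; must lie below `t_wgd` and above
#'   the ingroup root age.
#' @param topology_noise_prob Probability of applying one random
#'   nearest-neighbour interchange to a gene tree.
#' @param collapse_prob Probability that a locus shows assembly collapse, i.e.
#'   every lineage in `collapsible_lineages` retains a single observable copy.
#' @param collapsible_lineages Lineages subject to collapse. The default
#'   exempts Salmoninae, whose verified ohnologue pair anchors every sampled
#'   locus.
#' @param branch_noise_sd sdlog of the multiplicative lognormal noise applied
#'   per edge length (0 disables).
#' @param support_model List with `prob_weak` (chance an internal node gets a
#'   weak support) and `weak`/`strong` uniform ranges for simulated posterior
#'   supports.
#' @param expression List of expression-model settings: `n_tissues`,
#'   `n_response_tissues`, `n_reps`, log-scale profile `mu`/`sigma`,
#'   `drift_sd` (per sqrt(Myr)), `outgroup_sd`, neofunctionalization hazard
#'   `neo_hazard` (per Myr), `lib_scale`, negative-binomial `dispersion`
#'   (0 gives Poisson counts), `response_sd` and `response_drift_sd`.
#' @param rng_seed Integer seed; the same seed yields identical output.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(t_wgd = 95,
                       esox_split = 125,
                       ages = list(ingroup_root = 52, thy_cor = 50,
                                   salmoninae = 32.5, thymallinae = 15,
                                   coregoninae = 29.7, whitefish = 4.2),
                       lore_fraction = 0.271,
                       aore_redip_range = c(55, 90),
                       topology_noise_prob = 0.02,
                       collapse_prob = 1 / 3,
                       collapsible_lineages = c("Thymallinae", "Coregoninae"),
                       branch_noise_sd = 0.1,
                       support_model = list(prob_weak = 0.005,
                                            weak = c(0.5, 0.95),
                                            strong = c(0.95, 1)),
                       expression = list(n_tissues = 15,
                                         n_response_tissues = 9,
                                         n_reps = 3,
                                         mu = 4, sigma = 1.5,
                                         drift_sd = 0.12,
                                         outgroup_sd = 0.25,
                                         neo_hazard = 0.008,
                                         lib_scale = 1,
                                         dispersion = 0.05,
                                         response_sd = 1,
                                         response_drift_sd = 0.12),
                       rng_seed = 1L) {
  p <- list(
    t_wgd = t_wgd, esox_split = esox_split, ages = ages,
    lore_fraction = lore_fraction, aore_redip_range = aore_redip_range,
    topology_noise_prob = topology_noise_prob,
    collapse_prob = collapse_prob,
    collapsible_lineages = collapsible_lineages,
    branch_noise_sd = branch_noise_sd,
    support_model = support_model,
    expression = expression,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_params(p)
  structure(p, class = c("sim_params", "list"))
}

validate_sim_params <- function(p) {
  probs <- c(lore_fraction = p$lore_fraction,
             topology_noise_prob = p$topology_noise_prob,
             collapse_prob = p$collapse_prob,
             prob_weak = p$support_model$prob_weak)
  bad <- probs[probs < 0 | probs > 1]
  if (length(bad)) {
    abort(paste0(names(bad)[1], " must be in [0,1]"))
  }
  if (any(unlist(p$ages) <= 0)) abort("species-tree ages must be positive")
  if (p$esox_split <= p$t_wgd) abort("outgroup split must predate the WGD")
  if (max(p$aore_redip_range) >= p$t_wgd) {
    abort("AORe rediploidization times must postdate the WGD (be < t_wgd)")
  }
  if (min(p$aore_redip_range) <= p$ages$ingroup_root) {
    abort("AORe rediploidization times must predate the ingroup root")
  }
  a <- p$ages
  ok <- a$ingroup_root > a$thy_cor &&
    a$ingroup_root > a$salmoninae &&
    a$thy_cor > a$thymallinae &&
    a$thy_cor > a$coregoninae &&
    a$coregoninae > a$whitefish &&
    p$esox_split > a$ingroup_root
  if (!ok) abort("inconsistent species-tree ages: every child must be younger than its parent")
  invisible(p)
}
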