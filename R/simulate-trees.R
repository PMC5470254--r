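#' Simulate gene trees under ancestral or lineage-specific rediploidization
#'
#' For each locus a class is drawn (LORe with probability
#' `params$lore_fraction`, otherwise AORe). An AORe locus places a single
#' duplication node on the ingroup stem at a rediploidization age drawn from
#' `aore_redip_range`, each daughter containing the full species tree. A LORe
#' locus places one duplication per subfamily at an age drawn uniformly
#' between that lineage's crown and stem origin, so ohnologues diverge
#' independently within each lineage. Assembly collapse (a locus retaining a
#' single observable copy for the collapsible lineages), multiplicative
#' lognormal branch-length noise, at most one random NNI, and simulated node
#' supports are then applied. The returned truth table is sufficient to score
#' every downstream estimator.
#'
#' @param species_tree A [default_species_tree()] object.
#' @param params A [sim_params()] list.
#' @param n_loci Number of loci (>= 1).
#' @param seed Optional override of `params$rng_seed`.
#' @return A list with `trees` (named list of [ape::phylo]) and `truth`
#'   (tibble: `locus_id`, `true_class`, `collapsed`, `tau_ancestral`,
#'   one `tau_<lineage>` column per lineage, `event_branches`,
#'   `n_true_events`).
#' @examples
#' st <- default_species_tree()
#' sim <- simulate_gene_trees(st, sim_params(), n_loci = 5)
#' sim$truth
#' @export
simulate_gene_trees <- function(species_tree, params = sim_params(), n_loci,
                                seed = NULL) {
  validate_sim_params(params)
  if (n_loci < 1) abort("n_loci must be >= 1")
  set.seed(seed %||% params$rng_seed)

  lineages <- species_tree$lineages
  all_species <- setdiff(species_tree$map$species_code,
                         species_tree$map$species_code[species_tree$map$is_outgroup])
  og <- species_tree$outgroup
  esox <- species_tree$esox_split
  struct <- species_tree$struct
  stems <- setNames(lineages$mrca_label, lineages$lineage)

  trees <- vector("list", n_loci)
  truth <- vector("list", n_loci)

  for (i in seq_len(n_loci)) {
    locus <- sprintf("L%03d", i)
    is_lore <- runif(1) < params$lore_fraction
    collapsed <- runif(1) < params$collapse_prob
    coll_lin <- if (collapsed) {
      intersect(params$collapsible_lineages, lineages$lineage)
    } else {
      character(0)
    }

    if (!is_lore) {
      tau <- runif(1, params$aore_redip_range[1], params$aore_redip_range[2])
      keep <- list(all_species, all_species)
      for (lin in coll_lin) {
        side <- sample(1:2, 1)
        lin_sp <- species_tree$map$species_code[
          !species_tree$map$is_outgroup & species_tree$map$lineage == lin]
        keep[[side]] <- setdiff(keep[[side]], lin_sp)
      }
      s1 <- build_copy(struct, keep[[1]], tau, locus, 1L)
      s2 <- build_copy(struct, keep[[2]], tau, locus, 2L)
      ing <- if (is.null(s1) || is.null(s2)) {
        surv <- if (is.null(s1)) list(keep[[2]], 2L) else list(keep[[1]], 1L)
        build_copy(struct, surv[[1]], esox, locus, surv[[2]])
      } else {
        paste0("(", s1, ",", s2, "):", fmt_num(esox - tau))
      }
      nwk <- paste0("(", ing, ",", og, "|", locus, "_0:", fmt_num(esox), ");")
      taus <- setNames(rep(NA_real_, nrow(lineages)), lineages$lineage)
      tr_row <- tibble(
        locus_id = locus, true_class = "AORe", collapsed = collapsed,
        tau_ancestral = tau,
        event_branches = species_tree$struct$label,
        n_true_events = 1L
      )
    } else {
      taus <- setNames(
        runif(nrow(lineages), lineages$crown_age, lineages$stem_age),
        lineages$lineage
      )
      nwk <- paste0(
        "(", build_lore_copy(struct, esox, locus, taus, coll_lin), ",",
        og, "|", locus, "_0:", fmt_num(esox), ");"
      )
      ev_lin <- setdiff(lineages$lineage, coll_lin)
      tr_row <- tibble(
        locus_id = locus, true_class = "LORe", collapsed = collapsed,
        tau_ancestral = NA_real_,
        event_branches = paste(stems[ev_lin], collapse = ";"),
        n_true_events = length(ev_lin)
      )
    }
    for (lin in lineages$lineage) {
      tr_row[[paste0("tau_", lin)]] <-
        if (is_lore && !(lin %in% coll_lin)) taus[[lin]] else NA_real_
    }

    phy <- ape::read.tree(text = nwk)
    if (runif(1) < params$topology_noise_prob) {
      phy <- rep_to_phylo(rep_nni(phylo_to_rep(phy)))
    }
    if (params$branch_noise_sd > 0 && !is.null(phy$edge.length)) {
      phy$edge.length <- phy$edge.length *
        rlnorm(length(phy$edge.length), 0, params$branch_noise_sd)
    }
    phy$node.label <- simulate_supports(phy$Nnode, params$support_model)
    trees[[i]] <- phy
    truth[[i]] <- tr_row
  }

  trees <- setNames(trees, vapply(truth, function(x) x$locus_id, character(1)))
  list(trees = trees, truth = dplyr::bind_rows(truth))
}

# Newick fragment for one ohnologue copy of the (sub)tree rooted at `nd`,
# restricted to species in `keep`; unary nodes created by the restriction are
# suppressed, with branch lengths recomputed from node ages.
build_copy <- function(nd, keep, parent_age, locus, copy) {
  if (nd$tip) {
    if (!(nd$label %in% keep)) return(NULL)
    return(paste0(nd$label, "|", locus, "_", copy, ":", fmt_num(parent_age)))
  }
  surv <- Filter(function(ch) struct_survives(ch, keep), nd$children)
  if (length(surv) == 0L) return(NULL)
  if (length(surv) == 1L) return(build_copy(surv[[1]], keep, parent_age, locus, copy))
  kids <- vapply(surv, build_copy, character(1), keep, nd$age, locus, copy)
  paste0("(", paste(kids, collapse = ","), "):", fmt_num(parent_age - nd$age))
}

struct_survives <- function(nd, keep) {
  if (nd$tip) nd$label %in% keep
  else any(vapply(nd$children, struct_survives, logical(1), keep))
}

struct_species <- function(nd) {
  if (nd$tip) nd$label else unlist(lapply(nd$children, struct_species))
}

# LORe backbone: species-tree structure with each lineage clade replaced by a
# duplication node at that lineage's rediploidization age (or by a single
# copy when the lineage is collapsed).
build_lore_copy <- function(nd, parent_age, locus, taus, coll_lin) {
  lin <- nd$lineage_root
  if (!is.null(lin)) {
    keep <- struct_species(nd)
    if (lin %in% coll_lin) {
      return(build_copy(nd, keep, parent_age, locus, 1L))
    }
    tau <- taus[[lin]]
    s1 <- build_copy(nd, keep, tau, locus, 1L)
    s2 <- build_copy(nd, keep, tau, locus, 2L)
    return(paste0("(", s1, ",", s2, "):", fmt_num(parent_age - tau)))
  }
  if (nd$tip) {
    abort(paste0("species ", nd$label, " belongs to no lineage"))
  }
  kids <- vapply(nd$children, build_lore_copy, character(1), nd$age, locus,
                 taus, coll_lin)
  paste0("(", paste(kids, collapse = ","), "):", fmt_num(parent_age - nd$age))
}

simulate_supports <- function(n_node, model) {
  if (n_node == 0) return(NULL)
  weak <- runif(n_node) < model$prob_weak
  sup <- ifelse(weak,
                runif(n_node, model$weak[1], model$weak[2]),
                runif(n_node, model$strong[1], model$strong[2]))
  lab <- as.character(round(sup, 3))
  lab[1] <- ""  # root carries no support
  lab
}
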