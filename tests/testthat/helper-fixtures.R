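# Shared fixtures. Everything is generated in code; nothing is read from disk.

fix_map <- default_species_map()
fix_st <- default_species_tree()

# Toy one-species-per-subfamily map used by the hand-worked classification
# examples (Ssal = Salmoninae, Tbai = Thymallinae, Clav = Coregoninae).
toy_map <- tibble::tibble(
  species_code = c("Ssal", "Tbai", "Clav", "Eluc"),
  lineage = c("Salmoninae", "Thymallinae", "Coregoninae", NA),
  is_outgroup = c(FALSE, FALSE, FALSE, TRUE)
)

noise_free_params <- function(collapse_prob = 0, ...) {
  sim_params(topology_noise_prob = 0, collapse_prob = collapse_prob,
             branch_noise_sd = 0,
             support_model = list(prob_weak = 0, weak = c(0.5, 0.95),
                                  strong = c(0.95, 1)),
             ...)
}

# Random gene-tree-shaped phylo with duplicated species labels, for oracle
# comparisons (ingroup species only).
random_species_tree_sample <- function(n_tips, seed_species = fix_map) {
  codes <- seed_species$species_code[!seed_species$is_outgroup]
  phy <- ape::rtree(n_tips)
  phy$tip.label <- paste0(sample(codes, n_tips, replace = TRUE), "|g",
                          seq_len(n_tips))
  phy$node.label <- NULL
  phy
}

# Independent species-overlap oracle built on ape/phangorn primitives: a node
# is a duplication node iff two of its child subtrees share a species.
oracle_duplication_nodes <- function(phy, sep = "|") {
  sp <- sub(paste0("\\", sep, ".*$"), "", phy$tip.label)
  n_tip <- length(phy$tip.label)
  internal <- n_tip + seq_len(phy$Nnode)
  is_dup <- vapply(internal, function(v) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    if (length(kids) < 2) return(FALSE)
    sets <- lapply(kids, function(k) {
      if (k <= n_tip) sp[k]
      else unique(sp[unlist(phangorn::Descendants(phy, k, "tips"))])
    })
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (b > a && length(intersect(sets[[a]], sets[[b]]))) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  internal[is_dup]
}

permute_children <- function(phy) {
  rp <- redipr:::phylo_to_rep(phy)
  rp$children <- lapply(rp$children, rev)
  redipr:::rep_to_phylo(rp)
}
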