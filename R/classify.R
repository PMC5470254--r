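#' Root a gene tree on its outgroup and return the ingroup subtree
#'
#' Checks that at least one outgroup tip is present and that an edge separates
#' all outgroup tips from all ingroup tips (outgroup monophyly in the
#' unrooted sense), then returns the ingroup subtree rooted at the edge
#' adjacent to the outgroup attachment. Support values travel with the edges
#' they belong to.
#'
#' @param tree An [ape::phylo].
#' @param species_map Species map tibble (see [read_species_map()]).
#' @param sep Separator between species code and gene id in tip labels.
#' @return The rooted ingroup [ape::phylo] (outgroup pruned).
#' @examples
#' tr <- read_newick("(Eluc,(Ssal,Tbai));")
#' root_on_outgroup(tr, default_species_map())
#' @export
root_on_outgroup <- function(tree, species_map, sep = "|") {
  species_map <- validate_species_map(species_map)
  sp <- tip_species_codes(tree$tip.label, sep)
  unknown <- setdiff(sp, species_map$species_code)
  if (length(unknown)) {
    abort(paste0("tip(s) with unknown species: ", paste(unknown, collapse = ", ")))
  }
  og_codes <- species_map$species_code[species_map$is_outgroup]
  og_tips <- tree$tip.label[sp %in% og_codes]
  if (!length(og_tips)) abort("unrooted: outgroup absent")
  if (length(og_tips) == length(tree$tip.label)) {
    abort("tree contains only outgroup tips")
  }
  # Rooting is done on the package's own node representation so that support
  # values stay attached to the clades they belong to regardless of child
  # order (re-rooting via edge relabelling is notoriously fragile).
  rp <- phylo_to_rep(tree)
  og_idx <- which(sp %in% og_codes)
  ing_idx <- setdiff(seq_len(rp$n_tip), og_idx)
  tipsets <- node_tip_sets(rp)
  reach <- rep_reachable(rp)

  same_set <- function(a, b) {
    length(a) == length(b) && all(sort(a) == sort(b))
  }
  # Case 1: the ingroup forms a clade; its node is the ingroup root.
  for (i in reach) {
    if (same_set(tipsets[[i]], ing_idx)) {
      return(rep_subtree_phylo(rp, i))
    }
  }
  # Case 2: the outgroup forms a clade under the read root; prune it.
  og_clade <- NA_integer_
  for (i in reach) {
    if (i != rp$root && same_set(tipsets[[i]], og_idx)) og_clade <- i
  }
  if (!is.na(og_clade)) {
    p <- rp$parent[og_clade]
    if (p != rp$root) rp <- rep_reroot(rp, p)
    kids <- setdiff(rp$children[[rp$root]], og_clade)
    if (length(kids) == 1L) return(rep_subtree_phylo(rp, kids))
    rp$children[[rp$root]] <- kids
    return(rep_subtree_phylo(rp, rp$root))
  }
  abort("outgroup paraphyletic: no edge separates outgroup from ingroup")
}

node_tip_sets <- function(rp) {
  sets <- vector("list", rp$n)
  fill <- function(i) {
    if (i <= rp$n_tip) {
      sets[[i]] <<- i
    } else {
      for (ch in rp$children[[i]]) fill(ch)
      sets[[i]] <<- unlist(sets[rp$children[[i]]], use.names = FALSE)
    }
  }
  fill(rp$root)
  sets
}

rep_subtree_phylo <- function(rp, node) {
  if (node <= rp$n_tip) abort("ingroup too small after pruning outgroup")
  rp$root <- node
  rp$length[node] <- NA_real_
  rep_to_phylo(rp)
}

#' Collapse weakly supported edges into polytomies
#'
#' Every internal edge whose support is recorded and falls below `threshold`
#' is contracted (its child's children are attached to its parent, branch
#' lengths summed), so that all surviving bipartitions are supported at or
#' above the threshold. Nodes without a recorded support are kept. The tip
#' set is unchanged.
#'
#' @param tree A rooted [ape::phylo]; supports in `node.label`, interpreted as
#'   posterior probabilities in [0,1] (0-100 scales are rescaled with a
#'   warning).
#' @param threshold Support threshold in [0,1].
#' @return An [ape::phylo], possibly with polytomies.
#' @export
collapse_unsupported <- function(tree, threshold) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0,1]")
  if (threshold == 0) return(tree)
  rp <- phylo_to_rep(tree)
  repeat {
    reach <- rep_reachable(rp)
    cand <- reach[reach > rp$n_tip & reach != rp$root]
    cand <- cand[!is.na(rp$support[cand]) & rp$support[cand] < threshold]
    if (!length(cand)) break
    i <- cand[1]
    p <- rp$parent[i]
    kids <- rp$children[[i]]
    pos <- which(rp$children[[p]] == i)
    rp$children[[p]] <- append(rp$children[[p]][-pos], kids, after = pos - 1L)
    for (k in kids) {
      rp$parent[k] <- p
      if (!is.na(rp$length[i]) && !is.na(rp$length[k])) {
        rp$length[k] <- rp$length[k] + rp$length[i]
      }
    }
    rp$children[[i]] <- list()
  }
  rep_to_phylo(rp)
}

#' Find duplication nodes by species overlap
#'
#' A node of a rooted ingroup gene tree is a duplication node when (at least)
#' two of its child clades contain a common species - under a single
#' whole-genome duplication this is exactly the signature of the onset of
#' ohnologue divergence (rediploidization), with no gene birth-death model
#' needed. Each duplication node is mapped to the species-tree MRCA of the
#' species it spans.
#'
#' @param tree Rooted ingroup [ape::phylo] (outgroup pruned).
#' @param species_map Species map tibble.
#' @param species_tree Optional `species_tree` used to map spans to
#'   species-tree nodes.
#' @param sep Tip-label separator.
#' @return Tibble: `node` (ape node id), `is_root`, `span` (list of species
#'   codes), `n_children`, `polytomy_overlap`, `daughter_supports` (list),
#'   `mapped_node` (species-tree label or `NA`).
#' @export
find_duplication_nodes <- function(tree, species_map, species_tree = NULL,
                                   sep = "|") {
  species_map <- validate_species_map(species_map)
  sp <- tip_species_codes(tree$tip.label, sep)
  unknown <- setdiff(sp, species_map$species_code)
  if (length(unknown)) {
    abort(paste0("tip(s) with unknown species: ", paste(unknown, collapse = ", ")))
  }
  og <- species_map$species_code[species_map$is_outgroup]
  if (any(sp %in% og)) {
    abort("tree still contains outgroup tips; root_on_outgroup() first")
  }
  rp <- phylo_to_rep(tree)
  sets <- node_species_sets(rp, sp)
  reach <- rep_reachable(rp)
  internal <- sort(reach[reach > rp$n_tip])

  rows <- list()
  for (i in internal) {
    kids <- rp$children[[i]]
    if (length(kids) < 2) next
    kid_sets <- sets[kids]
    overlap <- FALSE
    for (a in seq_along(kids)) {
      for (b in seq_along(kids)) {
        if (b <= a) next
        if (length(intersect(kid_sets[[a]], kid_sets[[b]]))) overlap <- TRUE
      }
    }
    if (!overlap) next
    mapped <- if (!is.null(species_tree)) {
      mrca_branch(species_tree, sets[[i]])
    } else {
      NA_character_
    }
    rows[[length(rows) + 1L]] <- tibble(
      node = i,
      is_root = i == rp$root,
      span = list(sort(sets[[i]])),
      n_children = length(kids),
      polytomy_overlap = length(kids) > 2,
      daughter_supports = list(rp$support[kids]),
      mapped_node = mapped
    )
  }
  if (!length(rows)) {
    return(tibble(node = integer(), is_root = logical(), span = list(),
                  n_children = integer(), polytomy_overlap = logical(),
                  daughter_supports = list(), mapped_node = character()))
  }
  dplyr::bind_rows(rows)
}

#' Classify one gene tree as AORe, LORe, ambiguous or uninformative
#'
#' Applies the topological assay for the timing of rediploidization relative
#' to speciation. After rooting on the outgroup and collapsing weakly
#' supported edges:
#' * no duplication node: **uninformative** (e.g. full assembly collapse);
#' * the ingroup root is the only duplication node and each daughter clade
#'   holds at most one tip per species: **AORe** - the duplicates diverged
#'   before the lineages split, each daughter mirroring the species tree;
#' * one or more duplication nodes, all strictly below the ingroup root,
#'   none ancestral to another, each mapping below the ingroup root:
#'   **LORe** - ohnologues diverged independently within lineages, one
#'   rediploidization event per duplication node, assigned to the
#'   species-tree branch above its mapped node;
#' * anything else (root plus internal duplications, nested duplications, a
#'   species with more than two tips - possible small-scale duplication -, a
#'   polytomy whose members overlap, or a duplication spanning lineages whose
#'   MRCA is the ingroup root): **ambiguous**.
#'
#' Lineages represented by a single copy do not block classification; they
#' are flagged `single_copy`.
#'
#' @param tree An [ape::phylo]; raw (with outgroup) unless `prepared = TRUE`.
#' @param species_tree A `species_tree`.
#' @param species_map Species map tibble.
#' @param config A [run_config()] (uses `support_threshold`, `species_sep`).
#' @param locus_id Identifier recorded in the output.
#' @param prepared Set to `TRUE` when `tree` is already rooted, outgroup-free
#'   and support-collapsed.
#' @return One-row tibble: `locus_id`, `class`, `n_events`, `events`
#'   (list-column tibble with `branch_id`, `node`, `span`), `lineage_status`
#'   (list-column of named character), `notes`.
#' @export
classify_tree <- function(tree, species_tree, species_map = species_tree$map,
                          config = run_config(), locus_id = "locus",
                          prepared = FALSE) {
  if (!prepared) {
    tree <- root_on_outgroup(tree, species_map, sep = config$species_sep)
    tree <- collapse_unsupported(tree, config$support_threshold)
  }
  sp <- tip_species_codes(tree$tip.label, config$species_sep)
  dups <- find_duplication_nodes(tree, species_map, species_tree,
                                 sep = config$species_sep)

  lineage_status <- lineage_flags(sp, species_map)
  empty_events <- tibble(branch_id = character(), node = integer(),
                         span = list())
  row <- function(class, events = empty_events, notes = "") {
    tibble(locus_id = locus_id, class = class,
           n_events = nrow(events), events = list(events),
           lineage_status = list(lineage_status), notes = notes)
  }

  tip_counts <- table(sp)
  if (any(tip_counts > 2)) {
    return(row("ambiguous",
               notes = paste0("species with >2 tips: ",
                              paste(names(tip_counts)[tip_counts > 2],
                                    collapse = ","))))
  }
  if (nrow(dups) == 0) {
    return(row("uninformative", notes = "no duplication node"))
  }

  root_dup <- dups$is_root
  ingroup_root_label <- species_tree$struct$label

  if (any(root_dup)) {
    if (nrow(dups) > 1) {
      return(row("ambiguous", notes = "root duplication plus internal duplications"))
    }
    if (dups$polytomy_overlap[1]) {
      return(row("ambiguous", notes = "overlapping polytomy at root"))
    }
    # each daughter must hold <= 1 tip per species
    rp <- phylo_to_rep(tree)
    for (ch in rp$children[[rp$root]]) {
      ch_tips <- sp[intersect(rep_reachable_from(rp, ch), seq_len(rp$n_tip))]
      if (any(table(ch_tips) > 1)) {
        return(row("ambiguous", notes = "duplicated species within a root daughter"))
      }
    }
    ev <- tibble(branch_id = ingroup_root_label,
                 node = dups$node[1], span = dups$span[1])
    return(row("AORe", events = ev))
  }

  # all duplications strictly below the ingroup root
  if (any(dups$polytomy_overlap)) {
    return(row("ambiguous", notes = "overlapping polytomy at duplication node"))
  }
  rp <- phylo_to_rep(tree)
  for (a in dups$node) {
    for (b in dups$node) {
      if (a != b && node_is_ancestor(rp, a, b)) {
        return(row("ambiguous", notes = "nested duplication nodes"))
      }
    }
  }
  if (any(dups$mapped_node == ingroup_root_label, na.rm = TRUE)) {
    return(row("ambiguous",
               notes = "internal duplication spans lineages meeting at the ingroup root"))
  }
  ev <- tibble(branch_id = dups$mapped_node, node = dups$node, span = dups$span)
  row("LORe", events = ev)
}

rep_reachable_from <- function(rp, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, rp$children[[i]])
  }
  out
}

lineage_flags <- function(sp, species_map) {
  lins <- unique(species_map$lineage[!species_map$is_outgroup])
  status <- vapply(lins, function(lin) {
    lin_sp <- species_map$species_code[!species_map$is_outgroup &
                                         species_map$lineage == lin]
    counts <- table(sp[sp %in% lin_sp])
    if (length(counts) == 0) "absent"
    else if (any(counts >= 2)) "duplicated"
    else "single_copy"
  }, character(1))
  setNames(status, lins)
}

#' Classify a batch of gene trees
#'
#' Runs [classify_tree()] over a set of trees; individual failures are
#' recorded as class `"error"` and the run continues. The result carries both
#' the per-tree table and summary counts, and supports [tidy()], [glance()]
#' and [autoplot()].
#'
#' @param trees Named list of [ape::phylo] (names become locus ids) or a path
#'   readable by [read_gene_trees()].
#' @param species_tree A `species_tree`.
#' @param species_map Species map tibble.
#' @param config A [run_config()].
#' @return An object of class `redip_classification` with elements
#'   `classifications` (tibble) and `summary` (per-class counts and
#'   fractions).
#' @examples
#' st <- default_species_tree()
#' sim <- simulate_gene_trees(st, sim_params(), n_loci = 10)
#' cls <- classify_batch(sim$trees, st)
#' glance(cls)
#' @export
classify_batch <- function(trees, species_tree,
                           species_map = species_tree$map,
                           config = run_config()) {
  if (is.character(trees)) trees <- read_gene_trees(trees)
  if (!length(trees)) abort("need at least one tree")
  ids <- names(trees) %||% sprintf("tree_%03d", seq_along(trees))
  ids[ids == ""] <- sprintf("tree_%03d", which(ids == ""))

  rows <- purrr::map2(trees, ids, function(tr, id) {
    tryCatch(
      classify_tree(tr, species_tree, species_map, config, locus_id = id),
      error = function(e) {
        tibble(locus_id = id, class = "error", n_events = 0L,
               events = list(tibble(branch_id = character(),
                                    node = integer(), span = list())),
               lineage_status = list(character()),
               notes = conditionMessage(e))
      }
    )
  })
  classifications <- dplyr::bind_rows(rows)

  lv <- c("AORe", "LORe", "ambiguous", "uninformative", "error")
  summary <- classifications |>
    dplyr::count(class = factor(.data$class, levels = lv), .drop = FALSE) |>
    dplyr::mutate(class = as.character(.data$class),
                  fraction = .data$n / sum(.data$n))

  structure(
    list(classifications = classifications, summary = summary,
         config = config),
    class = "redip_classification"
  )
}

#' @export
print.redip_classification <- function(x, ...) {
  cat("Gene-tree rediploidization classification:",
      nrow(x$classifications), "trees\n")
  print(x$summary)
  invisible(x)
}

#' Long table of inferred rediploidization events
#'
#' @param classification A `redip_classification` or a tibble with columns
#'   `locus_id`, `class` and list-column `events`.
#' @return Tibble: `locus_id`, `class`, `branch_id`.
#' @export
classification_events <- function(classification) {
  df <- if (inherits(classification, "redip_classification")) {
    classification$classifications
  } else {
    classification
  }
  if (nrow(df) == 0) {
    return(tibble(locus_id = character(), class = character(),
                  branch_id = character()))
  }
  df |>
    dplyr::select("locus_id", "class", "events") |>
    tidyr::unnest("events") |>
    dplyr::select("locus_id", "class", "branch_id")
}
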