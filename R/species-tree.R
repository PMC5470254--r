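#' Dated species tree
#'
#' Builds the reference time-calibrated species phylogeny onto which
#' rediploidization events are mapped. The default emulates the salmonid
#' phylogeny: seven ingroup species in three subfamilies plus pike as
#' outgroup, with the ingroup root at 52 Ma, the Thymallinae-Coregoninae
#' split at 50 Ma, the Salmoninae crown at 32.5 Ma and the
#' Coregonus-Stenodus (whitefish) split at 4.2 Ma. Under these ages the
#' Salmoninae stem branch is 19.5 Myr long and the whitefish stem branch
#' 25.5 Myr, the two branch lengths used for rediploidization-rate
#' extrapolation.
#'
#' Internal nodes are labelled (`Salmonidae`, `Salmoninae`,
#' `Thymallinae_Coregoninae`, `Thymallinae`, `Coregoninae`, `whitefish`); a
#' species-tree *branch* is identified by the label of the node (or tip)
#' below it.
#'
#' @param params A [sim_params()] list supplying the ages.
#' @param species_map A species map (see [default_species_map()]).
#' @return An object of class `species_tree`: a list with the dated
#'   [ape::phylo] (`phy`, outgroup included), node `ages` named by label, the
#'   species `map`, per-`lineage` crown/stem ages, the WGD age and the
#'   ingroup structure used by the simulator.
#' @examples
#' st <- default_species_tree()
#' st$lineages
#' @export
default_species_tree <- function(params = sim_params(),
                                 species_map = default_species_map()) {
  validate_sim_params(params)
  validate_species_map(species_map)
  a <- params$ages

  tip <- function(code) list(label = code, age = 0, tip = TRUE)
  node <- function(label, age, ...) list(label = label, age = age, tip = FALSE,
                                         children = list(...))
  struct <- node(
    "Salmonidae", a$ingroup_root,
    node("Salmoninae", a$salmoninae, tip("Ssal"), tip("Blen")),
    node(
      "Thymallinae_Coregoninae", a$thy_cor,
      node("Thymallinae", a$thymallinae, tip("Tbai"), tip("Tgru")),
      node("Coregoninae", a$coregoninae,
           tip("Pcou"),
           node("whitefish", a$whitefish, tip("Sleu"), tip("Clav")))
    )
  )
  check_ages <- function(nd, parent_age) {
    if (nd$age >= parent_age) {
      abort(paste0("node ", nd$label, " (", nd$age,
                   " Ma) is not younger than its parent (", parent_age, " Ma)"))
    }
    if (!nd$tip) for (ch in nd$children) check_ages(ch, nd$age)
  }
  check_ages(struct, params$esox_split)

  struct <- mark_lineage_roots(struct, species_map)

  deparse_struct <- function(nd, parent_age) {
    if (nd$tip) {
      paste0(nd$label, ":", fmt_num(parent_age - nd$age))
    } else {
      kids <- vapply(nd$children, deparse_struct, character(1), nd$age)
      paste0("(", paste(kids, collapse = ","), ")", nd$label, ":",
             fmt_num(parent_age - nd$age))
    }
  }
  og <- species_map$species_code[species_map$is_outgroup][1]
  nwk <- paste0("(", deparse_struct(struct, params$esox_split), ",",
                og, ":", fmt_num(params$esox_split), ");")
  phy <- ape::read.tree(text = nwk)

  ages <- collect_ages(struct)
  ages[og] <- 0

  lineages <- lineage_table(struct, species_map)

  structure(
    list(phy = phy, ages = ages, map = species_map, lineages = lineages,
         wgd_age = params$t_wgd, esox_split = params$esox_split,
         struct = struct, outgroup = og),
    class = "species_tree"
  )
}

# Tag the node (or tip) whose species set equals a lineage's full species set.
mark_lineage_roots <- function(struct, species_map) {
  lin_sets <- split(species_map$species_code[!species_map$is_outgroup],
                    species_map$lineage[!species_map$is_outgroup])
  species_below <- function(nd) {
    if (nd$tip) nd$label else unlist(lapply(nd$children, species_below))
  }
  walk <- function(nd) {
    sp <- sort(species_below(nd))
    for (lin in names(lin_sets)) {
      if (identical(sp, sort(lin_sets[[lin]]))) nd$lineage_root <- lin
    }
    if (!nd$tip) nd$children <- lapply(nd$children, walk)
    nd
  }
  walk(struct)
}

collect_ages <- function(nd) {
  out <- setNames(nd$age, nd$label)
  if (!nd$tip) for (ch in nd$children) out <- c(out, collect_ages(ch))
  out
}

lineage_table <- function(struct, species_map) {
  rows <- list()
  walk <- function(nd, parent_age) {
    if (!is.null(nd$lineage_root)) {
      rows[[nd$lineage_root]] <<- tibble(
        lineage = nd$lineage_root,
        mrca_label = nd$label,
        crown_age = nd$age,
        stem_age = parent_age
      )
    }
    if (!nd$tip) for (ch in nd$children) walk(ch, nd$age)
  }
  walk(struct, attr(struct, "parent_age") %||% Inf)
  # stem of the lineage containing the ingroup root child uses the root age
  dplyr::bind_rows(rows)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Dated species tree:", length(x$phy$tip.label), "tips, outgroup",
      x$outgroup, "\nWGD age:", x$wgd_age, "Ma\n")
  print(x$lineages)
  invisible(x)
}

#' Species-tree branch above the most recent common ancestor of a species set
#'
#' The branch is identified by the label of the MRCA node (tip code for a
#' single species). Used to map inferred rediploidization events onto the
#' dated phylogeny.
#'
#' @param species_tree A `species_tree`.
#' @param species Character vector of species codes.
#' @return The MRCA node label (character scalar).
#' @export
mrca_branch <- function(species_tree, species) {
  species <- unique(species)
  phy <- species_tree$phy
  unknown <- setdiff(species, phy$tip.label)
  if (length(unknown)) {
    abort(paste0("species absent from species tree: ",
                 paste(unknown, collapse = ", ")))
  }
  if (length(species) == 1L) return(species)
  n_tip <- length(phy$tip.label)
  mrca <- ape::getMRCA(phy, species)
  lab <- phy$node.label[mrca - n_tip]
  if (is.na(lab) || lab == "") lab <- paste0("node_", mrca)
  lab
}

# Lineage stem-branch ids (label of the lineage MRCA node).
lineage_stem_branches <- function(species_tree) {
  setNames(species_tree$lineages$mrca_label, species_tree$lineages$lineage)
}
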