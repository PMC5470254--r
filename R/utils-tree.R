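# Lightweight rooted-tree representation used by the classifier and simulator.
#
# A "rep" is a list with parallel vectors indexed by node id (tips first, as in
# ape): children (list), parent (int), length (num), support (num), tip_label.
# Removed nodes simply become unreachable from the root; deparsing walks the
# children lists so holes are harmless.

phylo_to_rep <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  n <- n_tip + n_node
  children <- vector("list", n)
  parent <- rep(NA_integer_, n)
  len <- rep(NA_real_, n)
  has_len <- !is.null(phy$edge.length)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    ch <- phy$edge[i, 2L]
    children[[p]] <- c(children[[p]], ch)
    parent[ch] <- p
    if (has_len) len[ch] <- phy$edge.length[i]
  }
  support <- rep(NA_real_, n)
  if (!is.null(phy$node.label)) {
    support[n_tip + seq_len(n_node)] <- parse_support_labels(phy$node.label)
  }
  list(
    n_tip = n_tip, n = n, children = children, parent = parent,
    length = len, support = support, tip_label = phy$tip.label,
    root = n_tip + 1L
  )
}

# Node labels carrying support values: numeric strings, possibly on a 0-100
# bootstrap scale, which is rescaled to [0,1] with a warning.
parse_support_labels <- function(labels) {
  sup <- suppressWarnings(as.numeric(labels))
  finite <- sup[is.finite(sup)]
  if (length(finite) && any(finite > 1)) {
    warn("support values look like percentages (max > 1); rescaling to [0,1]")
    sup <- sup / 100
  }
  sup
}

fmt_num <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}

rep_to_newick <- function(rp, digits = 10) {
  deparse_node <- function(i) {
    if (i <= rp$n_tip) {
      s <- rp$tip_label[i]
    } else {
      kids <- vapply(rp$children[[i]], deparse_node, character(1))
      s <- paste0("(", paste(kids, collapse = ","), ")")
      if (!is.na(rp$support[i]) && i != rp$root) {
        s <- paste0(s, fmt_num(rp$support[i], digits))
      }
    }
    if (!is.na(rp$length[i]) && i != rp$root) {
      s <- paste0(s, ":", fmt_num(rp$length[i], digits))
    }
    s
  }
  paste0(deparse_node(rp$root), ";")
}

rep_to_phylo <- function(rp) {
  ape::read.tree(text = rep_to_newick(rp))
}

# Reachable nodes (root's connected component after splices/drops).
rep_reachable <- function(rp) {
  out <- integer(0)
  stack <- rp$root
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, rp$children[[i]])
  }
  out
}

# Character vector of species per tip label: the substring before the first
# separator (default "|"); a label without separator is itself a species code.
tip_species_codes <- function(labels, sep = "|") {
  vapply(strsplit(labels, sep, fixed = TRUE), `[[`, character(1), 1L)
}

# List (indexed by node id) of the unique species codes below each node.
node_species_sets <- function(rp, species) {
  sets <- vector("list", rp$n)
  fill <- function(i) {
    if (i <= rp$n_tip) {
      sets[[i]] <<- species[i]
    } else {
      for (ch in rp$children[[i]]) fill(ch)
      sets[[i]] <<- unique(unlist(sets[rp$children[[i]]]))
    }
  }
  fill(rp$root)
  sets
}

node_is_ancestor <- function(rp, a, b) {
  # TRUE if a is a strict ancestor of b
  p <- rp$parent[b]
  while (!is.na(p)) {
    if (p == a) return(TRUE)
    p <- rp$parent[p]
  }
  FALSE
}

# Re-root at an internal node by reversing parent pointers along the path to
# the old root. Edge supports are edge properties: a reversed edge's support
# moves to the node that is now its child. A unary old root is suppressed.
rep_reroot <- function(rp, new_root) {
  path <- integer(0)
  x <- new_root
  while (!is.na(rp$parent[x])) {
    path <- c(path, x)
    x <- rp$parent[x]
  }
  if (x == new_root) return(rp)
  nodes <- c(path, x)  # new_root, ..., old_root
  old_len <- rp$length
  old_sup <- rp$support
  for (i in seq_len(length(nodes) - 1L)) {
    ch <- nodes[i]
    pa <- nodes[i + 1L]
    rp$children[[pa]] <- setdiff(rp$children[[pa]], ch)
    rp$children[[ch]] <- c(rp$children[[ch]], pa)
    rp$parent[pa] <- ch
    rp$length[pa] <- old_len[ch]
    rp$support[pa] <- old_sup[ch]
  }
  rp$parent[new_root] <- NA_integer_
  rp$length[new_root] <- NA_real_
  rp$support[new_root] <- NA_real_
  rp$root <- new_root
  old_root <- x
  if (length(rp$children[[old_root]]) == 1L) {
    ch <- rp$children[[old_root]][[1]]
    pa <- rp$parent[old_root]
    rp$children[[pa]][rp$children[[pa]] == old_root] <- ch
    rp$parent[ch] <- pa
    if (!is.na(rp$length[old_root])) {
      rp$length[ch] <- sum(rp$length[ch], rp$length[old_root], na.rm = TRUE)
    }
    rp$children[[old_root]] <- list()
  }
  rp
}

# One random nearest-neighbour interchange: pick an internal edge (p, c) with
# both ends internal, then swap a random child of c with a random sibling of c.
rep_nni <- function(rp) {
  reach <- rep_reachable(rp)
  internal <- reach[reach > rp$n_tip]
  cand <- internal[internal != rp$root &
                     vapply(internal, function(i) length(rp$children[[i]]) >= 2, logical(1))]
  if (!length(cand)) return(rp)
  cnode <- if (length(cand) == 1L) cand else sample(cand, 1L)
  p <- rp$parent[cnode]
  sibs <- setdiff(rp$children[[p]], cnode)
  if (!length(sibs)) return(rp)
  s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
  gks <- rp$children[[cnode]]
  g <- if (length(gks) == 1L) gks else sample(gks, 1L)
  rp$children[[p]][rp$children[[p]] == s] <- g
  rp$children[[cnode]][rp$children[[cnode]] == g] <- s
  rp$parent[g] <- p
  rp$parent[s] <- cnode
  rp
}
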