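#' Read a Newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Internal-node labels
#' that parse as numbers are treated as support values; values on a 0-100
#' bootstrap scale are rescaled to [0,1] with a warning. Tip labels are kept
#' verbatim. Malformed parenthesis structure is reported with the character
#' offset at which it was detected.
#'
#' @param x A file path or a Newick string (detected by the presence of
#'   parentheses/semicolon).
#' @return An [ape::phylo] object; numeric supports are also available via
#'   [node_supports()].
#' @examples
#' tr <- read_newick("(A:1,(B:1,C:1)0.99:1);")
#' node_supports(tr)
#' @export
read_newick <- function(x) {
  txt <- if (grepl("[();]", x)) x else {
    if (!file.exists(x)) abort(paste0("no such file: ", x))
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  check_newick_syntax(txt)
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) abort("could not parse Newick string")
  if (!is.null(phy$node.label)) {
    sup <- parse_support_labels(phy$node.label)
    phy$node.label <- ifelse(is.na(sup), "", as.character(sup))
  }
  phy
}

# Balanced-parenthesis scan; errors name the 1-based character offset.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("malformed Newick: unmatched ')' at character ", i))
      }
    }
  }
  if (depth != 0L) {
    abort(paste0("malformed Newick: ", depth,
                 " unclosed '(' by character ", length(chars)))
  }
  if (!grepl(";", txt)) abort("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @return `node_supports()` returns a numeric vector, one value per internal
#'   node (`NA` where no support was recorded).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) {
    return(rep(NA_real_, tree$Nnode))
  }
  parse_support_labels(tree$node.label)
}

#' Write trees in Newick format
#'
#' `write_newick()` serialises one tree; `write_gene_trees()` writes a list of
#' trees one per line (the `trees.nwk` convention used throughout the
#' package). Reading back what was written reproduces the same topology,
#' branch lengths and supports.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path, or `NULL` to return the string.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' @rdname write_newick
#' @param trees A list of `ape::phylo` objects.
#' @export
write_gene_trees <- function(trees, path, digits = 10) {
  writeLines(vapply(trees, ape::write.tree, character(1), digits = digits), path)
  invisible(path)
}

#' @rdname write_newick
#' @param locus_ids Optional names for the trees; defaults to any names read
#'   from line order (`tree_001`, ...).
#' @export
read_gene_trees <- function(path, locus_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, read_newick)
  if (is.null(locus_ids)) {
    locus_ids <- sprintf("tree_%03d", seq_along(trees))
  }
  if (length(locus_ids) != length(trees)) {
    abort("locus_ids must have one entry per tree")
  }
  setNames(trees, locus_ids)
}
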