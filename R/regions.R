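#' Segment chromosomes into LORe/AORe blocks from classified loci
#'
#' Maximal runs of same-class (LORe/AORe) loci along each chromosome are
#' merged into blocks. Ambiguous, uninformative and error loci never break a
#' run - they are counted as discordant - and a single opposite-class locus
#' sandwiched between same-class neighbours is absorbed into the surrounding
#' block (also counted discordant) rather than splitting it. Blocks span from
#' their first to their last supporting locus; the boundary between adjacent
#' opposite-class blocks is placed at the midpoint between the flanking loci.
#'
#' @param loci Tibble with `locus_id`, `chrom`, `start`, `end`, `class`
#'   (0-based half-open coordinates). Join your classification onto the locus
#'   coordinates first.
#' @return Tibble of blocks: `chrom`, `start`, `end`, `class`,
#'   `n_supporting_loci`, `n_discordant_loci`.
#' @examples
#' loci <- tibble::tibble(
#'   locus_id = paste0("L", 1:6), chrom = "chr01",
#'   start = 1:6 * 1e6, end = 1:6 * 1e6 + 5000,
#'   class = c("AORe", "AORe", "AORe", "LORe", "LORe", "AORe")
#' )
#' segment_regions(loci)
#' @export
segment_regions <- function(loci) {
  req <- c("locus_id", "chrom", "start", "end", "class")
  missing_cols <- setdiff(req, names(loci))
  if (length(missing_cols)) {
    abort(paste0("loci lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(loci$start) | is.na(loci$end) | is.na(loci$chrom)
  if (any(bad)) {
    warn(paste0(sum(bad), " locus/loci without coordinates excluded"))
    loci <- loci[!bad, ]
  }
  if (nrow(loci) == 0) abort("no loci with coordinates to segment")

  loci |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(~ segment_one_chrom(.x)) |>
    dplyr::ungroup()
}

segment_one_chrom <- function(df) {
  decisive <- df$class %in% c("LORe", "AORe")
  dd <- df[decisive, ]
  if (nrow(dd) == 0) {
    return(tibble(start = integer(), end = integer(), class = character(),
                  n_supporting_loci = integer(), n_discordant_loci = integer()))
  }
  cls <- dd$class
  # absorb singleton flips flanked by a common class (iterate to a fixed point)
  repeat {
    r <- rle(cls)
    flip <- which(r$lengths == 1)
    flip <- flip[flip > 1 & flip < length(r$lengths)]
    flip <- flip[vapply(flip, function(i) {
      r$values[i - 1] == r$values[i + 1] && r$values[i] != r$values[i - 1]
    }, logical(1))]
    if (!length(flip)) break
    idx <- cumsum(r$lengths)[flip]  # position of each absorbed singleton
    cls[idx] <- r$values[flip - 1]
  }
  r <- rle(cls)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  supporting <- dd$class == cls

  blocks <- tibble(
    class = r$values,
    start = tapply(dd$start[supporting], run_id[supporting], min)[as.character(seq_along(r$values))],
    end = tapply(dd$end[supporting], run_id[supporting], max)[as.character(seq_along(r$values))],
    first_start = tapply(dd$start, run_id, min),
    last_end = tapply(dd$end, run_id, max)
  )
  blocks$start <- as.integer(blocks$start)
  blocks$end <- as.integer(blocks$end)

  if (nrow(blocks) > 1) {
    for (i in seq_len(nrow(blocks) - 1)) {
      mid <- as.integer((blocks$last_end[i] + blocks$first_start[i + 1]) %/% 2)
      blocks$end[i] <- mid
      blocks$start[i + 1] <- mid
    }
  }

  # discordant: every locus inside the block span not supporting its class
  n_disc <- integer(nrow(blocks))
  n_supp <- integer(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    inside <- df$start >= blocks$start[i] & df$start < blocks$end[i]
    n_supp[i] <- sum(inside & df$class == blocks$class[i])
    n_disc[i] <- sum(inside) - n_supp[i]
  }
  tibble(start = blocks$start, end = blocks$end, class = blocks$class,
         n_supporting_loci = n_supp, n_discordant_loci = n_disc)
}

#' Extrapolate genome-wide ohnologue counts from region blocks
#'
#' Assigns each annotated gene to the block containing its midpoint and
#' tallies genes (and ohnologue pairs, genes/2) per rediploidization class.
#' Fractions are over assigned genes; genes falling in no block are reported
#' as `unassigned`.
#'
#' @param blocks Block tibble from [segment_regions()].
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @return Tibble: `class`, `n_genes`, `n_pairs`, `fraction`, `pct`
#'   (fraction as a percentage rounded to 1 decimal; `NA` for `unassigned`).
#' @export
extrapolate_gene_counts <- function(blocks, genes) {
  if (is.null(genes) || nrow(genes) == 0) abort("empty gene annotation")
  mid <- (genes$start + genes$end) %/% 2
  cls <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(blocks))) {
    hit <- genes$chrom == blocks$chrom[i] &
      mid >= blocks$start[i] & mid < blocks$end[i]
    cls[hit] <- blocks$class[i]
  }
  assigned <- !is.na(cls) & cls %in% c("LORe", "AORe")
  n_lore <- sum(cls == "LORe", na.rm = TRUE)
  n_aore <- sum(cls == "AORe", na.rm = TRUE)
  n_un <- nrow(genes) - n_lore - n_aore
  tot <- n_lore + n_aore
  frac <- function(n) if (tot > 0) n / tot else NA_real_
  tibble(
    class = c("LORe", "AORe", "unassigned"),
    n_genes = c(n_lore, n_aore, n_un),
    n_pairs = c(n_lore, n_aore, n_un) / 2,
    fraction = c(frac(n_lore), frac(n_aore), NA_real_),
    pct = round(c(frac(n_lore), frac(n_aore), NA_real_) * 100, 1)
  )
}

#' Map rediploidization events onto species-tree branches
#'
#' Tallies, over all LORe-classified trees, the inferred rediploidization
#' events per species-tree branch, and reports each branch's share of LORe
#' trees. Lineage stem branches are additionally flagged with the stem
#' fraction used for rate extrapolation (events on the stem mean
#' rediploidization completed before the lineage's crown radiation).
#'
#' @param classification A `redip_classification` or tibble with `locus_id`,
#'   `class` and an `events` list-column.
#' @param species_tree A `species_tree`.
#' @return Tibble: `branch_id`, `n_trees`, `fraction_of_lore`,
#'   `is_lineage_stem`, `lineage`.
#' @export
map_events <- function(classification, species_tree) {
  ev <- classification_events(classification)
  lore <- ev[ev$class == "LORe", ]
  n_lore <- if (inherits(classification, "redip_classification")) {
    sum(classification$classifications$class == "LORe")
  } else {
    df <- classification
    sum(df$class == "LORe")
  }
  if (n_lore == 0 || nrow(lore) == 0) {
    return(tibble(branch_id = character(), n_trees = integer(),
                  fraction_of_lore = double(), is_lineage_stem = logical(),
                  lineage = character()))
  }
  known <- c(names(species_tree$ages), species_tree$phy$tip.label)
  bad <- setdiff(unique(lore$branch_id), known)
  if (length(bad)) {
    abort(paste0("event references unknown species-tree branch: ",
                 paste(bad, collapse = ", ")))
  }
  stems <- lineage_stem_branches(species_tree)
  lore |>
    dplyr::distinct(.data$locus_id, .data$branch_id) |>
    dplyr::count(.data$branch_id, name = "n_trees") |>
    dplyr::mutate(
      fraction_of_lore = .data$n_trees / n_lore,
      is_lineage_stem = .data$branch_id %in% stems,
      lineage = names(stems)[match(.data$branch_id, stems)]
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_trees))
}

#' Rediploidization rate (ohnologue pairs per Myr)
#'
#' Extrapolates how many ohnologue pairs completed rediploidization per
#' million years along a species-tree branch: `fraction * n_pairs /
#' branch_myr`, where `fraction` is the share of LORe trees whose event falls
#' on the branch, `n_pairs` the number of ohnologue pairs assumed present,
#' and `branch_myr` the branch length. With the genome-wide figures of the
#' salmonid system (40% of 2275 pairs over the 19.5-Myr Salmoninae stem) this
#' gives ~47 pairs/Myr.
#'
#' @param fraction Fraction of pairs resolved on the branch, in [0,1].
#' @param n_pairs Number of ohnologue pairs (>= 0).
#' @param branch_myr Branch length in Myr (> 0).
#' @return One-row tibble: inputs plus `rate` (unrounded), `rate_1dp` and the
#'   `display` string (`"~47"`).
#' @examples
#' rediploidization_rate(0.40, 2275, 19.5)
#' @export
rediploidization_rate <- function(fraction, n_pairs, branch_myr) {
  if (is.na(fraction) || fraction < 0 || fraction > 1) {
    abort("fraction must be in [0,1]")
  }
  if (n_pairs < 0) abort("n_pairs must be >= 0")
  if (branch_myr <= 0) abort("branch_myr must be > 0")
  rate <- fraction * n_pairs / branch_myr
  tibble(
    fraction = fraction, n_pairs = n_pairs, branch_myr = branch_myr,
    rate = rate, rate_1dp = round(rate, 1),
    display = paste0("~", round(rate))
  )
}
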