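#' Simulate a genome layout with LORe/AORe truth blocks
#'
#' Chromosomes are partitioned into equally sized blocks, each block is
#' assigned a rediploidization class, and every locus is placed inside a block
#' of its own truth class. This mirrors the empirical observation that loci
#' sharing a rediploidization history form large contiguous chromosomal
#' regions.
#'
#' @param loci Tibble with `locus_id` and `true_class` (`"LORe"`/`"AORe"`),
#'   typically the truth table from [simulate_gene_trees()].
#' @param n_chrom Number of chromosomes.
#' @param blocks_per_chrom Blocks per chromosome.
#' @param block_bp Block width in bp.
#' @param locus_bp Width of each simulated locus interval.
#' @param seed Optional seed.
#' @return A list with `loci` (tibble: `locus_id`, `chrom`, `start`, `end`,
#'   `true_class`) and `blocks` (truth tibble: `chrom`, `start`, `end`,
#'   `class`, `n_loci`). Coordinates are 0-based half-open.
#' @export
simulate_genome_layout <- function(loci, n_chrom = 10, blocks_per_chrom = 4,
                                   block_bp = 10e6, locus_bp = 5000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(loci) == 0) {
    return(list(
      loci = tibble(locus_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    true_class = character()),
      blocks = tibble(chrom = character(), start = integer(), end = integer(),
                      class = character(), n_loci = integer())
    ))
  }
  stopifnot(all(loci$true_class %in% c("LORe", "AORe")))
  n_blocks <- n_chrom * blocks_per_chrom
  counts <- table(factor(loci$true_class, levels = c("LORe", "AORe")))
  # blocks per class proportional to locus counts, at least one per non-empty
  # class
  b_lore <- if (counts[["LORe"]] == 0) 0L else
    max(1L, round(n_blocks * counts[["LORe"]] / nrow(loci)))
  if (counts[["AORe"]] > 0) b_lore <- min(b_lore, n_blocks - 1L)
  classes <- sample(c(rep("LORe", b_lore), rep("AORe", n_blocks - b_lore)))

  blocks <- tibble(
    chrom = rep(sprintf("chr%02d", seq_len(n_chrom)), each = blocks_per_chrom),
    start = rep((seq_len(blocks_per_chrom) - 1L) * block_bp, n_chrom),
    end = rep(seq_len(blocks_per_chrom) * block_bp, n_chrom),
    class = classes
  )
  blocks$block_i <- seq_len(n_blocks)

  grid_step <- max(locus_bp * 2L, 1e5)
  capacity <- floor(block_bp / grid_step)

  placed <- vector("list", 2)
  names(placed) <- c("LORe", "AORe")
  for (cls in c("LORe", "AORe")) {
    ids <- loci$locus_id[loci$true_class == cls]
    if (!length(ids)) next
    tgt <- blocks$block_i[blocks$class == cls]
    if (length(ids) > length(tgt) * capacity) {
      abort("more loci than available positions; increase blocks or block_bp")
    }
    assigned <- tgt[(seq_along(ids) - 1L) %% length(tgt) + 1L]
    pos <- integer(length(ids))
    for (b in unique(assigned)) {
      sel <- which(assigned == b)
      slots <- sort(sample.int(capacity, length(sel)) - 1L)
      pos[sel] <- blocks$start[b] + slots * grid_step
    }
    placed[[cls]] <- tibble(locus_id = ids,
                            chrom = blocks$chrom[assigned],
                            start = pos, end = pos + as.integer(locus_bp),
                            true_class = cls)
  }
  out_loci <- dplyr::arrange(dplyr::bind_rows(placed), .data$chrom, .data$start)

  blk <- dplyr::count(out_loci, .data$chrom,
                      block_start = (.data$start %/% block_bp) * block_bp)
  blocks <- blocks |>
    dplyr::left_join(blk, by = c("chrom", start = "block_start")) |>
    dplyr::mutate(n_loci = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("chrom", "start", "end", "class", "n_loci")

  list(loci = out_loci, blocks = as_tibble(blocks))
}

#' Simulate a gene annotation over truth blocks
#'
#' Places genes uniformly within the given blocks (in proportion to block
#' length); each gene inherits the class of its block. Used to exercise
#' genome-wide extrapolation of ohnologue counts.
#'
#' @param blocks Truth blocks from [simulate_genome_layout()].
#' @param n_genes Number of genes.
#' @param gene_bp Gene interval width.
#' @param seed Optional seed.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `true_class`.
#' @export
simulate_gene_annotation <- function(blocks, n_genes, gene_bp = 2000,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(blocks) == 0 || n_genes < 1) abort("need blocks and n_genes >= 1")
  widths <- blocks$end - blocks$start
  pick <- sample.int(nrow(blocks), n_genes, replace = TRUE,
                     prob = widths / sum(widths))
  start <- blocks$start[pick] +
    floor(runif(n_genes, 0, pmax(widths[pick] - gene_bp, 1)))
  tibble(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chrom = blocks$chrom[pick],
    start = as.integer(start),
    end = as.integer(start + gene_bp),
    true_class = blocks$class[pick]
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}
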