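test_that("segmentation merges runs and places midpoint boundaries", {
  loci <- tibble::tibble(
    locus_id = paste0("L", 1:6), chrom = "chr01",
    start = 1:6 * 1e6, end = 1:6 * 1e6 + 5000,
    class = c("AORe", "AORe", "AORe", "LORe", "LORe", "AORe")
  )
  blocks <- segment_regions(loci)
  expect_equal(blocks$class, c("AORe", "LORe", "AORe"))
  expect_equal(blocks$n_supporting_loci, c(3L, 2L, 1L))
  # boundary between block 1 and 2: midpoint of locus 3 end / locus 4 start
  expect_equal(blocks$end[1], (3e6 + 5000 + 4e6) %/% 2)
  expect_equal(blocks$start[2], blocks$end[1])

  one <- segment_regions(dplyr::mutate(loci, class = "LORe"))
  expect_equal(nrow(one), 1)
  expect_equal(one$class, "LORe")
  expect_equal(c(one$start, one$end), c(1e6, 6e6 + 5000))
})

test_that("non-decisive loci and singleton flips do not break runs", {
  loci <- tibble::tibble(
    locus_id = paste0("L", 1:7), chrom = "chr01",
    start = 1:7 * 1e6, end = 1:7 * 1e6 + 5000,
    class = c("AORe", "ambiguous", "AORe", "LORe", "AORe", "uninformative",
              "AORe")
  )
  blocks <- segment_regions(loci)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$class, "AORe")
  expect_equal(blocks$n_supporting_loci, 4L)
  expect_equal(blocks$n_discordant_loci, 3L)
})

test_that("segmentation is idempotent on its own supporting loci", {
  loci <- tibble::tibble(
    locus_id = paste0("L", 1:8), chrom = "chr01",
    start = 1:8 * 1e6, end = 1:8 * 1e6 + 5000,
    class = c("AORe", "AORe", "LORe", "LORe", "LORe", "AORe", "AORe", "AORe")
  )
  b1 <- segment_regions(loci)
  b2 <- segment_regions(loci)
  expect_identical(b1, b2)
  # feeding two representative loci per block back reproduces the classes
  rep_loci <- dplyr::bind_rows(
    dplyr::transmute(b1, locus_id = paste0("Ba", dplyr::row_number()),
                     chrom = chrom, start = start, end = start + 1000L,
                     class = class),
    dplyr::transmute(b1, locus_id = paste0("Bb", dplyr::row_number()),
                     chrom = chrom, start = end - 1000L, end = end,
                     class = class)
  )
  b3 <- segment_regions(rep_loci)
  expect_equal(b3$class, b1$class)
  expect_equal(c(b3$start[1], b3$end[nrow(b3)]),
               c(b1$start[1], b1$end[nrow(b1)]))
})

test_that("noise-free simulated layouts are recovered block by block", {
  sim <- simulate_gene_trees(fix_st, noise_free_params(rng_seed = 8),
                             n_loci = 80)
  layout <- simulate_genome_layout(
    dplyr::select(sim$truth, "locus_id", "true_class"),
    n_chrom = 3, blocks_per_chrom = 3, seed = 8)
  cls <- classify_batch(sim$trees, fix_st)
  loci <- dplyr::left_join(layout$loci,
                           dplyr::select(tidy(cls), "locus_id", "class"),
                           by = "locus_id")
  got <- segment_regions(dplyr::select(loci, -"true_class"))
  truth_occupied <- layout$blocks[layout$blocks$n_loci > 0, ]
  # same number of occupied runs per chromosome, same classes in order,
  # boundaries within one inter-locus gap of the truth
  for (ch in unique(truth_occupied$chrom)) {
    g <- got[got$chrom == ch, ]
    tr_runs <- rle(truth_occupied$class[truth_occupied$chrom == ch])$values
    expect_equal(g$class, tr_runs)
  }
  # every supporting locus sits in a truth block of the same class
  expect_equal(sum(got$n_discordant_loci), 0)
  expect_equal(sum(got$n_supporting_loci), nrow(loci))
})

test_that("gene-count extrapolation reproduces the printed fractions", {
  blocks <- tibble::tibble(
    chrom = c("chr01", "chr01"), start = c(0L, 100e6), end = c(100e6, 500e6),
    class = c("LORe", "AORe")
  )
  genes <- tibble::tibble(
    gene_id = sprintf("g%05d", 1:16786),
    chrom = "chr01",
    start = c(seq(0, 100e6 - 2000, length.out = 4550),
              seq(100e6, 500e6 - 2000, length.out = 16786 - 4550)),
    end = start + 1000
  )
  counts <- extrapolate_gene_counts(blocks, genes)
  expect_equal(counts$pct[counts$class == "LORe"], 27.1)
  expect_equal(counts$pct[counts$class == "AORe"], 72.9)
  expect_equal(counts$n_pairs[counts$class == "LORe"], 2275)
  # conservation: assigned + unassigned = total
  expect_equal(sum(counts$n_genes), 16786)
})

test_that("extrapolation handles edge cases and matches simulated truth", {
  blocks <- tibble::tibble(chrom = "chr01", start = 0L, end = 1000L,
                           class = "LORe")
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr01",
                          start = 10L, end = 20L)
  counts <- extrapolate_gene_counts(blocks, genes)
  expect_equal(counts$fraction[counts$class == "LORe"], 1)
  expect_equal(counts$pct[counts$class == "AORe"], 0)
  expect_error(extrapolate_gene_counts(blocks, genes[0, ]), "empty")

  sim <- simulate_gene_trees(fix_st, noise_free_params(rng_seed = 13),
                             n_loci = 50)
  layout <- simulate_genome_layout(
    dplyr::select(sim$truth, "locus_id", "true_class"), seed = 13)
  genes2 <- simulate_gene_annotation(layout$blocks, 1000, seed = 13)
  truth_blocks <- dplyr::rename(layout$blocks, n_supporting_loci = "n_loci")
  counts2 <- extrapolate_gene_counts(truth_blocks, genes2)
  expect_equal(counts2$n_genes[counts2$class == "LORe"],
               sum(genes2$true_class == "LORe"))
  expect_equal(counts2$n_genes[counts2$class == "AORe"],
               sum(genes2$true_class == "AORe"))
})

test_that("event mapping reports per-branch fractions of LORe trees", {
  # the printed worked example: 60 of 151 LORe trees with a Salmoninae-stem
  # event gives a 39.7% stem fraction
  empty_ev <- tibble::tibble(branch_id = character(), node = integer(),
                             span = list())
  mk_ev <- function(branch) tibble::tibble(branch_id = branch, node = 1L,
                                           span = list("x"))
  cls <- tibble::tibble(
    locus_id = sprintf("t%03d", 1:151),
    class = "LORe",
    events = c(replicate(60, mk_ev("Salmoninae"), simplify = FALSE),
               replicate(91, mk_ev("whitefish"), simplify = FALSE))
  )
  ev <- map_events(cls, fix_st)
  sal <- ev[ev$branch_id == "Salmoninae", ]
  expect_equal(sal$n_trees, 60L)
  expect_equal(round(sal$fraction_of_lore, 3), 0.397)
  expect_true(sal$is_lineage_stem)
  expect_equal(sal$lineage, "Salmoninae")

  none <- map_events(cls[0, ], fix_st)
  expect_equal(nrow(none), 0)
  bad <- tibble::tibble(locus_id = "x", class = "LORe",
                        events = list(mk_ev("NotABranch")))
  expect_error(map_events(bad, fix_st), "unknown species-tree branch")
})

test_that("event tallies equal truth tallies on noise-free simulations", {
  sim <- simulate_gene_trees(fix_st, noise_free_params(rng_seed = 19),
                             n_loci = 60)
  cls <- classify_batch(sim$trees, fix_st)
  ev <- map_events(cls, fix_st)
  truth_ev <- sim$truth |>
    dplyr::filter(.data$true_class == "LORe") |>
    tidyr::separate_rows("event_branches", sep = ";") |>
    dplyr::count(branch_id = .data$event_branches)
  got <- dplyr::arrange(dplyr::select(ev, "branch_id", "n_trees"), branch_id)
  want <- dplyr::arrange(dplyr::rename(truth_ev, n_trees = "n"), branch_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("rediploidization rates match the printed extrapolations", {
  sal <- rediploidization_rate(0.40, 2275, 19.5)
  expect_equal(sal$rate_1dp, 46.7)
  expect_equal(sal$display, "~47")
  whi <- rediploidization_rate(0.14, 2275, 25.5)
  expect_equal(whi$rate_1dp, 12.5)
  expect_equal(whi$display, "~12")
  expect_equal(rediploidization_rate(0, 2275, 19.5)$rate, 0)
  expect_error(rediploidization_rate(0.4, 2275, 0), "> 0")
  expect_error(rediploidization_rate(1.4, 2275, 10), "\\[0,1\\]")
})

test_that("the rate scales linearly in f and P and inversely in L", {
  grid <- expand.grid(f = c(0.1, 0.5, 0.9), P = c(10, 1000), L = c(2, 20))
  base <- purrr::pmap_dbl(grid, function(f, P, L) {
    rediploidization_rate(f, P, L)$rate
  })
  expect_equal(base, grid$f * grid$P / grid$L)
  expect_equal(rediploidization_rate(0.2, 100, 5)$rate * 3,
               rediploidization_rate(0.6, 100, 5)$rate)
  expect_equal(rediploidization_rate(0.2, 100, 5)$rate,
               rediploidization_rate(0.2, 100, 10)$rate * 2)
})
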