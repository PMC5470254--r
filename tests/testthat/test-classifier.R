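test_that("outgroup rooting returns the ingroup subtree or a clear error", {
  ing <- root_on_outgroup(read_newick("(Eluc,(Ssal,Tbai));"), fix_map)
  expect_equal(sort(ing$tip.label), c("Ssal", "Tbai"))
  expect_error(root_on_outgroup(read_newick("(Ssal,Tbai);"), fix_map),
               "outgroup absent")
  expect_error(
    root_on_outgroup(read_newick("((Eluc|a,Ssal),(Eluc|b,Tbai));"), fix_map),
    "paraphyletic")
  # two outgroup tips forming a clade are fine
  ing2 <- root_on_outgroup(
    read_newick("((Eluc|a,Eluc|b),(Ssal,Tbai));"), fix_map)
  expect_equal(sort(ing2$tip.label), c("Ssal", "Tbai"))
})

test_that("support collapse contracts exactly the weak edges", {
  t5 <- read_newick("((A,B)0.5,(C,(D,E)0.99)1);")
  c95 <- collapse_unsupported(t5, 0.95)
  # the 0.5 edge is gone: its parent gains a child
  rp <- redipr:::phylo_to_rep(c95)
  expect_equal(length(rp$children[[rp$root]]), 3)
  expect_equal(sort(c95$tip.label), sort(t5$tip.label))
  # thresholds 0 and all-strong supports are the identity
  expect_identical(write_newick(collapse_unsupported(t5, 0)), write_newick(t5))
  strong <- read_newick("((A,B)0.99,(C,D)0.98);")
  expect_identical(write_newick(collapse_unsupported(strong, 0.95)),
                   write_newick(strong))
  # missing supports are treated as passing
  nosup <- read_newick("((A,B),(C,D));")
  expect_identical(write_newick(collapse_unsupported(nosup, 0.95)),
                   write_newick(nosup))
  expect_error(collapse_unsupported(t5, 1.2), "\\[0,1\\]")
})

test_that("species-overlap duplication detection matches hand-worked cases", {
  d1 <- find_duplication_nodes(
    read_newick("((Ssal,(Tbai,Clav)),(Ssal,(Tbai,Clav)));"), toy_map, fix_st)
  expect_equal(nrow(d1), 1)
  expect_true(d1$is_root)
  expect_equal(d1$span[[1]], c("Clav", "Ssal", "Tbai"))
  expect_equal(d1$mapped_node, "Salmonidae")

  d3 <- find_duplication_nodes(
    read_newick("(((Ssal,Ssal),(Tbai,Tbai)),(Clav,Clav));"), toy_map, fix_st)
  expect_equal(nrow(d3), 3)
  expect_setequal(unlist(d3$span), c("Ssal", "Tbai", "Clav"))
  expect_false(any(d3$is_root))

  d0 <- find_duplication_nodes(read_newick("(Ssal,(Tbai,Clav));"), toy_map)
  expect_equal(nrow(d0), 0)

  expect_error(
    find_duplication_nodes(read_newick("(Xxxx,(Tbai,Clav));"), toy_map),
    "unknown species")
  expect_error(
    find_duplication_nodes(read_newick("(Eluc,(Tbai,Clav));"), toy_map),
    "outgroup tips")
})

test_that("duplication detection equals the clade-enumeration oracle", {
  set.seed(11)
  for (i in 1:200) {
    phy <- random_species_tree_sample(sample(4:12, 1))
    got <- sort(find_duplication_nodes(phy, fix_map)$node)
    want <- sort(oracle_duplication_nodes(phy))
    expect_equal(got, want)
  }
})

test_that("topology classes follow the AORe/LORe rules", {
  cls <- function(txt) classify_tree(read_newick(txt), fix_st, toy_map)
  aore <- cls("(Eluc,((Ssal,(Tbai,Clav)),(Ssal,(Tbai,Clav))));")
  expect_equal(aore$class, "AORe")
  expect_equal(aore$events[[1]]$branch_id, "Salmonidae")
  expect_equal(aore$n_events, 1)

  lore3 <- cls("(Eluc,(((Ssal,Ssal),(Tbai,Tbai)),(Clav,Clav)));")
  expect_equal(lore3$class, "LORe")
  expect_setequal(lore3$events[[1]]$branch_id, c("Ssal", "Tbai", "Clav"))
  expect_equal(lore3$n_events, 3)

  amb <- cls("(Eluc,((Ssal,(Tbai,Tbai)),(Ssal,Clav)));")
  expect_equal(amb$class, "ambiguous")

  lore1 <- cls("(Eluc,((Ssal,Ssal),(Tbai,Clav)));")
  expect_equal(lore1$class, "LORe")
  expect_equal(lore1$events[[1]]$branch_id, "Ssal")
  status <- lore1$lineage_status[[1]]
  expect_equal(status[["Salmoninae"]], "duplicated")
  expect_equal(status[["Thymallinae"]], "single_copy")
  expect_equal(status[["Coregoninae"]], "single_copy")

  expect_equal(cls("(Eluc,(Ssal,(Tbai,Clav)));")$class, "uninformative")
  # >2 tips of one species signals possible small-scale duplication
  expect_equal(cls("(Eluc,((Ssal,Ssal),(Ssal,Clav)));")$class, "ambiguous")
})

test_that("classification is invariant to child order", {
  sim <- simulate_gene_trees(fix_st, sim_params(rng_seed = 3), n_loci = 40)
  cls <- classify_batch(sim$trees, fix_st)
  flipped <- lapply(sim$trees, permute_children)
  cls2 <- classify_batch(flipped, fix_st)
  expect_equal(cls$classifications$class, cls2$classifications$class)
  expect_equal(cls$classifications$n_events, cls2$classifications$n_events)
})

test_that("noise-free simulations are classified with perfect accuracy", {
  sim <- simulate_gene_trees(fix_st, noise_free_params(rng_seed = 5),
                             n_loci = 50)
  cls <- classify_batch(sim$trees, fix_st)
  joined <- dplyr::left_join(tidy(cls),
                             sim$truth[, c("locus_id", "true_class")],
                             by = "locus_id")
  expect_true(all(joined$class == joined$true_class))
  # inferred event branches equal the truth branches
  expect_true(all(
    purrr::map2_lgl(joined$event_branches, joined$true_class,
                    function(b, tc) tc == "LORe" || b == "Salmonidae")
  ))
})

test_that("full collapse of every lineage leaves all loci uninformative", {
  p <- noise_free_params(collapse_prob = 1, rng_seed = 2)
  p$collapsible_lineages <- c("Salmoninae", "Thymallinae", "Coregoninae")
  sim <- simulate_gene_trees(fix_st, p, n_loci = 20)
  cls <- classify_batch(sim$trees, fix_st)
  expect_true(all(cls$classifications$class == "uninformative"))
})

test_that("raising the support threshold never flips AORe and LORe directly", {
  sim <- simulate_gene_trees(
    fix_st,
    sim_params(rng_seed = 9,
               support_model = list(prob_weak = 0.3, weak = c(0.5, 0.95),
                                    strong = c(0.95, 1))),
    n_loci = 60)
  thr <- c(0, 0.6, 0.9, 0.97)
  classes <- sapply(thr, function(t) {
    classify_batch(sim$trees, fix_st,
                   config = run_config(support_threshold = t)
    )$classifications$class
  })
  for (i in seq_len(nrow(classes))) {
    for (j in seq_len(length(thr) - 1)) {
      a <- classes[i, j]
      b <- classes[i, j + 1]
      direct_flip <- (a == "AORe" && b == "LORe") ||
        (a == "LORe" && b == "AORe")
      expect_false(direct_flip)
    }
  }
})

test_that("batch classification survives broken trees", {
  sim <- simulate_gene_trees(fix_st, noise_free_params(rng_seed = 1),
                             n_loci = 5)
  trees <- sim$trees
  trees$bad <- ape::read.tree(text = "(Ssal,Tbai);")  # no outgroup
  cls <- classify_batch(trees, fix_st)
  expect_equal(sum(cls$classifications$class == "error"), 1)
  expect_equal(nrow(cls$classifications), 6)
  expect_match(cls$classifications$notes[cls$classifications$class == "error"],
               "outgroup")
})
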