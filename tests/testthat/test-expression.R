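test_that("TMM factors behave as the closed forms require", {
  x <- matrix(rpois(400, 60), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  same <- cbind(s1 = x[, 1], s2 = x[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  depth <- cbind(s1 = x[, 1], s2 = 2L * x[, 1])
  expect_equal(unname(tmm_factors(depth)), c(1, 1))

  # composition bias: 5 genes 10-fold up in sample 2 pull its factor down
  comp <- cbind(s1 = x[, 1], s2 = x[, 1])
  comp[1:5, 2] <- comp[1:5, 2] * 10L
  f <- tmm_factors(comp)
  expect_lt(f[["s2"]], f[["s1"]])
  expect_equal(prod(f)^(1 / length(f)), 1, tolerance = 1e-12)

  expect_error(tmm_factors(x[, 1, drop = FALSE]), "two samples")
  allzero <- cbind(s1 = x[, 1], s2 = 0L)
  expect_error(tmm_factors(allzero), "all-zero")
})

test_that("CPM is depth-invariant and matches its definition", {
  m <- matrix(c(10, 90, 20, 180), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpm_matrix(m)
  expect_equal(cpm[, "s1"], c(g1 = 1e5, g2 = 9e5))
  # doubling all counts of a sample leaves its CPM unchanged
  expect_equal(cpm[, "s2"], cpm[, "s1"])
  single <- matrix(10, 1, 1, dimnames = list("g", "s"))
  single_lib <- rbind(single, other = 1e6 - 10)
  expect_equal(cpm_matrix(single_lib)["g", "s"], 10)
})

test_that("tissue profiles pool replicates by the mean", {
  counts <- matrix(c(10, 20, 30, 40, 50, 60), 1, 6,
                   dimnames = list("g1", paste0("s", 1:6)))
  samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                            tissue = rep(c("gill", "liver", "brain"), each = 2))
  prof <- tissue_profile(counts, samples)  # use raw values as-is
  expect_equal(as.numeric(prof[1, c("gill", "liver", "brain")]),
               c(15, 35, 55))
  expect_error(tissue_profile(counts, samples[1:3, ]), "without metadata")
})

test_that("pearson correlation matches the textbook cases", {
  expect_equal(pair_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pair_correlation(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pair_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(pair_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pair_correlation(1:3, 1:4), "length")
  expect_error(pair_correlation(1:2, 1:2), "at least 3")
})

test_that("condition log fold-changes and BH adjustment are exact", {
  cpm <- matrix(c(10, 10, 40, 10), 1, 4,
                dimnames = list("g1", paste0("s", 1:4)))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    tissue = c("gill", "gill", "gill", "liver"),
    condition = c("freshwater", "saltwater", "saltwater", "freshwater")
  )
  expect_warning(lfc <- response_logfc(cpm, samples, pseudocount = 0.5),
                 "liver")
  expect_equal(lfc$gill, log2(25.5 / 10.5))
  eq <- matrix(c(10, 10), 1, 2, dimnames = list("g1", c("a", "b")))
  eqs <- tibble::tibble(sample_id = c("a", "b"), tissue = "gill",
                        condition = c("freshwater", "saltwater"))
  expect_equal(response_logfc(eq, eqs)$gill, 0)

  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  # monotone in rank order, never below raw p
  set.seed(1)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("BH matches a hand-rolled step-up oracle", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:25, 1))
    expect_equal(bh_fdr(p), step_up(p))
  }
})

test_that("group comparison uses exact enumeration where prescribed", {
  gt <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_true(gt$exact)
  expect_equal(gt$p_value, 0.1)
  expect_equal(gt$direction, -1)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))  # ties: approximation path
  expect_false(same$exact)
  expect_equal(same$p_value, 1)

  with_na <- compare_groups(c(0.5, NA, 0.7), c(0.1, 0.2))
  expect_equal(with_na$n_excluded, 1)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("exact Wilcoxon p-values equal full enumeration", {
  enum_p <- function(x, y) {
    ranks <- rank(c(x, y))
    w_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    all_w <- apply(utils::combn(length(x) + length(y), length(x)), 2,
                   function(idx) {
                     sum(rank(c(x, y))[idx]) - length(x) * (length(x) + 1) / 2
                   })
    mean_w <- length(x) * length(y) / 2
    mean(abs(all_w - mean_w) >= abs(w_obs - mean_w) - 1e-9)
  }
  set.seed(3)
  for (i in 1:15) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:8, 1)
    vals <- sample(1:1000, n1 + n2)  # no ties
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    gt <- compare_groups(x, y)
    expect_true(gt$exact)
    expect_equal(gt$p_value, enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("a true location shift is detected with the right direction", {
  set.seed(4)
  lore <- rnorm(300, 0.8, 0.1)
  aore <- rnorm(300, 0.6, 0.15)
  gt <- compare_groups(lore, aore)
  expect_lt(gt$p_value, 1e-6)
  expect_equal(gt$direction, 1)
})

test_that("neofunctionalization calls follow the threshold rule", {
  set.seed(5)
  anc <- rnorm(15, 4, 1.5)
  novel <- rnorm(15, 4, 1.5)
  stopifnot(cor(novel, anc) < 0.6)
  expect_equal(classify_neofunctionalization(anc, novel, anc),
               "neofunctionalized_copy2")
  expect_equal(classify_neofunctionalization(novel, anc, anc),
               "neofunctionalized_copy1")
  expect_equal(classify_neofunctionalization(anc, anc, anc), "conserved")
  expect_equal(classify_neofunctionalization(novel, rnorm(15), anc),
               "both_diverged")
  expect_equal(classify_neofunctionalization(rep(1, 15), anc, anc),
               "unclassifiable")
  expect_error(classify_neofunctionalization(anc, novel, anc[1:5]), "length")
})

test_that("forced neofunctionalization is recovered from counts", {
  p <- sim_params(rng_seed = 53)
  p$expression$neo_hazard <- 1e6  # force neofunctionalization at any tau > 0
  n <- 500
  pairs <- tibble::tibble(pair_id = sprintf("P%03d", 1:n),
                          region_class = "sim", tau = 40)
  expr <- simulate_expression(pairs, p)
  div <- pair_divergence(expr$atlas_counts, expr$atlas_samples,
                         tibble::tibble(pair_id = pairs$pair_id,
                                        copy1 = paste0(pairs$pair_id, "_1"),
                                        copy2 = paste0(pairs$pair_id, "_2"),
                                        outgroup = paste0(pairs$pair_id, "_out")))
  truth <- expr$pair_truth
  expect_true(all(truth$neofunctionalized))
  called <- div$neofunct_status == paste0("neofunctionalized_copy",
                                          truth$neo_copy)
  expect_gte(mean(called), 0.95)
})

test_that("hypergeometric enrichment equals closed forms and brute force", {
  expect_equal(neofunct_enrichment(8, 8, 8, 20)$p_value, 1 / choose(20, 8))
  expect_equal(neofunct_enrichment(10, 10, 20, 20)$p_value, 1)

  brute <- function(k, n, K, N) {
    i <- k:min(n, K)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
  }
  set.seed(6)
  for (N in c(8, 15, 23, 30)) {
    for (rep in 1:10) {
      pick <- function(v) v[sample.int(length(v), 1)]
      K <- pick(0:N)
      n <- pick(0:N)
      k <- pick(max(0, n + K - N):min(n, K))
      expect_equal(neofunct_enrichment(k, n, K, N)$p_value,
                   brute(k, n, K, N), tolerance = 1e-12)
    }
  }
  expect_error(neofunct_enrichment(10, 5, 8, 20), "inconsistent")
})

test_that("window summaries average pair correlations per 4-Mb tile", {
  pd <- tibble::tibble(
    chrom = c("chr01", "chr01", "chr01"),
    start = c(1e6, 2e6, 9e6), end = c(1e6 + 100, 2e6 + 100, 9e6 + 100),
    r_tissue = c(0.2, 0.8, 0.9)
  )
  w <- window_correlation(pd, window_bp = 4e6)
  expect_equal(nrow(w), 2)
  expect_equal(w$mean_r, c(0.5, 0.9))
  expect_equal(w$high_cor, c(FALSE, TRUE))
  expect_equal(w$n_pairs, c(2L, 1L))
  empty <- window_correlation(pd[0, ], window_bp = 4e6)
  expect_equal(nrow(empty), 0)
})
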