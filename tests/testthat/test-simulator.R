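small_cfg <- function(...) {
  sim_config(n_cells = 8, layout = uniform_layout(2, 2e7), ...)
}

test_that("coalescent trees have the right shape and are reproducible", {
  tr <- sample_tree(3, seed = 1)
  expect_equal(length(tr$tip.label) + tr$Nnode, 5)
  expect_equal(nrow(tr$edge), 4)
  expect_error(sample_tree(2), ">= 3")
  t1 <- sample_tree(20, seed = 42)
  t2 <- sample_tree(20, seed = 42)
  expect_equal(nrfd(t1, t2), 0)
  expect_identical(t1$edge, t2$edge)
})

test_that("four-taxon coalescent topologies are balanced with probability 1/3", {
  set.seed(8)
  n_rep <- 900
  balanced <- 0
  for (i in seq_len(n_rep)) {
    tr <- sample_tree(4)
    # balanced iff the root's two children are both internal
    kids <- tr$edge[tr$edge[, 1] == 5, 2]
    if (all(kids > 4)) balanced <- balanced + 1
  }
  p_hat <- balanced / n_rep
  se <- sqrt(1 / 3 * 2 / 3 / n_rep)
  expect_lt(abs(p_hat - 1 / 3), 3.5 * se)
})

test_that("growth rescaling changes times but never the topology", {
  t0 <- sample_tree(15, growth = 0, seed = 4)
  t1 <- sample_tree(15, growth = 5, seed = 4)
  expect_equal(nrfd(t0, t1), 0)
  expect_false(isTRUE(all.equal(t0$edge.length, t1$edge.length)))
})

test_that("a silent simulation leaves every leaf diploid", {
  cfg <- small_cfg(lambda = 0, founder_multiplier = 0)
  sim <- simulate_dataset(cfg, noise_config("none"), seed = 2)
  expect_true(all(sim$clean$cn == 1L))      # 1 per allele
  expect_true(all(as_total(sim$clean)$cn == 2L))
  expect_equal(nrow(sim$events), 0)
})

test_that("WGD alone doubles every allele bin", {
  cfg <- small_cfg(lambda = 0, founder_multiplier = 0, wgd = TRUE)
  sim <- simulate_dataset(cfg, noise_config("none"), seed = 2)
  expect_true(all(sim$clean$cn == 2L))
})

test_that("per-edge event counts have the configured Poisson mean", {
  lambda <- 2
  counts <- integer(0)
  for (s in 1:3) {
    tree <- sample_tree(100, seed = s)
    evo <- evolve(tree, sim_config(n_cells = 100, layout = uniform_layout(2, 5e7),
                                   lambda = lambda, founder_multiplier = 0),
                  seed = s + 10)
    root <- 101
    per_node <- table(factor(evo$events$node, levels = seq_len(199)))
    counts <- c(counts, as.integer(per_node[-root]))
  }
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("gain copy counts follow the geometric distribution with mean delta", {
  set.seed(33)
  tree <- sample_tree(60, seed = 21)
  evo <- evolve(tree, sim_config(n_cells = 60, layout = uniform_layout(4, 5e7),
                                 lambda = 4, delta = 2), seed = 5)
  copies <- evo$events$copies[evo$events$type == "gain"]
  expect_true(all(copies >= 1))
  se <- sqrt(2 * (2 - 1)) / sqrt(length(copies))  # geometric variance d(d-1)
  expect_lt(abs(mean(copies) - 2), 4 * se)
})

test_that("binned profiles follow the region-count rounding rule", {
  lay <- uniform_layout(1, 4e6)             # 4 bins of 1000 regions
  nr <- lay$n_regions[[1]]
  base <- matrix(c(1L, nr), ncol = 2)
  # a 3-bin-long extra copy fully covering bins 2-4 on allele A
  g_full <- list(chr1 = list(A = rbind(base, matrix(c(1001L, 4000L), ncol = 2)),
                             B = base))
  p <- genomes_to_profiles(list(cellA = g_full), lay)
  a_bins <- p$bins$allele == "A"
  expect_equal(unname(p$cn["cellA", a_bins]), c(1, 2, 2, 2))
  expect_equal(unname(p$cn["cellA", !a_bins]), c(1, 1, 1, 1))
  # an extra copy over exactly half of bin 1 rounds 1.5 up to 2
  g_half <- list(chr1 = list(A = rbind(base, matrix(c(1L, 500L), ncol = 2)),
                             B = base))
  p2 <- genomes_to_profiles(list(cellA = g_half), lay)
  expect_equal(unname(p2$cn["cellA", a_bins])[1], 2)
  # under half (499 regions) rounds down
  g_under <- list(chr1 = list(A = rbind(base, matrix(c(1L, 499L), ncol = 2)),
                              B = base))
  p3 <- genomes_to_profiles(list(cellA = g_under), lay)
  expect_equal(unname(p3$cn["cellA", a_bins])[1], 1)
})

test_that("deletions can take the last copy and empty chromosomes are skipped", {
  lay <- uniform_layout(2, 3e6)
  cfg <- sim_config(n_cells = 5, layout = lay, lambda = 8, p_gain = 0,
                    beta = 3e6, founder_multiplier = 10)
  sim <- simulate_dataset(cfg, noise_config("none"), seed = 14)
  expect_true(any(sim$clean$cn == 0L))       # full losses occur
  expect_true(all(sim$clean$cn >= 0L))
})

test_that("jitter alters bins at the analytic Gaussian-tail rates", {
  lay <- uniform_layout(1, 5e7)
  n <- lay$n_bins[[1]]
  for (c_val in c(2, 3)) {
    cn <- matrix(as.integer(c_val), 40, n,
                 dimnames = list(paste0("c", 1:40), NULL))
    x <- cnp_set(cn, lay)
    y <- apply_jitter(x, 0.1, seed = c_val)
    frac <- mean(y$cn != c_val)
    expected <- 2 * (1 - pnorm(0.5 / (c_val * 0.1)))
    se <- sqrt(expected * (1 - expected) / length(cn))
    expect_lt(abs(frac - expected), 4 * se)
  }
  # zero bins never fluctuate; r_j = 0 is the identity
  z <- cnp_set(matrix(0L, 2, n, dimnames = list(c("a", "b"), NULL)), lay)
  expect_identical(apply_jitter(z, 0.1, seed = 1)$cn, z$cn)
  x <- random_cnp(3)
  expect_identical(apply_jitter(x, 0, seed = 1)$cn, x$cn)
})

test_that("boundary noise moves a two-segment boundary like a rounded unit Gaussian", {
  lay <- uniform_layout(1, 2e7)              # 20 bins
  cn <- matrix(rep(c(2L, 3L), each = 10), 1, 20, dimnames = list("a", NULL))
  x <- cnp_set(cn, lay)
  set.seed(99)
  shifts <- replicate(4000, {
    y <- apply_boundary(x, 0.1)
    sum(y$cn == 2L) - 10L                    # boundary displacement in bins
  })
  # segment length 10, r_b 0.1 => shift ~ round(N(0, 1))
  p0 <- pnorm(0.5) - pnorm(-0.5)
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(mean(shifts == 0) - p0), 4 * se)
  expect_lt(abs(mean(shifts)), 4 * 1 / sqrt(4000))
  p1 <- pnorm(1.5) - pnorm(0.5)
  expect_lt(abs(mean(shifts == 1) - p1), 4 * sqrt(p1 * (1 - p1) / 4000))
})

test_that("boundary noise is the identity on flat chromosomes and at rate 0", {
  x <- make_cnp(list(a = rep(2, 8), b = rep(3, 8)), n_bins_per_chrom = 4)
  expect_identical(apply_boundary(x, 0.2, seed = 1)$cn, x$cn)
  y <- random_cnp(3)
  expect_identical(apply_boundary(y, 0, seed = 1)$cn, y$cn)
})

test_that("noise models conserve the bin structure", {
  sim <- simulate_dataset(small_cfg(lambda = 3), noise_config("high"), seed = 6)
  expect_identical(dim(sim$noisy$cn), dim(sim$clean$cn))
  expect_identical(sim$noisy$bins, sim$clean$bins)
  expect_true(all(sim$noisy$cn >= 0L))
})

test_that("full simulations are reproducible and noise-free bundles are self-consistent", {
  s1 <- simulate_dataset(small_cfg(lambda = 2), noise_config("high"), seed = 17)
  s2 <- simulate_dataset(small_cfg(lambda = 2), noise_config("high"), seed = 17)
  expect_identical(s1$clean$cn, s2$clean$cn)
  expect_identical(s1$noisy$cn, s2$noisy$cn)
  expect_equal(nrfd(s1$tree, s2$tree), 0)
  s3 <- simulate_dataset(small_cfg(lambda = 2), noise_config("none"), seed = 17)
  expect_identical(s3$clean$cn, s3$noisy$cn)
})

test_that("clone labels are exactly the leaf sets of the selected clades", {
  cfg <- sim_config(n_cells = 40, layout = uniform_layout(2, 5e7), n_clones = 3)
  sim <- simulate_dataset(cfg, noise_config("none"), seed = 23)
  labs <- setdiff(unique(sim$clones), "none")
  expect_equal(length(labs), 3)
  splits <- oracle_splits(sim$tree)
  for (cl in labs) {
    cells <- names(sim$clones)[sim$clones == cl]
    expect_gte(length(cells), 40 / (4 * 3))
    expect_lte(length(cells), 40 / 3 + 1e-9)
    key <- paste(sort(cells), collapse = "|")
    first <- sort(sim$tree$tip.label)[1]
    if (first %in% cells) {
      key <- paste(sort(setdiff(sim$tree$tip.label, cells)), collapse = "|")
    }
    expect_true(key %in% splits)
  }
  # clone F1 of the truth tree against its own clones is exactly 1
  expect_equal(clone_f1(sim$tree, sim$clones), 1)
})

test_that("hg38 default simulations produce the expected genome scale", {
  sim <- simulate_dataset(sim_config(n_cells = 3, lambda = 1),
                          noise_config("none"), seed = 1)
  expect_gt(ncol(sim$clean$cn), 5700)
  expect_equal(nrow(sim$clean$layout$chromosomes), 22)
})
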