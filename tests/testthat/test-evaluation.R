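test_that("nrfd is zero on identical trees and one against a star", {
  tr <- sample_tree(12, seed = 3)
  expect_equal(nrfd(tr, tr), 0)
  star <- ape::read.tree(text = paste0("(", paste(tr$tip.label, collapse = ","), ");"))
  expect_equal(nrfd(tr, star), 1)
  expect_equal(nrfd(star, tr), 1)
  expect_error(nrfd(tr, sample_tree(11, seed = 1)), "leaf sets")
})

test_that("nrfd matches the explicit bipartition count on a worked 5-leaf pair", {
  # both trees have two nontrivial splits and share exactly one ({d,e})
  t1 <- ape::read.tree(text = "((a,b),c,(d,e));")
  t2 <- ape::read.tree(text = "((a,c),b,(d,e));")
  expect_equal(nrfd(t1, t2), (1 + 1) / (2 + 2))
})

test_that("nrfd agrees with the brute-force oracle on random binary and multifurcating trees", {
  set.seed(15)
  for (rep in 1:6) {
    t1 <- sample_tree(9)
    t2 <- sample_tree(9)
    expect_equal(nrfd(t1, t2), oracle_nrfd(t1, t2))
    expect_equal(nrfd(t1, t2), nrfd(t2, t1))
    # collapse a random internal edge of t2: fewer asserted splits only
    t2m <- ape::di2multi(t2, tol = stats::quantile(t2$edge.length, 0.3))
    expect_equal(nrfd(t1, t2m), oracle_nrfd(t1, t2m))
  }
})

test_that("clone F1 handles the worked caterpillar case and clade clones", {
  tr <- ape::read.tree(text = "(((a,b),d),(c,e));")
  clones <- c(a = "k1", b = "k1", c = "k1")
  # best side for {a,b,c} is {a,b}: precision 1, recall 2/3, F1 0.8
  expect_equal(clone_f1(tr, clones), 0.8)
  expect_equal(oracle_best_f1(tr, c("a", "b", "c")), 0.8)
  # clones that are exact clades score 1; averaging over clones is plain
  clones2 <- c(a = "k1", b = "k1", c = "k2", e = "k2")
  got <- clone_f1(tr, clones2)
  expect_equal(got, (1 + oracle_best_f1(tr, c("c", "e"))) / 2)
})

test_that("clone F1 equals the exhaustive bipartition-side oracle on random cases", {
  set.seed(44)
  for (rep in 1:5) {
    tr <- sample_tree(10)
    cells <- sample(tr$tip.label, 4)
    clones <- stats::setNames(rep("k", 4), cells)
    expect_equal(clone_f1(tr, clones), oracle_best_f1(tr, cells))
  }
  expect_error(clone_f1(sample_tree(5, seed = 1), c(x = "none")), "no labelled")
})

test_that("breakpoint precision/recall follows the informative-set definition", {
  x <- make_cnp(list(a = c(2, 3, 3, 1)))
  y <- make_cnp(list(a = c(2, 3, 1, 1)))
  pr <- breakpoint_precision_recall(x, y)
  expect_equal(as.vector(pr), c(0.5, 0.5))  # TP=1 (pos 1), FP=1, FN=1
  # identical informative profiles: perfect scores
  expect_equal(as.vector(breakpoint_precision_recall(x, x)), c(1, 1))
  # flat clean, one spurious breakpoint: precision 0, recall 1 (0/0 -> 1)
  f <- make_cnp(list(a = c(2, 2, 2, 2)))
  g <- make_cnp(list(a = c(2, 2, 3, 2)))
  pr2 <- breakpoint_precision_recall(f, g)
  expect_equal(as.vector(pr2), c(0, 1))
  expect_error(breakpoint_precision_recall(x, make_cnp(list(a = c(2, 2)))),
               "layout")
})

test_that("pooled counts equal a naive per-position confusion matrix", {
  set.seed(9)
  clean <- random_cnp(5, n_bins = 20, n_chrom = 2)
  noisy <- apply_jitter(clean, 0.15, seed = 2)
  pr <- breakpoint_precision_recall(clean, noisy)
  # naive recount, cell by cell and chromosome by chromosome
  tp <- fp <- fn <- 0
  for (i in 1:5) {
    for (k in 1:2) {
      ix <- (k - 1) * 20 + 1:20
      bx <- diff(clean$cn[i, ix]) != 0
      bn <- diff(noisy$cn[i, ix]) != 0
      tp <- tp + sum(bx & bn); fp <- fp + sum(bn & !bx); fn <- fn + sum(bx & !bn)
    }
  }
  expect_equal(unname(attr(pr, "counts")), c(tp, fp, fn))
  expect_equal(unname(pr["precision"]), tp / (tp + fp))
})

test_that("clade-induced ARI is 1 for clade-aligned clusterings", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  clusters <- c(a = "x", b = "x", c = "x", d = "x",
                e = "y", f = "y", g = "y", h = "y")
  expect_equal(clade_induced_ari(tr, clusters), 1)
  one <- stats::setNames(rep("z", 8), letters[1:8])
  expect_equal(clade_induced_ari(tr, one), 1)
})

test_that("clade-induced ARI matches brute force when a cluster spans two clades", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  clusters <- c(a = "x", b = "x", e = "x", f = "x",
                c = "y", d = "y", g = "y", h = "y")
  got <- clade_induced_ari(tr, clusters)
  # oracle: subtrees of a pruned tree are the restrictions of the original
  # tree's bipartition sides to the remaining leaves
  all_leaves <- letters[1:8]
  sides0 <- c(
    list(c("a","b"), c("c","d"), c("e","f"), c("g","h"),
         c("a","b","c","d"), c("e","f","g","h")),
    as.list(all_leaves), list(all_leaves)
  )
  sides0 <- unique(c(sides0, lapply(sides0, function(s) setdiff(all_leaves, s))))
  f1 <- function(s, truth) {
    tp <- length(intersect(s, truth)); if (tp == 0) return(0)
    p <- tp / length(s); r <- tp / length(truth); 2 * p * r / (p + r)
  }
  best <- -Inf
  for (ord in list(c("x", "y"), c("y", "x"))) {
    assigned <- stats::setNames(rep("__unassigned__", 8), all_leaves)
    left <- all_leaves
    for (cl in ord) {
      truth <- names(clusters)[clusters == cl]
      avail <- unique(Filter(length, lapply(sides0, intersect, left)))
      sc <- vapply(avail, f1, 0, truth = truth)
      pick <- avail[[which.max(sc)]]
      assigned[pick] <- cl
      left <- setdiff(left, pick)
    }
    best <- max(best, oracle_ari(assigned, clusters[all_leaves]))
  }
  expect_equal(got, best)
})

test_that("clade-induced ARI is invariant to cluster relabeling and bounded enumeration", {
  set.seed(2)
  tr <- sample_tree(10)
  clusters <- stats::setNames(sample(c("p", "q"), 10, replace = TRUE),
                              tr$tip.label)
  a1 <- clade_induced_ari(tr, clusters)
  relab <- c(p = "zebra", q = "apple")[clusters]
  names(relab) <- names(clusters)
  expect_equal(clade_induced_ari(tr, relab), a1)
  many <- stats::setNames(as.character(1:9), tr$tip.label[1:9])
  expect_error(clade_induced_ari(tr, many), "greedy")
  expect_silent(clade_induced_ari(tr, many, greedy = TRUE))
})

test_that("package ARI agrees with the contingency-table formula", {
  set.seed(31)
  for (rep in 1:5) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(mclust::adjustedRandIndex(a, b), oracle_ari(a, b))
  }
})

test_that("sibling dissimilarity averages cherry Hamming fractions", {
  x <- make_cnp(list(a = c(2, 2, 2, 2), b = c(2, 2, 3, 3),
                     c = c(2, 2, 2, 2), d = c(2, 2, 2, 2)))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(sibling_dissimilarity(tr, x), (0.5 + 0) / 2)
  # identical profiles everywhere: 0
  y <- make_cnp(list(a = c(2, 2), b = c(2, 2), c = c(2, 2), d = c(2, 2)))
  expect_equal(sibling_dissimilarity(tr, y), 0)
  # permuting bins leaves the value unchanged
  set.seed(1)
  perm <- sample(4)
  xp <- x
  xp$cn <- x$cn[, perm]
  colnames(xp$cn) <- colnames(x$cn)
  expect_equal(sibling_dissimilarity(tr, xp), 0.25)
})

test_that("evaluate_tree assembles the available metrics", {
  sim <- simulate_dataset(sim_config(n_cells = 10, layout = uniform_layout(2, 2e7),
                                     n_clones = 2), noise_config("low"), seed = 12)
  tr <- infer_lineage(sim$noisy, "standard", "root", "balme")
  rep <- evaluate_tree(tr, truth = sim$tree, clones = sim$clones,
                       clean = sim$clean, noisy = sim$noisy,
                       profiles = sim$noisy)
  expect_true(all(c("nrfd", "clone_f1", "precision", "recall",
                    "altered_fraction", "sibling_dissimilarity") %in% names(rep)))
  expect_gte(rep$nrfd, 0); expect_lte(rep$nrfd, 1)
  expect_gte(rep$precision, 0); expect_lte(rep$recall, 1)
})
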