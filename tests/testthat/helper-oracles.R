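# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# tiny cnp_set from a list of per-cell copy-number vectors over a layout
# with one or more chromosomes (total mode unless alleles given)
make_cnp <- function(vectors, n_bins_per_chrom = NULL, bin_size = 1e6,
                     allele_mode = "total") {
  n_bins <- length(vectors[[1]])
  if (is.null(n_bins_per_chrom)) n_bins_per_chrom <- n_bins
  stopifnot(n_bins %% n_bins_per_chrom == 0)
  n_chrom <- n_bins / n_bins_per_chrom /
    (if (allele_mode == "allele") 2 else 1)
  layout <- genome_layout(
    chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                             length = rep(n_bins_per_chrom * bin_size, n_chrom)),
    bin_size = bin_size
  )
  cn <- do.call(rbind, vectors)
  if (is.null(names(vectors))) {
    rownames(cn) <- paste0("cell", seq_along(vectors))
  } else rownames(cn) <- names(vectors)
  cnp_set(cn, layout, allele_mode)
}

# a small random cnp_set for property tests
random_cnp <- function(n_cells, n_bins = 30, n_chrom = 3, max_cn = 6) {
  vecs <- lapply(seq_len(n_cells), function(i) {
    sample(0:max_cn, n_bins * n_chrom, replace = TRUE,
           prob = c(1, 2, 8, 3, 2, 1, 1))
  })
  make_cnp(vecs, n_bins_per_chrom = n_bins)
}

# direct (definition-level) evaluation of one distance variant on two
# integer vectors that form a single chromosome
oracle_pair_distance <- function(s, t, space, form) {
  if (space == "breakpoint") {
    s <- diff(s); t <- diff(t)
  }
  d <- abs(s - t)
  switch(form,
    manhattan = sum(d),
    euclidean = sqrt(sum(d^2)),
    root = sum(sqrt(d)),
    log = sum(log(1 + d))
  )
}

# random unrooted binary tree with positive branch lengths and its exact
# additive (path-length) matrix
random_additive_case <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = labels)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 2)
  D <- ape::cophenetic.phylo(tr)[labels, labels]
  list(tree = tr, D = D)
}

# exhaustive balanced-length minimum over all unrooted topologies (n <= 7)
oracle_bme_optimum <- function(D) {
  labels <- rownames(D)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  min(vapply(trees, balanced_length, 0, D = D))
}

# brute-force nontrivial bipartitions of a tree: for every internal edge,
# the tip set below it, canonicalised as a sorted label string away from
# the alphabetically first label
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labels <- sort(tree$tip.label)
  n <- length(labels)
  tips_below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  keys <- vapply(internal, function(nd) {
    side <- tips_below(nd)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    if (labels[1] %in% side) side <- setdiff(labels, side)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

oracle_nrfd <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  if (length(s1) + length(s2) == 0) return(0)
  length(union(setdiff(s1, s2), setdiff(s2, s1))) / (length(s1) + length(s2))
}

# adjusted Rand index from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# best-F1 side by exhaustive enumeration over both sides of every
# nontrivial bipartition
oracle_best_f1 <- function(tree, clone) {
  tree <- ape::unroot(tree)
  labels <- tree$tip.label
  n <- length(labels)
  tips_below <- function(node) {
    if (node <= n) return(labels[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  sides <- list()
  for (nd in unique(tree$edge[, 2])) {
    s <- tips_below(nd)
    if (length(s) < 2 || length(s) > n - 2) next
    sides <- c(sides, list(s), list(setdiff(labels, s)))
  }
  f1 <- vapply(sides, function(s) {
    tp <- length(intersect(s, clone))
    if (tp == 0) return(0)
    p <- tp / length(s); r <- tp / length(clone)
    2 * p * r / (p + r)
  }, 0)
  max(f1)
}
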