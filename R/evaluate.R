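## ---- bipartition machinery ----------------------------------------------

# all clades (tip index sets w.r.t. `labels`) hanging below internal edges
# of `tree`; used to enumerate one side of every internal bipartition
internal_clades <- function(tree, labels) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  tip_map <- match(tree$tip.label, labels)
  sets <- lapply(pp, function(s) sort(tip_map[s]))
  # drop the root "clade" (all tips), which is not an edge
  sets[lengths(sets) < n]
}

canonical_split_key <- function(set, n) {
  # orient every split away from taxon 1 so both sides map to one key
  if (1 %in% set) set <- setdiff(seq_len(n), set)
  paste(set, collapse = ",")
}

# canonical keys of all nontrivial bipartitions of `tree`
nontrivial_splits <- function(tree, labels) {
  n <- length(labels)
  sets <- internal_clades(tree, labels)
  sets <- sets[lengths(sets) >= 2 & lengths(sets) <= n - 2]
  unique(vapply(sets, canonical_split_key, "", n = n))
}

#' Normalized Robinson–Foulds distance
#'
#' Size of the symmetric difference between the two trees' nontrivial
#' bipartition sets, divided by the total number of nontrivial bipartitions
#' in the two trees. Trees are compared as unrooted; multifurcating trees
#' simply assert fewer bipartitions and are penalized only for the splits
#' they actually make. 0 means identical topologies, 1 maximally different
#' (e.g., any binary tree against the star tree).
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return A number in `[0, 1]`.
#' @export
nrfd <- function(t1, t2) {
  labels <- sort(t1$tip.label)
  if (!identical(labels, sort(t2$tip.label))) {
    stop("trees have different leaf sets")
  }
  s1 <- nontrivial_splits(ape::unroot(t1), labels)
  s2 <- nontrivial_splits(ape::unroot(t2), labels)
  denom <- length(s1) + length(s2)
  if (denom == 0) return(0)
  (sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))) / denom
}

# logical membership matrix (n x sides) of both sides of every nontrivial
# bipartition of the unrooted tree; single leaves are added as a fallback
# when the tree asserts no nontrivial split (n <= 3 or a star)
split_side_matrix <- function(tree, labels) {
  n <- length(labels)
  tree <- ape::unroot(tree)
  sets <- internal_clades(tree, labels)
  sets <- sets[lengths(sets) >= 2 & lengths(sets) <= n - 2]
  if (length(sets) == 0) {
    memb <- diag(n) > 0
    return(cbind(memb, !memb))
  }
  memb <- matrix(FALSE, n, length(sets))
  for (i in seq_along(sets)) memb[sets[[i]], i] <- TRUE
  cbind(memb, !memb)                                        # complements
}

#' Clone-detection F1 score
#'
#' For each ground-truth clone (a subset of cells), finds the bipartition
#' side of the reconstructed tree with maximum F1 score against that clone
#' — the side is treated as the predicted clone membership — and averages
#' the maxima over clones. Both sides of every nontrivial bipartition are
#' searched, since an unrooted tree has no canonical clade orientation. A
#' score of 1 means every clone is exactly a clade side.
#'
#' @param tree An `ape::phylo` tree.
#' @param clones Named character vector mapping cell ids to clone labels;
#'   cells labelled `"none"` or `NA` are not part of any clone.
#' @return Mean of the per-clone maximal F1 scores.
#' @export
clone_f1 <- function(tree, clones) {
  clones <- clones[!is.na(clones) & clones != "none"]
  if (length(clones) == 0) stop("no labelled clones")
  if (!all(names(clones) %in% tree$tip.label)) {
    stop("clone cells must be leaves of the tree")
  }
  labels <- tree$tip.label
  memb <- split_side_matrix(tree, labels)
  side_size <- colSums(memb)
  per_clone <- vapply(unique(clones), function(cl) {
    cells <- match(names(clones)[clones == cl], labels)
    tp <- colSums(memb[cells, , drop = FALSE])
    precision <- ifelse(side_size > 0, tp / side_size, 0)
    recall <- tp / length(cells)
    f1 <- ifelse(tp > 0, 2 * precision * recall / (precision + recall), 0)
    max(f1)
  }, 0)
  mean(per_clone)
}

#' Breakpoint detection precision and recall
#'
#' Compares the informative breakpoints of noisy profiles against clean
#' ones: within every chromosome (and allele) of every cell, the
#' informative set is the positions with a nonzero breakpoint. Counts are
#' pooled over all cells and chromosomes before computing
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, with
#' `TP = |X intersect X'|`, `FP = |X' - X|`, `FN = |X - X'|` (clean set X,
#' noisy set X'). An undefined 0/0 ratio is reported as 1 (no errors were
#' possible).
#'
#' @param clean,noisy [cnp_set()]s over the same layout and cells.
#' @return Named numeric vector `c(precision, recall)` with the pooled
#'   `tp`, `fp`, `fn` counts attached as attribute `"counts"`.
#' @export
breakpoint_precision_recall <- function(clean, noisy) {
  stopifnot(inherits(clean, "cnp_set"), inherits(noisy, "cnp_set"))
  if (!layouts_equal(clean$layout, noisy$layout) ||
      !identical(dim(clean$cn), dim(noisy$cn))) {
    stop("clean and noisy profiles must share the same layout and cells")
  }
  x <- to_breakpoints(clean)$bp != 0
  xp <- to_breakpoints(noisy)$bp != 0
  tp <- sum(x & xp)
  fp <- sum(xp & !x)
  fn <- sum(x & !xp)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  structure(c(precision = precision, recall = recall),
            counts = c(tp = tp, fp = fp, fn = fn))
}

#' Fraction of profile entries altered by noise
#'
#' @param clean,noisy [cnp_set()]s over the same layout and cells.
#' @return Fraction of (cell, bin) entries whose copy number differs.
#' @export
altered_fraction <- function(clean, noisy) {
  stopifnot(identical(dim(clean$cn), dim(noisy$cn)))
  mean(clean$cn != noisy$cn)
}

## all permutations of 1..k as a list (k <= 8 by the caller's contract)
all_orderings <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in all_orderings(k - 1)) {
      out[[length(out) + 1]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

# candidate rooted-subtree leaf sets of the current (possibly tiny) tree
subtree_leaf_sets <- function(leaves, tree) {
  sets <- as.list(leaves)                       # single leaves
  if (length(leaves) >= 2) sets <- c(sets, list(leaves))   # whole tree
  if (!is.null(tree) && length(tree$tip.label) >= 3) {
    labels <- tree$tip.label
    clades <- internal_clades(tree, labels)
    sets <- c(sets, lapply(clades, function(s) labels[s]),
              lapply(clades, function(s) labels[-s]))
  }
  unique(sets)
}

f1_score <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  if (tp == 0) return(0)
  p <- tp / length(pred)
  r <- tp / length(truth)
  2 * p * r / (p + r)
}

#' Clade-induced adjusted Rand index
#'
#' Quantifies the concordance between a cell lineage tree and a set of
#' independently derived clusters. For a given ordering of the clusters,
#' each cluster in turn is matched to the subtree of the (remaining) tree
#' with maximum F1 score against it; the subtree's cells are assigned that
#' cluster's induced label and pruned, and the process continues until no
#' clusters remain or the tree is empty. The adjusted Rand index is then
#' computed between the induced labels and the input clusters, and the
#' maximum over all cluster orderings is returned (cells left unassigned
#' share one leftover label). With more than 8 clusters the full
#' enumeration is refused; set `greedy = TRUE` to use a single ordering by
#' decreasing cluster size instead.
#'
#' @param tree An `ape::phylo` tree.
#' @param clusters Named character vector mapping cell ids (leaves) to
#'   cluster labels.
#' @param greedy Use the single size-ordered pass instead of enumerating
#'   orderings.
#' @return The maximal ARI (a number `<= 1`; 1 when clusters coincide with
#'   disjoint clades).
#' @export
clade_induced_ari <- function(tree, clusters, greedy = FALSE) {
  stopifnot(all(names(clusters) %in% tree$tip.label))
  labs <- unique(clusters)
  k <- length(labs)
  if (k > 8 && !greedy) {
    stop("more than 8 clusters: ordering enumeration is infeasible; ",
         "use greedy = TRUE for a single size-ordered pass")
  }
  orderings <- if (greedy) {
    list(order(-table(clusters)[labs]))
  } else {
    all_orderings(k)
  }
  best <- -Inf
  cells <- names(clusters)
  for (ord in orderings) {
    t_cur <- tree
    leaves <- tree$tip.label
    induced <- stats::setNames(rep("__unassigned__", length(cells)), cells)
    for (ci in ord) {
      if (length(leaves) == 0) break
      truth <- cells[clusters == labs[ci]]
      cand <- subtree_leaf_sets(leaves, t_cur)
      scores <- vapply(cand, f1_score, 0, truth = truth)
      pick <- cand[[which.max(scores)]]
      induced[intersect(pick, cells)] <- labs[ci]
      leaves <- setdiff(leaves, pick)
      t_cur <- if (length(leaves) >= 3 && !is.null(t_cur)) {
        ape::drop.tip(t_cur, setdiff(t_cur$tip.label, leaves))
      } else NULL
    }
    ari <- mclust::adjustedRandIndex(induced[cells], clusters[cells])
    if (is.nan(ari)) {
      # degenerate contingency (e.g. all-singleton partitions): 1 iff the
      # two partitions have identical co-membership
      same <- identical(outer(induced[cells], induced[cells], "=="),
                        outer(clusters[cells], clusters[cells], "=="))
      ari <- if (same) 1 else 0
    }
    if (ari > best) best <- ari
  }
  best
}

#' Sibling dissimilarity of a tree given profiles
#'
#' Mean normalized Hamming distance between the copy-number profiles of
#' sibling cells: over all cherries (pairs of leaves sharing a parent),
#' the fraction of bins at which the two cells' copy numbers differ,
#' averaged over cherries. Lower values mean closely placed cells have
#' more similar profiles.
#'
#' @param tree An `ape::phylo` tree whose leaves all appear in `profiles`.
#' @param profiles A [cnp_set()].
#' @return A number in `[0, 1]`, or `NA` if the tree has no cherry.
#' @export
sibling_dissimilarity <- function(tree, profiles) {
  stopifnot(inherits(profiles, "cnp_set"))
  if (!all(tree$tip.label %in% rownames(profiles$cn))) {
    stop("all leaves must have profiles")
  }
  n <- length(tree$tip.label)
  tip_edges <- tree$edge[tree$edge[, 2] <= n, , drop = FALSE]
  parents <- split(tip_edges[, 2], tip_edges[, 1])
  cherries <- Filter(function(p) length(p) == 2, parents)
  if (length(cherries) == 0) return(NA_real_)
  mean(vapply(cherries, function(p) {
    a <- tree$tip.label[p[1]]; b <- tree$tip.label[p[2]]
    mean(profiles$cn[a, ] != profiles$cn[b, ])
  }, 0))
}

#' Evaluate a reconstructed tree against ground truth
#'
#' Convenience wrapper assembling the available metrics for one tree/truth
#' pair into a single report.
#'
#' @param tree Reconstructed `ape::phylo`.
#' @param truth Ground-truth `ape::phylo` (for NRFD).
#' @param clones Optional named clone assignment (for [clone_f1()]).
#' @param clean,noisy Optional [cnp_set()] pair (for breakpoint
#'   precision/recall and altered fraction).
#' @param profiles Optional [cnp_set()] (for [sibling_dissimilarity()]).
#' @return A named list of metric values (class `eval_report`).
#' @export
evaluate_tree <- function(tree, truth = NULL, clones = NULL, clean = NULL,
                          noisy = NULL, profiles = NULL) {
  out <- list()
  if (!is.null(truth)) out$nrfd <- nrfd(tree, truth)
  if (!is.null(clones) && any(clones != "none", na.rm = TRUE)) {
    out$clone_f1 <- clone_f1(tree, clones)
  }
  if (!is.null(clean) && !is.null(noisy)) {
    pr <- breakpoint_precision_recall(clean, noisy)
    out$precision <- unname(pr["precision"])
    out$recall <- unname(pr["recall"])
    out$altered_fraction <- altered_fraction(clean, noisy)
  }
  if (!is.null(profiles)) {
    out$sibling_dissimilarity <- sibling_dissimilarity(tree, profiles)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
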