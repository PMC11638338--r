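#' Simulation configuration
#'
#' Generative parameters for the copy-number evolution simulator. Defaults
#' reproduce the baseline study conditions: 250 cells over the 22 hg38
#' autosomes with 1 Mbp bins and a 1 kbp minimum CNA unit, a mean of 2
#' segmental CNAs per tree edge with a 10x burst on the tumor founder,
#' unbiased allele and gain/loss choices, exponentially distributed event
#' lengths with mean 5 Mbp, and geometrically distributed gain magnitudes
#' with mean 2 extra copies.
#'
#' @param n_cells Number of sampled cells (tree leaves).
#' @param layout A [genome_layout()]; default hg38 autosomes.
#' @param lambda Mean number of segmental CNAs per (non-root) edge.
#' @param founder_multiplier The root (tumor founder) receives
#'   `Poisson(founder_multiplier * lambda)` segmental events.
#' @param alpha Probability that an event hits allele A (Bernoulli draw).
#' @param p_gain Probability that a segmental event is a gain (else a
#'   deletion).
#' @param beta Mean segmental CNA length in bp (exponential), rounded up to
#'   whole regions and truncated at the chromosome end.
#' @param delta Mean number of additional copies for a gain; the copy count
#'   has support 1, 2, ... with success probability `1/delta` (geometric).
#' @param wgd If `TRUE`, the founder genome undergoes a whole-genome
#'   duplication (every chromosome of both alleles doubled) before any
#'   other event. Only the founder can undergo WGD.
#' @param n_clones Number of clonal expansions to plant: that many disjoint
#'   ancestral clades are selected and their ancestors receive
#'   whole-chromosome and chromosome-arm CNAs in addition to segmental
#'   events.
#' @param p_arm Probability that a clonal event is arm-level rather than
#'   whole-chromosome.
#' @param p_chrom_del Probability that a clonal event is a deletion rather
#'   than a duplication; defaults to 0.5, or 0.8 when `wgd = TRUE` (tumors
#'   after WGD trend back toward triploidy).
#' @param clonal_events_mean Mean number of chromosomal events per clone
#'   ancestor (Poisson, minimum 1).
#' @param growth Population growth rate of the coalescent; affects only the
#'   (cosmetic) node times, never the topology, since events are drawn per
#'   edge.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cells = 250, layout = genome_layout(), lambda = 2,
                       founder_multiplier = 10, alpha = 0.5, p_gain = 0.5,
                       beta = 5e6, delta = 2, wgd = FALSE, n_clones = 0,
                       p_arm = 0.75, p_chrom_del = if (wgd) 0.8 else 0.5,
                       clonal_events_mean = 2, growth = 0) {
  stopifnot(n_cells >= 3, lambda >= 0, founder_multiplier >= 0,
            alpha >= 0, alpha <= 1, p_gain >= 0, p_gain <= 1,
            beta >= layout$region_size, delta >= 1,
            p_arm >= 0, p_arm <= 1, p_chrom_del >= 0, p_chrom_del <= 1,
            n_clones >= 0, growth >= 0)
  if (n_clones > 0 && n_clones >= n_cells / 2) stop("n_clones must be < n_cells / 2")
  structure(list(n_cells = n_cells, layout = layout, lambda = lambda,
                 founder_multiplier = founder_multiplier, alpha = alpha,
                 p_gain = p_gain, beta = beta, delta = delta, wgd = wgd,
                 n_clones = n_clones, p_arm = p_arm,
                 p_chrom_del = p_chrom_del,
                 clonal_events_mean = clonal_events_mean, growth = growth),
            class = "sim_config")
}

#' Sample a ground-truth cell lineage tree
#'
#' Rooted binary tree with `n_cells` leaves drawn from the neutral Kingman
#' coalescent (uniformly random pair merges), the standard model for an
#' exponentially growing tumor cell population. The `growth` rate only
#' rescales node times (documented as cosmetic: genome evolution places a
#' Poisson number of events on each edge regardless of its duration).
#'
#' @param n_cells Number of leaves (>= 3).
#' @param growth Exponential growth rate; 0 leaves coalescent times as-is.
#' @param seed Optional integer seed for reproducibility.
#' @return A rooted binary `ape::phylo` with `2 * n_cells - 1` nodes and
#'   tips labelled `cell1 ... cellN`.
#' @export
sample_tree <- function(n_cells, growth = 0, seed = NULL) {
  if (n_cells < 3) stop("n_cells must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rcoal(n_cells, tip.label = paste0("cell", seq_len(n_cells)))
  if (growth > 0) {
    # compress ancient coalescences, as in an exponentially growing population
    depth <- ape::node.depth.edgelength(tree)
    age <- max(depth) - depth
    new_age <- log1p(growth * age) / growth
    parent <- tree$edge[, 1]
    child <- tree$edge[, 2]
    tree$edge.length <- new_age[parent] - new_age[child]
  }
  tree
}

## ---- run-list genome representation -------------------------------------
## A chromosome copy on one allele is an ordered sequence of reference
## regions (M bp each), stored as an integer matrix of maximal runs
## [start_region, end_region]. The diploid root has one run [1, n_regions]
## per chromosome per allele. Duplications insert runs in tandem; deletions
## remove them. Copy numbers are recovered by counting how often each
## reference region occurs.

empty_runs <- function() matrix(integer(0), ncol = 2)

runs_length <- function(r) if (nrow(r) == 0) 0L else sum(r[, 2] - r[, 1] + 1L)

# split a run list after the first `pos` positions (current coordinates)
runs_split <- function(r, pos) {
  if (pos <= 0) return(list(left = empty_runs(), right = r))
  lens <- r[, 2] - r[, 1] + 1L
  cum <- cumsum(lens)
  if (pos >= cum[length(cum)]) return(list(left = r, right = empty_runs()))
  i <- which(cum >= pos)[1]
  prev <- if (i > 1) cum[i - 1] else 0L
  take <- as.integer(pos - prev)
  left <- r[seq_len(i - 1), , drop = FALSE]
  if (take > 0) left <- rbind(left, c(r[i, 1], r[i, 1] + take - 1L))
  right <- empty_runs()
  if (take < lens[i]) right <- rbind(right, c(r[i, 1] + take, r[i, 2]))
  if (i < nrow(r)) right <- rbind(right, r[(i + 1):nrow(r), , drop = FALSE])
  list(left = left, right = right)
}

# apply a segmental gain/deletion at current position `s`, length `L`
runs_segment_event <- function(r, s, L, gain, copies = 1L) {
  a <- runs_split(r, s - 1L)
  b <- runs_split(a$right, L)
  if (gain) {
    rbind(a$left, b$left[rep(seq_len(nrow(b$left)), copies + 1L), , drop = FALSE],
          b$right)
  } else {
    rbind(a$left, b$right)
  }
}

# restrict runs to reference interval [lo, hi]: delete or duplicate in place
runs_arm_event <- function(r, lo, hi, del) {
  if (nrow(r) == 0) return(r)
  out <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    a <- r[i, 1]; b <- r[i, 2]
    ov_lo <- max(a, lo); ov_hi <- min(b, hi)
    if (ov_lo > ov_hi) {               # no overlap with the arm
      out[[i]] <- r[i, , drop = FALSE]
    } else if (del) {                  # keep the parts outside the arm
      keep <- empty_runs()
      if (a < ov_lo) keep <- rbind(keep, c(a, ov_lo - 1L))
      if (b > ov_hi) keep <- rbind(keep, c(ov_hi + 1L, b))
      out[[i]] <- keep
    } else {                           # tandem-duplicate the overlapping part
      seg <- c(ov_lo, ov_hi)
      pieces <- empty_runs()
      if (a < ov_lo) pieces <- rbind(pieces, c(a, ov_lo - 1L))
      pieces <- rbind(pieces, seg, seg)
      if (b > ov_hi) pieces <- rbind(pieces, c(ov_hi + 1L, b))
      out[[i]] <- pieces
    }
  }
  do.call(rbind, out)
}

new_diploid_genome <- function(layout) {
  lapply(layout$n_regions, function(nr) {
    list(A = matrix(c(1L, nr), ncol = 2), B = matrix(c(1L, nr), ncol = 2))
  })
}

## one segmental CNA on a genome; returns list(genome, log_row) or NULL if
## no non-empty chromosome is available
draw_segmental_event <- function(genome, config) {
  layout <- config$layout
  M <- layout$region_size
  for (try in 1:25) {
    allele <- if (stats::rbinom(1, 1, config$alpha) == 1) 1L else 2L
    lens <- vapply(genome, function(g) runs_length(g[[allele]]), 0L)
    if (all(lens == 0)) next
    k <- sample.int(length(lens), 1, prob = lens)
    cur_len <- lens[k]
    gain <- stats::rbinom(1, 1, config$p_gain) == 1
    L <- max(1L, as.integer(ceiling(stats::rexp(1, 1 / config$beta) / M)))
    L <- min(L, cur_len)
    s <- if (cur_len == L) 1L else sample.int(cur_len - L + 1L, 1)
    copies <- if (gain) stats::rgeom(1, 1 / config$delta) + 1L else 1L
    genome[[k]][[allele]] <- runs_segment_event(genome[[k]][[allele]], s, L,
                                                gain, copies)
    return(list(genome = genome,
                log = data.frame(type = if (gain) "gain" else "deletion",
                                 allele = c("A", "B")[allele],
                                 chrom = layout$chromosomes$name[k],
                                 start = s, length = L,
                                 copies = if (gain) copies else NA_integer_,
                                 stringsAsFactors = FALSE)))
  }
  NULL
}

## one clonal whole-chromosome or arm-level event
draw_chromosomal_event <- function(genome, config) {
  layout <- config$layout
  allele <- sample.int(2, 1)
  k <- sample.int(nrow(layout$chromosomes), 1)
  arm <- stats::rbinom(1, 1, config$p_arm) == 1
  del <- stats::rbinom(1, 1, config$p_chrom_del) == 1
  nr <- layout$n_regions[k]
  r <- genome[[k]][[allele]]
  if (arm) {
    split_at <- max(1L, as.integer(round(layout$arm_fraction * nr)))
    short <- stats::rbinom(1, 1, 0.5) == 1
    lo <- if (short) 1L else split_at + 1L
    hi <- if (short) split_at else nr
    genome[[k]][[allele]] <- runs_arm_event(r, lo, hi, del)
    type <- if (del) "arm_deletion" else "arm_duplication"
  } else {
    genome[[k]][[allele]] <- if (del) empty_runs() else rbind(r, r)
    type <- if (del) "chrom_deletion" else "chrom_duplication"
  }
  list(genome = genome,
       log = data.frame(type = type, allele = c("A", "B")[allele],
                        chrom = layout$chromosomes$name[k],
                        start = NA_integer_, length = NA_integer_,
                        copies = NA_integer_, stringsAsFactors = FALSE))
}

## choose n_clones disjoint clades with sizes as close as possible to
## n_cells / n_clones and within [n_cells / (4 n_clones), n_cells / n_clones]
select_clone_nodes <- function(tree, n_clones) {
  n <- length(tree$tip.label)
  target <- n / n_clones
  lo <- n / (4 * n_clones)
  clades <- clade_tip_sets(tree)         # internal (non-root) nodes only
  sizes <- lengths(clades)
  ok <- which(sizes >= lo & sizes <= target)
  ok <- ok[order(abs(sizes[ok] - target))]
  chosen <- integer(0)
  used <- logical(n)
  for (i in ok) {
    tips <- clades[[i]]
    if (!any(used[tips])) {
      chosen <- c(chosen, as.integer(names(clades)[i]))
      used[tips] <- TRUE
    }
    if (length(chosen) == n_clones) break
  }
  if (length(chosen) < n_clones) {
    stop("could not select ", n_clones, " disjoint clades of suitable size; ",
         "try fewer clones or more cells")
  }
  chosen
}

# tip index sets of all internal non-root nodes, named by node id
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nodes <- setdiff(unique(tree$edge[, 1]), root)
  sets <- lapply(nodes, function(nd) {
    unlist(tip_descendants(tree, nd))
  })
  names(sets) <- nodes
  sets
}

# tip descendants of an internal node, plain edge walk
tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Evolve genomes along a cell lineage tree
#'
#' Places a diploid genome at the root, applies the founder events
#' (`Poisson(founder_multiplier * lambda)` segmental CNAs, optionally
#' preceded by a WGD), then walks the tree from root to leaves: each node
#' inherits its parent's genome altered by `Poisson(lambda)` segmental
#' CNAs. When `n_clones > 0`, the selected clone-ancestor nodes
#' additionally receive whole-chromosome/arm-level CNAs. Events that land
#' on a fully deleted chromosome are redrawn (bounded retries).
#'
#' @param tree Rooted binary `ape::phylo` (see [sample_tree()]).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list with `genomes` (per-leaf run-list genomes, named by cell),
#'   `events` (per-node event log), and `clones` (named character vector
#'   mapping each cell to a clone label, `"none"` outside any clone).
#' @export
evolve <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  root <- n + 1L

  clone_nodes <- integer(0)
  clones <- stats::setNames(rep("none", n), tree$tip.label)
  if (config$n_clones > 0) {
    clone_nodes <- select_clone_nodes(tree, config$n_clones)
    for (i in seq_along(clone_nodes)) {
      tips <- tip_descendants(tree, clone_nodes[i])
      clones[tips] <- paste0("clone", i)
    }
  }

  genomes <- vector("list", max(tree$edge))
  log_rows <- list()
  add_log <- function(node, rows) {
    if (!is.null(rows) && nrow(rows) > 0) {
      rows$node <- node
      log_rows[[length(log_rows) + 1]] <<- rows
    }
  }

  apply_segmental <- function(genome, n_events, node) {
    if (n_events > 0) {
      for (e in seq_len(n_events)) {
        ev <- draw_segmental_event(genome, config)
        if (is.null(ev)) break
        genome <- ev$genome
        add_log(node, ev$log)
      }
    }
    genome
  }

  g <- new_diploid_genome(config$layout)
  if (config$wgd) {
    g <- lapply(g, function(ch) lapply(ch, function(r) rbind(r, r)))
    add_log(root, data.frame(type = "wgd", allele = NA_character_,
                             chrom = NA_character_, start = NA_integer_,
                             length = NA_integer_, copies = NA_integer_,
                             stringsAsFactors = FALSE))
  }
  n_founder <- stats::rpois(1, config$founder_multiplier * config$lambda)
  genomes[[root]] <- apply_segmental(g, n_founder, root)

  edges <- reorder(tree, "cladewise")$edge     # parents precede children
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    g <- genomes[[parent]]
    g <- apply_segmental(g, stats::rpois(1, config$lambda), child)
    if (child %in% clone_nodes) {
      n_cl <- max(1L, stats::rpois(1, config$clonal_events_mean))
      for (e in seq_len(n_cl)) {
        ev <- draw_chromosomal_event(g, config)
        g <- ev$genome
        add_log(child, ev$log)
      }
    }
    genomes[[child]] <- g
  }

  events <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(type = character(0), allele = character(0), chrom = character(0),
               start = integer(0), length = integer(0), copies = integer(0),
               node = integer(0))
  leaf_genomes <- genomes[seq_len(n)]
  names(leaf_genomes) <- tree$tip.label
  list(genomes = leaf_genomes, events = events, clones = clones)
}

#' Bin evolved genomes into clean copy-number profiles
#'
#' Maps each genome's regions back to the reference and groups them into
#' the layout's fixed-size bins: the copy number of a bin is the mean copy
#' count of the reference regions it covers, rounded half-up. An unmutated
#' diploid genome yields 1 in every allele-bin.
#'
#' @param genomes Named list of run-list genomes (from [evolve()]).
#' @param layout The [genome_layout()] the genomes evolved on.
#' @return An allele-specific [cnp_set()].
#' @export
genomes_to_profiles <- function(genomes, layout) {
  bins <- bin_table(layout, "allele")
  rpb <- layout$regions_per_bin
  n_cells <- length(genomes)
  cn <- matrix(0L, nrow = n_cells, ncol = nrow(bins),
               dimnames = list(names(genomes), NULL))
  # per-chromosome region counts in each bin (the last bin may be short)
  rib <- lapply(seq_along(layout$n_bins), function(k) {
    nb <- layout$n_bins[k]
    counts <- rep(rpb, nb)
    counts[nb] <- layout$n_regions[k] - (nb - 1L) * rpb
    counts
  })
  col0 <- 0L
  for (k in seq_along(layout$n_bins)) {
    nb <- layout$n_bins[k]
    for (al in 1:2) {
      cols <- col0 + seq_len(nb)
      for (ci in seq_len(n_cells)) {
        cnt <- region_bin_counts(genomes[[ci]][[k]][[al]], nb, rpb)
        cn[ci, cols] <- as.integer(floor(cnt / rib[[k]] + 0.5))
      }
      col0 <- col0 + nb
    }
  }
  cnp_set(cn, layout, "allele")
}

# total regions contributed to each of nb bins by a run list
region_bin_counts <- function(r, nb, rpb) {
  cnt <- numeric(nb)
  if (nrow(r) == 0) return(cnt)
  for (i in seq_len(nrow(r))) {
    a <- r[i, 1]; b <- r[i, 2]
    j1 <- (a - 1L) %/% rpb + 1L
    j2 <- (b - 1L) %/% rpb + 1L
    if (j1 == j2) {
      cnt[j1] <- cnt[j1] + (b - a + 1L)
    } else {
      cnt[j1] <- cnt[j1] + (j1 * rpb - (a - 1L))
      cnt[j2] <- cnt[j2] + (b - (j2 - 1L) * rpb)
      if (j2 > j1 + 1L) {
        mid <- (j1 + 1L):(j2 - 1L)
        cnt[mid] <- cnt[mid] + rpb
      }
    }
  }
  cnt
}

#' Simulate a complete ground-truth dataset
#'
#' Runs the full pipeline: coalescent tree, genome evolution, clean binned
#' profiles, and noisy profiles under the given noise setting. All
#' randomness flows from `seed` through three named sub-streams (tree,
#' events, noise) so that partial reruns are reproducible.
#'
#' @param config A [sim_config()].
#' @param noise A [noise_config()]; with the `"none"` preset the noisy
#'   profiles equal the clean ones.
#' @param seed Integer seed.
#' @return A `cnp_sim` list: `tree`, `clean`, `noisy` (both [cnp_set()]s),
#'   `clones`, `events`, `config`, `noise`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), noise = noise_config("none"),
                             seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1, 3)
  tree <- sample_tree(config$n_cells, growth = config$growth, seed = sub[1])
  evo <- evolve(tree, config, seed = sub[2])
  clean <- genomes_to_profiles(evo$genomes, config$layout)
  noisy <- apply_noise(clean, noise, seed = sub[3])
  structure(list(tree = tree, clean = clean, noisy = noisy,
                 clones = evo$clones, events = evo$events,
                 config = config, noise = noise, seed = seed),
            class = "cnp_sim")
}

#' @export
print.cnp_sim <- function(x, ...) {
  cat(sprintf("<cnp_sim> %d cells, %d bins, noise r_b=%g r_j=%g, %d events, seed %d\n",
              nrow(x$clean$cn), ncol(x$clean$cn), x$noise$r_b, x$noise$r_j,
              nrow(x$events), x$seed))
  invisible(x)
}
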