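#' Read a copy-number profile table
#'
#' Two tab-separated layouts are accepted, both with a header row and
#' 1-based inclusive coordinates:
#' \describe{
#'   \item{long}{columns `cell`, `chrom`, `start`, `end`, `cn` and optionally
#'     `cn_b`. When `cn_b` is present the table is read as allele-specific
#'     (`cn` = allele A, `cn_b` = allele B).}
#'   \item{wide}{rows = cells (first column `cell`), remaining columns named
#'     `chrom:start-end`; total copy numbers only.}
#' }
#' All cells must share exactly the same bins, bins must have a uniform
#' width (the final bin of a chromosome may be shorter), and copy numbers
#' must be non-negative integers; violations are reported with the
#' offending cell and locus.
#'
#' @param path Path to a TSV file.
#' @param format `"auto"` (default; detected from the header), `"long"` or
#'   `"wide"`.
#' @param region_size Minimum CNA unit for the reconstructed layout
#'   (default 1,000 bp); a file carries no region information.
#' @return A [cnp_set()].
#' @export
read_cnp_table <- function(path, format = c("auto", "long", "wide"),
                           region_size = 1000) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto") {
    format <- if (all(c("cell", "chrom", "start", "end", "cn") %in% names(tab)))
      "long" else "wide"
  }
  if (format == "long") {
    req <- c("cell", "chrom", "start", "end", "cn")
    if (!all(req %in% names(tab))) {
      stop("long-format table must have columns cell, chrom, start, end, cn")
    }
    allele_mode <- if ("cn_b" %in% names(tab)) "allele" else "total"
    build_cnp_from_long(tab, allele_mode, region_size)
  } else {
    if (names(tab)[1] != "cell") stop("wide-format table must start with a 'cell' column")
    cells <- as.character(tab$cell)
    coords <- parse_bin_labels(names(tab)[-1])
    long <- data.frame(
      cell = rep(cells, each = nrow(coords)),
      chrom = rep(coords$chrom, length(cells)),
      start = rep(coords$start, length(cells)),
      end = rep(coords$end, length(cells)),
      cn = as.vector(t(as.matrix(tab[, -1, drop = FALSE]))),
      stringsAsFactors = FALSE
    )
    build_cnp_from_long(long, "total", region_size)
  }
}

parse_bin_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- which(lengths(m) != 4)
  if (length(bad) > 0) stop(sprintf("cannot parse bin column '%s'", labels[bad[1]]))
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.numeric(vapply(m, `[`, "", 3)),
             end = as.numeric(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

build_cnp_from_long <- function(tab, allele_mode, region_size) {
  tab$cell <- as.character(tab$cell)
  tab$chrom <- as.character(tab$chrom)
  cn_cols <- if (allele_mode == "allele") c("cn", "cn_b") else "cn"
  for (cc in cn_cols) {
    v <- tab[[cc]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      i <- bad[1]
      stop(sprintf("non-integer or negative copy number for cell '%s' at %s:%d-%d",
                   tab$cell[i], tab$chrom[i], tab$start[i], tab$end[i]))
    }
  }

  chroms <- unique(tab$chrom)
  first <- tab[tab$cell == tab$cell[1], , drop = FALSE]
  widths <- first$end - first$start + 1
  bin_size <- max(widths)
  # reconstruct layout from the first cell's bins
  chrom_len <- vapply(chroms, function(ch) max(first$end[first$chrom == ch]), 0)
  for (ch in chroms) {
    b <- first[first$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    w <- b$end - b$start + 1
    nb <- nrow(b) / (if (allele_mode == "allele") 1 else 1)
    exp_start <- rep((seq_len(length(unique(b$start))) - 1) * bin_size + 1,
                     each = nrow(b) / length(unique(b$start)))
    if (any(w[b$start < max(b$start)] != bin_size)) {
      i <- which(w != bin_size & b$start < max(b$start))[1]
      stop(sprintf("mixed bin widths for cell '%s' at %s:%d-%d (expected %d bp bins)",
                   b$cell[i], ch, b$start[i], b$end[i], as.integer(bin_size)))
    }
    if (!all(b$start == exp_start)) {
      stop(sprintf("bins on %s are not contiguous %d bp windows from position 1",
                   ch, as.integer(bin_size)))
    }
  }
  if (bin_size %% region_size != 0) region_size <- bin_size
  layout <- genome_layout(
    chromosomes = data.frame(name = chroms, length = as.numeric(chrom_len[chroms]),
                             stringsAsFactors = FALSE),
    bin_size = bin_size, region_size = region_size
  )

  cells <- unique(tab$cell)
  bins <- bin_table(layout, allele_mode)
  n_exp <- sum(layout$n_bins)
  key <- function(chrom, start) paste(chrom, start)
  pos_a <- which(bins$allele %in% c("A", "total"))
  slot <- match(key(tab$chrom, tab$start), key(bins$chrom[pos_a], bins$start[pos_a]))
  if (anyNA(slot)) {
    i <- which(is.na(slot))[1]
    stop(sprintf("cell '%s' has a bin %s:%d-%d absent from the shared layout",
                 tab$cell[i], tab$chrom[i], tab$start[i], tab$end[i]))
  }
  cn <- matrix(NA_integer_, nrow = length(cells), ncol = nrow(bins),
               dimnames = list(cells, NULL))
  row_ix <- match(tab$cell, cells)
  cn[cbind(row_ix, pos_a[slot])] <- as.integer(tab$cn)
  if (allele_mode == "allele") {
    pos_b <- which(bins$allele == "B")
    cn[cbind(row_ix, pos_b[slot])] <- as.integer(tab$cn_b)
  }
  if (anyNA(cn)) {
    miss <- which(is.na(cn), arr.ind = TRUE)[1, ]
    stop(sprintf("cell '%s' is missing bin %s (inconsistent bins across cells)",
                 cells[miss[1]], bin_labels(bins)[miss[2]]))
  }
  n_per_cell <- table(tab$cell)
  if (length(unique(n_per_cell)) > 1) {
    stop(sprintf("cell '%s' has %d rows but other cells have %d (inconsistent bins)",
                 names(n_per_cell)[which.min(n_per_cell)], min(n_per_cell),
                 max(n_per_cell)))
  }
  cnp_set(cn, layout, allele_mode)
}

#' Write a copy-number profile table
#'
#' Inverse of [read_cnp_table()]: `read_cnp_table(write_cnp_table(x, f))`
#' reproduces `x` exactly (bit-exact integer copy numbers, identical bins).
#'
#' @param x A [cnp_set()].
#' @param path Output TSV path.
#' @param format `"long"` (default; required for allele-specific profiles)
#'   or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_cnp_table <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cnp_set"))
  if (nrow(x$cn) == 0) stop("empty profile set")
  if (format == "wide") {
    if (x$allele_mode == "allele") {
      stop("wide format stores one value per bin; write allele-specific profiles in long format")
    }
    out <- data.frame(cell = rownames(x$cn), x$cn, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    a_ix <- which(x$bins$allele %in% c("A", "total"))
    out <- data.frame(
      cell = rep(rownames(x$cn), each = length(a_ix)),
      chrom = rep(x$bins$chrom[a_ix], nrow(x$cn)),
      start = rep(x$bins$start[a_ix], nrow(x$cn)),
      end = rep(x$bins$end[a_ix], nrow(x$cn)),
      cn = as.vector(t(x$cn[, a_ix, drop = FALSE])),
      stringsAsFactors = FALSE
    )
    if (x$allele_mode == "allele") {
      b_ix <- which(x$bins$allele == "B")
      out$cn_b <- as.vector(t(x$cn[, b_ix, drop = FALSE]))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a semicolon-terminated Newick file.
#' @return An `ape::phylo` tree; multifurcations are preserved.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file: ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick file: ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in Newick tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  tree
}

#' Write a Newick tree
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @param clamp_negative Replace negative branch lengths by 0 on output
#'   (default `TRUE`; branch lengths are cosmetic for all metrics here).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, clamp_negative = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (clamp_negative && !is.null(tree$edge.length)) {
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
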