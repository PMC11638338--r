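#' Copy-number profile sets
#'
#' A `cnp_set` holds the binned integer copy-number profiles of a set of
#' cells over one shared [genome_layout()]. Profiles are stored as a single
#' cells x bins integer matrix; in allele-specific mode each chromosome
#' contributes two blocks of columns (alleles A and B), in total mode one.
#'
#' @param cn Integer matrix, rows = cells (rownames are cell ids),
#'   columns = bins in the order given by [bin_table()].
#' @param layout A [genome_layout()].
#' @param allele_mode `"total"` (one vector per chromosome) or `"allele"`
#'   (two vectors per chromosome).
#' @return An object of class `cnp_set`.
#' @export
cnp_set <- function(cn, layout, allele_mode = c("total", "allele")) {
  allele_mode <- match.arg(allele_mode)
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  cn <- as.matrix(cn)
  bins <- bin_table(layout, allele_mode)
  if (ncol(cn) != nrow(bins)) {
    stop(sprintf("profile matrix has %d columns but layout implies %d bins",
                 ncol(cn), nrow(bins)))
  }
  if (is.null(rownames(cn))) stop("cn must have cell ids as rownames")
  if (anyDuplicated(rownames(cn))) stop("duplicate cell ids")
  bad <- which(is.na(cn) | cn < 0 | cn != floor(cn), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid copy number for cell '%s' at bin %s",
                 rownames(cn)[bad[1, 1]], bin_labels(bins)[bad[1, 2]]))
  }
  storage.mode(cn) <- "integer"
  colnames(cn) <- bin_labels(bins)
  structure(list(cn = cn, bins = bins, layout = layout,
                 allele_mode = allele_mode),
            class = "cnp_set")
}

#' Bin coordinate table for a layout
#'
#' Enumerates the bins of a layout in the canonical column order used by
#' `cnp_set` matrices: chromosomes in layout order and, in allele-specific
#' mode, allele A then allele B within each chromosome. Coordinates are
#' 1-based inclusive; the last bin of a chromosome ends at the chromosome
#' length.
#'
#' @inheritParams cnp_set
#' @return Data frame with columns `chrom`, `allele`, `bin`, `start`, `end`.
#' @export
bin_table <- function(layout, allele_mode = c("total", "allele")) {
  allele_mode <- match.arg(allele_mode)
  alleles <- if (allele_mode == "allele") c("A", "B") else "total"
  out <- do.call(rbind, lapply(seq_len(nrow(layout$chromosomes)), function(k) {
    nb <- layout$n_bins[[k]]
    len <- layout$chromosomes$length[[k]]
    starts <- (seq_len(nb) - 1) * layout$bin_size + 1
    ends <- pmin(seq_len(nb) * layout$bin_size, len)
    do.call(rbind, lapply(alleles, function(a) {
      data.frame(chrom = layout$chromosomes$name[[k]], allele = a,
                 bin = seq_len(nb), start = starts, end = ends,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

bin_labels <- function(bins) {
  suffix <- ifelse(bins$allele == "total", "", paste0("_", bins$allele))
  sprintf("%s%s:%.0f-%.0f", bins$chrom, suffix, bins$start, bins$end)
}

# list of column index vectors, one per (chromosome, allele) block, in order
chrom_blocks <- function(x) {
  key <- paste(x$bins$chrom, x$bins$allele)
  split(seq_len(nrow(x$bins)), factor(key, levels = unique(key)))
}

#' @export
print.cnp_set <- function(x, ...) {
  cat(sprintf("<cnp_set> %d cells x %d bins (%s mode, %d chromosomes)\n",
              nrow(x$cn), ncol(x$cn), x$allele_mode, nrow(x$layout$chromosomes)))
  invisible(x)
}

#' @export
dim.cnp_set <- function(x) dim(x$cn)

#' Cell identifiers of a profile set
#' @param x A `cnp_set`.
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(x) rownames(x$cn)

#' Collapse allele-specific profiles to total copy numbers
#'
#' Sums the A and B allele copy numbers of each bin. Total-mode input is
#' returned unchanged.
#'
#' @param x A `cnp_set`.
#' @return A total-mode `cnp_set`.
#' @export
as_total <- function(x) {
  stopifnot(inherits(x, "cnp_set"))
  if (x$allele_mode == "total") return(x)
  a_cols <- which(x$bins$allele == "A")
  b_cols <- which(x$bins$allele == "B")
  cnp_set(x$cn[, a_cols, drop = FALSE] + x$cn[, b_cols, drop = FALSE],
          x$layout, "total")
}

#' Breakpoint profiles of a profile set
#'
#' The breakpoint profile of a copy-number vector `C = (c_1, ..., c_n)` is
#' the vector of successive differences `b_i = c_{i+1} - c_i`,
#' `i = 1, ..., n-1`, computed independently within each chromosome (and
#' allele); no breakpoint spans a chromosome boundary. Nonzero entries mark
#' boundaries between copy-number segments.
#'
#' @param x A `cnp_set`.
#' @return An object of class `bp_set` with fields `bp` (cells x positions
#'   integer matrix), `bins` (metadata of the left bin of each adjacent
#'   pair), `layout` and `allele_mode`. A single-bin chromosome contributes
#'   no columns.
#' @export
to_breakpoints <- function(x) {
  stopifnot(inherits(x, "cnp_set"))
  blocks <- chrom_blocks(x)
  keep <- unlist(lapply(blocks, function(ix) ix[-length(ix)]), use.names = FALSE)
  nxt <- unlist(lapply(blocks, function(ix) ix[-1]), use.names = FALSE)
  bp <- x$cn[, nxt, drop = FALSE] - x$cn[, keep, drop = FALSE]
  bins <- x$bins[keep, , drop = FALSE]
  rownames(bins) <- NULL
  colnames(bp) <- bin_labels(bins)
  structure(list(bp = bp, bins = bins, layout = x$layout,
                 allele_mode = x$allele_mode),
            class = "bp_set")
}

#' @export
print.bp_set <- function(x, ...) {
  cat(sprintf("<bp_set> %d cells x %d breakpoint positions (%s mode)\n",
              nrow(x$bp), ncol(x$bp), x$allele_mode))
  invisible(x)
}
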