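#' hg38 autosome lengths
#'
#' Chromosome lengths (bp) of the 22 human autosomes in the GRCh38/hg38
#' reference assembly, the default genome over which profiles are binned.
#'
#' @return A data frame with columns `name` and `length`.
#' @export
hg38_autosomes <- function() {
  data.frame(
    name = paste0("chr", 1:22),
    length = c(
      248956422L, 242193529L, 198295559L, 190214555L, 181538259L,
      170805979L, 159345973L, 145138636L, 138394717L, 133797422L,
      135086622L, 133275309L, 114364328L, 107043718L, 101991189L,
      90338345L, 83257441L, 80373285L, 58617616L, 64444167L,
      46709983L, 50818468L
    ),
    stringsAsFactors = FALSE
  )
}

#' Define a binned genome layout
#'
#' A layout fixes the chromosome set, the bin size used for copy-number
#' profiles, the minimum copy-number-alteration unit (the "region" size `M`),
#' and the fraction of each chromosome assigned to the short arm. All
#' profiles in a dataset must share one layout.
#'
#' @param chromosomes Data frame with columns `name` and `length` (bp).
#'   Defaults to the 22 hg38 autosomes.
#' @param bin_size Bin width in bp (default 1 Mbp). Must be a multiple of
#'   `region_size`.
#' @param region_size Minimum CNA size `M` in bp (default 1,000 bp).
#' @param arm_fraction Fraction of each chromosome's length assigned to the
#'   short arm (default 0.5).
#' @return An object of class `genome_layout` with per-chromosome bin and
#'   region counts. The number of bins on chromosome k is
#'   `ceiling(length_k / bin_size)`; the last bin may be short.
#' @export
genome_layout <- function(chromosomes = hg38_autosomes(), bin_size = 1e6,
                          region_size = 1000, arm_fraction = 0.5) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (bin_size <= 0 || region_size <= 0) stop("bin_size and region_size must be positive")
  if (bin_size < region_size) stop("bin_size must be >= region_size")
  if (bin_size %% region_size != 0) stop("bin_size must be a multiple of region_size")
  if (arm_fraction <= 0 || arm_fraction >= 1) stop("arm_fraction must be in (0, 1)")
  chromosomes$name <- as.character(chromosomes$name)
  layout <- list(
    chromosomes = chromosomes,
    bin_size = bin_size,
    region_size = region_size,
    arm_fraction = arm_fraction,
    n_bins = as.integer(ceiling(chromosomes$length / bin_size)),
    n_regions = as.integer(ceiling(chromosomes$length / region_size)),
    regions_per_bin = as.integer(bin_size %/% region_size)
  )
  names(layout$n_bins) <- names(layout$n_regions) <- chromosomes$name
  structure(layout, class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "<genome_layout> %d chromosomes, %.3g Gbp total, bin %g kbp (%d bins), region %g kbp\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e9,
    x$bin_size / 1e3, sum(x$n_bins), x$region_size / 1e3
  ))
  invisible(x)
}

layouts_equal <- function(a, b) {
  identical(a$chromosomes$name, b$chromosomes$name) &&
    identical(a$chromosomes$length, b$chromosomes$length) &&
    a$bin_size == b$bin_size
}

#' Uniform layout with equally sized chromosomes
#'
#' Convenience constructor for the simulation settings that use `x`
#' chromosomes of a common length rather than hg38.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (default 100 Mbp).
#' @inheritParams genome_layout
#' @return A `genome_layout`.
#' @export
uniform_layout <- function(n_chrom, chrom_length = 1e8, bin_size = 1e6,
                           region_size = 1000, arm_fraction = 0.5) {
  genome_layout(
    chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                             length = rep(as.integer(chrom_length), n_chrom)),
    bin_size = bin_size, region_size = region_size, arm_fraction = arm_fraction
  )
}
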