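#' Noise configuration
#'
#' Error rates for the two noise models applied to clean profiles. The
#' presets mirror the calibrated study settings: `none` = (0, 0),
#' `low` = (r_b 0.02, r_j 0.1), `high` = (r_b 0.04, r_j 0.1). The rates
#' were chosen so that breakpoint detection in noisy vs clean profiles has
#' precision/recall in the ranges reported for real CNA-calling pipelines.
#'
#' @param preset `"none"`, `"low"` or `"high"`; ignored when both rates are
#'   given explicitly.
#' @param r_b Boundary error rate (SD of a segment's redrawn length, as a
#'   fraction of the segment length).
#' @param r_j Jitter error rate (SD of a bin's redrawn copy number, as a
#'   fraction of the copy number).
#' @return A `noise_config` object.
#' @export
noise_config <- function(preset = c("none", "low", "high"), r_b = NULL, r_j = NULL) {
  if (is.null(r_b) && is.null(r_j)) {
    preset <- match.arg(preset)
    rates <- switch(preset, none = c(0, 0), low = c(0.02, 0.1), high = c(0.04, 0.1))
    r_b <- rates[1]; r_j <- rates[2]
  } else {
    if (is.null(r_b)) r_b <- 0
    if (is.null(r_j)) r_j <- 0
    preset <- "custom"
  }
  stopifnot(r_b >= 0, r_j >= 0)
  structure(list(preset = preset, r_b = r_b, r_j = r_j), class = "noise_config")
}

#' Jitter noise: per-bin Gaussian copy-number fluctuation
#'
#' Each bin with copy number `c` is independently redrawn from
#' `Normal(c, (c * r_j)^2)`, rounded to the nearest integer and clamped at
#' 0. Bins with `c = 0` never change (their SD is 0). The probability that
#' a bin changes value is the two-sided Gaussian tail
#' `2 * (1 - pnorm(0.5 / (c * r_j)))`, so larger copy numbers fluctuate
#' more: at `r_j = 0.1` about 9.55% of copy-3 bins and 1.24% of copy-2
#' bins change, while copy-1 bins essentially never do.
#'
#' @param x A [cnp_set()].
#' @param r_j Jitter error rate (>= 0).
#' @param seed Optional integer seed.
#' @return A [cnp_set()] with the same layout.
#' @export
apply_jitter <- function(x, r_j, seed = NULL) {
  stopifnot(inherits(x, "cnp_set"), r_j >= 0)
  if (r_j == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  cn <- x$cn
  drawn <- stats::rnorm(length(cn), mean = as.numeric(cn),
                        sd = as.numeric(cn) * r_j)
  new_cn <- matrix(pmax(0L, as.integer(round(drawn))), nrow = nrow(cn),
                   dimnames = dimnames(cn))
  cnp_set(new_cn, x$layout, x$allele_mode)
}

#' Boundary noise: Gaussian resampling of segment lengths
#'
#' Models the poor resolution of CNA callers at the edges of constant
#' copy-number segments. Within each chromosome (and allele) of each cell,
#' maximal equal-copy runs (segments) are identified; scanning left to
#' right, every segment except the last has its length redrawn from
#' `Normal(L, (L * r_b)^2)` rounded to whole bins, which moves its boundary
#' with the next segment — an extension overwrites neighboring bins with
#' this segment's value, a shrinkage cedes bins to the neighbor, and the
#' neighbor absorbs the residual, so boundary errors do not accumulate
#' along the chromosome and the total bin count is conserved. Boundaries
#' are kept in order (a small segment overrun by its neighbors may vanish,
#' as real callers miss small segments). A chromosome that is a single
#' segment has no internal boundary and is never altered.
#'
#' @param x A [cnp_set()].
#' @param r_b Boundary error rate (>= 0).
#' @param seed Optional integer seed.
#' @return A [cnp_set()] with the same layout.
#' @export
apply_boundary <- function(x, r_b, seed = NULL) {
  stopifnot(inherits(x, "cnp_set"), r_b >= 0)
  if (r_b == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  cn <- x$cn
  blocks <- chrom_blocks(x)
  for (ci in seq_len(nrow(cn))) {
    for (ix in blocks) {
      v <- cn[ci, ix]
      r <- rle(as.vector(v))
      m <- length(r$lengths)
      if (m < 2) next
      L <- r$lengths
      total <- length(v)
      # boundary j sits at the cumulative clean length; segment j's length
      # redraw shifts it by round(N(0, (r_b L_j)^2)), the neighbor absorbing
      # the residual (shifts do not accumulate)
      bound <- cumsum(L)[-m] + round(stats::rnorm(m - 1, 0, r_b * L[-m]))
      bound <- pmin(pmax(bound, seq_len(m - 1)), total - rev(seq_len(m - 1)))
      bound <- sort(bound)
      cn[ci, ix] <- rep.int(r$values, diff(c(0L, bound, total)))
    }
  }
  cnp_set(cn, x$layout, x$allele_mode)
}

#' Apply a full noise configuration
#'
#' Jitter first (bin-level read-count fluctuation exists in the raw data),
#' then boundary noise (segmentation error made by a caller on top of the
#' fluctuating counts).
#'
#' @param x A [cnp_set()].
#' @param noise A [noise_config()].
#' @param seed Optional integer seed.
#' @return A [cnp_set()].
#' @export
apply_noise <- function(x, noise, seed = NULL) {
  stopifnot(inherits(noise, "noise_config"))
  if (!is.null(seed)) set.seed(seed)
  x <- apply_jitter(x, noise$r_j)
  apply_boundary(x, noise$r_b)
}
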