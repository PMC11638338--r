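#' Named benchmark settings
#'
#' @return Character vector of setting names accepted by
#'   [run_benchmark()]: `baseline-{none,low,high}` (default simulation,
#'   varying noise) and `clones{2,4,6}-{none,low,high}` (the same with 2,
#'   4 or 6 planted clones).
#' @export
benchmark_settings <- function() {
  as.vector(outer(c("baseline", "clones2", "clones4", "clones6"),
                  c("none", "low", "high"), paste, sep = "-"))
}

#' Run a replicated simulation benchmark
#'
#' For each replicate: simulate a dataset under the named setting, infer
#' trees from the noisy profiles with the two headline variants
#' (standard-root and breakpoint-root, both under balanced minimum
#' evolution), and score them against the ground truth. Results are
#' deterministic given `seed`.
#'
#' @param setting One of [benchmark_settings()].
#' @param n_replicates Number of independent datasets (>= 1).
#' @param seed Integer master seed; per-replicate seeds are derived from it.
#' @param n_cells Number of cells per dataset (default 250).
#' @param ... Further overrides passed to [sim_config()] (e.g. `lambda`).
#' @return Data frame with one row per replicate: NRFD for each variant
#'   and, for clone settings, the clone F1 scores; per-column means are in
#'   `attr(, "means")`.
#' @export
run_benchmark <- function(setting = "baseline-high", n_replicates = 5,
                          seed = 1, n_cells = 250, ...) {
  if (!setting %in% benchmark_settings()) {
    stop("unknown setting '", setting, "'; valid settings: ",
         paste(benchmark_settings(), collapse = ", "))
  }
  parts <- strsplit(setting, "-", fixed = TRUE)[[1]]
  n_clones <- if (parts[1] == "baseline") 0 else as.integer(sub("clones", "", parts[1]))
  noise <- noise_config(parts[2])
  config <- sim_config(n_cells = n_cells, n_clones = n_clones, ...)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    sim <- simulate_dataset(config, noise, seed = rep_seeds[r])
    t_std <- infer_lineage(sim$noisy, "standard", "root", "balme")
    t_bp <- infer_lineage(sim$noisy, "breakpoint", "root", "balme")
    row <- data.frame(
      replicate = r, seed = rep_seeds[r],
      nrfd_standard_root = nrfd(t_std, sim$tree),
      nrfd_breakpoint_root = nrfd(t_bp, sim$tree)
    )
    if (n_clones > 0) {
      row$f1_standard_root <- clone_f1(t_std, sim$clones)
      row$f1_breakpoint_root <- clone_f1(t_bp, sim$clones)
    }
    row
  })
  out <- do.call(rbind, rows)
  num <- setdiff(names(out), c("replicate", "seed"))
  attr(out, "means") <- colMeans(out[, num, drop = FALSE])
  out
}
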