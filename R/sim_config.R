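#' Simulation configuration for the synthetic capture screen
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate the
#' capture-library design the pipeline is built for: ~150-bp sheared fragments
#' sequenced paired-end 100, indels of 1-5 bp at the Cas9 cut (3 bp upstream
#' of the PAM), deletions outnumbering insertions 4:1, PCR clonal duplicates,
#' and a small per-base substitution error rate.
#'
#' @param genome_length genome size in bases.
#' @param gc_content GC fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param fragment_length_mean,fragment_length_sd sheared-fragment length
#'   distribution (bases).
#' @param read_length read length in bases (>= 35).
#' @param depth_per_region expected read pairs per capture region.
#' @param clonal_rate fraction of pairs duplicated as exact PCR clones.
#' @param subst_error_rate per-base substitution sequencing-error probability.
#' @param indel_size_range integer pair, inclusive range of indel sizes.
#' @param deletion_prob probability that a planted indel is a deletion
#'   (default 0.8, i.e. 4:1 deletions to insertions).
#' @param min_capture_overlap minimum fragment/region overlap (bases) for a
#'   fragment to be captured by the hybridization baits; fragment starts are
#'   uniform (staggered) over the window this allows.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       gc_content = 0.42,
                       seed = 1L,
                       fragment_length_mean = 150,
                       fragment_length_sd = 20,
                       read_length = 100L,
                       depth_per_region = 300L,
                       clonal_rate = 0,
                       subst_error_rate = 0,
                       indel_size_range = c(1L, 5L),
                       deletion_prob = 0.8,
                       min_capture_overlap = 100L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    seed = as.integer(seed),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    read_length = as.integer(read_length),
    depth_per_region = as.integer(depth_per_region),
    clonal_rate = clonal_rate,
    subst_error_rate = subst_error_rate,
    indel_size_range = as.integer(indel_size_range),
    deletion_prob = deletion_prob,
    min_capture_overlap = as.integer(min_capture_overlap)
  )
  for (f in c("gc_content", "clonal_rate", "subst_error_rate", "deletion_prob")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: ", f, " must be a fraction in [0, 1]")
    }
  }
  if (cfg$read_length < 35L) stop("sim_config: read_length must be >= 35")
  if (cfg$genome_length < 2000L) {
    stop("sim_config: genome_length must be at least 10x the 200-bp region length")
  }
  if (cfg$min_capture_overlap < 1L) {
    stop("sim_config: min_capture_overlap must be positive")
  }
  if (length(cfg$indel_size_range) != 2L ||
      cfg$indel_size_range[1] < 1L ||
      cfg$indel_size_range[1] > cfg$indel_size_range[2]) {
    stop("sim_config: indel_size_range must be an increasing positive pair")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(unclass(x))) {
    cat(" ", f, "=", paste(x[[f]], collapse = ".."), "\n")
  }
  invisible(x)
}
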