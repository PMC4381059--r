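#' Simulate peak BED sets with a known shared fraction
#'
#' Builds two peak sets over disjoint genomic slots so that exactly
#' `n_shared` intervals are common to both sets (identical coordinates) and
#' the rest are set-specific and non-overlapping. Useful as ground truth for
#' the peak-set algebra.
#'
#' @param genome_length contig length in bases.
#' @param n_shared number of intervals present in both sets.
#' @param n_a_specific,n_b_specific set-specific interval counts.
#' @param width interval width.
#' @param chrom contig name.
#' @param seed optional integer seed.
#' @return list with GRanges `set_a` and `set_b`.
#' @export
simulate_peak_sets <- function(genome_length, n_shared, n_a_specific = 0L,
                               n_b_specific = 0L, width = 200L,
                               chrom = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_tot <- n_shared + n_a_specific + n_b_specific
  gap <- 50L
  need <- n_tot * (width + gap)
  if (need > genome_length) {
    stop("genome_length too small for ", n_tot, " disjoint intervals")
  }
  slot_starts <- sort(sample.int(genome_length - width,
                                 size = n_tot) )
  ## enforce disjointness by spreading: fall back to a regular grid when the
  ## random draw collides
  if (any(diff(slot_starts) < width)) {
    slot_starts <- seq(1L, by = width + gap, length.out = n_tot)
  }
  idx <- sample.int(n_tot)
  shared <- slot_starts[idx[seq_len(n_shared)]]
  a_only <- slot_starts[idx[n_shared + seq_len(n_a_specific)]]
  b_only <- slot_starts[idx[n_shared + n_a_specific + seq_len(n_b_specific)]]

  mk <- function(starts, prefix) {
    if (!length(starts)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = sort(starts), width = width)
    )
    gr$name <- sprintf("%s%04d", prefix, seq_along(gr))
    gr
  }
  list(
    set_a = GenomicRanges::sort(c(mk(shared, "shared"), mk(a_only, "aonly"))),
    set_b = GenomicRanges::sort(c(mk(shared, "shared"), mk(b_only, "bonly")))
  )
}
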