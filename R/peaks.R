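#' Split two peak sets into common and guide-specific parts
#'
#' Peaks observed with two different guide RNAs are taken as
#' guide-independent binding; they are identified by a >= 1 bp overlap and
#' subtracted, leaving guide-specific peaks. The common set is materialized
#' from set A's coordinates.
#'
#' @param peaks_a,peaks_b peak sets (GRanges, BED path, or data.frame).
#' @return list with `common` (A peaks touching any B peak), `a_specific`,
#'   `b_specific`, and `common_b` (the B-side coordinates of the common
#'   peaks, for symmetry checks).
#' @export
split_grna_specific <- function(peaks_a, peaks_b) {
  a <- as_intervals(peaks_a, "peaks_a")
  b <- as_intervals(peaks_b, "peaks_b")
  a_hit <- IRanges::overlapsAny(a, b, ignore.strand = TRUE)
  b_hit <- IRanges::overlapsAny(b, a, ignore.strand = TRUE)
  list(
    common = a[a_hit],
    a_specific = a[!a_hit],
    b_specific = b[!b_hit],
    common_b = b[b_hit]
  )
}

#' Intersect two replicate peak sets
#'
#' Retains replicate-1 peaks with a >= 1 bp overlap in replicate 2
#' (replicate-1 coordinates kept), the high-confidence set used for
#' downstream analysis.
#'
#' @param rep1,rep2 peak sets (GRanges, BED path, or data.frame).
#' @return GRanges of rep1 peaks confirmed in rep2.
#' @export
intersect_replicates <- function(rep1, rep2) {
  r1 <- as_intervals(rep1, "rep1")
  r2 <- as_intervals(rep2, "rep2")
  r1[IRanges::overlapsAny(r1, r2, ignore.strand = TRUE)]
}

#' Fraction of peaks overlapping a feature set
#'
#' @param peaks peak set (GRanges, BED path, or data.frame).
#' @param features feature set, e.g. DNase hypersensitive sites or GC-skew
#'   regions.
#' @return list with `percent` (0-100) and `per_peak` logical vector.
#' @export
overlap_fraction <- function(peaks, features) {
  pk <- as_intervals(peaks, "peaks")
  ft <- as_intervals(features, "features")
  if (length(pk) == 0L) return(list(percent = NA_real_, per_peak = logical(0)))
  hit <- IRanges::overlapsAny(pk, ft, ignore.strand = TRUE)
  list(percent = 100 * mean(hit), per_peak = hit)
}

#' Remove peaks overlapping a blacklist
#'
#' @param peaks peak set.
#' @param blacklist blacklist regions (e.g. sequencing-artefact regions).
#' @return list with `filtered` (GRanges) and `n_removed`.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  pk <- as_intervals(peaks, "peaks")
  bl <- as_intervals(blacklist, "blacklist")
  hit <- IRanges::overlapsAny(pk, bl, ignore.strand = TRUE)
  list(filtered = pk[!hit], n_removed = sum(hit))
}
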