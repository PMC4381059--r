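#' Build 200-bp capture regions around candidate sites
#'
#' Each candidate site (a ChIP peak, a predicted off-target locus, or a
#' random control) yields one 200-bp window centered on the site midpoint,
#' with its reference sequence extracted from the genome. Note that a
#' predicted off-target site and a ChIP peak covering the same locus can
#' yield shifted windows because their midpoints differ; both conventions
#' are kept distinct by recording the category.
#'
#' @param sites candidate sites (GRanges, BED path, or data.frame with
#'   0-based `chrom`/`start`/`end`).
#' @param genome genome (DNAStringSet, FASTA path, or character vector).
#' @param categories character vector recycled along `sites`
#'   (e.g. `"chip_S1"`, `"predicted_S2"`, `"random_control"`).
#' @param region_length window length (default 200).
#' @return data.frame (one row per kept site): `region_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `category`, `seq`. Sites whose
#'   window would run off the contig are skipped with a warning.
#' @export
make_capture_regions <- function(sites, genome, categories = "site",
                                 region_length = 200L) {
  gr <- as_intervals(sites, "sites")
  gn <- load_genome(genome)
  half <- region_length %/% 2L
  categories <- rep_len(categories, length(gr))

  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  center0 <- (start0 + end0) %/% 2L
  rs0 <- center0 - half
  re0 <- rs0 + region_length

  clen <- setNames(Biostrings::width(gn), names(gn))[chrom]
  ok <- !is.na(clen) & rs0 >= 0L & re0 <= clen
  if (any(!ok)) {
    warning(sum(!ok), " site(s) within ", half,
            " bp of a contig edge; skipped")
  }
  idx <- which(ok)
  seqs <- vapply(idx, function(i) {
    substr(as.character(gn[[chrom[i]]]), rs0[i] + 1L, re0[i])
  }, character(1))

  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("region%04d", seq_along(gr))
  data.frame(
    region_id = nm[idx],
    chrom = chrom[idx], start = rs0[idx], end = re0[idx],
    category = categories[idx],
    seq = seqs,
    stringsAsFactors = FALSE
  )
}

#' Tile a capture region with hybridization baits
#'
#' A 200-bp region is covered by three 100-bp baits with a 50-bp walking
#' step (offsets 0, 50 and 100), so adjacent baits overlap by 50 bp and the
#' union of baits covers the region exactly. Baits are reported on the plus
#' strand.
#'
#' @param region_seq region reference sequence (length `bait_len + 2*step`),
#'   or one row of the [make_capture_regions()] data.frame.
#' @param bait_len bait length (default 100).
#' @param step walking step (default 50).
#' @return data.frame with `bait`, `offset`, `seq`.
#' @export
tile_baits <- function(region_seq, bait_len = 100L, step = 50L) {
  if (is.data.frame(region_seq)) region_seq <- region_seq$seq[1]
  L <- nchar(region_seq)
  if (L != bait_len + 2L * step) {
    stop("region length (", L, ") must equal bait_len + 2*step (",
         bait_len + 2L * step, ")")
  }
  offsets <- c(0L, step, 2L * step)
  data.frame(
    bait = seq_along(offsets),
    offset = offsets,
    seq = vapply(offsets, function(o) substr(region_seq, o + 1L, o + bait_len),
                 character(1)),
    stringsAsFactors = FALSE
  )
}

#' Pick random control regions
#'
#' Samples `n` non-overlapping fixed-length regions uniformly over the
#' genome, avoiding an exclusion set (e.g. the targeted regions themselves),
#' reproducibly for a fixed seed.
#'
#' @param genome genome (DNAStringSet, FASTA path, or character vector).
#' @param n number of control regions.
#' @param length region length (default 200).
#' @param exclusions optional intervals to avoid (GRanges/BED/data.frame).
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param max_tries sampling attempts before giving up.
#' @return GRanges of `n` disjoint regions (with `name` metadata).
#' @export
pick_random_controls <- function(genome, n, length = 200L, exclusions = NULL,
                                 seed = NULL, max_tries = 50L * n) {
  gn <- load_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  excl <- if (!is.null(exclusions)) as_intervals(exclusions, "exclusions")
          else GenomicRanges::GRanges()

  lens <- Biostrings::width(gn)
  eligible <- lens >= length
  if (!any(eligible)) stop("no contig can hold a region of length ", length)
  total_excl <- sum(GenomicRanges::width(GenomicRanges::reduce(excl)))
  if (sum(lens[eligible]) - total_excl < n * length) {
    stop("insufficient eligible space for ", n, " control regions")
  }

  picked <- GenomicRanges::GRanges()
  tries <- 0L
  while (length(picked) < n && tries < max_tries) {
    tries <- tries + 1L
    ci <- sample(which(eligible), 1L, prob = lens[eligible])
    s0 <- sample.int(lens[ci] - length + 1L, 1L) - 1L
    cand <- GenomicRanges::GRanges(
      names(gn)[ci], IRanges::IRanges(start = s0 + 1L, width = length)
    )
    if (length(excl) && IRanges::overlapsAny(cand, excl)) next
    if (length(picked) && IRanges::overlapsAny(cand, picked)) next
    picked <- c(picked, cand)
  }
  if (length(picked) < n) {
    stop("could not place ", n, " non-overlapping control regions in ",
         max_tries, " attempts")
  }
  picked$name <- sprintf("random%04d", seq_len(n))
  GenomicRanges::sort(picked)
}
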