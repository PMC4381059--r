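#' Scan a genome for off-target sites of a protospacer
#'
#' Finds every 23-bp window (20-mer plus PAM) on both strands whose PAM
#' matches one of the supplied IUPAC patterns and whose 20-mer differs from
#' the protospacer by at most `max_mismatches` substitutions. This is the
#' sequence-similarity route to candidate off-target sites, complementary to
#' ChIP-based discovery.
#'
#' Windows containing non-ACGT bases (including an ambiguous base under the
#' PAM's N) are skipped. Coordinates are reported over the 20-nt protospacer
#' match. Mismatch positions are numbered 1-20 with position 20 PAM-adjacent.
#'
#' @param genome DNAStringSet, FASTA path, or named character vector.
#' @param target a [target_site()].
#' @param max_mismatches maximum protospacer mismatches (0-20).
#' @param pam_patterns character vector of 3-mer IUPAC PAM patterns; defaults
#'   to the target's own pattern.
#' @param mask optional BED/GRanges of regions whose hits are dropped
#'   (e.g. a repeat mask); no masking by default.
#' @return a [GenomicRanges::GRanges] (1-based internally; use
#'   [write_hits_bed()] for 0-based BED6+ output), sorted by (chrom, start),
#'   with metadata columns `matched_seq`, `pam`, `mismatch_count`,
#'   `mismatch_positions` (comma-joined), `pam_pattern`.
#' @export
scan_genome <- function(genome, target, max_mismatches = 4L,
                        pam_patterns = NULL, mask = NULL) {
  stopifnot(is(target, "target_site"))
  if (max_mismatches < 0L || max_mismatches > 20L) {
    stop("max_mismatches must lie in 0-20")
  }
  gn <- load_genome(genome)
  if (is.null(pam_patterns)) pam_patterns <- target$pam_pattern
  proto <- target$protospacer
  rc_proto <- revcomp(proto)

  hits <- list()
  for (chrom in names(gn)) {
    chr <- gn[[chrom]]
    chr_str <- as.character(chr)
    clen <- nchar(chr_str)
    if (clen < 23L) next

    ## plus strand: protospacer 20-mer followed by PAM
    m <- Biostrings::matchPattern(proto, chr, max.mismatch = max_mismatches)
    st <- IRanges::start(m)                    # 1-based 20-mer start
    keep <- st + 22L <= clen
    st <- st[keep]
    if (length(st)) {
      seq20 <- substring(chr_str, st, st + 19L)
      pam3 <- substring(chr_str, st + 20L, st + 22L)
      hits[[length(hits) + 1L]] <- .scan_collect(chrom, st, "+", seq20, pam3,
                                                 proto, pam_patterns,
                                                 max_mismatches)
    }

    ## minus strand: reverse-complemented protospacer, PAM upstream on plus
    m <- Biostrings::matchPattern(rc_proto, chr, max.mismatch = max_mismatches)
    st <- IRanges::start(m)
    keep <- st >= 4L
    st <- st[keep]
    if (length(st)) {
      seq20 <- revcomp(substring(chr_str, st, st + 19L))
      pam3 <- revcomp(substring(chr_str, st - 3L, st - 1L))
      hits[[length(hits) + 1L]] <- .scan_collect(chrom, st, "-", seq20, pam3,
                                                 proto, pam_patterns,
                                                 max_mismatches)
    }
  }

  if (!length(hits)) {
    gr <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, hits)
    df <- df[!duplicated(df[, c("chrom", "start", "strand")]), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start, width = 20L),
      strand = df$strand,
      matched_seq = df$matched_seq, pam = df$pam,
      mismatch_count = df$mismatch_count,
      mismatch_positions = df$mismatch_positions,
      pam_pattern = df$pam_pattern
    )
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  }
  if (!is.null(mask) && length(gr)) {
    mk <- as_intervals(mask, "mask")
    gr <- gr[!IRanges::overlapsAny(gr, mk, ignore.strand = TRUE)]
  }
  gr
}

## Filter candidate placements by PAM pattern and ACGT content, compute
## mismatch positions in protospacer numbering (20 = PAM-adjacent).
.scan_collect <- function(chrom, start1, strand, seq20, pam3, proto,
                          pam_patterns, max_mismatches) {
  ok <- is_acgt(seq20) & is_acgt(pam3)
  pam_ok <- rep(FALSE, length(pam3))
  pat_used <- rep(NA_character_, length(pam3))
  for (pp in pam_patterns) {
    hit <- ok & !pam_ok & matches_iupac(pam3, pp)
    pat_used[hit] <- pp
    pam_ok <- pam_ok | hit
  }
  keep <- ok & pam_ok
  if (!any(keep)) return(NULL)
  seq20 <- seq20[keep]; pam3 <- pam3[keep]; start1 <- start1[keep]
  pat_used <- pat_used[keep]

  pchars <- strsplit(proto, "")[[1]]
  mm_list <- lapply(seq20, function(s) {
    which(strsplit(s, "")[[1]] != pchars)
  })
  mm_n <- lengths(mm_list)
  keep2 <- mm_n <= max_mismatches    # defensive; matchPattern guarantees this
  data.frame(
    chrom = chrom, start = start1, strand = strand,
    matched_seq = seq20, pam = pam3,
    mismatch_count = mm_n,
    mismatch_positions = vapply(mm_list, paste, "", collapse = ","),
    pam_pattern = pat_used,
    stringsAsFactors = FALSE
  )[keep2, , drop = FALSE]
}

#' Write scan hits as BED6+ (0-based half-open)
#'
#' Extra columns: matched sequence, observed PAM, mismatch count,
#' comma-joined mismatch positions.
#'
#' @param hits GRanges from [scan_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    name = paste0("hit", seq_along(hits)),
    score = hits$mismatch_count,
    strand = as.character(GenomicRanges::strand(hits)),
    matched_seq = hits$matched_seq,
    pam = hits$pam,
    mismatch_count = hits$mismatch_count,
    mismatch_positions = hits$mismatch_positions
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap predicted off-target hits with ChIP peaks
#'
#' Marks, for each hit, whether any peak interval overlaps it by at least one
#' base, and summarizes the counts. Chromosomes present in only one of the
#' two sets trigger a warning and count as non-overlap.
#'
#' @param hits GRanges from [scan_genome()].
#' @param peaks peaks as GRanges, BED path, or data.frame.
#' @return list with `per_hit` (logical vector along `hits`), `n_hits`,
#'   `n_overlapping`.
#' @export
rank_hits_vs_peaks <- function(hits, peaks) {
  pk <- as_intervals(peaks, "peaks")
  if (length(hits) == 0L) {
    return(list(per_hit = logical(0), n_hits = 0L, n_overlapping = 0L))
  }
  ch <- unique(as.character(GenomicRanges::seqnames(hits)))
  cp <- unique(as.character(GenomicRanges::seqnames(pk)))
  if (length(pk) && !any(ch %in% cp)) {
    warning("no shared chromosome names between hits and peaks; ",
            "treating all hits as non-overlapping")
  }
  ov <- suppressWarnings(IRanges::overlapsAny(hits, pk, ignore.strand = TRUE))
  list(per_hit = ov, n_hits = length(hits), n_overlapping = sum(ov))
}
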