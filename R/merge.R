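#' Merge one read pair by exact 3'/5' overlap
#'
#' Mate 2 is reverse-complemented, then the longest exact overlap (>=
#' `min_overlap` bases) between the 3' end of one read and the 5' end of the
#' other is sought, trying both read orders. If found, the two sequences are
#' combined into one (`len1 + len2 - overlap`); if a read contains the other
#' entirely, the merged product is the longer read. If no overlap is found
#' the two reads are returned separately.
#'
#' @param seq1,seq2 mate sequences as read (mate 2 will be
#'   reverse-complemented internally).
#' @param min_overlap minimum exact overlap (default 5).
#' @return list with `merged` (logical), `seqs` (length-1 character if
#'   merged, else the two reads with mate 2 reverse-complemented),
#'   `overlap` (bases, 0 if unmerged).
#' @export
merge_pairs <- function(seq1, seq2, min_overlap = 5L) {
  rc2 <- revcomp(seq2)
  o1 <- suffix_prefix_overlap(seq1, rc2, min_overlap)
  o2 <- suffix_prefix_overlap(rc2, seq1, min_overlap)
  if (o1 == 0L && o2 == 0L) {
    return(list(merged = FALSE, seqs = c(seq1, rc2), overlap = 0L))
  }
  if (o1 >= o2) {
    merged <- paste0(seq1, substr(rc2, o1 + 1L, nchar(rc2)))
    o <- o1
  } else {
    merged <- paste0(rc2, substr(seq1, o2 + 1L, nchar(seq1)))
    o <- o2
  }
  list(merged = TRUE, seqs = merged, overlap = o)
}

## Merge a whole table of assigned pairs into classifiable sequences: one
## row per merged read, or two rows for unmergeable pairs.
merge_pair_table <- function(pairs, min_overlap = 5L) {
  n <- nrow(pairs)
  rc2 <- revcomp(pairs$seq2)
  merged <- logical(n)
  mseq <- character(n)
  for (i in seq_len(n)) {
    o1 <- suffix_prefix_overlap(pairs$seq1[i], rc2[i], min_overlap)
    o2 <- suffix_prefix_overlap(rc2[i], pairs$seq1[i], min_overlap)
    if (o1 == 0L && o2 == 0L) next
    merged[i] <- TRUE
    mseq[i] <- if (o1 >= o2) {
      paste0(pairs$seq1[i], substr(rc2[i], o1 + 1L, nchar(rc2[i])))
    } else {
      paste0(rc2[i], substr(pairs$seq1[i], o2 + 1L, nchar(pairs$seq1[i])))
    }
  }
  um <- !merged
  data.frame(
    pair_id = c(pairs$id[merged], pairs$id[um], pairs$id[um]),
    region_id = c(pairs$region_id[merged], pairs$region_id[um],
                  pairs$region_id[um]),
    seq = c(mseq[merged], pairs$seq1[um], rc2[um]),
    merged = c(rep(TRUE, sum(merged)), rep(FALSE, 2L * sum(um))),
    stringsAsFactors = FALSE
  )
}
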