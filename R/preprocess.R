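## 3' quality trim: drop trailing bases whose Phred score (offset 33) is
## below threshold.
.trim_qual3 <- function(seq, qual, threshold) {
  if (threshold <= 0) return(list(seq = seq, qual = qual))
  for (i in seq_along(seq)) {
    q <- utf8ToInt(qual[i]) - 33L
    keep <- length(q)
    while (keep > 0L && q[keep] < threshold) keep <- keep - 1L
    if (keep < length(q)) {
      seq[i] <- substr(seq[i], 1L, keep)
      qual[i] <- substr(qual[i], 1L, keep)
    }
  }
  list(seq = seq, qual = qual)
}

## Strip leading/trailing N bases (sequence and quality in step).
.trim_n <- function(seq, qual) {
  lead <- attr(regexpr("^N*", seq), "match.length")
  if (any(lead > 0L)) {
    seq <- substr(seq, lead + 1L, nchar(seq))
    qual <- substr(qual, lead + 1L, nchar(qual))
  }
  trail <- attr(regexpr("N*$", seq), "match.length")
  if (any(trail > 0L)) {
    seq <- substr(seq, 1L, nchar(seq) - trail)
    qual <- substr(qual, 1L, nchar(qual) - trail)
  }
  list(seq = seq, qual = qual)
}

## Remove adapter read-through: truncate at the first full-adapter match, or
## trim a terminal prefix of the adapter (>= 5 bp) from the 3' end.
.trim_adapter <- function(seq, qual, adapter) {
  if (is.null(adapter)) return(list(seq = seq, qual = qual))
  hit <- regexpr(adapter, seq, fixed = TRUE)
  cut <- ifelse(hit > 0L, hit - 1L, nchar(seq))
  for (i in seq_along(seq)) {
    if (hit[i] > 0L) next
    len <- nchar(seq[i])
    for (k in min(nchar(adapter) - 1L, len):5L) {
      if (k < 5L) break
      if (substr(seq[i], len - k + 1L, len) == substr(adapter, 1L, k)) {
        cut[i] <- len - k
        break
      }
    }
  }
  list(seq = substr(seq, 1L, cut), qual = substr(qual, 1L, cut))
}

#' Quality/adapter/N filtering of paired capture reads
#'
#' Trims 3' low-quality tails, adapter read-through and leading/trailing N
#' bases from both mates, then discards the whole pair if either mate is
#' shorter than `min_len` after trimming.
#'
#' @param pairs data.frame with `seq1`, `qual1`, `seq2`, `qual2` (e.g. from
#'   [simulate_capture_reads()] or two [read_fastq()] calls), or a
#'   length-2 character vector of FASTQ paths (R1, R2).
#' @param min_len minimum post-trimming read length (default 35).
#' @param qual_threshold Phred threshold for 3' quality trimming.
#' @param adapter optional adapter sequence to remove.
#' @return list with `pairs` (filtered data.frame) and `n_discarded_pairs`.
#' @export
preprocess_reads <- function(pairs, min_len = 35L, qual_threshold = 20L,
                             adapter = NULL) {
  if (is.character(pairs) && length(pairs) == 2L) {
    r1 <- read_fastq(pairs[1]); r2 <- read_fastq(pairs[2])
    if (nrow(r1) != nrow(r2)) stop("R1/R2 record counts differ")
    pairs <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                        seq2 = r2$seq, qual2 = r2$qual,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2))) {
    bad <- which(nchar(pairs$seq1) != nchar(pairs$qual1) |
                   nchar(pairs$seq2) != nchar(pairs$qual2))[1]
    stop("malformed FASTQ record at index ", bad,
         ": sequence/quality length mismatch")
  }

  for (mate in 1:2) {
    s <- pairs[[paste0("seq", mate)]]
    q <- pairs[[paste0("qual", mate)]]
    t1 <- .trim_qual3(s, q, qual_threshold)
    t2 <- .trim_adapter(t1$seq, t1$qual, adapter)
    t3 <- .trim_n(t2$seq, t2$qual)
    pairs[[paste0("seq", mate)]] <- t3$seq
    pairs[[paste0("qual", mate)]] <- t3$qual
  }
  keep <- nchar(pairs$seq1) >= min_len & nchar(pairs$seq2) >= min_len
  list(pairs = pairs[keep, , drop = FALSE],
       n_discarded_pairs = sum(!keep))
}
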