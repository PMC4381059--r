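## Sliding-window search of a short word (+ PAM) against one strand of a
## region, counting Hamming mismatches. Returns 1-based plus-strand start
## positions of the word match.
.word_scan <- function(region_chars, word, pam_pattern, max_mm) {
  L <- length(region_chars)
  wlen <- nchar(word)
  n_win <- L - wlen - 3L + 1L
  if (n_win < 1L) return(data.frame(pos = integer(0), mm = integer(0)))
  wchars <- strsplit(word, "")[[1]]
  mm <- integer(n_win)
  for (j in seq_len(wlen)) {
    mm <- mm + (region_chars[seq_len(n_win) + j - 1L] != wchars[j])
  }
  pam3 <- paste0(region_chars[seq_len(n_win) + wlen],
                 region_chars[seq_len(n_win) + wlen + 1L],
                 region_chars[seq_len(n_win) + wlen + 2L])
  ok <- mm <= max_mm & matches_iupac(pam3, pam_pattern) & is_acgt(pam3)
  word_ok <- vapply(seq_len(n_win), function(i) {
    all(region_chars[i:(i + wlen - 1L)] %in% c("A", "C", "G", "T"))
  }, logical(1))
  ok <- ok & word_ok
  data.frame(pos = which(ok), mm = mm[ok])
}

#' Find seed matches in a region sequence
#'
#' Reports every placement, on both strands, of the target's PAM-proximal
#' 12-bp seed with at most `max_mm` mismatches immediately 5' of a
#' PAM-matching 3-mer. A region "has a seed match" iff the result is
#' non-empty. Used to ask whether ChIP-bound regions carry partial matches
#' to the target.
#'
#' @param region_seq a single region sequence (e.g. the central 100 bp of a
#'   peak).
#' @param target a [target_site()].
#' @param seed_len seed length; the last `seed_len` nt of the protospacer.
#' @param max_mm maximum seed mismatches.
#' @param pam IUPAC 3-mer PAM pattern.
#' @return data.frame with `position` (0-based start of the seed match on
#'   the given/plus strand), `strand`, `mismatch_count`.
#' @export
seed_match <- function(region_seq, target, seed_len = 12L, max_mm = 4L,
                       pam = "NGG") {
  stopifnot(is(target, "target_site"))
  region_seq <- toupper(region_seq)
  L <- nchar(region_seq)
  if (L < seed_len + 3L) stop("region_seq shorter than seed + PAM")
  seed <- substr(target$protospacer, 20L - seed_len + 1L, 20L)

  fwd <- .word_scan(strsplit(region_seq, "")[[1]], seed, pam, max_mm)
  rev <- .word_scan(strsplit(revcomp(region_seq), "")[[1]], seed, pam, max_mm)

  out <- rbind(
    if (nrow(fwd)) data.frame(position = fwd$pos - 1L, strand = "+",
                              mismatch_count = fwd$mm),
    if (nrow(rev)) data.frame(position = L - (rev$pos - 1L) - seed_len,
                              strand = "-", mismatch_count = rev$mm)
  )
  if (is.null(out)) {
    out <- data.frame(position = integer(0), strand = character(0),
                      mismatch_count = integer(0))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Count exact core+PAM matches in a region sequence
#'
#' Counts placements on both strands of the target's 5-bp PAM-proximal core
#' followed immediately by a PAM-matching 3-mer, with no mismatches allowed.
#'
#' @inheritParams seed_match
#' @param pam IUPAC 3-mer PAM pattern.
#' @return integer count (0 allowed).
#' @export
core_match <- function(region_seq, target, pam = "NGG") {
  stopifnot(is(target, "target_site"))
  region_seq <- toupper(region_seq)
  if (nchar(region_seq) < 8L) stop("region_seq shorter than core + PAM")
  core <- target$core5
  fwd <- .word_scan(strsplit(region_seq, "")[[1]], core, pam, 0L)
  rev <- .word_scan(strsplit(revcomp(region_seq), "")[[1]], core, pam, 0L)
  nrow(fwd) + nrow(rev)
}
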