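#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(revcomp_cpp(as.character(x)))
}

## Vectorized test of 3-mers (or any fixed-length strings) against an IUPAC
## pattern of the same length. Non-ACGT observed bases never match.
matches_iupac <- function(seqs, pattern) {
  stopifnot(length(pattern) == 1L)
  pat <- strsplit(toupper(pattern), "")[[1]]
  ok <- rep(TRUE, length(seqs))
  for (i in seq_along(pat)) {
    allowed <- IUPAC_SETS[[pat[i]]]
    if (is.null(allowed)) stop("invalid IUPAC code in pattern: ", pat[i])
    ok <- ok & substr(seqs, i, i) %in% allowed
  }
  ok
}

is_acgt <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

## Accept a genome as DNAStringSet, FASTA path, or named character vector.
load_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    gn <- Biostrings::DNAStringSet(genome)
    if (is.null(names(gn))) names(gn) <- paste0("chr", seq_along(gn))
    return(gn)
  }
  stop("genome must be a DNAStringSet, a FASTA path, or a character vector")
}

## Accept intervals as GRanges, BED path, or data.frame with 0-based
## half-open start/end columns; returns GRanges (1-based internally).
as_intervals <- function(x, what = "intervals") {
  if (is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("file not found for ", what, ": ", x)
    return(rtracklayer::import(x, format = "BED"))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
    )
    if (!is.null(x$name)) gr$name <- x$name
    if (!is.null(x$strand)) GenomicRanges::strand(gr) <- x$strand
    return(gr)
  }
  stop(what, " must be a GRanges, a BED path, or a data.frame")
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param ids,seqs,quals character vectors of equal length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals)
  )
  invisible(path)
}
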