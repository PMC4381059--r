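# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: character-vector sliding windows instead of
# Biostrings matching, quadratic loops instead of findOverlaps, explicit
# hypergeometric tail sums instead of fisher.test, and Biostrings'
# dynamic-programming aligner instead of the anchor classifier.

# Brute-force protospacer scan: every 23-bp window on both strands, Hamming
# mismatches counted by character comparison.
oracle_scan <- function(genome_str, chrom, proto, max_mm, pam_pattern) {
  iupac <- list(N = c("A", "C", "G", "T"), G = "G", A = "A", C = "C", T = "T")
  scan_one <- function(chars, proto) {
    L <- length(chars)
    nwin <- L - 23L + 1L
    if (nwin < 1L) return(data.frame())
    p <- strsplit(proto, "")[[1]]
    mm <- integer(nwin)
    for (j in 1:20) mm <- mm + (chars[seq_len(nwin) + j - 1L] != p[j])
    pat <- strsplit(pam_pattern, "")[[1]]
    pam_ok <- rep(TRUE, nwin)
    for (j in 1:3) {
      pam_ok <- pam_ok & chars[seq_len(nwin) + 19L + j] %in% iupac[[pat[j]]]
    }
    ## windows containing any non-ACGT base are skipped (running count)
    bad <- cumsum(c(0L, !(chars %in% c("A", "C", "G", "T"))))
    acgt <- (bad[seq_len(nwin) + 23L] - bad[seq_len(nwin)]) == 0L
    ok <- mm <= max_mm & pam_ok & acgt
    data.frame(pos = which(ok), mm = mm[ok])
  }
  chars <- strsplit(genome_str, "")[[1]]
  fwd <- scan_one(chars, proto)
  rc_chars <- rev(unname(c(A = "T", C = "G", G = "C", T = "A",
                           N = "N")[chars]))
  rev <- scan_one(rc_chars, proto)
  L <- length(chars)
  out <- rbind(
    if (nrow(fwd)) data.frame(chrom = chrom, start0 = fwd$pos - 1L,
                              strand = "+", mm = fwd$mm),
    if (nrow(rev)) data.frame(chrom = chrom,
                              ## window start on minus maps back to plus:
                              ## protospacer 20-mer occupies the last 20 of
                              ## the 23-bp window
                              start0 = L - (rev$pos - 1L) - 23L + 3L,
                              strand = "-", mm = rev$mm)
  )
  if (is.null(out)) out <- data.frame(chrom = character(0),
                                      start0 = integer(0),
                                      strand = character(0), mm = integer(0))
  out[order(out$start0, out$strand), , drop = FALSE]
}

# Sliding-window NGG/CCN counter over one window sequence.
oracle_pam_count <- function(win) {
  ch <- strsplit(win, "")[[1]]
  L <- length(ch)
  cnt <- 0L
  for (i in seq_len(L - 2L)) {
    if (ch[i + 1L] == "G" && ch[i + 2L] == "G") cnt <- cnt + 1L  # NGG, plus
    if (ch[i] == "C" && ch[i + 1L] == "C") cnt <- cnt + 1L       # CCN = minus NGG
  }
  cnt
}

# Quadratic all-pairs >=1 bp overlap check on two GRanges.
oracle_overlap_any <- function(a, b) {
  sa <- as.character(GenomicRanges::seqnames(a))
  sb <- as.character(GenomicRanges::seqnames(b))
  s1 <- GenomicRanges::start(a); e1 <- GenomicRanges::end(a)
  s2 <- GenomicRanges::start(b); e2 <- GenomicRanges::end(b)
  vapply(seq_along(a), function(i) {
    any(sb == sa[i] & s2 <= e1[i] & e2 >= s1[i])
  }, logical(1))
}

# Exhaustive one-sided hypergeometric tail for a 2x2 table: probability of
# t_ind or more treated indels given the margins.
oracle_fisher_tail <- function(t_ind, t_oth, c_ind, c_oth) {
  n_t <- t_ind + t_oth
  n_c <- c_ind + c_oth
  K <- t_ind + c_ind
  N <- n_t + n_c
  ks <- max(0L, K - n_c):min(n_t, K)
  logp <- lchoose(n_t, ks) + lchoose(n_c, K - ks) - lchoose(N, K)
  sum(exp(logp[ks >= t_ind]))
}

# Alignment-based read class oracle: global alignment of the read within a
# locally chosen reference window, unit costs. Returns WT/SNP/insertion/
# deletion labels.
oracle_align_class <- function(seqs, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), ref, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 0, gapExtension = 1
  )
  nid <- Biostrings::nindel(aln)
  ins_w <- Biostrings::insertion(nid)[, "WidthSum"]
  del_w <- Biostrings::deletion(nid)[, "WidthSum"]
  net <- ins_w - del_w
  mm <- Biostrings::nmismatch(aln)
  ifelse(net < 0, "deletion",
         ifelse(net > 0, "insertion",
                ifelse(del_w > 0, "SNP",      # balanced indel: not WT
                       ifelse(mm > 0, "SNP", "WT"))))
}

# Random DNA string helper.
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Random sequence essentially never matches a 20-mer within 6 mismatches,
# so scan-oracle comparisons are only informative on genomes seeded with
# near-miss variants: assorted mismatch loads (0-7), strands and PAMs.
plant_variant_genome <- function(g, target, seed) {
  set.seed(seed)
  n_var <- 12L
  mm_counts <- c(0L, 1L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 6L, 7L, 2L)
  pams <- c("TGG", "AGG", "CGG", "GGG", "TAG", "CAG",
            "TGG", "AAG", "TTT", "CGG", "TGG", "GTG")
  plants <- data.frame(
    name = sprintf("v%02d", seq_len(n_var)),
    protospacer = target$protospacer,
    pam = pams,
    chrom = "chr1",
    window_start = 200L + (seq_len(n_var) - 1L) *
      ((nchar(g) - 500L) %/% n_var),
    strand = rep(c("+", "-"), length.out = n_var),
    mismatch_positions = vapply(mm_counts, function(k) {
      paste(sort(sample(1:20, k)), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  plant_sites(Biostrings::DNAStringSet(c(chr1 = g)), plants)$genome
}

hits_df <- function(h) {
  data.frame(start0 = GenomicRanges::start(h) - 1L,
             strand = as.character(GenomicRanges::strand(h)),
             mm = if (length(h)) h$mismatch_count else integer(0))
}
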