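## Apply per-base substitution errors to a character vector of reads.
.apply_subst_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(lens[i], n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate captured paired-end reads with known indel truth
#'
#' Emulates a targeted sequence-capture library: for each 200-bp region,
#' `depth_per_region` fragments are drawn with Normal(`fragment_length_mean`,
#' `fragment_length_sd`) lengths and start positions uniform over
#' `[region_start - fragment_length, region_end]` (random shearing, so read
#' pairs are staggered). A fraction `true_indel_freq` of fragments is
#' designated mutant and carries one indel whose left edge sits at the cut
#' site (Cas9 cuts 3 bp upstream of the PAM); the indel is realized only
#' when the cut falls strictly inside the fragment, and the per-read truth
#' table records the realized state. Indel sizes are uniform over
#' `indel_size_range` with deletions chosen with probability
#' `deletion_prob`. Substitution errors are applied per base, then a
#' fraction `clonal_rate` of pairs is emitted again as exact PCR duplicates.
#' Base qualities are constant high quality ("I", Q40).
#'
#' @param genome genome (DNAStringSet, FASTA path, or character vector).
#' @param regions data.frame from [make_capture_regions()].
#' @param truth data.frame with `region_id`, `true_indel_freq`, and
#'   optionally `cut_offset` (signed bases relative to the region center,
#'   default 0) and `pam_strand` (`"+"`/`"-"`, recorded only).
#' @param config a [sim_config()].
#' @param seed optional seed; defaults to `config$seed`; pass `NA` to use
#'   the current RNG state.
#' @param fastq_prefix if non-NULL, write `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return data.frame, one row per emitted pair (duplicates included):
#'   `id`, `region_id`, `seq1`, `qual1`, `seq2`, `qual2`, `start1`,
#'   `start2` (0-based mapped starts), `orientation`, `fragment_length`,
#'   `is_duplicate`, `mutant`, `realized_indel`, `indel_size` (signed, 0 if
#'   none), `cut_pos` (0-based genome coordinate of the cut).
#' @export
simulate_capture_reads <- function(genome, regions, truth, config,
                                   seed = NULL, fastq_prefix = NULL) {
  stopifnot(is(config, "sim_config"))
  gn <- load_genome(genome)
  if (is.null(seed)) seed <- config$seed
  if (!is.na(seed)) set.seed(seed)

  if (is.null(truth$cut_offset)) truth$cut_offset <- 0L
  if (is.null(truth$pam_strand)) truth$pam_strand <- "+"
  if (!all(regions$region_id %in% truth$region_id)) {
    stop("truth must cover every region (true_indel_freq 0 allowed)")
  }
  tr <- truth[match(regions$region_id, truth$region_id), ]
  if (any(tr$true_indel_freq < 0 | tr$true_indel_freq > 1)) {
    stop("true_indel_freq must lie in [0, 1]")
  }

  rl <- config$read_length
  out <- vector("list", nrow(regions))
  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    chr <- as.character(gn[[rg$chrom]])
    clen <- nchar(chr)
    if (rg$start < 0L || rg$end > clen) stop("region outside genome: ", rg$region_id)
    n <- config$depth_per_region
    L <- pmax(40L, pmin(as.integer(round(rnorm(n, config$fragment_length_mean,
                                               config$fragment_length_sd))),
                        2L * as.integer(config$fragment_length_mean)))
    ## staggered (uniform) 0-based starts, restricted to fragments that
    ## overlap the baited region by at least min_capture_overlap bases --
    ## hybridization capture does not retain barely-touching fragments
    mco <- pmin(config$min_capture_overlap, L, rg$end - rg$start)
    lo <- rg$start - L + mco
    hi <- rg$end - mco
    hi <- pmax(hi, lo)
    s0 <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
    s0 <- pmax(0L, pmin(s0, clen - L))

    ## cut: junction after 1-based position cut1; left edge of indel at cut
    cut1 <- rg$start + 100L + tr$cut_offset[ri]
    freq <- tr$true_indel_freq[ri]
    mutant <- runif(n) < freq
    sz <- sample(seq(config$indel_size_range[1], config$indel_size_range[2]),
                 n, replace = TRUE)
    is_del <- runif(n) < config$deletion_prob
    realized <- mutant & (s0 + 1L <= cut1) & (cut1 <= s0 + L - 1L)

    frag <- character(n)
    for (i in seq_len(n)) {
      a <- s0[i] + 1L
      if (!realized[i]) {
        frag[i] <- substr(chr, a, a + L[i] - 1L)
      } else if (is_del[i]) {
        left <- substr(chr, a, cut1)
        right <- substr(chr, cut1 + sz[i] + 1L,
                        min(clen, cut1 + sz[i] + L[i]))
        frag[i] <- substr(paste0(left, right), 1L, L[i])
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), sz[i], replace = TRUE),
                     collapse = "")
        left <- substr(chr, a, cut1)
        right <- substr(chr, cut1 + 1L, min(clen, cut1 + L[i]))
        frag[i] <- substr(paste0(left, ins, right), 1L, L[i])
      }
    }
    flen <- nchar(frag)
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp(substr(frag, pmax(1L, flen - rl + 1L), flen))
    r1 <- .apply_subst_errors(r1, config$subst_error_rate)
    r2 <- .apply_subst_errors(r2, config$subst_error_rate)

    df <- data.frame(
      id = sprintf("%s_frag%05d", rg$region_id, seq_len(n)),
      region_id = rg$region_id,
      seq1 = r1, qual1 = strrep("I", nchar(r1)),
      seq2 = r2, qual2 = strrep("I", nchar(r2)),
      start1 = s0, start2 = s0 + L - nchar(r2),
      orientation = "FR", fragment_length = L,
      is_duplicate = FALSE, mutant = mutant, realized_indel = realized,
      indel_size = ifelse(realized, ifelse(is_del, -sz, sz), 0L),
      cut_pos = cut1,                        # 0-based coordinate of junction
      stringsAsFactors = FALSE
    )
    if (config$clonal_rate > 0) {
      dup <- runif(n) < config$clonal_rate
      if (any(dup)) {
        d <- df[dup, , drop = FALSE]
        d$id <- paste0(d$id, ".dup")
        d$is_duplicate <- TRUE
        df <- rbind(df, d)
      }
    }
    out[[ri]] <- df
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL

  if (!is.null(fastq_prefix)) {
    write_fastq(reads$id, reads$seq1, reads$qual1,
                paste0(fastq_prefix, "_R1.fastq"))
    write_fastq(reads$id, reads$seq2, reads$qual2,
                paste0(fastq_prefix, "_R2.fastq"))
  }
  reads
}
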