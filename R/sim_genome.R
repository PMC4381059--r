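#' Generate a random genome
#'
#' Draws an i.i.d. random sequence with expected G and C frequencies of
#' `gc_content / 2` each. Reproducible for a fixed `seed` in the config.
#'
#' @param config a [sim_config()].
#' @param name chromosome name for the single synthetic contig.
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @export
make_genome <- function(config, name = "chrS") {
  stopifnot(is(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  bases <- sample(names(p), config$genome_length, replace = TRUE, prob = p)
  gn <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(gn) <- name
  gn
}

## Deterministic base substitution used when planting mismatches: cycle
## A -> C -> G -> T -> A so a given position always mutates the same way.
.next_base <- function(b) {
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  unname(cyc[b])
}

#' Plant target and off-target sites into a genome
#'
#' Writes 23-bp protospacer+PAM words into the genome at chosen loci, with a
#' chosen set of protospacer mismatches, on either strand. Mismatch positions
#' are numbered 1-20 with 20 PAM-adjacent; the mismatched base is substituted
#' deterministically (A->C->G->T->A) so planted words are reproducible.
#'
#' @param genome a genome (see [scan_genome()] for accepted forms).
#' @param plants data.frame with columns `name`, `protospacer` (20-nt),
#'   `pam` (concrete 3-mer to write, e.g. `"AGG"`), `chrom`, `window_start`
#'   (0-based start of the whole 23-bp window on the plus strand), `strand`
#'   (`"+"`/`"-"`), `mismatch_positions` (comma-joined integers, `""` for
#'   an exact site).
#' @return list with `genome` (modified DNAStringSet) and `truth`, a
#'   data.frame of planted loci in 0-based half-open protospacer coordinates
#'   (`chrom`, `start`, `end`, `name`, `mismatch_count`, `strand`,
#'   `planted_seq`, `pam`).
#' @export
plant_sites <- function(genome, plants) {
  gn <- load_genome(genome)
  need <- c("name", "protospacer", "pam", "chrom", "window_start", "strand",
            "mismatch_positions")
  stopifnot(all(need %in% names(plants)))

  ## reject overlapping 23-mers up front
  ord <- order(plants$chrom, plants$window_start)
  pl <- plants[ord, , drop = FALSE]
  if (nrow(pl) > 1L) {
    same <- pl$chrom[-1L] == pl$chrom[-nrow(pl)]
    gap <- pl$window_start[-1L] - pl$window_start[-nrow(pl)]
    if (any(same & gap < 23L)) stop("planted 23-mers must not overlap")
  }

  chr_seqs <- setNames(as.character(gn), names(gn))
  truth <- vector("list", nrow(plants))
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    proto <- toupper(p$protospacer)
    if (nchar(proto) != 20L) stop("protospacer must be 20 nt")
    mmpos <- integer(0)
    if (!is.na(p$mismatch_positions) && nzchar(p$mismatch_positions)) {
      mmpos <- as.integer(strsplit(p$mismatch_positions, ",")[[1]])
    }
    if (any(mmpos < 1L | mmpos > 20L)) {
      stop("mismatch positions must lie in 1-20")
    }
    var <- strsplit(proto, "")[[1]]
    var[mmpos] <- .next_base(var[mmpos])
    var <- paste(var, collapse = "")
    word <- paste0(var, toupper(p$pam))          # protospacer then PAM, 5'->3'
    if (p$strand == "-") word <- revcomp(word)

    s1 <- p$window_start + 1L                     # 1-based window start
    chr <- chr_seqs[[p$chrom]]
    if (is.null(chr) || s1 < 1L || (s1 + 22L) > nchar(chr)) {
      stop("planted window outside genome bounds: row ", i)
    }
    substr(chr, s1, s1 + 22L) <- word
    chr_seqs[[p$chrom]] <- chr

    ## protospacer 20-mer coordinates within the 23-bp window
    if (p$strand == "+") {
      ps <- p$window_start; pe <- p$window_start + 20L
    } else {
      ps <- p$window_start + 3L; pe <- p$window_start + 23L
    }
    truth[[i]] <- data.frame(
      chrom = p$chrom, start = ps, end = pe, name = p$name,
      mismatch_count = length(mmpos), strand = p$strand,
      planted_seq = var, pam = toupper(p$pam),
      stringsAsFactors = FALSE
    )
  }
  out <- Biostrings::DNAStringSet(unlist(chr_seqs))
  names(out) <- names(gn)
  list(genome = out, truth = do.call(rbind, truth))
}
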