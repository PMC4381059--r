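#' Define a CRISPR target site
#'
#' A target site is a 20-nt protospacer written 5' to 3' so that its last base
#' is immediately adjacent to the PAM. The PAM-proximal 12 nt form the seed
#' and the last 5 nt the core, the regions of the protospacer where mismatches
#' are least tolerated by Cas9.
#'
#' @param name short label, e.g. `"S1"`.
#' @param protospacer 20-nt uppercase A/C/G/T string.
#' @param pam_pattern IUPAC-degenerate 3-mer PAM pattern; `"NGG"` is the
#'   canonical *S. pyogenes* PAM, `"NAG"` a weak alternative.
#' @param chrom,start,end,strand optional genomic locus of the protospacer
#'   (0-based half-open coordinates).
#' @return object of class `target_site` with derived `seed12` and `core5`.
#' @examples
#' s1 <- target_site("S1", "GCTCCCTACGCATGCGTCCC")
#' s1$core5  # "GTCCC"
#' @export
target_site <- function(name, protospacer, pam_pattern = "NGG",
                        chrom = NULL, start = NULL, end = NULL, strand = NULL) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L || !is_acgt(protospacer)) {
    stop("protospacer must be a 20-nt A/C/G/T string")
  }
  if (nchar(pam_pattern) != 3L) stop("pam_pattern must be a 3-mer")
  out <- structure(
    list(
      name = name,
      protospacer = protospacer,
      pam_pattern = toupper(pam_pattern),
      seed12 = substr(protospacer, 9L, 20L),
      core5 = substr(protospacer, 16L, 20L),
      chrom = chrom, start = start, end = end, strand = strand
    ),
    class = "target_site"
  )
  out
}

#' @export
print.target_site <- function(x, ...) {
  cat("<target_site>", x$name, "\n")
  cat("  protospacer:", x$protospacer, "+", x$pam_pattern, "\n")
  cat("  seed12:", x$seed12, "  core5:", x$core5, "\n")
  invisible(x)
}
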