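#' PAM density of genomic regions
#'
#' Counts NGG trinucleotide occurrences on both DNA strands of the central
#' `window` bases of each region (minus-strand occurrences are CCN words on
#' the plus strand), expressed as a percentage of the window length.
#' Overlapping occurrences all count (a GGG run contributes one NGG start
#' per position). The region center is `floor((start + end) / 2)` in 0-based
#' coordinates.
#'
#' @param regions regions (GRanges, BED path, or data.frame).
#' @param genome genome (DNAStringSet, FASTA path, or character vector).
#' @param window central window size in bases (default 100).
#' @param set_label label carried into the result, e.g. `"S1-specific"`.
#' @return object of class `pam_density_result`: list with `set_label`,
#'   `density` (percent per region), `n`, `median`, `mean`, `sd`,
#'   `n_skipped` (regions whose window ran off the contig).
#' @export
pam_density <- function(regions, genome, window = 100L, set_label = "regions") {
  gr <- as_intervals(regions, "regions")
  gn <- load_genome(genome)
  half <- window %/% 2L

  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  center0 <- (start0 + end0) %/% 2L
  win_start1 <- center0 - half + 1L               # 1-based window start
  win_end1 <- win_start1 + window - 1L

  clen <- setNames(Biostrings::width(gn), names(gn))[chrom]
  ok <- !is.na(clen) & win_start1 >= 1L & win_end1 <= clen
  if (any(!ok)) {
    warning(sum(!ok), " region(s) too close to a contig edge; skipped")
  }
  seqs <- Biostrings::DNAStringSet(vapply(which(ok), function(i) {
    substr(as.character(gn[[chrom[i]]]), win_start1[i], win_end1[i])
  }, character(1)))

  n_plus <- Biostrings::vcountPattern("NGG", seqs, fixed = FALSE)
  n_minus <- Biostrings::vcountPattern("CCN", seqs, fixed = FALSE)
  dens <- 100 * (n_plus + n_minus) / window

  structure(
    list(set_label = set_label, density = dens, n = length(dens),
         median = if (length(dens)) median(dens) else NA_real_,
         mean = if (length(dens)) mean(dens) else NA_real_,
         sd = if (length(dens) > 1L) sd(dens) else NA_real_,
         n_skipped = sum(!ok)),
    class = "pam_density_result"
  )
}

#' @export
print.pam_density_result <- function(x, ...) {
  cat("<pam_density_result>", x$set_label, " n =", x$n, "\n")
  cat(sprintf("  median %.1f%%  mean %.1f%%  sd %.1f\n",
              x$median, x$mean, x$sd))
  invisible(x)
}

#' Letter groupings of PAM-density distributions
#'
#' Runs pairwise two-sample t-tests between groups and assigns letters so
#' that two groups share a letter iff they are not significantly different
#' at `alpha`. Letters correspond to maximal cliques of the
#' "not significantly different" graph, ordered by group mean.
#'
#' @param results list of [pam_density()] results or named list of numeric
#'   vectors.
#' @param alpha significance threshold for the pairwise t-tests.
#' @return data.frame with `set_label`, `n`, `mean`, `median`, `sd`,
#'   `letters`; attribute `"pairwise_p"` holds the p-value matrix. Pairs
#'   with degenerate (zero) variance in both groups are flagged in attribute
#'   `"degenerate_pairs"` and compared on means alone.
#' @export
compare_density_groups <- function(results, alpha = 1e-4) {
  vals <- lapply(results, function(r) {
    if (inherits(r, "pam_density_result")) r$density else as.numeric(r)
  })
  labs <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "pam_density_result")) r$set_label
    else if (!is.null(names(results)[i]) && nzchar(names(results)[i])) names(results)[i]
    else paste0("group", i)
  }, character(1))
  k <- length(vals)
  if (k < 2L) stop("need at least two groups")
  if (any(lengths(vals) < 2L)) stop("each group needs at least two regions")

  pmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  degen <- character(0)
  notdiff <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      p <- tryCatch(t.test(vals[[i]], vals[[j]])$p.value, error = function(e) NA_real_)
      if (is.na(p)) {
        degen <- c(degen, paste(labs[i], labs[j], sep = " vs "))
        same <- isTRUE(all.equal(mean(vals[[i]]), mean(vals[[j]])))
        notdiff[i, j] <- notdiff[j, i] <- same
      } else {
        pmat[i, j] <- pmat[j, i] <- p
        notdiff[i, j] <- notdiff[j, i] <- p >= alpha
      }
    }
  }
  diag(notdiff) <- TRUE

  g <- igraph::graph_from_adjacency_matrix(notdiff, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  ## order cliques by the mean of their groups so letter A is the
  ## lowest-density clique
  cl_means <- vapply(cliques, function(cl) {
    mean(vapply(as.integer(cl), function(i) mean(vals[[i]]), numeric(1)))
  }, numeric(1))
  cliques <- cliques[order(cl_means)]
  letts <- rep("", k)
  for (ci in seq_along(cliques)) {
    mem <- as.integer(cliques[[ci]])
    letts[mem] <- paste0(letts[mem], LETTERS[ci])
  }

  out <- data.frame(
    set_label = labs,
    n = lengths(vals),
    mean = vapply(vals, mean, numeric(1)),
    median = vapply(vals, median, numeric(1)),
    sd = vapply(vals, sd, numeric(1)),
    letters = letts,
    stringsAsFactors = FALSE
  )
  attr(out, "pairwise_p") <- pmat
  attr(out, "degenerate_pairs") <- degen
  out
}
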