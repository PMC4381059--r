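#' Build a k-mer index over capture-region reference sequences
#'
#' Indexes every k-mer of each region's reference (both strands) for fast
#' candidate lookup during read-pair assignment.
#'
#' @param regions data.frame from [make_capture_regions()].
#' @param k k-mer length (default 20, the minimum anchor size).
#' @return object of class `region_index`.
#' @export
build_region_index <- function(regions, k = 20L) {
  env <- new.env(hash = TRUE, size = nrow(regions) * 400L)
  add <- function(kmer, entry) {
    cur <- env[[kmer]]
    env[[kmer]] <- if (is.null(cur)) entry else rbind(cur, entry)
  }
  for (i in seq_len(nrow(regions))) {
    s <- regions$seq[i]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    for (j in seq_along(starts)) {
      add(fwd[j], cbind(region = i, strand = 1L, offset0 = starts[j] - 1L))
    }
    rc <- revcomp(s)
    rcs <- substring(rc, starts, starts + k - 1L)
    for (j in seq_along(starts)) {
      ## rc-string k-mer j corresponds to a plus-strand k-mer starting at
      ## L - (j - 1) - k (0-based)
      add(rcs[j], cbind(region = i, strand = -1L, offset0 = L - (j - 1L) - k))
    }
  }
  structure(list(env = env, k = k, regions = regions), class = "region_index")
}

#' Assign read pairs to capture regions
#'
#' Each pair is matched against the region references: candidate regions are
#' found through exact shared k-mers (probed every `probe_step` bases along
#' both mates, so any shared anchor of at least `k + probe_step - 1` bases
#' is detected), then, when more than one region is in play, scored by the
#' longest common substring with the read in either orientation. A pair is
#' assigned iff a strictly unique best region exists; ties (e.g. two
#' identical region sequences) leave the pair unassigned. Mapped start
#' positions and pair orientation are estimated from the first anchoring
#' k-mer of each mate, for downstream clonal deduplication.
#'
#' @param pairs data.frame with `seq1`, `seq2` (and any other columns, which
#'   are preserved).
#' @param regions data.frame from [make_capture_regions()], or a prebuilt
#'   [build_region_index()].
#' @param probe_step spacing of probe k-mers along each mate.
#' @return `pairs` with columns added: `region_id` (NA if unassigned),
#'   `unique` (logical), `map_start1`, `map_start2` (0-based genome
#'   coordinates), `map_orientation`.
#' @export
assign_to_regions <- function(pairs, regions, probe_step = 10L) {
  idx <- if (inherits(regions, "region_index")) regions
         else build_region_index(regions)
  k <- idx$k
  reg <- idx$regions
  n <- nrow(pairs)

  mk_probes <- function(seqs, mate) {
    lens <- nchar(seqs)
    ok <- lens >= k
    np <- ifelse(ok, (lens - k) %/% probe_step + 1L, 0L)
    pair_main <- rep(seq_along(seqs), np)
    pos_main <- sequence(np, from = 1L, by = probe_step)
    extra <- ok & ((lens - k) %% probe_step != 0L)
    pair <- c(pair_main, which(extra))
    pos <- c(pos_main, (lens - k + 1L)[extra])
    data.frame(pair = pair, mate = mate, p0 = pos - 1L,
               len = lens[pair],
               kmer = substring(seqs[pair], pos, pos + k - 1L),
               stringsAsFactors = FALSE)
  }
  probes <- rbind(mk_probes(pairs$seq1, 1L), mk_probes(pairs$seq2, 2L))
  hits <- mget(probes$kmer, envir = idx$env, ifnotfound = list(NULL))
  hreg <- vapply(hits, function(h) {
    if (is.null(h)) NA_integer_ else h[1L, 1L]
  }, integer(1))
  hmulti <- vapply(hits, function(h) {
    !is.null(h) && nrow(h) > 1L && length(unique(h[, 1L])) > 1L
  }, logical(1))

  ## per-pair candidate-region range over single-region probe hits
  valid <- !is.na(hreg) & !hmulti
  pv <- probes$pair[valid]; rv <- hreg[valid]
  o <- order(pv, rv)
  pvs <- pv[o]; rvs <- rv[o]
  firsts <- !duplicated(pvs)
  lasts <- !duplicated(pvs, fromLast = TRUE)
  rmin <- rep(NA_integer_, n); rmax <- rep(NA_integer_, n)
  rmin[pvs[firsts]] <- rvs[firsts]
  rmax[pvs[lasts]] <- rvs[lasts]
  has_multi <- rep(FALSE, n)
  has_multi[unique(probes$pair[hmulti])] <- TRUE

  best <- rep(NA_integer_, n)
  simple <- !is.na(rmin) & rmin == rmax & !has_multi
  best[simple] <- rmin[simple]

  ## slow path: pairs touching several regions (or only multi-region k-mers)
  hard <- which((!is.na(rmin) & rmin != rmax) | has_multi)
  if (length(hard)) {
    rows_by_pair <- split(which(!is.na(hreg) | hmulti),
                          probes$pair[!is.na(hreg) | hmulti])
    for (i in hard) {
      rows <- rows_by_pair[[as.character(i)]]
      cand <- unique(unlist(lapply(hits[rows], function(h) h[, 1L])))
      sc <- vapply(cand, function(ri) {
        rs <- reg$seq[ri]
        max(lcs_substring(pairs$seq1[i], rs)[1],
            lcs_substring(revcomp(pairs$seq1[i]), rs)[1],
            lcs_substring(pairs$seq2[i], rs)[1],
            lcs_substring(revcomp(pairs$seq2[i]), rs)[1])
      }, numeric(1))
      top <- which(sc == max(sc))
      if (length(top) == 1L) best[i] <- cand[top]
    }
  }

  ## mapped-start estimates from the first probe hit of each mate that
  ## points at the assigned region
  ms <- matrix(NA_integer_, n, 2L)
  strand1 <- rep(NA_integer_, n)
  agree <- which(!is.na(hreg) & !is.na(best[probes$pair]) &
                   hreg == best[probes$pair])
  key <- probes$pair[agree] * 2L + probes$mate[agree]
  sel <- agree[!duplicated(key)]
  if (length(sel)) {
    off0 <- vapply(hits[sel], function(h) h[1L, 3L], numeric(1))
    strd <- vapply(hits[sel], function(h) h[1L, 2L], numeric(1))
    pr <- probes$pair[sel]
    rstart0 <- reg$start[best[pr]]
    est <- ifelse(strd == 1L,
                  rstart0 + off0 - probes$p0[sel],
                  rstart0 + off0 + probes$p0[sel] + k - probes$len[sel])
    m1 <- probes$mate[sel] == 1L
    ms[cbind(pr, probes$mate[sel])] <- as.integer(est)
    strand1[pr[m1]] <- as.integer(strd[m1])
  }

  pairs$region_id <- ifelse(is.na(best), NA_character_, reg$region_id[best])
  pairs$unique <- !is.na(best)
  pairs$map_start1 <- ms[, 1L]
  pairs$map_start2 <- ms[, 2L]
  pairs$map_orientation <- ifelse(is.na(strand1), NA_character_,
                                  ifelse(strand1 == 1L, "FR", "RF"))
  pairs
}
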