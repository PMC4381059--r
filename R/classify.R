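.DISCARD <- function(reason) {
  list(class = "discarded", net = NA_integer_, offset = NA_real_,
       nmm = NA_integer_, anchor = NA_integer_, span = NA_integer_,
       reason = reason)
}

## Core anchor-based classification; returns a plain list (hot path).
##
## A chain of exact anchors is grown outward from the primary (longest
## common substring) anchor: each unanchored read flank is matched against
## the corresponding side of the reference until no match of at least
## min_anchor2 bases remains. The chain handles reads carrying both an
## indel and sequencing errors (three or more clean segments); anchors
## shorter than min_anchor2 are ignored because a 1-4-base remainder
## matches somewhere in the reference flank by chance and would fake a
## length difference.
.classify_core <- function(seq, ref, min_anchor, min_span, min_anchor2 = 5L) {
  rlen <- nchar(ref)
  a <- lcs_substring(seq, ref)
  s <- seq
  ## only consult the reverse orientation when the forward anchor leaves
  ## room for a better one
  if (a[1] < 0.6 * nchar(seq)) {
    seq_rc <- revcomp(seq)
    a_r <- lcs_substring(seq_rc, ref)
    if (a_r[1] > a[1]) { s <- seq_rc; a <- a_r }
  }
  if (a[1] < min_anchor) return(.DISCARD("anchor"))
  n <- nchar(s)

  ## anchor rows: qs, qe, rs, re (1-based, read and reference coordinates)
  anchors <- matrix(c(a[2], a[2] + a[1] - 1L, a[3], a[3] + a[1] - 1L),
                    nrow = 1L)
  repeat {                                    # extend leftward
    qs0 <- anchors[1L, 1L]; rs0 <- anchors[1L, 3L]
    if (qs0 <= 1L || rs0 <= 1L) break
    b <- lcs_substring(substr(s, 1L, qs0 - 1L), substr(ref, 1L, rs0 - 1L))
    if (b[1] < min_anchor2) break
    anchors <- rbind(c(b[2], b[2] + b[1] - 1L, b[3], b[3] + b[1] - 1L),
                     anchors)
  }
  repeat {                                    # extend rightward
    k <- nrow(anchors)
    qe0 <- anchors[k, 2L]; re0 <- anchors[k, 4L]
    if (qe0 >= n || re0 >= rlen) break
    b <- lcs_substring(substr(s, qe0 + 1L, n), substr(ref, re0 + 1L, rlen))
    if (b[1] < min_anchor2) break
    anchors <- rbind(anchors,
                     c(qe0 + b[2], qe0 + b[2] + b[1] - 1L,
                       re0 + b[3], re0 + b[3] + b[1] - 1L))
  }

  k <- nrow(anchors)
  span <- anchors[k, 4L] - anchors[1L, 3L] + 1L
  if (span < min_span) return(.DISCARD("span"))
  net <- (anchors[k, 2L] - anchors[1L, 1L] + 1L) - span

  if (k == 1L) {
    return(list(class = "WT", net = 0L, offset = 0, nmm = 0L,
                anchor = a[1], span = as.integer(span), reason = ""))
  }
  gap_q <- anchors[2:k, 1L] - anchors[1:(k - 1L), 2L] - 1L
  gap_r <- anchors[2:k, 3L] - anchors[1:(k - 1L), 4L] - 1L

  if (net != 0L) {
    cls <- if (net < 0L) "deletion" else "insertion"
    nmm <- 0L
    j <- which.max(abs(gap_q - gap_r))        # the indel-bearing gap
    offset <- (anchors[j, 4L] + anchors[j + 1L, 3L] - 1) / 2 - 100
  } else if (any(gap_q != gap_r)) {
    ## balanced insertion+deletion: length-preserving, not wild type
    cls <- "SNP"
    nmm <- 0L
    j <- which.max(abs(gap_q - gap_r))
    offset <- (anchors[j, 4L] + anchors[j + 1L, 3L] - 1) / 2 - 100
  } else {
    nmm <- 0L
    for (j in which(gap_q > 0L)) {
      nmm <- nmm + hamming_mm(
        substr(s, anchors[j, 2L] + 1L, anchors[j + 1L, 1L] - 1L),
        substr(ref, anchors[j, 4L] + 1L, anchors[j + 1L, 3L] - 1L)
      )
    }
    cls <- if (nmm > 0L) "SNP" else "WT"
    offset <- if (cls == "SNP" && any(gap_q > 0L)) {
      j <- which(gap_q > 0L)[1L]
      (anchors[j, 4L] + anchors[j + 1L, 3L] - 1) / 2 - 100
    } else 0
  }
  list(class = cls, net = as.integer(net), offset = as.numeric(offset),
       nmm = as.integer(nmm), anchor = a[1], span = as.integer(span),
       reason = "")
}

#' Classify one capture read against its region reference
#'
#' Anchor-based length classification. The longest common substring between
#' the read (either orientation) and the 200-bp reference is the primary
#' anchor; reads whose anchor is shorter than `min_anchor` are discarded.
#' Further anchors (each at least 5 bp) are chained outward over the
#' unanchored read flanks against the corresponding sides of the reference,
#' so reads carrying both an indel and sequencing errors are still measured
#' end to end. The implied reference span is the distance between the outer
#' anchor endpoints on the reference; reads spanning less than `min_span`
#' are discarded. The net length difference between the read segment and
#' the reference span between the outer endpoints determines the class:
#' negative = deletion, positive = insertion, zero with all inter-anchor
#' bases equal = WT, zero with mismatches (or a balanced insertion plus
#' deletion) = SNP. The indel center offset is the midpoint of the
#' indel-bearing inter-anchor gap on the reference, relative to the region
#' center (0-based).
#'
#' @param seq read sequence (merged pair or single read).
#' @param region_ref 200-nt region reference sequence.
#' @param min_anchor minimum primary-anchor length (default 20).
#' @param min_span minimum implied reference span (default 100).
#' @return one-row data.frame: `class` (`WT`/`SNP`/`insertion`/`deletion`/
#'   `discarded`), `net_indel_size`, `indel_center_offset`,
#'   `n_mismatches`, `anchor_len`, `span`, `reason`.
#' @export
classify_read <- function(seq, region_ref, min_anchor = 20L, min_span = 100L) {
  r <- .classify_core(seq, region_ref, min_anchor, min_span)
  data.frame(class = r$class, net_indel_size = r$net,
             indel_center_offset = r$offset, n_mismatches = r$nmm,
             anchor_len = r$anchor, span = r$span, reason = r$reason,
             stringsAsFactors = FALSE)
}

#' Classify a table of merged reads
#'
#' @param reads data.frame with `seq` and `region_id` (see
#'   [assign_to_regions()] and [merge_pairs()]).
#' @param regions data.frame from [make_capture_regions()].
#' @param min_anchor,min_span see [classify_read()].
#' @return `reads` with classification columns bound on.
#' @export
classify_reads <- function(reads, regions, min_anchor = 20L, min_span = 100L) {
  refs <- setNames(regions$seq, regions$region_id)
  n <- nrow(reads)
  cls <- character(n); net <- integer(n); off <- numeric(n)
  nmm <- integer(n); anc <- integer(n); spn <- integer(n); rsn <- character(n)
  for (i in seq_len(n)) {
    ref <- refs[[reads$region_id[i]]]
    r <- if (is.null(ref)) .DISCARD("no_region")
         else .classify_core(reads$seq[i], ref, min_anchor, min_span)
    cls[i] <- r$class; net[i] <- r$net; off[i] <- r$offset
    nmm[i] <- r$nmm; anc[i] <- r$anchor; spn[i] <- r$span; rsn[i] <- r$reason
  }
  reads$class <- cls
  reads$net_indel_size <- net
  reads$indel_center_offset <- off
  reads$n_mismatches <- nmm
  reads$anchor_len <- anc
  reads$span <- spn
  reads$reason <- rsn
  reads
}
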