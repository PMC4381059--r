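#' Remove PCR-clonal read pairs
#'
#' Capture libraries are made by random shearing, so independent fragments
#' are staggered; read pairs mapping to the same start positions in the same
#' orientation are PCR duplicates of one original molecule. Exactly one pair
#' is retained per (chrom, start1, start2, orientation) key, the first
#' encountered (stable order). Pairs without mapping coordinates cannot be
#' keyed and pass through unaffected.
#'
#' @param pairs data.frame with mapped start columns: `map_start1`,
#'   `map_start2`, `map_orientation` (as produced by
#'   [assign_to_regions()]), or `start1`, `start2`, `orientation`; an
#'   optional `chrom` or `region_id` column joins the key.
#' @return list with `pairs` (deduplicated, original order kept) and
#'   `n_removed`.
#' @export
remove_clonal <- function(pairs) {
  cols <- if (all(c("map_start1", "map_start2", "map_orientation") %in% names(pairs))) {
    c("map_start1", "map_start2", "map_orientation")
  } else if (all(c("start1", "start2", "orientation") %in% names(pairs))) {
    c("start1", "start2", "orientation")
  } else {
    stop("pairs must carry start1/start2/orientation (or map_*) columns")
  }
  space <- if (!is.null(pairs$chrom)) pairs$chrom
           else if (!is.null(pairs$region_id)) pairs$region_id
           else ""
  mapped <- !is.na(pairs[[cols[1]]]) & !is.na(pairs[[cols[2]]])
  key <- paste(space, pairs[[cols[1]]], pairs[[cols[2]]], pairs[[cols[3]]],
               sep = ":")
  dup <- mapped & duplicated(ifelse(mapped, key, paste0("u", seq_len(nrow(pairs)))))
  list(pairs = pairs[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Extract pair mapping coordinates from a SAM file
#'
#' Minimal reader for plain-text SAM: pulls primary-alignment coordinates of
#' both mates per read name, for use as clonal-deduplication keys.
#'
#' @param path SAM path.
#' @return data.frame with `id`, `chrom`, `start1`, `start2` (0-based
#'   leftmost positions; NA if a mate is unmapped), `orientation`
#'   (`"FR"`/`"RF"`).
#' @export
read_sam_coords <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln)) {
    return(data.frame(id = character(0), chrom = character(0),
                      start1 = integer(0), start2 = integer(0),
                      orientation = character(0)))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  qname <- qname[primary]; flag <- flag[primary]
  rname <- rname[primary]; pos <- pos[primary]
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  pos[unmapped] <- NA_integer_
  first <- bitwAnd(flag, 0x40L) != 0L
  rev1 <- bitwAnd(flag, 0x10L) != 0L

  ids <- unique(qname)
  i1 <- match(ids, ifelse(first, qname, NA))
  i2 <- match(ids, ifelse(!first, qname, NA))
  data.frame(
    id = ids,
    chrom = ifelse(!is.na(i1), rname[i1], rname[i2]),
    start1 = ifelse(!is.na(i1), pos[i1] - 1L, NA_integer_),
    start2 = ifelse(!is.na(i2), pos[i2] - 1L, NA_integer_),
    orientation = ifelse(!is.na(i1) & !rev1[pmax(i1, 1L)], "FR", "RF"),
    stringsAsFactors = FALSE
  )
}
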