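#' Per-region indel summaries with exclusion flags
#'
#' Tallies classified reads per region and computes the indel percentage as
#' `100 * (n_ins + n_del) / n_total`, where `n_total` counts all classified
#' (non-discarded) reads, SNP reads included. Flags regions for exclusion
#' from significance testing: `low_coverage` (fewer than `min_reads`
#' classified reads), `homopolymer` (reference contains a run of
#' `homopolymer_len` or more identical bases, where indel-calling artefacts
#' concentrate), `high_background` (untreated-sample indel percentage above
#' `background_pct`, indicating strain/reference mismatch rather than
#' nuclease activity).
#'
#' @param classified data.frame from [classify_reads()].
#' @param regions data.frame from [make_capture_regions()].
#' @param untreated optional data.frame with `region_id` and `indel_pct`
#'   from the untreated sample (e.g. a previous `summarize_regions()` run).
#' @param min_reads minimum classified reads per region (default 25).
#' @param homopolymer_len homopolymer run length that triggers exclusion.
#'   Default 5; 6 is a documented variant.
#' @param background_pct untreated indel percentage above which a region is
#'   excluded (default 5).
#' @return data.frame, one row per region: counts per class, `n_discarded`
#'   audit count, `indel_pct`, logical flag columns and `excluded`.
#' @export
summarize_regions <- function(classified, regions, untreated = NULL,
                              min_reads = 25L, homopolymer_len = 5L,
                              background_pct = 5) {
  ids <- regions$region_id
  cls <- classified$class
  rid <- classified$region_id
  cnt <- function(label) {
    v <- table(factor(rid[cls == label], levels = ids))
    as.integer(v)
  }
  n_wt <- cnt("WT"); n_snp <- cnt("SNP")
  n_ins <- cnt("insertion"); n_del <- cnt("deletion")
  n_disc <- cnt("discarded")
  n_total <- n_wt + n_snp + n_ins + n_del
  indel_pct <- ifelse(n_total > 0L, 100 * (n_ins + n_del) / n_total, NA_real_)

  hp_pat <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                    homopolymer_len, homopolymer_len,
                    homopolymer_len, homopolymer_len)
  flag_hp <- grepl(hp_pat, regions$seq)
  flag_low <- n_total < min_reads

  flag_bg <- rep(FALSE, length(ids))
  if (!is.null(untreated)) {
    u <- untreated$indel_pct[match(ids, untreated$region_id)]
    flag_bg <- !is.na(u) & u > background_pct
  }

  data.frame(
    region_id = ids,
    category = if (!is.null(regions$category)) regions$category else NA,
    n_total = n_total, n_wt = n_wt, n_snp = n_snp,
    n_ins = n_ins, n_del = n_del, n_discarded = n_disc,
    indel_pct = indel_pct,
    flag_low_coverage = flag_low,
    flag_homopolymer = flag_hp,
    flag_high_background = flag_bg,
    excluded = flag_low | flag_hp | flag_bg,
    stringsAsFactors = FALSE
  )
}

#' Fisher's exact enrichment test of indels per region
#'
#' For each region, tests whether indel-carrying reads are enriched in the
#' treated sample relative to the untreated control, using a one-sided
#' Fisher's exact test on the 2x2 table (indel / non-indel) x (treated /
#' control). Non-indel pools WT and SNP reads. Regions excluded by either
#' summary's flags are never called significant; no multiple-testing
#' correction is applied by default (the raw threshold is reported with n).
#'
#' @param treated,control data.frames from [summarize_regions()].
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @param direction `"forward"` tests enrichment in the treated sample;
#'   `"reverse"` tests enrichment in the control.
#' @param p_adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return data.frame per region: the 2x2 counts, `fisher_p`, `excluded`,
#'   `significant`.
#' @export
fisher_significance <- function(treated, control, alpha = 0.01,
                                direction = c("forward", "reverse"),
                                p_adjust = "none") {
  direction <- match.arg(direction)
  ids <- treated$region_id
  ctl <- control[match(ids, control$region_id), ]

  t_ind <- treated$n_ins + treated$n_del
  t_oth <- treated$n_wt + treated$n_snp
  c_ind <- ctl$n_ins + ctl$n_del
  c_oth <- ctl$n_wt + ctl$n_snp
  excluded <- treated$excluded | ctl$excluded | is.na(c_ind) |
    (t_ind + t_oth == 0L) | (c_ind + c_oth == 0L)

  p <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    if (is.na(c_ind[i]) || (t_ind[i] + t_oth[i]) == 0L ||
        (c_ind[i] + c_oth[i]) == 0L) next
    m <- matrix(c(t_ind[i], t_oth[i], c_ind[i], c_oth[i]),
                nrow = 2L, byrow = TRUE)
    if (direction == "reverse") m <- m[2:1, ]
    p[i] <- fisher.test(m, alternative = "greater")$p.value
  }
  p_eff <- if (p_adjust == "none") p else stats::p.adjust(p, method = p_adjust)

  data.frame(
    region_id = ids,
    treated_indel = t_ind, treated_other = t_oth,
    control_indel = c_ind, control_other = c_oth,
    fisher_p = p,
    p_adjusted = if (p_adjust == "none") p else p_eff,
    excluded = excluded,
    significant = !excluded & !is.na(p_eff) & p_eff < alpha,
    stringsAsFactors = FALSE
  )
}

#' Indel size and position histograms
#'
#' @param classified data.frame from [classify_reads()].
#' @return list with `size` (data.frame `region_id`, `size`, `n`; deletions
#'   negative) and `position` (data.frame `region_id`, `offset`, `n`;
#'   offsets relative to the region center).
#' @export
indel_profiles <- function(classified) {
  ind <- classified[classified$class %in% c("insertion", "deletion"), ,
                    drop = FALSE]
  if (!nrow(ind)) {
    return(list(
      size = data.frame(region_id = character(0), size = integer(0),
                        n = integer(0)),
      position = data.frame(region_id = character(0), offset = numeric(0),
                            n = integer(0))
    ))
  }
  sz <- as.data.frame(table(region_id = ind$region_id,
                            size = ind$net_indel_size),
                      stringsAsFactors = FALSE)
  sz <- sz[sz$Freq > 0L, ]
  names(sz)[3] <- "n"
  sz$size <- as.integer(sz$size)

  po <- as.data.frame(table(region_id = ind$region_id,
                            offset = round(ind$indel_center_offset)),
                      stringsAsFactors = FALSE)
  po <- po[po$Freq > 0L, ]
  names(po)[3] <- "n"
  po$offset <- as.numeric(po$offset)
  list(size = sz[order(sz$region_id, sz$size), ],
       position = po[order(po$region_id, po$offset), ])
}

#' Capture coverage and fold enrichment
#'
#' Mean assigned read pairs per targeted 200-bp region versus random control
#' regions, and the implied fold enrichment of the capture. When the random
#' mean is zero the enrichment is infinite; a floored estimate using a
#' minimum of one read per random region is reported separately.
#'
#' @param assigned data.frame from [assign_to_regions()].
#' @param regions data.frame from [make_capture_regions()]; rows with
#'   `category == random_category` are the controls.
#' @param random_category category label of the control regions.
#' @return list: `mean_targeted`, `mean_random`, `fold_enrichment`,
#'   `fold_enrichment_floored`, `per_region` (data.frame of counts).
#' @export
coverage_stats <- function(assigned, regions,
                           random_category = "random_control") {
  counts <- table(factor(assigned$region_id, levels = regions$region_id))
  per <- data.frame(region_id = regions$region_id,
                    category = regions$category,
                    n_pairs = as.integer(counts),
                    stringsAsFactors = FALSE)
  is_rand <- per$category == random_category
  mt <- mean(per$n_pairs[!is_rand])
  mr <- if (any(is_rand)) mean(per$n_pairs[is_rand]) else 0
  list(
    mean_targeted = mt,
    mean_random = mr,
    fold_enrichment = if (mr > 0) mt / mr else Inf,
    fold_enrichment_floored = mt / max(mr, 1),
    per_region = per
  )
}
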