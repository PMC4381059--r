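.screen_defaults <- function() {
  list(
    seed = 1L,
    ## synthetic genome & library
    genome_length = 120000L, gc_content = 0.42,
    read_length = 100L, fragment_length_mean = 150, fragment_length_sd = 20,
    depth_per_region = 150L, clonal_rate = 0.1, subst_error_rate = 0.001,
    indel_size_range = c(1L, 5L), deletion_prob = 0.8,
    ## screen design
    n_offtargets_per_target = 6L, offtarget_mismatches = 3L,
    n_random_controls = 20L,
    target_indel_freqs = c(S1 = 0.168, S2 = 0.156),
    offtarget_indel_freq_active = 0.113,
    ## scan
    max_mm = 4L, pam = "NGG", seed_len = 12L,
    ## capture pipeline thresholds
    min_len = 35L, qual_threshold = 20L, min_overlap = 5L,
    min_anchor = 20L, min_span = 100L,
    min_reads = 25L, homopolymer_len = 5L, background_pct = 5,
    alpha = 0.01, direction = "forward"
  )
}

#' Validate and normalize a screen configuration
#'
#' Fills defaults (minimum 25 reads per region, alpha 0.01, up to 4
#' protospacer mismatches, homopolymer run 5, 5% background) and checks
#' every threshold against its documented range. Accepts a named list or a
#' YAML/JSON file path.
#'
#' @param config named list, path to a YAML/JSON file, or `NULL` for all
#'   defaults.
#' @return normalized config list (class `captor_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  defaults <- .screen_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)

  chk <- function(cond, msg) if (!cond) stop("config error: ", msg)
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must lie in (0, 1]")
  chk(cfg$max_mm >= 0 && cfg$max_mm <= 20, "max_mm must lie in 0-20")
  chk(cfg$seed_len >= 1 && cfg$seed_len <= 20, "seed_len must lie in 1-20")
  chk(cfg$min_reads >= 1, "min_reads must be positive")
  chk(cfg$homopolymer_len >= 2, "homopolymer_len must be >= 2")
  chk(cfg$background_pct >= 0 && cfg$background_pct <= 100,
      "background_pct must lie in 0-100")
  chk(cfg$min_anchor >= 1, "min_anchor must be positive")
  chk(cfg$min_span >= 1, "min_span must be positive")
  chk(cfg$min_len >= 1, "min_len must be positive")
  chk(cfg$direction %in% c("forward", "reverse"),
      "direction must be 'forward' or 'reverse'")
  for (f in c("gc_content", "clonal_rate", "subst_error_rate", "deletion_prob")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must lie in [0, 1]"))
  }
  structure(cfg, class = c("captor_config", "list"))
}

#' Run the capture indel pipeline on one sample
#'
#' Chains quality filtering, region assignment, clonal deduplication, pair
#' merging, read classification and per-region summarization.
#'
#' @param pairs read-pair data.frame (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param regions data.frame from [make_capture_regions()].
#' @param cfg a [validate_config()] result (or NULL for defaults).
#' @param untreated optional untreated-sample summary for background
#'   flagging.
#' @param index optional prebuilt [build_region_index()].
#' @return list: `summary`, `classified`, `assigned`, `n_discarded_pairs`,
#'   `n_clonal_removed`, `coverage`.
#' @export
run_capture_pipeline <- function(pairs, regions, cfg = NULL, untreated = NULL,
                                 index = NULL) {
  cfg <- if (inherits(cfg, "captor_config")) cfg else validate_config(cfg)
  pre <- preprocess_reads(pairs, min_len = cfg$min_len,
                          qual_threshold = cfg$qual_threshold)
  asn <- assign_to_regions(pre$pairs,
                           if (is.null(index)) regions else index)
  kept <- asn[!is.na(asn$region_id), , drop = FALSE]
  ded <- remove_clonal(kept)
  merged <- merge_pair_table(ded$pairs, min_overlap = cfg$min_overlap)
  classified <- classify_reads(merged, regions,
                               min_anchor = cfg$min_anchor,
                               min_span = cfg$min_span)
  summary <- summarize_regions(classified, regions, untreated = untreated,
                               min_reads = cfg$min_reads,
                               homopolymer_len = cfg$homopolymer_len,
                               background_pct = cfg$background_pct)
  list(summary = summary, classified = classified, assigned = asn,
       n_discarded_pairs = pre$n_discarded_pairs,
       n_clonal_removed = ded$n_removed,
       coverage = coverage_stats(kept, regions))
}

## Default synthetic screen targets: the two guide RNAs with their genomic
## PAMs.
.screen_targets <- function() {
  data.frame(
    name = c("S1", "S2"),
    protospacer = c("GCTCCCTACGCATGCGTCCC", "AATGGCTCAGGTTTGTCGCG"),
    pam = c("AGG", "CGG"),
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic off-target screen
#'
#' End-to-end exercise of the whole package with known ground truth: builds
#' a random genome; plants the two target sites plus mismatched off-target
#' sites (one of which is nuclease-active); scans the genome for predicted
#' off-target sites; builds 200-bp capture regions with tiled baits around
#' every predicted site plus random controls; simulates treated and
#' untreated capture libraries (the active sites carry indels at their
#' configured frequencies, with the cut 3 bp upstream of the PAM); runs the
#' capture indel pipeline on both samples; and calls per-region significance
#' with Fisher's exact test.
#'
#' @param config see [validate_config()].
#' @return report bundle: list with `config`, `truth`, `scan_hits`,
#'   `regions`, `baits`, `treated`, `control`, `significance`, `profiles`,
#'   `coverage`, `provenance`.
#' @export
run_screen <- function(config = NULL) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  targets_df <- .screen_targets()
  scfg <- sim_config(
    genome_length = cfg$genome_length, gc_content = cfg$gc_content,
    seed = cfg$seed, read_length = cfg$read_length,
    fragment_length_mean = cfg$fragment_length_mean,
    fragment_length_sd = cfg$fragment_length_sd,
    depth_per_region = cfg$depth_per_region, clonal_rate = cfg$clonal_rate,
    subst_error_rate = cfg$subst_error_rate,
    indel_size_range = cfg$indel_size_range,
    deletion_prob = cfg$deletion_prob
  )

  ## --- genome with planted sites -------------------------------------
  genome0 <- make_genome(scfg)
  n_sites <- nrow(targets_df) * (1L + cfg$n_offtargets_per_target)
  spacing <- (cfg$genome_length - 2000L) %/% n_sites
  if (spacing < 1200L) stop("genome_length too small for the screen design")
  slots <- 1000L + spacing * (seq_len(n_sites) - 1L)
  ## nudge each planting slot so its 200-bp capture window is free of
  ## homopolymer runs -- targets are picked the way a capture design would
  ## pick them, since homopolymer regions are excluded from analysis anyway
  gstr <- as.character(genome0[[1]])
  hp_pat <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                    cfg$homopolymer_len, cfg$homopolymer_len,
                    cfg$homopolymer_len, cfg$homopolymer_len)
  for (j in seq_along(slots)) {
    tries <- 0L
    while (tries < 15L &&
           grepl(hp_pat, substr(gstr, slots[j] - 95L, slots[j] + 115L))) {
      slots[j] <- slots[j] + 37L
      tries <- tries + 1L
    }
  }
  plants <- list(); si <- 0L
  for (ti in seq_len(nrow(targets_df))) {
    tg <- targets_df[ti, ]
    si <- si + 1L
    plants[[si]] <- data.frame(
      name = tg$name, protospacer = tg$protospacer, pam = tg$pam,
      chrom = "chrS", window_start = slots[si], strand = "+",
      mismatch_positions = "", stringsAsFactors = FALSE
    )
    for (oi in seq_len(cfg$n_offtargets_per_target)) {
      si <- si + 1L
      mmp <- paste(sample(1:20, cfg$offtarget_mismatches), collapse = ",")
      plants[[si]] <- data.frame(
        name = sprintf("%s_OT%d", tg$name, oi),
        protospacer = tg$protospacer, pam = tg$pam,
        chrom = "chrS", window_start = slots[si],
        strand = if (oi %% 2L == 0L) "-" else "+",
        mismatch_positions = mmp, stringsAsFactors = FALSE
      )
    }
  }
  planted <- plant_sites(genome0, do.call(rbind, plants))
  genome <- planted$genome
  truth_sites <- planted$truth

  ## --- predicted off-target scan -------------------------------------
  scan_hits <- list()
  for (ti in seq_len(nrow(targets_df))) {
    tg <- target_site(targets_df$name[ti], targets_df$protospacer[ti],
                      cfg$pam)
    h <- scan_genome(genome, tg, max_mismatches = cfg$max_mm,
                     pam_patterns = cfg$pam)
    if (length(h)) h$target <- targets_df$name[ti]
    scan_hits[[ti]] <- h
  }
  hits <- suppressWarnings(do.call(c, scan_hits))

  ## --- capture regions & baits ---------------------------------------
  site_names <- truth_sites$name[match(
    paste(GenomicRanges::start(hits) - 1L, as.character(GenomicRanges::strand(hits))),
    paste(truth_sites$start, truth_sites$strand)
  )]
  site_names[is.na(site_names)] <- sprintf("novel%03d", which(is.na(site_names)))
  sites_gr <- GenomicRanges::granges(hits)
  sites_gr$name <- site_names
  categories <- paste0("predicted_", hits$target)
  regions <- make_capture_regions(sites_gr, genome, categories)

  controls <- pick_random_controls(
    genome, cfg$n_random_controls,
    exclusions = GenomicRanges::resize(sites_gr, 600L, fix = "center")
  )
  regions <- rbind(
    regions,
    make_capture_regions(controls, genome, "random_control")
  )
  ## one capture region per distinct site: a site predicted for both guides
  ## keeps its first row
  regions <- regions[!duplicated(regions$region_id), , drop = FALSE]
  baits <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    b <- tile_baits(regions$seq[i])
    b$region_id <- regions$region_id[i]
    b
  }))

  ## --- ground-truth indel frequencies & cut positions ----------------
  strand_of <- truth_sites$strand[match(regions$region_id, truth_sites$name)]
  freq <- rep(0, nrow(regions))
  for (nm in names(cfg$target_indel_freqs)) {
    freq[regions$region_id == nm] <- cfg$target_indel_freqs[[nm]]
  }
  active_ot <- "S2_OT1"
  freq[regions$region_id == active_ot] <- cfg$offtarget_indel_freq_active
  cut_off <- ifelse(is.na(strand_of), 0L,
                    ifelse(strand_of == "+", 7L, -7L))
  truth <- data.frame(
    region_id = regions$region_id,
    true_indel_freq = freq,
    cut_offset = cut_off,
    pam_strand = ifelse(is.na(strand_of), "+", strand_of),
    stringsAsFactors = FALSE
  )

  ## --- simulate treated & untreated libraries ------------------------
  treated_reads <- simulate_capture_reads(genome, regions, truth, scfg,
                                          seed = NA)
  truth0 <- truth; truth0$true_indel_freq <- 0
  control_reads <- simulate_capture_reads(genome, regions, truth0, scfg,
                                          seed = NA)

  ## --- capture indel pipeline ----------------------------------------
  index <- build_region_index(regions)
  control_run <- run_capture_pipeline(control_reads, regions, cfg,
                                      index = index)
  treated_run <- run_capture_pipeline(treated_reads, regions, cfg,
                                      untreated = control_run$summary,
                                      index = index)
  sig <- fisher_significance(treated_run$summary, control_run$summary,
                             alpha = cfg$alpha, direction = cfg$direction)
  profiles <- indel_profiles(treated_run$classified)

  ## capture efficiency: compare baited regions against non-baited random
  ## genomic windows, which receive no library fragments
  uncaptured <- pick_random_controls(
    genome, cfg$n_random_controls,
    exclusions = c(GenomicRanges::resize(sites_gr, 600L, fix = "center"),
                   GenomicRanges::granges(controls))
  )
  uncaptured$name <- sprintf("uncaptured%04d", seq_along(uncaptured))
  cov_regions <- rbind(regions,
                       make_capture_regions(uncaptured, genome,
                                            "uncaptured_random"))
  cov_assigned <- assign_to_regions(treated_reads,
                                    build_region_index(cov_regions))
  coverage <- coverage_stats(cov_assigned[!is.na(cov_assigned$region_id), ],
                             cov_regions,
                             random_category = "uncaptured_random")

  list(
    config = cfg,
    targets = targets_df,
    truth_sites = truth_sites,
    scan_hits = as.data.frame(hits),
    regions = regions[, c("region_id", "chrom", "start", "end", "category")],
    baits = baits,
    truth = truth,
    treated = treated_run,
    control = control_run,
    significance = sig,
    profiles = profiles,
    coverage = coverage,
    provenance = list(
      package = as.character(utils::packageVersion("captor")),
      seed = cfg$seed,
      config_hash = rlang::hash(unclass(cfg))
    )
  )
}

#' Write a screen report bundle to disk
#'
#' Emits TSV tables (regions, baits, summaries, significance, histograms)
#' and a JSON report with headline numbers and provenance. Output is
#' deterministic for a fixed config (no timestamps in the report body).
#'
#' @param bundle result of [run_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(bundle$regions, "regions")
  wt(bundle$baits, "baits")
  wt(bundle$treated$summary, "treated_summary")
  wt(bundle$control$summary, "control_summary")
  wt(bundle$significance, "significance")
  wt(bundle$profiles$size, "indel_sizes")
  wt(bundle$profiles$position, "indel_positions")

  sig <- bundle$significance
  report <- list(
    n_regions = nrow(bundle$regions),
    n_tested = sum(!sig$excluded),
    n_significant = sum(sig$significant),
    significant_regions = sig$region_id[sig$significant],
    mean_targeted_coverage = bundle$coverage$mean_targeted,
    fold_enrichment_floored = bundle$coverage$fold_enrichment_floored,
    provenance = bundle$provenance
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
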