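test_that("random genome respects composition and is reproducible", {
  cfg0 <- sim_config(genome_length = 5000, gc_content = 0, seed = 11)
  g0 <- as.character(make_genome(cfg0)[[1]])
  expect_false(grepl("[GC]", g0))

  cfg <- sim_config(genome_length = 1e6, gc_content = 0.42, seed = 12)
  g <- as.character(make_genome(cfg)[[1]])
  gc_obs <- nchar(gsub("[AT]", "", g)) / nchar(g)
  expect_lt(abs(gc_obs - 0.42), 0.005)

  g2 <- as.character(make_genome(cfg)[[1]])
  expect_identical(g, g2)

  expect_error(sim_config(gc_content = 1.2), "fraction")
  expect_error(sim_config(read_length = 20), "read_length")
})

test_that("planted sites round-trip through the scanner", {
  s1 <- target_site("S1", "GCTCCCTACGCATGCGTCCC")
  s2 <- target_site("S2", "AATGGCTCAGGTTTGTCGCG")
  cfg <- sim_config(genome_length = 30000, seed = 21)
  gn <- make_genome(cfg)
  plants <- data.frame(
    name = c("S1_exact", "S2_mm3", "S1_minus"),
    protospacer = c(s1$protospacer, s2$protospacer, s1$protospacer),
    pam = c("AGG", "CGG", "AGG"),
    chrom = "chrS",
    window_start = c(5000L, 12000L, 20000L),
    strand = c("+", "+", "-"),
    mismatch_positions = c("", "3,9,17", ""),
    stringsAsFactors = FALSE
  )
  pl <- plant_sites(gn, plants)

  h1 <- scan_genome(pl$genome, s1, max_mismatches = 0)
  expect_equal(length(h1), 2L)           # exact plus + exact minus plant
  expect_equal(GenomicRanges::start(h1) - 1L,
               sort(pl$truth$start[pl$truth$name %in% c("S1_exact", "S1_minus")]))
  expect_setequal(as.character(GenomicRanges::strand(h1)), c("+", "-"))
  expect_true(all(h1$mismatch_count == 0L))
  ## minus-strand hit reports the protospacer-oriented (reverse-complemented)
  ## context
  minus <- h1[as.character(GenomicRanges::strand(h1)) == "-"]
  expect_equal(minus$matched_seq, s1$protospacer)
  expect_equal(minus$pam, "AGG")

  h2 <- scan_genome(pl$genome, s2, max_mismatches = 4)
  planted2 <- h2[GenomicRanges::start(h2) - 1L ==
                   pl$truth$start[pl$truth$name == "S2_mm3"]]
  expect_equal(length(planted2), 1L)
  expect_equal(planted2$mismatch_count, 3L)
  expect_equal(planted2$mismatch_positions, "3,9,17")
  ## no hit below the planted mismatch count
  expect_length(scan_genome(pl$genome, s2, max_mismatches = 2), 0L)

  expect_error(
    plant_sites(gn, transform(plants[1, ], mismatch_positions = "0,5")),
    "1-20"
  )
  expect_error(
    plant_sites(gn, transform(rbind(plants[1, ], plants[1, ]),
                              window_start = c(5000L, 5010L))),
    "overlap"
  )
})

test_that("null capture simulation classifies as pure WT", {
  cfg <- sim_config(genome_length = 20000, seed = 31, depth_per_region = 60,
                    subst_error_rate = 0, clonal_rate = 0)
  gn <- make_genome(cfg)
  sites <- data.frame(chrom = "chrS", start = c(4000, 9000),
                      end = c(4020, 9020), name = c("rA", "rB"))
  regs <- make_capture_regions(sites, gn, "chip_S1")
  truth <- data.frame(region_id = regs$region_id, true_indel_freq = 0)
  reads <- simulate_capture_reads(gn, regs, truth, cfg)
  res <- run_capture_pipeline(reads, regs, NULL)
  expect_equal(sum(res$summary$n_snp), 0L)
  expect_equal(sum(res$summary$n_ins), 0L)
  expect_equal(sum(res$summary$n_del), 0L)
  expect_true(all(res$summary$indel_pct == 0))
  expect_gt(sum(res$summary$n_wt), 0L)
})

test_that("simulated indel frequency is recovered within binomial error", {
  cfg <- sim_config(genome_length = 20000, seed = 32, depth_per_region = 500,
                    subst_error_rate = 0, clonal_rate = 0)
  gn <- make_genome(cfg)
  sites <- data.frame(chrom = "chrS", start = 6000, end = 6020, name = "r1")
  regs <- make_capture_regions(sites, gn, "chip_S1")
  truth <- data.frame(region_id = "r1", true_indel_freq = 0.15)
  reads <- simulate_capture_reads(gn, regs, truth, cfg)
  res <- run_capture_pipeline(reads, regs, NULL)
  est <- res$summary$indel_pct / 100
  expect_lt(abs(est - 0.15), 3 * sqrt(0.15 * 0.85 / 500))
})

test_that("clonal duplicates collapse to distinct fragment keys", {
  cfg <- sim_config(genome_length = 20000, seed = 33, depth_per_region = 200,
                    clonal_rate = 0.5, subst_error_rate = 0)
  gn <- make_genome(cfg)
  sites <- data.frame(chrom = "chrS", start = 5000, end = 5020, name = "r1")
  regs <- make_capture_regions(sites, gn, "chip_S1")
  truth <- data.frame(region_id = "r1", true_indel_freq = 0)
  reads <- simulate_capture_reads(gn, regs, truth, cfg)
  expect_gt(sum(reads$is_duplicate), 0L)
  ded <- remove_clonal(reads[, setdiff(names(reads),
                                       c("map_start1", "map_start2",
                                         "map_orientation"))])
  key <- paste(reads$region_id, reads$start1, reads$start2, reads$orientation)
  expect_identical(nrow(ded$pairs), length(unique(key)))
})

test_that("identical config yields byte-identical FASTQ", {
  cfg <- sim_config(genome_length = 10000, seed = 34, depth_per_region = 40,
                    clonal_rate = 0.3, subst_error_rate = 0.01)
  gn <- make_genome(cfg)
  sites <- data.frame(chrom = "chrS", start = 5000, end = 5020, name = "r1")
  regs <- make_capture_regions(sites, gn, "chip_S1")
  truth <- data.frame(region_id = "r1", true_indel_freq = 0.2)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_capture_reads(gn, regs, truth, cfg, fastq_prefix = d1)
  simulate_capture_reads(gn, regs, truth, cfg, fastq_prefix = d2)
  for (m in c("_R1.fastq", "_R2.fastq")) {
    expect_identical(readLines(paste0(d1, m)), readLines(paste0(d2, m)))
  }
  ## region outside the genome is refused
  bad <- transform(regs, start = 9950, end = 10150)
  expect_error(simulate_capture_reads(gn, bad, truth, cfg), "outside")
})

test_that("simulated peak sets have the requested overlap structure", {
  ps0 <- simulate_peak_sets(50000, n_shared = 0, n_a_specific = 5,
                            n_b_specific = 5, seed = 41)
  expect_length(intersect_replicates(ps0$set_a, ps0$set_b), 0L)

  ps <- simulate_peak_sets(200000, n_shared = 150, n_a_specific = 20,
                           n_b_specific = 30, seed = 42)
  sp <- split_grna_specific(ps$set_a, ps$set_b)
  expect_length(sp$common, 150L)
  expect_length(sp$a_specific, 20L)
  expect_length(sp$b_specific, 30L)

  ## identical sets: intersection is the set itself
  expect_length(intersect_replicates(ps$set_a, ps$set_a), length(ps$set_a))
})
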