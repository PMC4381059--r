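set.seed(401)
REF <- rand_dna(200, gc = 0.45)

mk_pairs <- function(seq1, seq2, qual1 = strrep("I", nchar(seq1)),
                     qual2 = strrep("I", nchar(seq2))) {
  data.frame(id = sprintf("p%02d", seq_along(seq1)),
             seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
             stringsAsFactors = FALSE)
}

test_that("read preprocessing trims and applies the 35-bp pair rule", {
  clean <- mk_pairs(substr(REF, 1, 100), revcomp(substr(REF, 51, 150)))
  out <- preprocess_reads(clean)
  expect_identical(out$pairs$seq1, clean$seq1)
  expect_equal(out$n_discarded_pairs, 0L)

  ## 10 trailing low-quality bases are trimmed
  lowq <- mk_pairs(substr(REF, 1, 100), substr(REF, 1, 100),
                   qual1 = paste0(strrep("I", 90), strrep("#", 10)))
  out2 <- preprocess_reads(lowq)
  expect_equal(nchar(out2$pairs$seq1), 90L)
  expect_equal(nchar(out2$pairs$qual1), 90L)

  ## a mate shrinking below 35 bp discards the whole pair
  short <- mk_pairs(substr(REF, 1, 40), substr(REF, 1, 100),
                    qual1 = paste0(strrep("I", 34), strrep("#", 6)))
  out3 <- preprocess_reads(short)
  expect_equal(nrow(out3$pairs), 0L)
  expect_equal(out3$n_discarded_pairs, 1L)

  ## leading/trailing N bases are stripped
  enn <- mk_pairs(paste0("NN", substr(REF, 1, 60), "N"), substr(REF, 1, 60))
  out4 <- preprocess_reads(enn)
  expect_equal(out4$pairs$seq1, substr(REF, 1, 60))

  ## adapter read-through is removed
  ad <- "AGATCGGAAGAGC"
  adp <- mk_pairs(paste0(substr(REF, 1, 60), ad), substr(REF, 1, 60),
                  qual1 = strrep("I", 60 + nchar(ad)))
  out5 <- preprocess_reads(adp, adapter = ad)
  expect_equal(out5$pairs$seq1, substr(REF, 1, 60))

  bad <- mk_pairs("ACGT", "ACGT", qual1 = "II")
  expect_error(preprocess_reads(bad), "malformed")
})

test_that("clonal removal keeps one pair per key and is idempotent", {
  p <- data.frame(
    id = sprintf("p%d", 1:7),
    start1 = c(10, 10, 10, 10, 10, 11, 12),
    start2 = c(60, 60, 60, 60, 60, 61, 62),
    orientation = "FR",
    stringsAsFactors = FALSE
  )
  d1 <- remove_clonal(p)
  expect_equal(nrow(d1$pairs), 3L)       # 5 clones collapse to the first
  expect_equal(d1$pairs$id[1], "p1")     # first occurrence retained
  expect_equal(d1$n_removed, 4L)
  d2 <- remove_clonal(d1$pairs)
  expect_identical(d2$pairs, d1$pairs)   # idempotent
  expect_equal(d2$n_removed, 0L)

  ## staggered starts are all retained
  stag <- transform(p, start1 = 1:7, start2 = 51:57)
  expect_equal(nrow(remove_clonal(stag)$pairs), 7L)

  ## unmapped pairs pass through even when duplicated
  um <- data.frame(id = c("u1", "u2"), start1 = NA, start2 = NA,
                   orientation = NA)
  expect_equal(nrow(remove_clonal(um)$pairs), 2L)
})

test_that("SAM coordinates feed the clonal key", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t99\tchr1\t101\t60\t100M\t=\t201\t200\tACGT\tIIII",
    "r1\t147\tchr1\t201\t60\t100M\t=\t101\t-200\tACGT\tIIII",
    "r2\t99\tchr1\t101\t60\t100M\t=\t201\t200\tACGT\tIIII",
    "r2\t147\tchr1\t201\t60\t100M\t=\t101\t-200\tACGT\tIIII",
    "r3\t83\tchr1\t301\t60\t100M\t=\t151\t-250\tACGT\tIIII",
    "r3\t163\tchr1\t151\t60\t100M\t=\t301\t250\tACGT\tIIII"
  )
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  co <- read_sam_coords(f)
  expect_equal(nrow(co), 3L)
  expect_equal(co$start1[co$id == "r1"], 100L)   # 0-based
  expect_equal(co$orientation[co$id == "r3"], "RF")
  ded <- remove_clonal(co)
  expect_equal(nrow(ded$pairs), 2L)              # r1/r2 share a key
})

test_that("pairs are assigned to a strictly unique best region", {
  set.seed(402)
  regions <- data.frame(
    region_id = c("rA", "rB", "rBcopy"),
    chrom = "chr1", start = c(0, 300, 600), end = c(200, 500, 800),
    category = "chip_S1",
    seq = c(rand_dna(200), NA, NA), stringsAsFactors = FALSE
  )
  regions$seq[2] <- rand_dna(200)
  regions$seq[3] <- regions$seq[2]       # duplicated reference

  pa <- mk_pairs(substr(regions$seq[1], 26, 125),
                 revcomp(substr(regions$seq[1], 76, 175)))
  asA <- assign_to_regions(pa, regions)
  expect_equal(asA$region_id, "rA")
  expect_equal(asA$map_start1, 0 + 25)
  expect_equal(asA$map_orientation, "FR")

  ## a read matching two identical regions equally stays unassigned
  pb <- mk_pairs(substr(regions$seq[2], 26, 125),
                 revcomp(substr(regions$seq[2], 76, 175)))
  asB <- assign_to_regions(pb, regions)
  expect_true(is.na(asB$region_id))

  ## a read from nowhere stays unassigned
  pn <- mk_pairs(rand_dna(100), rand_dna(100))
  expect_true(is.na(assign_to_regions(pn, regions)$region_id))
})

test_that("simulated pairs are assigned to their true region", {
  cfg <- sim_config(genome_length = 30000, seed = 403, depth_per_region = 100,
                    subst_error_rate = 0.001, clonal_rate = 0)
  gn <- make_genome(cfg)
  sites <- data.frame(chrom = "chrS", start = c(4000, 12000, 22000),
                      end = c(4020, 12020, 22020),
                      name = c("r1", "r2", "r3"))
  regs <- make_capture_regions(sites, gn, "chip_S1")
  truth <- data.frame(region_id = regs$region_id, true_indel_freq = 0)
  reads <- simulate_capture_reads(gn, regs, truth, cfg)
  asn <- assign_to_regions(reads, regs)
  ok <- !is.na(asn$region_id)
  expect_gte(mean(ok), 0.99)
  expect_true(all(asn$region_id[ok] == reads$region_id[ok]))
})

test_that("pair merging reconstructs fragments by exact overlap", {
  frag <- substr(REF, 26, 175)                   # 150-bp fragment
  r1 <- substr(frag, 1, 100)
  r2 <- revcomp(substr(frag, 51, 150))
  m <- merge_pairs(r1, r2)
  expect_true(m$merged)
  expect_equal(nchar(m$seqs), 150L)
  expect_equal(m$seqs, frag)
  expect_equal(m$overlap, 50L)

  ## disjoint fragment halves do not merge
  m2 <- merge_pairs(substr(REF, 1, 60), revcomp(substr(REF, 120, 180)))
  expect_false(m2$merged)
  expect_length(m2$seqs, 2L)

  ## identical reads merge to the read itself (full containment)
  r <- substr(REF, 1, 80)
  m3 <- merge_pairs(r, revcomp(r))
  expect_true(m3$merged)
  expect_equal(m3$seqs, r)

  ## overlap below the minimum is rejected
  a <- paste0(rand_dna(60, gc = 0.2), "ACGT")
  b <- paste0("ACGT", rand_dna(60, gc = 0.8))
  expect_false(merge_pairs(a, revcomp(b), min_overlap = 5)$merged)
})

test_that("anchor classification recovers WT, SNP and indel reads", {
  wt <- substr(REF, 26, 175)
  expect_equal(classify_read(wt, REF)$class, "WT")
  ## reverse-orientation WT
  expect_equal(classify_read(revcomp(wt), REF)$class, "WT")

  snp <- wt
  substr(snp, 75, 75) <- chartr("ACGT", "CGTA", substr(snp, 75, 75))
  r <- classify_read(snp, REF)
  expect_equal(r$class, "SNP")
  expect_equal(r$net_indel_size, 0L)
  expect_equal(r$n_mismatches, 1L)

  ## 2-bp deletion at reference position 100 (read center)
  del <- paste0(substr(REF, 26, 100), substr(REF, 103, 177))
  rd <- classify_read(del, REF)
  expect_equal(rd$class, "deletion")
  expect_equal(rd$net_indel_size, -2L)
  expect_lt(abs(rd$indel_center_offset), 4)

  ## 1-bp insertion
  ins <- paste0(substr(REF, 26, 100), "X", substr(REF, 101, 174))
  ins <- gsub("X", "T", ins)
  ri <- classify_read(ins, REF)
  ## the inserted base can coincide with the next reference base; accept
  ## insertion with net +1 whenever lengths force it
  expect_equal(ri$class, "insertion")
  expect_equal(ri$net_indel_size, 1L)

  ## too-short anchor and too-short span are discarded
  expect_equal(classify_read(rand_dna(60), REF)$class, "discarded")
  expect_equal(classify_read(substr(REF, 50, 120), REF)$class, "discarded")
})

test_that("region summaries count, flag and compute indel percentages", {
  regions <- data.frame(region_id = c("r1", "r2", "r3"),
                        category = "chip_S1",
                        seq = c(rand_dna(200), rand_dna(200),
                                paste0(substr(REF, 1, 100), "AAAAA",
                                       substr(REF, 106, 200))),
                        stringsAsFactors = FALSE)
  cls <- data.frame(
    region_id = c(rep("r1", 100), rep("r2", 24), rep("r3", 30)),
    class = c(rep("WT", 80), rep("SNP", 5), rep("deletion", 10),
              rep("insertion", 5),
              rep("WT", 24), rep("WT", 30)),
    stringsAsFactors = FALSE
  )
  s <- summarize_regions(cls, regions)
  expect_equal(s$indel_pct[s$region_id == "r1"], 15)
  expect_equal(s$n_total, s$n_wt + s$n_snp + s$n_ins + s$n_del)
  expect_true(s$flag_low_coverage[s$region_id == "r2"])   # 24 < 25 reads
  expect_true(s$flag_homopolymer[s$region_id == "r3"])
  expect_false(s$excluded[s$region_id == "r1"])

  ## homopolymer length 6 variant does not flag a 5-run
  s6 <- summarize_regions(cls, regions, homopolymer_len = 6L)
  expect_false(s6$flag_homopolymer[s6$region_id == "r3"])

  ## high background flag from the untreated sample
  unt <- data.frame(region_id = c("r1", "r2", "r3"),
                    indel_pct = c(8, 0, 0))
  sb <- summarize_regions(cls, regions, untreated = unt)
  expect_true(sb$flag_high_background[sb$region_id == "r1"])
  expect_true(sb$excluded[sb$region_id == "r1"])
})

test_that("Fisher significance equals the hypergeometric tail oracle", {
  mk_sum <- function(ids, wt, snp, ins, del, excluded = FALSE) {
    data.frame(region_id = ids, n_total = wt + snp + ins + del,
               n_wt = wt, n_snp = snp, n_ins = ins, n_del = del,
               indel_pct = 100 * (ins + del) / (wt + snp + ins + del),
               excluded = excluded, stringsAsFactors = FALSE)
  }
  tr <- mk_sum("rX", wt = 160, snp = 10, ins = 10, del = 20)
  ct <- mk_sum("rX", wt = 190, snp = 8, ins = 1, del = 1)
  fs <- fisher_significance(tr, ct)
  expect_equal(fs$fisher_p, oracle_fisher_tail(30, 170, 2, 198),
               tolerance = 1e-12)
  expect_true(fs$significant)

  ## random tables agree with the oracle
  set.seed(404)
  for (i in 1:20) {
    a <- sample(0:30, 1); b <- sample(50:200, 1)
    c_ <- sample(0:10, 1); d <- sample(50:200, 1)
    tr_i <- mk_sum("r", wt = b, snp = 0, ins = a, del = 0)
    ct_i <- mk_sum("r", wt = d, snp = 0, ins = c_, del = 0)
    expect_equal(fisher_significance(tr_i, ct_i)$fisher_p,
                 oracle_fisher_tail(a, b, c_, d), tolerance = 1e-9)
  }

  ## identical tables are never significant one-sided
  same <- mk_sum("rY", wt = 180, snp = 0, ins = 10, del = 10)
  fs2 <- fisher_significance(same, same)
  expect_gte(fs2$fisher_p, 0.5)
  expect_false(fs2$significant)

  ## excluded regions are never significant even with strong enrichment
  trx <- mk_sum("rZ", wt = 100, snp = 0, ins = 50, del = 50, excluded = TRUE)
  ctx <- mk_sum("rZ", wt = 200, snp = 0, ins = 0, del = 0)
  expect_false(fisher_significance(trx, ctx)$significant)

  ## reverse direction swaps the comparison
  fr <- fisher_significance(ct, tr, direction = "reverse")
  expect_equal(fr$fisher_p, oracle_fisher_tail(30, 170, 2, 198),
               tolerance = 1e-12)
})

test_that("indel profiles keep sign conventions and offsets", {
  cls <- data.frame(
    region_id = "r1",
    class = c(rep("deletion", 6), rep("insertion", 2), "WT"),
    net_indel_size = c(rep(-1L, 6), 1L, 2L, 0L),
    indel_center_offset = c(rep(1, 6), -2, 0, 0),
    stringsAsFactors = FALSE
  )
  pr <- indel_profiles(cls)
  expect_equal(pr$size$n[pr$size$size == -1], 6L)
  expect_true(all(pr$size$size %in% c(-5:-1, 1:5)))
  expect_equal(sum(pr$size$n), 8L)
  expect_equal(sum(pr$position$n), 8L)

  only_del <- cls[cls$class == "deletion", ]
  pr2 <- indel_profiles(only_del)
  expect_equal(nrow(pr2$size), 1L)
  expect_equal(pr2$size$size, -1L)
})

test_that("coverage statistics report enrichment over random regions", {
  regions <- data.frame(region_id = c("t1", "t2", "rc1", "rc2"),
                        category = c("chip_S1", "chip_S1",
                                     "random_control", "random_control"),
                        seq = NA, stringsAsFactors = FALSE)
  asn <- data.frame(region_id = c(rep("t1", 150), rep("t2", 150)))
  cv <- coverage_stats(asn, regions)
  expect_equal(cv$mean_targeted, 150)
  expect_equal(cv$mean_random, 0)
  expect_identical(cv$fold_enrichment, Inf)
  expect_equal(cv$fold_enrichment_floored, 150)

  asn2 <- data.frame(region_id = rep(c("t1", "t2", "rc1", "rc2"), each = 10))
  cv2 <- coverage_stats(asn2, regions)
  expect_equal(cv2$fold_enrichment, 1)
})
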