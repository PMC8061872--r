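test_that("window calls apply the inclusive 1.5-fold rule", {
  w <- toy_windows(4)
  young <- toy_enrichment(c(3.0, 2.0, 2.0, 1.0), w)
  old <- toy_enrichment(c(2.0, 2.0, 3.0, 1.0), w)
  calls <- call_windows(young, old, fold = 1.5)
  # young/old = 1.5 exactly -> loss (threshold inclusive); old/young 1.5 -> gain
  expect_equal(calls$call, c("loss", "none", "gain", "none"))
  expect_equal(calls$fold_change, c(2 / 3, 1, 1.5, 1))

  # null: identical tracks give no calls
  null_calls <- call_windows(young, young)
  expect_true(all(null_calls$call == "none"))

  # undefined windows are 'none' with NA fold change
  y2 <- toy_enrichment(c(3, NA, 2, 1), w)
  c2 <- call_windows(y2, old)
  expect_equal(c2$call[2], "none")
  expect_true(is.na(c2$fold_change[2]))

  expect_error(call_windows(young, toy_enrichment(rep(1, 3))), "misaligned")
})

test_that("gain/loss calls are symmetric under age-label swap on null data", {
  cfg <- sim_config(seed = 41, genome_scale = 1 / 100,
                    aging_loss = c(male = 0, female = 0))
  chip <- simulate_chip(cfg)
  tracks <- normalize_samples(chip, chip$layout, "no_spike")
  meta <- sapply(chip$samples, function(s) paste(s$meta$sex, s$meta$age))
  ym <- mean_track(tracks[meta == "male young"])
  om <- mean_track(tracks[meta == "male old"])
  fwd <- call_windows(ym, om)
  rev <- call_windows(om, ym)
  expect_equal(sum(fwd$call == "loss"), sum(rev$call == "gain"))
  expect_equal(sum(fwd$call == "gain"), sum(rev$call == "loss"))
  # and with no planted effect both classes are rare
  expect_lt(sum(fwd$call != "none") / nrow(fwd), 0.05)
})

test_that("Fisher sex comparison matches exact enumeration", {
  expect_equal(fisher_sex_compare(5, 10, 5, 10), 1)
  # hand-enumerated table (8,2;1,9)
  expect_equal(fisher_sex_compare(8, 10, 1, 10),
               fisher_enum_oracle(8, 2, 1, 9), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:50) {
    r1 <- sample(0:20, 1); r2 <- sample(0:20, 1)
    a <- if (r1 > 0) sample(0:r1, 1) else 0
    c_ <- if (r2 > 0) sample(0:r2, 1) else 0
    got <- fisher_sex_compare(a, r1, c_, r2)
    expect_equal(got, fisher_enum_oracle(a, r1 - a, c_, r2 - c_), tolerance = 1e-9,
                 label = sprintf("table (%d/%d, %d/%d)", a, r1, c_, r2))
  }
  expect_error(fisher_sex_compare(5, 3, 1, 10), "inconsistent")
})

test_that("compartment breakdown reports percentages summing to 100", {
  w <- toy_windows(10)
  w$compartment <- c(rep("pericentromere", 6), rep("euchromatin", 4))
  young <- toy_enrichment(rep(3, 10), w)
  old <- toy_enrichment(c(rep(1, 6), rep(3, 4)), w)
  calls <- call_windows(young, old)
  b <- compartment_breakdown(calls, "loss")
  expect_equal(sum(b$percent), 100)
  expect_equal(b$n[b$compartment == "pericentromere"], 6)
  empty <- compartment_breakdown(call_windows(young, young), "loss")
  expect_equal(nrow(empty), 0)
})

test_that("subtraction track aggregates fine windows into coarse means", {
  layout <- one_chrom_layout(50000)
  w <- partition_windows(layout, 5000)
  w$compartment <- "euchromatin"; w$repeat_fraction <- 0.1
  y <- enrichment_track(w, 1:10, method = "no_spike")
  o <- enrichment_track(w, rep(1, 10), method = "no_spike")
  sub <- subtraction_track(y, o, agg_window = 25000)
  # mean of members oracle: windows 1-5 and 6-10
  expect_equal(sub$young, c(mean(1:5), mean(6:10)))
  expect_equal(sub$difference, c(mean(1:5) - 1, mean(6:10) - 1))
  ident <- subtraction_track(y, y, agg_window = 25000)
  expect_equal(ident$difference, c(0, 0))
})

test_that("repeat-binned profiles report means, SEs and missing bins", {
  w <- toy_windows(6)
  w$repeat_fraction <- c(0.05, 0.05, 0.5, 0.5, 0.95, 0.95)
  tr <- enrichment_track(w, rep(2.5, 6), method = "no_spike")
  prof <- repeat_binned_profile(tr, rep("chrA", 6), bin_edges = c(0, 0.3, 0.7, 1))
  filled <- prof[prof$n > 0, ]
  expect_true(all(filled$mean == 2.5))
  expect_true(all(filled$se == 0))
  # empty bins are missing, not zero
  tr2 <- enrichment_track(w, c(1, 1, 2, 2, 8, 8), method = "no_spike")
  prof2 <- repeat_binned_profile(tr2, rep("chrA", 6), bin_edges = c(0, 0.3, 0.7, 0.99, 1))
  expect_true(is.na(prof2$mean[prof2$bin_lo == 0.99]))
  expect_equal(prof2$mean[prof2$bin_lo == 0.7], 8)
  expect_error(repeat_binned_profile(tr, rep("chrA", 6), bin_edges = c(0.1, 1)),
               "partition")
})

test_that("TSS metaprofiles are strand-oriented and bounds-aware", {
  layout <- one_chrom_layout(20000)
  w <- partition_windows(layout, 100)
  w$compartment <- "euchromatin"; w$repeat_fraction <- 0
  flat <- enrichment_track(w, rep(3, nrow(w)), method = "no_spike")
  genes <- gene_annotation(data.frame(
    gene_id = "g1", chrom = "chrA", tss_bp = 10000, strand = "+"), layout)
  prof <- tss_metaprofile(flat, genes, flank = 5000)
  expect_equal(nrow(prof), 101)
  expect_true(all(prof$mean == 3))

  # planted dip at the TSS, direct-lookup oracle
  sig <- rep(4, nrow(w))
  tss_bin <- 10000 %/% 100 + 1
  sig[tss_bin + (-3:3)] <- 0.5
  dip <- enrichment_track(w, sig, method = "no_spike")
  prof2 <- tss_metaprofile(dip, genes, flank = 5000)
  expect_equal(prof2$mean[prof2$offset == 0], 0.5)
  expect_equal(prof2$mean[abs(prof2$offset) > 400], rep(4, sum(abs(prof2$offset) > 400)))

  # minus-strand gene: mirrored profile
  sig3 <- rep(1, nrow(w)); sig3[tss_bin + 5] <- 9 # 500 bp downstream on + strand
  asym <- enrichment_track(w, sig3, method = "no_spike")
  plus <- tss_metaprofile(asym, genes, flank = 5000)
  minus_genes <- gene_annotation(data.frame(
    gene_id = "g1", chrom = "chrA", tss_bp = 10000, strand = "-"), layout)
  minus <- tss_metaprofile(asym, minus_genes, flank = 5000)
  expect_equal(plus$mean[plus$offset == 500], 9)
  expect_equal(minus$mean[minus$offset == -500], 9)

  # flank beyond chromosome end contributes only in-bounds bins
  edge_genes <- gene_annotation(data.frame(
    gene_id = "g2", chrom = "chrA", tss_bp = 1000, strand = "+"), layout)
  prof3 <- tss_metaprofile(flat, edge_genes, flank = 5000)
  expect_true(all(prof3$n[prof3$offset < -1000] == 0))
  expect_true(all(prof3$n[prof3$offset >= -1000] == 1))
})

test_that("top-quantile overlap behaves at its extremes and at chance", {
  set.seed(7)
  w <- toy_windows(500)
  a <- enrichment_track(w, rlnorm(500), method = "no_spike")
  expect_equal(top_quantile_overlap(a, a), 100)
  b <- a; b$signal <- sample(a$signal)
  ov <- mean(replicate(20, {
    b$signal <- sample(a$signal)
    top_quantile_overlap(a, b, q = 0.2)
  }))
  expect_equal(ov, 20, tolerance = 0.2)
})

test_that("replicate concordance is a unit-diagonal symmetric correlation", {
  set.seed(8)
  w <- toy_windows(100)
  base <- rlnorm(100, 0, 0.5)
  t1 <- enrichment_track(w, base, method = "no_spike")
  t2 <- enrichment_track(w, base, method = "no_spike")
  m <- replicate_concordance(list(t1, t2))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_equal(m[1, 2], 1)
  anti <- enrichment_track(w, max(base) + min(base) - base, method = "no_spike")
  expect_equal(replicate_concordance(list(t1, anti))[1, 2], -1)
  # noisy replicates from the generator correlate strongly
  cfg <- sim_config(seed = 43, genome_scale = 1 / 250)
  chip <- simulate_chip(cfg)
  tracks <- normalize_samples(chip, chip$layout, "no_spike")
  meta <- sapply(chip$samples, function(s) paste(s$meta$sex, s$meta$age))
  ax <- !(chip$windows$chrom %in% c("chrY", "dot"))
  mm <- replicate_concordance(tracks[meta == "male young"], domain = ax)
  expect_true(all(mm[upper.tri(mm)] > 0.75))
})
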