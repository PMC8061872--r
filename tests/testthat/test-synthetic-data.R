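test_that("the generator is a pure function of config and seed", {
  cfg <- sim_config(seed = 13, genome_scale = 1 / 500, n_genes = 100,
                    n_te_families = 30, n_sat_families = 20,
                    lifespan = list(n_male = 80, n_female = 100))
  a <- simulate_chip(cfg)
  b <- simulate_chip(cfg)
  expect_identical(a$samples[[1]]$chip$counts, b$samples[[1]]$chip$counts)
  expect_identical(a$samples[[7]]$spike_input$counts, b$samples[[7]]$spike_input$counts)
  expect_identical(simulate_rnaseq(cfg)$counts, simulate_rnaseq(cfg)$counts)
  expect_identical(simulate_lifespan(cfg)$records, simulate_lifespan(cfg)$records)
  # a different seed changes the draw
  cfg2 <- sim_config(seed = 14, genome_scale = 1 / 500, n_genes = 100,
                     n_te_families = 30, n_sat_families = 20)
  expect_false(identical(simulate_chip(cfg2)$samples[[1]]$chip$counts,
                         a$samples[[1]]$chip$counts))
})

test_that("noise-free mode reproduces the documented mean structure exactly", {
  cfg <- sim_config(seed = 5, genome_scale = 1 / 500, nb_dispersion = 0,
                    aging_loss = c(male = 0, female = 0))
  chip <- simulate_chip(cfg)
  meta <- sapply(chip$samples, function(s) paste(s$meta$sex, s$meta$age))
  young <- chip$samples[[which(meta == "male young")[1]]]
  old <- chip$samples[[which(meta == "male old")[1]]]
  # no aging effect planted: old/young ChIP means identical on every window
  expect_equal(old$chip$counts, young$chip$counts)
  # ChIP mean = Input mean x (1 + gain x repeat fraction), with the neo-Y
  # deficit on repeat-rich arm windows
  w <- chip$windows
  e <- 1 + cfg$heterochromatin_gain * w$repeat_fraction
  ded <- w$compartment == "neoY_arm" & w$repeat_fraction > 0.7
  e[ded] <- e[ded] * (1 - cfg$neoY_deficit)
  expect_equal(young$chip$counts, young$input$counts * e, tolerance = 1e-12)
  # female libraries carry no Y/neo-Y reads
  fem <- chip$samples[[which(meta == "female young")[1]]]
  expect_true(all(fem$input$counts[w$chrom == "chrY"] == 0))
  # spike reads make up spike_fraction of the expected library
  sp_frac <- sum(young$spike_chip$counts) /
    (sum(young$spike_chip$counts) + sum(young$chip$counts))
  expect_equal(sp_frac, cfg$spike_fraction, tolerance = 1e-6)
})

test_that("planted pericentromeric aging loss appears at the configured size", {
  cfg <- sim_config(seed = 17, genome_scale = 1 / 50)
  chip <- simulate_chip(cfg)
  tracks <- normalize_samples(chip, chip$layout, "no_spike")
  meta <- sapply(chip$samples, function(s) paste(s$meta$sex, s$meta$age))
  ym <- mean_track(tracks[meta == "male young"])
  om <- mean_track(tracks[meta == "male old"])
  peri <- chip$windows$compartment == "pericentromere"
  ratio <- mean(om$signal[peri] / ym$signal[peri], na.rm = TRUE)
  expect_equal(ratio, 1 - cfg$aging_loss[["male"]], tolerance = 0.03)
})

test_that("gDNA coverage carries the planted Y-enrichment exactly at zero noise", {
  cfg <- sim_config(seed = 19, gdna_dispersion = 0, n_te_families = 40,
                    n_sat_families = 10)
  g <- simulate_gdna(cfg)
  lr <- log2((g$counts$male / g$depth[["male"]]) /
             (g$counts$female / g$depth[["female"]]))
  expect_equal(unname(lr[g$families$y_enriched]),
               rep(cfg$gdna_log2_bias, sum(g$families$y_enriched)),
               tolerance = 1e-12)
  expect_equal(unname(lr[!g$families$y_enriched]),
               rep(0, sum(!g$families$y_enriched)), tolerance = 1e-12)
  # with no planted Y-enriched families, no family is biased in expectation
  cfg0 <- sim_config(seed = 19, gdna_dispersion = 0, y_enriched_fraction = 0,
                     n_sat_y_enriched = 0, n_te_families = 40, n_sat_families = 10)
  g0 <- simulate_gdna(cfg0)
  expect_true(all(abs(log2((g0$counts$male / g0$depth[["male"]]) /
                           (g0$counts$female / g0$depth[["female"]]))) < 1e-12))
})

test_that("RNA counts carry the planted expression structure", {
  cfg <- sim_config(seed = 23, n_genes = 300, n_te_families = 60,
                    n_sat_families = 40, rna_dispersion = 0)
  rna <- simulate_rnaseq(cfg)
  # identical library scalars in noise-free mode: size factors all 1
  counts <- filter_rrna(rna$counts, rna$features$is_rrna)
  young <- rna$samples$age == "young"
  sf <- size_factors(counts[, young])
  expect_equal(unname(sf), rep(1, sum(young)), tolerance = 1e-6)
  # planted male bias on Y-enriched TEs equals te_male_bias exactly
  feats <- rna$features[!rna$features$is_rrna, ]
  te_y <- feats$type == "TE" & feats$y_enriched
  m <- rna$samples$sex == "male" & young
  f <- rna$samples$sex == "female" & young
  ratio <- rowMeans(counts[te_y, m]) / rowMeans(counts[te_y, f])
  expect_equal(unname(ratio), rep(cfg$te_male_bias, sum(te_y)), tolerance = 1e-9)
  # expected repeat transcript fraction calibrated to the configured targets
  fr <- repeat_transcript_fraction(counts, feats$type,
                                   paste(rna$samples$sex, rna$samples$age, sep = "_"))
  expect_equal(fr$percent[fr$group == "female_young"],
               100 * cfg$female_repeat_fraction, tolerance = 0.05)
  expect_equal(fr$percent[fr$group == "male_young"],
               100 * rna$truth$expected_repeat_fraction[["male"]], tolerance = 0.05)
})

test_that("lifespan records honour the Gompertz medians and the stop rule", {
  cfg <- sim_config(seed = 29)
  life <- simulate_lifespan(cfg)
  rec <- life$records
  expect_identical(rec, simulate_lifespan(cfg)$records)
  expect_equal(nrow(rec), cfg$lifespan$n_male + cfg$lifespan$n_female)
  expect_true(all(rec$time_days > 0))
  # male hazard is higher: males die earlier on average
  expect_lt(mean(rec$time_days[rec$sex == "male" & rec$event == "death"]),
            mean(rec$time_days[rec$sex == "female" & rec$event == "death"]))
  # administrative stop: nothing observed past the stop day, and everything
  # at the stop day that is not a death is censored
  expect_false(is.na(life$stop_day))
  expect_true(all(rec$time_days <= life$stop_day))
  # the stop triggers when the shorter-lived sex (males) crosses 50%
  expect_equal(life$stop_day, 78, tolerance = 3)
  # without the stop rule, both sexes run to completion
  cfg2 <- sim_config(seed = 29, lifespan = list(admin_stop = FALSE))
  life2 <- simulate_lifespan(cfg2)
  expect_true(is.na(life2$stop_day))
  expect_gt(max(life2$records$time_days[life2$records$sex == "female"]),
            life$stop_day)
})
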