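test_that("per-family enrichment cancels copy number and depth", {
  chip <- c(a = 10, b = 20, c = 30)
  input <- c(a = 5, b = 10, c = 10)
  # hand oracle: (chip/2) / (input/1)
  e <- repeat_chip_enrichment(chip, input, chip_auto_median = 2, input_auto_median = 1)
  expect_equal(unname(e), c((10 / 2) / 5, (20 / 2) / 10, (30 / 2) / 10))
  # chip == input at equal scalars: enrichment 1
  expect_equal(unname(repeat_chip_enrichment(input, input, 3, 3)), rep(1, 3))
  # doubling a family's copy number doubles chip AND input: unchanged
  e2 <- repeat_chip_enrichment(chip * 2, input * 2, 2, 1)
  expect_equal(e2, e)
  # library-depth rescaling moves the autosome medians with the counts
  e3 <- repeat_chip_enrichment(chip * 10, input, 2 * 10, 1)
  expect_equal(e3, e)
  # zero input -> undefined
  expect_true(is.na(repeat_chip_enrichment(c(x = 1), c(x = 0), 1, 1)))
})

test_that("per-chromosome-class enrichment keeps classes independent", {
  chip <- list(autosome_X = c(a = 10, b = 4), neoY = c(a = 7, b = 0))
  input <- list(autosome_X = c(a = 5, b = 2), neoY = c(a = 5, b = 0))
  out <- per_chromosome_enrichment(chip, input, 1, 1)
  expect_equal(out$enrichment[out$family == "a" & out$class == "autosome_X"], 2)
  expect_equal(out$enrichment[out$family == "a" & out$class == "neoY"], 7 / 5)
  # family absent from a class: missing, not zero
  expect_true(is.na(out$enrichment[out$family == "b" & out$class == "neoY"]))
  identical_out <- per_chromosome_enrichment(
    list(x = chip$autosome_X, y = chip$autosome_X),
    list(x = input$autosome_X, y = input$autosome_X), 1, 1)
  expect_equal(identical_out$enrichment[identical_out$class == "x"],
               identical_out$enrichment[identical_out$class == "y"])
})

test_that("Y-enrichment classification thresholds the depth-normalized ratio", {
  out <- classify_y_enrichment(c(f1 = 100, f2 = 300, f3 = 120),
                               c(f1 = 100, f2 = 100, f3 = 100))
  expect_equal(out$log2_mf, c(0, log2(3), log2(1.2)))
  expect_equal(out$y_enriched, c(FALSE, TRUE, FALSE))
  # depth normalization: a deeper male library is not called enrichment
  out2 <- classify_y_enrichment(c(f1 = 200), c(f1 = 100),
                                male_depth = 2, female_depth = 1)
  expect_false(out2$y_enriched)
  expect_error(classify_y_enrichment(c(0, 1), c(1, 1)), "zero coverage")
})

test_that("planted Y-enriched families are recovered from noisy gDNA", {
  cfg <- sim_config(seed = 47)
  g <- simulate_gdna(cfg)
  cls <- classify_y_enrichment(
    setNames(g$counts$male, g$counts$family),
    setNames(g$counts$female, g$counts$family),
    male_depth = g$depth[["male"]], female_depth = g$depth[["female"]])
  truth <- g$families$y_enriched
  sens <- mean(cls$y_enriched[truth])
  spec <- mean(!cls$y_enriched[!truth])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("rRNA filtering drops exactly the flagged rows", {
  m <- matrix(1:12, nrow = 4, dimnames = list(paste0("f", 1:4), NULL))
  expect_identical(filter_rrna(m, rep(FALSE, 4)), m)
  out <- filter_rrna(m, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rownames(out), c("f2", "f4"))
  expect_error(filter_rrna(m, rep(TRUE, 4)), "no features")
})

test_that("median-of-ratios size factors match the hand oracle", {
  m <- matrix(rep(c(10, 100, 50, 4), 3), nrow = 4)
  expect_equal(unname(size_factors(m)), rep(1, 3))
  m2 <- cbind(m[, 1], 2 * m[, 1], m[, 1])
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # hand oracle on a 4x3 matrix with a zero-containing feature excluded
  m3 <- matrix(c(10, 20, 40,
                 100, 50, 200,
                 0, 5, 5,
                 8, 8, 8), nrow = 4, byrow = TRUE)
  keep <- c(1, 2, 4)
  geo <- exp(rowMeans(log(m3[keep, ])))
  oracle <- apply(m3[keep, ] / geo, 2, median)
  expect_equal(unname(size_factors(m3)), unname(oracle))
})

test_that("NB Wald fold changes are zero on identical groups and antisymmetric", {
  counts <- matrix(rep(c(100, 20, 550), 6), nrow = 3,
                   dimnames = list(paste0("f", 1:3), NULL))
  de <- nb_wald_de(counts, rep(c("a", "b"), each = 3))
  expect_equal(de$log2fc, rep(0, 3), tolerance = 1e-4)
  expect_false(any(de$significant))

  set.seed(9)
  c2 <- matrix(rnbinom(60, mu = 200, size = 20), nrow = 10,
               dimnames = list(paste0("g", 1:10), NULL))
  cond <- rep(c("a", "b"), each = 3)
  fwd <- nb_wald_de(c2, factor(cond, levels = c("a", "b")), sf = rep(1, 6))
  rev <- nb_wald_de(c2, factor(cond, levels = c("b", "a")), sf = rep(1, 6))
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-3)
  expect_equal(fwd$p, rev$p, tolerance = 1e-3)

  # BH adjustment is monotone in raw p
  ord <- order(fwd$p)
  expect_true(all(diff(fwd$padj[ord]) >= -1e-12))
})

test_that("NB Wald recovers a planted high-count fold change", {
  set.seed(10)
  n <- 150
  c2 <- cbind(sapply(1:3, function(j) rnbinom(n, mu = 600, size = 20)),
              sapply(1:3, function(j) rnbinom(n, mu = 2400, size = 20)))
  rownames(c2) <- paste0("g", 1:n)
  de <- nb_wald_de(c2, rep(c("a", "b"), each = 3), sf = rep(1, 6))
  expect_equal(mean(de$log2fc), 2, tolerance = 0.1)
  expect_gt(mean(de$significant), 0.95)
})

test_that("NB Wald agrees with an established NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  n <- 60
  mu <- rlnorm(n, log(300), 0.8)
  fc <- rep(c(1, 3), length.out = n)
  counts <- cbind(sapply(1:3, function(j) rnbinom(n, mu = mu, size = 20)),
                  sapply(1:3, function(j) rnbinom(n, mu = mu * fc, size = 20)))
  rownames(counts) <- paste0("g", 1:n)
  colnames(counts) <- paste0("s", 1:6)
  cond <- factor(rep(c("a", "b"), each = 3))
  de <- nb_wald_de(counts, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, S4Vectors::DataFrame(cond = cond),
                                        ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  keep <- !is.na(ref$log2FoldChange)
  expect_gt(cor(de$log2fc, ref$log2FoldChange[keep]), 0.98)
  expect_equal(de$log2fc, ref$log2FoldChange[keep], tolerance = 0.15)
  # size factors match the reference median-of-ratios implementation
  expect_equal(unname(size_factors(counts)),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
})

test_that("copy-number normalization isolates dosage-independent expression", {
  expr <- matrix(c(40, 10, 80, 20), nrow = 2,
                 dimnames = list(c("teA", "teB"), c("m", "f")))
  cm <- c(4, 1); cf <- c(1, 1)
  # male expression exactly proportional to male copies: normalized ratio 1
  out <- copy_number_normalized_expression(
    matrix(c(40, 10, 10, 10), 2, dimnames = dimnames(expr)), cm, cf,
    sex = c("male", "female"))
  expect_equal(unname(out[, "m"] / out[, "f"]), c(1, 1))
  # residual bias beyond copy number survives normalization:
  # male (40,10) over copies (4,1) vs female (80,20) over copies (1,1)
  out2 <- copy_number_normalized_expression(expr, cm, cf, c("male", "female"))
  expect_equal(unname(out2[, "m"] / out2[, "f"]), c(40 / 4 / 80, 10 / 20))
  # copies of 1 everywhere: identity
  out3 <- copy_number_normalized_expression(expr, c(1, 1), c(1, 1), c("male", "female"))
  expect_equal(out3, expr)
  expect_error(copy_number_normalized_expression(expr, c(0, 1), cf, c("male", "female")),
               "positive")
})

test_that("repeat transcript fraction and origin split sum correctly", {
  counts <- matrix(c(90, 10, 0,
                     50, 25, 25), ncol = 2,
                   dimnames = list(c("gene1", "te1", "sat1"), c("s1", "s2")))
  fr <- repeat_transcript_fraction(counts, c("gene", "TE", "satellite"),
                                   group = c("g1", "g2"))
  expect_equal(fr$percent[fr$group == "g1"], 10)
  expect_equal(fr$percent[fr$group == "g2"], 50)
  all_rep <- repeat_transcript_fraction(counts, c("TE", "TE", "satellite"),
                                        group = c("g", "g"))
  expect_equal(all_rep$percent, 100)

  oc <- data.frame(neoY = c(10, 0), autosome_X = c(10, 20))
  out <- origin_split_expression(oc)
  expect_equal(sum(out$percent), 100)
  expect_equal(out$percent[out$class == "neoY"], 25)
  single <- origin_split_expression(data.frame(neoY = 5, autosome_X = 0))
  expect_equal(single$percent[single$class == "neoY"], 100)
})
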