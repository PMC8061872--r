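#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions the pipeline was designed for: a male/female diploid
#' genome with a repeat-rich neo-Y (published karyotype proportions, scaled
#' down), ~20% spike-in chromatin per ChIP sample, 4 ChIP replicates and 3
#' RNA replicates per sex and age, negative-binomial counts, and planted
#' effects — stronger age-dependent pericentromeric H3K9me3 loss in males
#' (40% vs 10%), a 30% H3K9me3 deficit on repeat-rich neo-Y windows,
#' male-biased expression of Y-enriched TE families, satellite de-repression
#' in old males, and sex-specific Gompertz lifespans with planted medians of
#' 78 (male) and 110 (female) days.
#'
#' Negative-binomial counts use the mean/dispersion parameterization with
#' variance \eqn{\mu + \alpha \mu^2}; `nb_dispersion = 0` switches the
#' generator to its noise-free mode where counts equal their expectations
#' exactly (useful for checking the documented mean structure).
#'
#' @param seed integer; together with the config it fully determines every
#'   output.
#' @param genome_scale fraction of the published chromosome lengths to retain.
#' @param window_size analysis window in bp.
#' @param baseline_signal expected Input reads per full diploid window.
#' @param heterochromatin_gain multiplicative ChIP boost per unit repeat
#'   fraction (true enrichment = 1 + gain x repeat_fraction).
#' @param neoY_deficit fractional H3K9me3 reduction planted on neo-Y arm
#'   windows with repeat fraction > 0.7.
#' @param aging_loss named vector `c(male=, female=)`: fractional
#'   pericentromeric ChIP reduction in old flies.
#' @param spike_fraction proportion of spike-in chromatin per library.
#' @param nb_dispersion NB dispersion of ChIP/Input window counts.
#' @param chip_replicates,rna_replicates replicates per sex/age condition.
#' @param n_genes,n_te_families,n_sat_families feature counts for the RNA and
#'   repeat layers.
#' @param y_enriched_fraction fraction of TE families planted as Y-enriched.
#' @param n_sat_y_enriched number of satellites planted as Y-enriched.
#' @param te_male_bias expression fold-increase for Y-enriched TEs in males.
#' @param y_te_baseline_boost baseline expression boost of Y-enriched TE
#'   families in both sexes (they are high-copy, hence more transcribed).
#' @param female_repeat_fraction target expected fraction of non-rRNA
#'   transcripts from repeats in young females (calibrates repeat baselines;
#'   with the default boosts the young-male expectation works out to ~8.0%).
#' @param sat_share share of female repeat expression carried by satellites.
#' @param n_sat_up_old_male,sat_aging_bias satellite de-repression planted in
#'   old males: how many families, and their fold-increase.
#' @param rna_dispersion NB dispersion of RNA counts.
#' @param gdna_log2_bias planted log2 male/female genomic coverage of
#'   Y-enriched families.
#' @param gdna_dispersion NB dispersion of gDNA family coverage (deep gDNA
#'   coverage is close to Poisson).
#' @param gdna_mean expected gDNA reads per family at equal depth.
#' @param neoy_origin_share named vector: expected share of a TE family's male
#'   transcripts originating from the neo-Y, for Y-enriched and unbiased
#'   families (calibrated so ~47% of young-male TE transcripts are neo-Y
#'   derived).
#' @param lifespan list: `n_male`, `n_female`, `vial_size`, Gompertz `shape`
#'   (1/day), planted `median_male`/`median_female` (days; the Gompertz rate is
#'   solved from these), daily escape hazard `escape_rate`, and `admin_stop`
#'   (stop the whole assay once the shorter-lived sex drops below 50%
#'   survivorship, censoring every fly still alive).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_scale = 1 / 500,
                       window_size = 5000,
                       baseline_signal = 200,
                       heterochromatin_gain = 6,
                       neoY_deficit = 0.30,
                       aging_loss = c(male = 0.40, female = 0.10),
                       spike_fraction = 0.20,
                       nb_dispersion = 0.02,
                       chip_replicates = 4L,
                       rna_replicates = 3L,
                       n_genes = 2000L,
                       n_te_families = 303L,
                       n_sat_families = 780L,
                       y_enriched_fraction = 81 / 303,
                       n_sat_y_enriched = 9L,
                       te_male_bias = 4,
                       y_te_baseline_boost = 2.3,
                       female_repeat_fraction = 0.037,
                       sat_share = 0.08,
                       n_sat_up_old_male = 21L,
                       sat_aging_bias = 3,
                       rna_dispersion = 0.05,
                       gdna_log2_bias = 2,
                       gdna_dispersion = 0.01,
                       gdna_mean = 1000,
                       neoy_origin_share = c(y_enriched = 0.585, unbiased = 0.08),
                       lifespan = list()) {
  ls_def <- list(n_male = 1304L, n_female = 1765L, vial_size = 20L,
                 shape = 0.09, median_male = 78, median_female = 110,
                 escape_rate = 3e-4, admin_stop = TRUE)
  ls_def[names(lifespan)] <- lifespan
  cfg <- list(
    seed = as.integer(seed), genome_scale = genome_scale,
    window_size = window_size, baseline_signal = baseline_signal,
    heterochromatin_gain = heterochromatin_gain, neoY_deficit = neoY_deficit,
    aging_loss = aging_loss, spike_fraction = spike_fraction,
    nb_dispersion = nb_dispersion,
    chip_replicates = as.integer(chip_replicates),
    rna_replicates = as.integer(rna_replicates),
    n_genes = as.integer(n_genes),
    n_te_families = as.integer(n_te_families),
    n_sat_families = as.integer(n_sat_families),
    y_enriched_fraction = y_enriched_fraction,
    n_sat_y_enriched = as.integer(n_sat_y_enriched),
    te_male_bias = te_male_bias, y_te_baseline_boost = y_te_baseline_boost,
    female_repeat_fraction = female_repeat_fraction, sat_share = sat_share,
    n_sat_up_old_male = as.integer(n_sat_up_old_male),
    sat_aging_bias = sat_aging_bias, rna_dispersion = rna_dispersion,
    gdna_log2_bias = gdna_log2_bias, gdna_dispersion = gdna_dispersion,
    gdna_mean = gdna_mean, neoy_origin_share = neoy_origin_share,
    lifespan = ls_def
  )
  fr <- c(cfg$neoY_deficit, cfg$aging_loss, cfg$spike_fraction,
          cfg$y_enriched_fraction, cfg$female_repeat_fraction, cfg$sat_share)
  if (any(fr < 0 | fr > 1)) stop("sim_config: fractions must lie in [0,1]")
  if (cfg$nb_dispersion < 0 || cfg$rna_dispersion < 0 || cfg$gdna_dispersion < 0) {
    stop("sim_config: dispersions must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

# NB draw with variance mu + alpha mu^2; alpha == 0 is the generator's
# noise-free mode (counts equal their expectation exactly).
rnb <- function(mu, alpha) {
  if (alpha == 0) return(mu)
  stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
}

rbeta_meansd <- function(n, mean, conc) {
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Build the simulated genome: layout, windows, repeat fractions, compartments
#'
#' Scales the published karyotype, tiles it into windows, and draws per-window
#' repeat fractions: high (with a gradient declining away from the centromere)
#' inside each chromosome's true pericentromere (placed at its published
#' proportion of the chromosome), low on euchromatic arms, uniformly high on
#' the neo-Y and the dot. Compartment labels record the planted truth; the
#' boundary-rule caller can be exercised against them.
#'
#' @param cfg a [sim_config()].
#' @return list with `layout`, `windows` (compartments and repeat fractions
#'   populated) and `neoy_peri_bp` (planted neo-Y pericentromere span in bp).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  layout <- miranda_layout(scale = cfg$genome_scale)
  windows <- partition_windows(layout, cfg$window_size)
  dist <- window_chrom_distance(windows, layout)
  neoy_peri_bp <- round(9.8e6 * cfg$genome_scale)
  with_sim_seed(cfg$seed + 11L, {
    rf <- numeric(nrow(windows))
    comp <- character(nrow(windows))
    for (i in seq_len(nrow(layout))) {
      chrom <- layout$name[i]
      idx <- which(windows$chrom == chrom)
      d <- dist[idx]
      len <- layout$length_bp[i]
      link <- layout$linkage[i]
      if (link == "dot") {
        rf[idx] <- rbeta_meansd(length(idx), 0.85, 25)
        comp[idx] <- "dot"
      } else if (link == "Y_neoY") {
        peri <- d < neoy_peri_bp
        rf[idx] <- ifelse(peri, rbeta_meansd(length(idx), 0.90, 30),
                          rbeta_meansd(length(idx), 0.80, 12))
        comp[idx] <- ifelse(peri, "neoY_pericentromere", "neoY_arm")
      } else {
        peri_bp <- layout$pericentric_mb[i] / layout$assembly_mb[i] * len
        peri <- d < peri_bp
        # repeat density declines mildly from the centromere outwards
        grad <- 0.92 - 0.15 * pmin(d / peri_bp, 1)
        peri_rf <- stats::rbeta(length(idx), grad * 30, (1 - grad) * 30)
        rf[idx] <- ifelse(peri, peri_rf, rbeta_meansd(length(idx), 0.15, 25))
        comp[idx] <- ifelse(peri, "pericentromere", "euchromatin")
      }
    }
    rf <- pmin(pmax(rf, 0), 1)
    windows$repeat_fraction <- rf
    windows$compartment <- comp
  })
  list(layout = layout, windows = windows, neoy_peri_bp = neoy_peri_bp)
}

heterochromatic_compartments <- c("pericentromere", "neoY_pericentromere", "dot")

# planted true enrichment per window for one sex/age
true_enrichment <- function(cfg, windows, sex, age) {
  e <- 1 + cfg$heterochromatin_gain * windows$repeat_fraction
  neo_def <- windows$compartment == "neoY_arm" & windows$repeat_fraction > 0.7
  e[neo_def] <- e[neo_def] * (1 - cfg$neoY_deficit)
  if (age == "old") {
    peri <- windows$compartment %in% heterochromatic_compartments
    e[peri] <- e[peri] * (1 - cfg$aging_loss[[sex]])
  }
  e
}

spike_layout <- function(cfg) {
  chr <- data.frame(
    name = c("spk1", "spk2", "spk3"), muller = c("s1", "s2", "s3"),
    linkage = "autosome", centromere_side = "right",
    length_bp = rep(30 * cfg$window_size, 3)
  )
  genome_layout(chr)
}

#' Simulate spike-in normalized ChIP/Input window counts
#'
#' For every sample (sex x age x replicate) draws Input counts
#' NB(baseline x copy-number x window-width fraction) and ChIP counts
#' NB(Input mean x true enrichment), where true enrichment is
#' `1 + heterochromatin_gain x repeat_fraction`, reduced by `neoY_deficit` on
#' repeat-rich (>0.7) neo-Y arm windows and by the sex's `aging_loss` on
#' pericentromeric (incl. neo-Y pericentromere and dot) windows of old
#' samples. Each library also carries counts from a miniature fixed spike
#' genome whose true enrichment (per-window, three chromosomes spanning low to
#' high enrichment) is identical across all samples and conditions, scaled so
#' spike reads make up `spike_fraction` of the library in expectation.
#' Female libraries have no Y/neo-Y reads (copy number zero).
#'
#' @param cfg a [sim_config()].
#' @param genome optionally a pre-built [simulate_genome()] result.
#' @return list: `layout`, `windows`, `spike_windows`, `samples` (list of
#'   per-sample lists with `meta`, `chip`, `input`, `spike_chip`,
#'   `spike_input`, `spike_totals`), and `truth` (per-window true enrichment
#'   per condition, and the spike genome's true enrichment).
#' @export
simulate_chip <- function(cfg, genome = simulate_genome(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  windows <- genome$windows
  layout <- genome$layout
  width_frac <- (windows$end - windows$start) / cfg$window_size
  slayout <- spike_layout(cfg)
  swin <- partition_windows(slayout, cfg$window_size)
  base_e <- c(spk1 = 1, spk2 = 3, spk3 = 8)
  spike_e <- with_sim_seed(cfg$seed + 23L, {
    exp(log(base_e[swin$chrom]) + stats::rnorm(nrow(swin), 0, 0.15))
  })
  conds <- expand.grid(sex = c("male", "female"), age = c("young", "old"),
                       rep = seq_len(cfg$chip_replicates),
                       stringsAsFactors = FALSE)
  truth_e <- sapply(c("male_young", "male_old", "female_young", "female_old"),
                    function(k) {
                      p <- strsplit(k, "_")[[1]]
                      true_enrichment(cfg, windows, p[1], p[2])
                    })
  cn <- list(male = sex_copy_number(layout$linkage, "male"),
             female = sex_copy_number(layout$linkage, "female"))
  names(cn$male) <- names(cn$female) <- layout$name
  samples <- with_sim_seed(cfg$seed + 37L, {
    lapply(seq_len(nrow(conds)), function(j) {
      sex <- conds$sex[j]; age <- conds$age[j]; rep <- conds$rep[j]
      copies <- cn[[sex]][windows$chrom]
      input_mu <- cfg$baseline_signal * (copies / 2) * width_frac
      e <- true_enrichment(cfg, windows, sex, age)
      chip_mu <- input_mu * e
      input_counts <- rnb(input_mu, cfg$nb_dispersion)
      chip_counts <- rnb(chip_mu, cfg$nb_dispersion)
      # spike library scaled to spike_fraction of expected total
      sf <- cfg$spike_fraction / (1 - cfg$spike_fraction)
      sp_input_mu <- rep(sum(input_mu) * sf / nrow(swin), nrow(swin))
      sp_chip_mu <- sum(chip_mu) * sf * spike_e / sum(spike_e)
      sp_input <- rnb(sp_input_mu, cfg$nb_dispersion)
      sp_chip <- rnb(sp_chip_mu, cfg$nb_dispersion)
      meta <- list(sex = sex, age = age, replicate = rep, assay = "ChIP")
      list(
        meta = meta,
        chip = coverage_track(windows, chip_counts, sum(chip_counts),
                              species = "sample", meta = meta),
        input = coverage_track(windows, input_counts, sum(input_counts),
                               species = "sample", meta = meta),
        spike_chip = coverage_track(swin, sp_chip, sum(sp_chip),
                                    species = "spike", meta = meta),
        spike_input = coverage_track(swin, sp_input, sum(sp_input),
                                     species = "spike", meta = meta),
        spike_totals = spike_counts(chip_sample = sum(chip_counts),
                                    input_sample = sum(input_counts),
                                    chip_spike = sum(sp_chip),
                                    input_spike = sum(sp_input))
      )
    })
  })
  list(layout = layout, windows = windows, spike_windows = swin,
       samples = samples,
       truth = list(enrichment = truth_e, spike_enrichment = spike_e,
                    neoy_peri_bp = genome$neoy_peri_bp))
}

#' Repeat-family table of the simulated genome
#'
#' TE and satellite families with planted Y-enrichment flags and sex-specific
#' copy numbers (Y-enriched families carry `2^gdna_log2_bias`-fold more copies
#' in males). The copy numbers drive the gDNA layer and the copy-number-aware
#' expression normalization.
#'
#' @param cfg a [sim_config()].
#' @return data frame: `family`, `class`, `y_enriched`, `copies_female`,
#'   `copies_male`, `copies_autosome_X`, `copies_neoY`.
#' @export
simulate_repeat_families <- function(cfg) {
  n_te <- cfg$n_te_families
  n_sat <- cfg$n_sat_families
  n_y <- round(cfg$y_enriched_fraction * n_te)
  with_sim_seed(cfg$seed + 51L, {
    fam <- data.frame(
      family = c(sprintf("TE_%03d", seq_len(n_te)),
                 sprintf("SAT_%03d", seq_len(n_sat))),
      class = c(rep("TE", n_te), rep("satellite", n_sat)),
      stringsAsFactors = FALSE
    )
    y_te <- sample(n_te, n_y)
    y_sat <- if (n_sat > 0) n_te + sample(n_sat, min(cfg$n_sat_y_enriched, n_sat)) else integer()
    fam$y_enriched <- FALSE
    fam$y_enriched[c(y_te, y_sat)] <- TRUE
    fam$copies_female <- round(stats::rlnorm(nrow(fam), log(40), 0.6)) + 1
    extra <- ifelse(fam$y_enriched, 2^cfg$gdna_log2_bias, 1)
    fam$copies_male <- round(fam$copies_female * extra)
    # per-chromosome-class haploid copies (male genome view)
    fam$copies_neoY <- round(fam$copies_male - fam$copies_female * 0.999)
    fam$copies_neoY[fam$copies_neoY < 0] <- 0
    fam$copies_autosome_X <- fam$copies_male - fam$copies_neoY
    fam
  })
}

#' Simulate male and female genomic-DNA coverage per repeat family
#'
#' Family coverage is proportional to copy number; Y-enriched families are
#' planted with `2^gdna_log2_bias`-fold more male coverage, all others are
#' equal in expectation. Libraries are given unequal depths (exercised by the
#' single-copy depth normalization in [classify_y_enrichment()]).
#'
#' @param cfg a [sim_config()].
#' @param families optionally a pre-built [simulate_repeat_families()] table.
#' @return list: `families`, `counts` (data frame `family`, `male`, `female`),
#'   `depth` (named single-copy depth scalars), `truth` (planted flags).
#' @export
simulate_gdna <- function(cfg, families = simulate_repeat_families(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed + 67L, {
    depth <- c(male = 1.15, female = 1.0)
    base <- cfg$gdna_mean * families$copies_female / mean(families$copies_female)
    mu_f <- base * depth[["female"]]
    mu_m <- base * ifelse(families$y_enriched, 2^cfg$gdna_log2_bias, 1) * depth[["male"]]
    counts <- data.frame(
      family = families$family,
      male = rnb(mu_m, cfg$gdna_dispersion),
      female = rnb(mu_f, cfg$gdna_dispersion)
    )
    list(families = families, counts = counts, depth = depth,
         truth = families[, c("family", "y_enriched")])
  })
}

#' Simulate the RNA-seq count matrix
#'
#' Features are genes, TE families, satellite families and rRNA scaffolds;
#' samples are sex x age x replicate. NB counts around planted means:
#' Y-enriched TE families are boosted `y_te_baseline_boost`-fold in both sexes
#' (high copy number) and a further `te_male_bias`-fold in males; a planted
#' subset of satellites is up-regulated `sat_aging_bias`-fold in old males;
#' rRNA rows are large and flagged for the filtering stage. Repeat baselines
#' are calibrated so the expected repeat fraction of non-rRNA transcripts in
#' young females equals `female_repeat_fraction`. Male TE transcripts are
#' additionally attributed to chromosome-of-origin classes (autosome/X vs
#' neo-Y) by a multinomial split at the planted origin shares.
#'
#' @param cfg a [sim_config()].
#' @param families optionally a pre-built [simulate_repeat_families()] table.
#' @return list: `counts` (features x samples integer matrix), `features`
#'   (metadata incl. `type`, `is_rrna`, `y_enriched`, copy numbers), `samples`
#'   (metadata data frame), `origin_counts` (male TE counts split by
#'   chromosome class), `truth` (planted log2 fold changes and shares).
#' @export
simulate_rnaseq <- function(cfg, families = simulate_repeat_families(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed + 83L, {
    gene_mu <- stats::rlnorm(cfg$n_genes, log(100), 1)
    G <- sum(gene_mu)
    R_f <- G * cfg$female_repeat_fraction / (1 - cfg$female_repeat_fraction)
    te <- families$class == "TE"
    sat <- families$class == "satellite"
    te_w <- ifelse(families$y_enriched[te], cfg$y_te_baseline_boost, 1) *
      stats::rlnorm(sum(te), 0, 0.5)
    sat_w <- stats::rlnorm(sum(sat), 0, 0.5)
    te_mu_f <- R_f * (1 - cfg$sat_share) * te_w / sum(te_w)
    sat_mu_f <- R_f * cfg$sat_share * sat_w / sum(sat_w)
    sat_up <- rep(FALSE, sum(sat))
    sat_up[sample(sum(sat), min(cfg$n_sat_up_old_male, sum(sat)))] <- TRUE

    n_rrna <- 5L
    rrna_mu <- rep(G * 0.05 / n_rrna, n_rrna)

    features <- data.frame(
      feature_id = c(sprintf("gene_%04d", seq_len(cfg$n_genes)),
                     families$family, sprintf("rRNA_%d", seq_len(n_rrna))),
      type = c(rep("gene", cfg$n_genes), families$class, rep("rRNA", n_rrna)),
      stringsAsFactors = FALSE
    )
    features$is_rrna <- features$type == "rRNA"
    features$y_enriched <- c(rep(FALSE, cfg$n_genes), families$y_enriched,
                             rep(FALSE, n_rrna))
    features$copies_female <- c(rep(1, cfg$n_genes), families$copies_female,
                                rep(1, n_rrna))
    features$copies_male <- c(rep(1, cfg$n_genes), families$copies_male,
                              rep(1, n_rrna))

    samples <- expand.grid(sex = c("male", "female"), age = c("young", "old"),
                           rep = seq_len(cfg$rna_replicates),
                           stringsAsFactors = FALSE)
    samples$sample_id <- with(samples, sprintf("%s_%s_r%d", sex, age, rep))

    mean_for <- function(sex, age) {
      te_mu <- te_mu_f * ifelse(families$y_enriched[te] & sex == "male",
                                cfg$te_male_bias, 1)
      sat_mu <- sat_mu_f * ifelse(sat_up & sex == "male" & age == "old",
                                  cfg$sat_aging_bias, 1)
      c(gene_mu, te_mu, sat_mu, rrna_mu)
    }
    counts <- sapply(seq_len(nrow(samples)), function(j) {
      rnb(mean_for(samples$sex[j], samples$age[j]), cfg$rna_dispersion)
    })
    rownames(counts) <- features$feature_id
    colnames(counts) <- samples$sample_id

    # male TE transcripts attributed to chromosome class of origin
    te_ids <- families$family[te]
    share <- ifelse(families$y_enriched[te],
                    cfg$neoy_origin_share[["y_enriched"]],
                    cfg$neoy_origin_share[["unbiased"]])
    male_cols <- which(samples$sex == "male")
    origin <- lapply(male_cols, function(j) {
      k <- counts[te_ids, j]
      neoY <- stats::rbinom(length(k), size = round(k), prob = share)
      data.frame(family = te_ids, neoY = neoY, autosome_X = round(k) - neoY,
                 sample_id = samples$sample_id[j])
    })
    origin_counts <- do.call(rbind, origin)

    truth <- list(
      te_male_log2fc = stats::setNames(
        ifelse(families$y_enriched[te], log2(cfg$te_male_bias), 0), te_ids),
      sat_old_male_up = stats::setNames(sat_up, families$family[sat]),
      expected_repeat_fraction = c(
        male = {
          m <- mean_for("male", "young"); idx <- features$type %in% c("TE", "satellite")
          sum(m[idx]) / sum(m[!features$is_rrna])
        },
        female = cfg$female_repeat_fraction),
      neoy_origin_share = cfg$neoy_origin_share
    )
    list(counts = counts, features = features, samples = samples,
         origin_counts = origin_counts, truth = truth)
  })
}

#' Simulate per-fly lifespan records
#'
#' Event times are Gompertz per sex (rate solved from the planted medians at
#' the configured shape), recorded at 1-day resolution. Flies escaping the
#' vial (daily exponential hazard) are censored at escape time. If
#' `admin_stop` is set, the whole assay is stopped on the day the
#' shorter-lived sex's survivorship falls below 50% and every fly still alive
#' is censored on that day (administrative truncation).
#'
#' @param cfg a [sim_config()].
#' @return list: `records` (data frame `fly_id`, `sex`, `vial_id`,
#'   `time_days`, `event` in death/censored, `reason`), `truth` (planted
#'   continuous medians and Gompertz parameters), `stop_day` (`NA` when no
#'   administrative stop applied).
#' @export
simulate_lifespan <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ls <- cfg$lifespan
  b <- ls$shape
  rate_for <- function(med) b * log(2) / expm1(b * med)
  rates <- c(male = rate_for(ls$median_male), female = rate_for(ls$median_female))
  with_sim_seed(cfg$seed + 101L, {
    one_sex <- function(sex, n) {
      death <- flexsurv::rgompertz(n, shape = b, rate = rates[[sex]])
      escape <- if (ls$escape_rate > 0) stats::rexp(n, rate = ls$escape_rate) else rep(Inf, n)
      time <- ceiling(pmin(death, escape))
      data.frame(
        fly_id = sprintf("%s_%05d", sex, seq_len(n)),
        sex = sex,
        vial_id = sprintf("%s_v%03d", sex, ((seq_len(n) - 1) %/% ls$vial_size) + 1),
        time_days = pmax(time, 1),
        event = ifelse(death <= escape, "death", "censored"),
        reason = ifelse(death <= escape, "death", "escape"),
        stringsAsFactors = FALSE
      )
    }
    rec <- rbind(one_sex("male", ls$n_male), one_sex("female", ls$n_female))
    stop_day <- NA_real_
    if (isTRUE(ls$admin_stop)) {
      half_day <- function(sex) {
        r <- rec[rec$sex == sex, ]
        d <- sort(r$time_days[r$event == "death"])
        # first day on which more than half the flies have died
        k <- ceiling(nrow(r) / 2)
        if (length(d) < k) Inf else d[k]
      }
      stop_day <- min(half_day("male"), half_day("female"))
      trunc <- rec$time_days > stop_day
      rec$event[trunc] <- "censored"
      rec$reason[trunc] <- "administrative"
      rec$time_days[trunc] <- stop_day
    }
    list(records = rec,
         truth = list(median_male = ls$median_male,
                      median_female = ls$median_female,
                      shape = b, rates = rates),
         stop_day = stop_day)
  })
}
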