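#' Read a pipeline configuration
#'
#' Accepts either a YAML file path or a config list. Recognised fields:
#' `seed`, `sim` (arguments to [sim_config()]), `method` (normalization,
#' default `"no_spike"`), `fold` (window-call threshold), `excluded_replicates`
#' (character vector like `"male_old_1"`), `lfc_threshold`, `p_threshold`,
#' `y_threshold_log2`.
#'
#' @param config list or YAML path.
#' @return normalized config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, sim = list(), method = "no_spike", fold = 1.5,
                   excluded_replicates = character(),
                   lfc_threshold = 0.58, p_threshold = 0.05,
                   y_threshold_log2 = 0.585)
  defaults[names(config)] <- config
  if (defaults$fold <= 0 || defaults$lfc_threshold < 0 || defaults$p_threshold <= 0) {
    stop("pipeline_config: thresholds must be positive")
  }
  defaults$method <- match.arg(defaults$method,
                               c("no_spike", "scale_factor", "regression", "quantile"))
  defaults
}

# per-spike-window ratio track for one sample (depth-normalized within species)
spike_signal_of <- function(s) {
  ch <- s$spike_chip$counts / sum(s$spike_chip$counts)
  inp <- s$spike_input$counts / sum(s$spike_input$counts)
  ifelse(inp > 0, ch / inp, NA_real_)
}

#' Normalize all ChIP samples of a simulated (or loaded) experiment
#'
#' Computes per-sample enrichment under the requested normalization method.
#' The no-spike route scales by library size and the euchromatic Muller B +
#' Muller E median; the spike routes post-process that signal using each
#' sample's spike-in (scale factor, log-linear regression to the pooled spike
#' reference, or quantile-quantile matching to it).
#'
#' @param chip a [simulate_chip()] result (or an equivalently shaped list of
#'   loaded samples).
#' @param layout the genome layout (for Muller labels).
#' @param method normalization method.
#' @return list of [enrichment_track()]s, one per sample.
#' @export
normalize_samples <- function(chip, layout, method = "no_spike") {
  w <- chip$windows
  auto_eu <- w$chrom %in% layout$name[layout$muller %in% c("B", "E")] &
    w$compartment == "euchromatin"
  if (!any(auto_eu)) stop("normalize_samples: no autosomal euchromatic normalization windows")
  base <- lapply(chip$samples, function(s) no_spike_signal(s$chip, s$input, auto_eu))
  if (method == "no_spike") return(base)
  if (method == "scale_factor") {
    return(lapply(seq_along(base), function(j) {
      apply_scale_factor(base[[j]], spike_scale_factor(chip$samples[[j]]$spike_totals))
    }))
  }
  spikes <- lapply(chip$samples, spike_signal_of)
  pooled_chip <- Reduce(`+`, lapply(chip$samples, function(s) s$spike_chip$counts))
  pooled_input <- Reduce(`+`, lapply(chip$samples, function(s) s$spike_input$counts))
  reference <- ifelse(pooled_input > 0,
                      (pooled_chip / sum(pooled_chip)) / (pooled_input / sum(pooled_input)),
                      NA_real_)
  lapply(seq_along(base), function(j) {
    if (method == "regression") {
      regression_adjust(base[[j]], spikes[[j]], reference)
    } else {
      quantile_adjust(base[[j]], spikes[[j]], reference)$signal
    }
  })
}

sample_key <- function(meta) paste(meta$sex, meta$age, meta$replicate, sep = "_")

#' Run the full synthetic-data pipeline
#'
#' Simulate -> normalize -> replicate means -> window calls per sex ->
#' compartment attribution and Fisher sex comparison -> Y-enrichment
#' classification from gDNA -> rRNA filtering, size factors and TE
#' differential expression (young males vs young females) -> repeat
#' transcript fractions and origin split -> survivorship. Writes BED/BedGraph
#' /TSV outputs plus a machine-readable `summary.json`; deterministic given
#' the seed.
#'
#' @param config a [pipeline_config()] input (list or YAML path).
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return invisible list: `summary` plus the main intermediate objects.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- pipeline_config(config)
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  genome <- stage("simulate", simulate_genome(scfg))
  chip <- stage("simulate", simulate_chip(scfg, genome))
  families <- stage("simulate", simulate_repeat_families(scfg))
  gdna <- stage("simulate", simulate_gdna(scfg, families))
  rna <- stage("simulate", simulate_rnaseq(scfg, families))
  life <- stage("simulate", simulate_lifespan(scfg))

  tracks <- stage("normalize", normalize_samples(chip, genome$layout, cfg$method))
  keys <- vapply(chip$samples, function(s) sample_key(s$meta), character(1))
  keep <- !(keys %in% cfg$excluded_replicates)

  cond_mean <- function(sex, age) {
    sel <- keep & vapply(chip$samples, function(s) {
      s$meta$sex == sex && s$meta$age == age
    }, logical(1))
    mean_track(tracks[sel])
  }
  calls <- stage("diffwindows", {
    lapply(stats::setNames(c("male", "female"), c("male", "female")), function(sx) {
      call_windows(cond_mean(sx, "young"), cond_mean(sx, "old"), fold = cfg$fold)
    })
  })
  loss_counts <- vapply(calls, function(cs) sum(cs$call == "loss"), numeric(1))
  totals <- vapply(calls, function(cs) sum(!is.na(cs$fold_change)), numeric(1))
  fisher_p <- stage("diffwindows", fisher_sex_compare(
    loss_counts[["male"]], totals[["male"]],
    loss_counts[["female"]], totals[["female"]]))
  breakdown <- lapply(calls, compartment_breakdown)

  ycalls <- stage("repeats", {
    cls <- classify_y_enrichment(
      stats::setNames(gdna$counts$male, gdna$counts$family),
      stats::setNames(gdna$counts$female, gdna$counts$family),
      male_depth = gdna$depth[["male"]], female_depth = gdna$depth[["female"]],
      threshold_log2 = cfg$y_threshold_log2)
    cls
  })

  de <- stage("de", {
    counts <- filter_rrna(rna$counts, rna$features$is_rrna)
    feats <- rna$features[!rna$features$is_rrna, ]
    young <- rna$samples$age == "young"
    te_rows <- feats$type == "TE"
    nb_wald_de(counts[te_rows, young, drop = FALSE],
               condition = factor(rna$samples$sex[young], levels = c("female", "male")),
               sf = size_factors(counts[, young, drop = FALSE]),
               lfc_threshold = cfg$lfc_threshold, p_threshold = cfg$p_threshold)
  })
  fractions <- stage("fractions", {
    counts <- filter_rrna(rna$counts, rna$features$is_rrna)
    feats <- rna$features[!rna$features$is_rrna, ]
    repeat_transcript_fraction(counts, feats$type,
                               paste(rna$samples$sex, rna$samples$age, sep = "_"))
  })
  young_male_ids <- rna$samples$sample_id[rna$samples$sex == "male" &
                                            rna$samples$age == "young"]
  origin <- stage("fractions", origin_split_expression(
    rna$origin_counts[rna$origin_counts$sample_id %in% young_male_ids, ]))

  surv <- stage("survival", survivorship_by_group(life$records))

  summary <- list(
    seed = cfg$seed,
    method = cfg$method,
    n_windows = nrow(chip$windows),
    loss_windows = as.list(loss_counts),
    gain_windows = lapply(calls, function(cs) sum(cs$call == "gain")),
    analyzable_windows = as.list(totals),
    loss_compartments = lapply(breakdown, function(b) {
      stats::setNames(as.list(b$n), b$compartment)
    }),
    fisher_p = fisher_p,
    y_enriched_families = sum(ycalls$y_enriched),
    te_de = list(up_in_male = sum(de$significant & de$log2fc > 0),
                 down_in_male = sum(de$significant & de$log2fc < 0)),
    repeat_fraction_pct = stats::setNames(as.list(fractions$percent), fractions$group),
    te_origin_pct = stats::setNames(as.list(origin$percent), origin$class),
    median_lifespan = lapply(surv, function(s) s$median_label)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- chip$windows
    write_bed(data.frame(chrom = w$chrom, start = w$start, end = w$end,
                         name = w$compartment), file.path(out_dir, "compartments.bed"))
    write_bedgraph(w, w$repeat_fraction, file.path(out_dir, "repeat_fraction.bedgraph"))
    for (sx in names(calls)) {
      cs <- calls[[sx]]
      sel <- cs$call != "none"
      write_bed(data.frame(chrom = cs$chrom[sel], start = cs$start[sel],
                           end = cs$end[sel], name = cs$call[sel],
                           score = 1000 * abs(log2(cs$fold_change[sel]))),
                file.path(out_dir, paste0("calls_", sx, ".bed")))
      write_bedgraph(w, cond_mean(sx, "young")$signal,
                     file.path(out_dir, paste0("signal_", sx, "_young.bedgraph")))
    }
    utils::write.table(ycalls, file.path(out_dir, "y_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de, file.path(out_dir, "te_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(life$records, file.path(out_dir, "lifespan_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (sx in names(surv)) {
      utils::write.table(as.data.frame(surv[[sx]]$curve),
                         file.path(out_dir, paste0("survival_", sx, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(summary = summary, calls = calls, breakdown = breakdown,
                 fisher_p = fisher_p, ycalls = ycalls, de = de,
                 fractions = fractions, origin = origin, surv = surv,
                 chip = chip, tracks = tracks, gdna = gdna, rna = rna,
                 lifespan = life, config = cfg))
}
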