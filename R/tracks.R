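#' Window-aligned coverage track
#'
#' Raw read counts over a fixed window grid for one sequencing library
#' (ChIP or Input), tagged with the species the reads mapped to (`"sample"`
#' for the study genome, `"spike"` for the spike-in genome).
#'
#' @param windows the `window_table` the counts are aligned to.
#' @param counts non-negative numeric vector, one value per window.
#' @param library_total total mapped reads of the library; defaults to
#'   `sum(counts)` and must be at least that.
#' @param species `"sample"` or `"spike"`.
#' @param meta named list of sample metadata (sex, age, replicate, assay ...).
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(windows, counts, library_total = sum(counts),
                           species = c("sample", "spike"), meta = list()) {
  species <- match.arg(species)
  stopifnot(inherits(windows, "window_table"))
  if (length(counts) != nrow(windows)) stop("coverage_track: counts/window length mismatch")
  if (any(counts < 0)) stop("coverage_track: counts must be non-negative")
  if (library_total < sum(counts)) stop("coverage_track: library_total below summed counts")
  structure(
    list(windows = windows, counts = as.numeric(counts),
         library_total = library_total, species = species, meta = meta),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d windows, %s reads in library, species=%s\n",
              nrow(x$windows), format(x$library_total, big.mark = ","), x$species))
  invisible(x)
}

#' Window-aligned enrichment track
#'
#' Per-window ChIP signal (ChIP/Input ratio scale) under a named normalization
#' method. Windows where Input coverage was zero carry `NA` (the signal is
#' undefined there, never infinite).
#'
#' @param windows the aligned `window_table`.
#' @param signal numeric vector of per-window signal (`NA` where undefined).
#' @param method one of `"no_spike"`, `"scale_factor"`, `"regression"`,
#'   `"quantile"`.
#' @param meta named list of sample metadata.
#' @return An `enrichment_track` object.
#' @export
enrichment_track <- function(windows, signal,
                             method = c("no_spike", "scale_factor", "regression", "quantile"),
                             meta = list()) {
  method <- match.arg(method)
  stopifnot(inherits(windows, "window_table"))
  if (length(signal) != nrow(windows)) stop("enrichment_track: signal/window length mismatch")
  if (any(signal <= 0, na.rm = TRUE)) stop("enrichment_track: signal must be positive where defined")
  structure(list(windows = windows, signal = as.numeric(signal),
                 method = method, meta = meta),
            class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("<enrichment_track> %d windows, method=%s, %d undefined\n",
              nrow(x$windows), x$method, sum(is.na(x$signal))))
  invisible(x)
}

#' Spike-in mapped-read totals for one library pair
#'
#' Mapped-read totals for a ChIP/Input library pair split by species: reads
#' mapping to the study genome (`chip_sample`, `input_sample`) and to the
#' spike-in genome (`chip_spike`, `input_spike`). Used by
#' [spike_scale_factor()].
#'
#' @param chip_sample,input_sample,chip_spike,input_spike non-negative totals.
#' @return A `spike_counts` object.
#' @export
spike_counts <- function(chip_sample, input_sample, chip_spike, input_spike) {
  vals <- c(chip_sample, input_sample, chip_spike, input_spike)
  if (any(vals < 0)) stop("spike_counts: totals must be non-negative")
  structure(list(chip_sample = chip_sample, input_sample = input_sample,
                 chip_spike = chip_spike, input_spike = input_spike),
            class = "spike_counts")
}

#' Write a per-window value vector as BedGraph
#'
#' 0-based half-open BedGraph; values written with 6 significant digits;
#' `NA` windows are skipped (BedGraph has no missing-value encoding).
#'
#' @param windows a `window_table`.
#' @param values per-window numeric vector.
#' @param path output file.
#' @export
write_bedgraph <- function(windows, values, path) {
  stopifnot(length(values) == nrow(windows))
  keep <- !is.na(values)
  df <- data.frame(windows$chrom[keep], windows$start[keep], windows$end[keep],
                   signif(values[keep], 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BedGraph file
#'
#' @param path BedGraph file (4 columns, 0-based half-open).
#' @return data frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  df
}

#' Write intervals as BED
#'
#' @param df data frame with `chrom`, `start`, `end` and optionally `name` and
#'   `score` columns (score capped at 1000 per BED convention).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  out <- df[, c("chrom", "start", "end")]
  if (!is.null(df$name)) out$name <- df$name
  if (!is.null(df$score)) out$score <- pmin(round(df$score), 1000)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of windows/calls
#' @param path BED file (>= 3 columns).
#' @return data frame with `chrom`, `start`, `end` (+ `name`, `score` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}
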