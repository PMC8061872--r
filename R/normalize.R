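#' ChIP signal without spike-in normalization
#'
#' The default normalization: each track (ChIP and Input separately) is scaled
#' by its library size, then by the median of its own values over a designated
#' set of normalization windows — the euchromatic arms of the two major
#' autosomes (Muller B and Muller E) — so that the Input track has median 1
#' there. Signal is the per-window ratio of the two normalized tracks
#' (ChIP/Input). Windows with zero Input coverage get `NA` signal and are
#' excluded from medians and downstream calls.
#'
#' The result is invariant to rescaling either library's sequencing depth.
#'
#' @param chip,input window-aligned [coverage_track()]s for the same sample.
#' @param norm_windows logical or integer index of the autosomal euchromatic
#'   normalization windows.
#' @return An [enrichment_track()] with method `"no_spike"`.
#' @export
no_spike_signal <- function(chip, input, norm_windows) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (nrow(chip$windows) != nrow(input$windows)) stop("no_spike_signal: tracks not window-aligned")
  if (is.logical(norm_windows)) norm_windows <- which(norm_windows)
  if (!length(norm_windows)) stop("no_spike_signal: no normalization windows supplied")
  norm_one <- function(tr) {
    x <- tr$counts / tr$library_total
    m <- stats::median(x[norm_windows], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) stop("no_spike_signal: zero median over normalization windows")
    x / m
  }
  c_n <- norm_one(chip)
  i_n <- norm_one(input)
  sig <- ifelse(i_n > 0, c_n / i_n, NA_real_)
  sig[!is.na(sig) & sig <= 0] <- NA_real_
  enrichment_track(chip$windows, sig, method = "no_spike", meta = chip$meta)
}

#' Spike-in scale factor
#'
#' Converts spike-in mapped-read totals into a multiplicative scale factor
#' applied to a sample's no-spike enrichment:
#'
#' \deqn{c = 1 + \frac{ChIP_{sample} / (Input_{spike}/Input_{sample})}
#'                    {Input_{spike} + ChIP_{spike}}}
#'
#' evaluated left-associatively exactly as written. The expression is not
#' scale-free: multiplying all four totals by a constant changes `c`; it is a
#' property of absolute mapped-read totals, which is intentional (the spike-in
#' fraction of the library carries the quantitative information).
#'
#' @param s a [spike_counts()] object.
#' @return scale factor `c` (equals 1 when `chip_sample` is 0).
#' @export
spike_scale_factor <- function(s) {
  stopifnot(inherits(s, "spike_counts"))
  if (s$input_spike <= 0 || s$input_sample <= 0) {
    stop("spike_scale_factor: Input totals must be positive")
  }
  denom <- s$input_spike + s$chip_spike
  if (denom <= 0) stop("spike_scale_factor: zero denominator")
  1 + (s$chip_sample / (s$input_spike / s$input_sample)) / denom
}

#' Apply a spike-in scale factor to an enrichment track
#'
#' @param track an [enrichment_track()] (typically no-spike signal).
#' @param c scale factor from [spike_scale_factor()].
#' @return scaled [enrichment_track()] with method `"scale_factor"`.
#' @export
apply_scale_factor <- function(track, c) {
  stopifnot(inherits(track, "enrichment_track"), is.numeric(c), c > 0)
  enrichment_track(track$windows, track$signal * c, method = "scale_factor",
                   meta = track$meta)
}

#' Regression-based spike-in adjustment
#'
#' Fits a monotone log-linear regression mapping this sample's spike-in signal
#' onto a pooled reference spike-in signal (both on log scale, window-aligned
#' across the spike genome), then applies the fitted transform to the sample's
#' signal. When the sample's spike distribution already equals the reference,
#' the transform is the identity; a sample whose spike signal is uniformly
#' inflated k-fold has its signal deflated k-fold.
#'
#' @param sample_signal [enrichment_track()] over the study genome.
#' @param sample_spike_signal numeric vector of spike-genome signal for this
#'   sample (positive; window-aligned with `reference_spike_signal`).
#' @param reference_spike_signal numeric vector, pooled reference spike signal.
#' @return adjusted [enrichment_track()] with method `"regression"`.
#' @export
regression_adjust <- function(sample_signal, sample_spike_signal, reference_spike_signal) {
  stopifnot(inherits(sample_signal, "enrichment_track"))
  ok <- is.finite(sample_spike_signal) & is.finite(reference_spike_signal) &
        sample_spike_signal > 0 & reference_spike_signal > 0
  if (sum(ok) < 3) stop("regression_adjust: too few usable spike windows")
  x <- log(sample_spike_signal[ok])
  y <- log(reference_spike_signal[ok])
  if (stats::sd(x) == 0) stop("regression_adjust: degenerate (constant) spike signal")
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  if (b[2] <= 0) stop("regression_adjust: fitted spike relationship is not increasing")
  sig <- sample_signal$signal
  adj <- ifelse(is.na(sig), NA_real_, exp(b[1] + b[2] * log(sig)))
  enrichment_track(sample_signal$windows, adj, method = "regression",
                   meta = sample_signal$meta)
}

# empirical quantile map taking distribution of `from` onto `to`, on log2 scale,
# linearly interpolated between matched quantiles and extended by unit-slope
# shift beyond the observed range (a pure location shift maps exactly).
make_qq_map <- function(from, to, n_quantiles = 1000) {
  p <- stats::ppoints(n_quantiles)
  xq <- stats::quantile(log2(from), p, names = FALSE, type = 7)
  yq <- stats::quantile(log2(to), p, names = FALSE, type = 7)
  o <- !duplicated(xq)
  xq <- xq[o]; yq <- yq[o]
  function(v) {
    lv <- log2(v)
    out <- stats::approx(xq, yq, xout = lv, rule = 1)$y
    below <- !is.na(lv) & lv < xq[1]
    above <- !is.na(lv) & lv > xq[length(xq)]
    out[below] <- yq[1] + (lv[below] - xq[1])
    out[above] <- yq[length(yq)] + (lv[above] - xq[length(xq)])
    2^out
  }
}

#' Quantile-quantile spike-in adjustment
#'
#' Builds the empirical quantile map taking this sample's spike-signal
#' distribution onto an aggregate spike reference (pooled over all samples'
#' spike ChIP and Input coverages) and applies the same map, by interpolation
#' on log2 scale, to the sample's signal. After adjustment the sample's
#' spike-signal quantiles equal the reference quantiles (to interpolation
#' tolerance), and re-applying the map with the already-matched spike signal
#' is the identity (idempotence).
#'
#' @param sample_signal [enrichment_track()] over the study genome.
#' @param sample_spike_signal positive numeric vector of this sample's spike
#'   signal.
#' @param aggregate_spike_reference positive numeric vector, the pooled
#'   reference spike-signal distribution.
#' @return list with `signal` (adjusted [enrichment_track()], method
#'   `"quantile"`) and `spike_signal` (the sample's spike signal after the same
#'   map, for idempotence checks and replicate QC).
#' @export
quantile_adjust <- function(sample_signal, sample_spike_signal, aggregate_spike_reference) {
  stopifnot(inherits(sample_signal, "enrichment_track"))
  if (!length(aggregate_spike_reference)) stop("quantile_adjust: empty reference")
  sp <- sample_spike_signal[is.finite(sample_spike_signal) & sample_spike_signal > 0]
  ref <- aggregate_spike_reference[is.finite(aggregate_spike_reference) & aggregate_spike_reference > 0]
  if (!length(sp) || !length(ref)) stop("quantile_adjust: empty spike distributions")
  qmap <- make_qq_map(sp, ref)
  sig <- sample_signal$signal
  adj <- ifelse(is.na(sig), NA_real_, qmap(sig))
  list(
    signal = enrichment_track(sample_signal$windows, adj, method = "quantile",
                              meta = sample_signal$meta),
    spike_signal = qmap(sample_spike_signal)
  )
}

#' Subsample a coverage track to a target depth
#'
#' Multivariate-hypergeometric thinning: draws `target_total` reads without
#' replacement from the window counts, so expectations stay proportional to
#' the original counts. Deterministic given `seed`.
#'
#' @param track a [coverage_track()].
#' @param target_total target read total (<= `sum(track$counts)`).
#' @param seed integer RNG seed.
#' @return thinned [coverage_track()].
#' @export
subsample_track <- function(track, target_total, seed = 1L) {
  stopifnot(inherits(track, "coverage_track"))
  total <- sum(track$counts)
  if (target_total > total) stop("subsample_track: target exceeds available reads")
  if (target_total == total) return(track)
  counts <- round(track$counts)
  new <- numeric(length(counts))
  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  withr_seed({
    remaining_pool <- sum(counts)
    remaining_draw <- target_total
    for (i in seq_along(counts)) {
      if (remaining_draw == 0) break
      remaining_pool <- remaining_pool - counts[i]
      # draws from this window: hypergeometric of (this window, rest of pool)
      k <- stats::rhyper(1, counts[i], remaining_pool, remaining_draw)
      new[i] <- k
      remaining_draw <- remaining_draw - k
    }
  })
  coverage_track(track$windows, new, library_total = target_total,
                 species = track$species, meta = track$meta)
}

#' Flag replicates with depressed ChIP efficacy
#'
#' A replicate whose enrichment is jointly depressed in both the sample and
#' spike-in (the signature of an inefficient pull-down) is flagged when its
#' median pericentromeric signal falls below `frac` of the median of its
#' replicate group. Exclusion itself is a manual, config-level decision; this
#' function only flags.
#'
#' @param tracks list of [enrichment_track()]s forming one replicate group
#'   (same sex and age).
#' @param pericentromere logical/integer index of pericentromeric windows.
#' @param frac flagging fraction of the group median (default 0.5).
#' @return logical vector, `TRUE` where flagged.
#' @export
flag_low_efficacy <- function(tracks, pericentromere, frac = 0.5) {
  med <- vapply(tracks, function(t) stats::median(t$signal[pericentromere], na.rm = TRUE),
                numeric(1))
  med < frac * stats::median(med)
}
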