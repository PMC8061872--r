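#' Average enrichment tracks across replicates
#'
#' Arithmetic mean of per-replicate signal per window; windows undefined in a
#' replicate are averaged over the replicates where they are defined (all-NA
#' windows stay NA). Failed replicates are excluded upstream via config.
#'
#' @param tracks list of window-aligned [enrichment_track()]s.
#' @return an [enrichment_track()] of the replicate mean.
#' @export
mean_track <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  n <- nrow(tracks[[1]]$windows)
  sig <- rowMeans(sapply(tracks, function(t) {
    if (nrow(t$windows) != n) stop("mean_track: tracks not window-aligned")
    t$signal
  }), na.rm = TRUE)
  sig[is.nan(sig)] <- NA_real_
  enrichment_track(tracks[[1]]$windows, sig, method = tracks[[1]]$method,
                   meta = tracks[[1]]$meta[setdiff(names(tracks[[1]]$meta), "replicate")])
}

#' Call windows gaining or losing H3K9me3 between ages
#'
#' Threshold-based calls on the ratio of replicate-mean signal: a window is a
#' `loss` when young/old >= `fold` and a `gain` when old/young >= `fold`
#' (threshold inclusive); windows where either mean is undefined or
#' non-positive are `none`. No p-values and no multiple-testing correction
#' are involved — the calls are pure fold-change thresholds.
#'
#' @param young,old window-aligned replicate-mean [enrichment_track()]s.
#' @param fold call threshold (default 1.5).
#' @return A `window_call_set`: data frame with window coordinates,
#'   `compartment`, `young`, `old`, `fold_change` (old/young) and `call` in
#'   gain/loss/none.
#' @export
call_windows <- function(young, old, fold = 1.5) {
  stopifnot(inherits(young, "enrichment_track"), inherits(old, "enrichment_track"))
  if (nrow(young$windows) != nrow(old$windows)) stop("call_windows: misaligned tracks")
  y <- young$signal
  o <- old$signal
  ok <- !is.na(y) & !is.na(o) & y > 0 & o > 0
  fc <- ifelse(ok, o / y, NA_real_)
  call <- rep("none", length(y))
  call[ok & (y / o >= fold)] <- "loss"
  call[ok & (o / y >= fold)] <- "gain"
  out <- young$windows[, c("chrom", "start", "end", "compartment")]
  out$young <- y
  out$old <- o
  out$fold_change <- fc
  out$call <- call
  structure(out, class = c("window_call_set", "data.frame"), fold = fold)
}

#' Fisher's exact test for the sex comparison of window calls
#'
#' Two-sided exact p for the 2x2 table (called, not-called) x (male, female),
#' under the conventional rule: the sum of probabilities of all tables with
#' the observed margins whose hypergeometric probability does not exceed the
#' observed table's.
#'
#' @param loss_m,total_m called and total analyzable windows in males.
#' @param loss_f,total_f the same for females.
#' @return two-sided p-value.
#' @export
fisher_sex_compare <- function(loss_m, total_m, loss_f, total_f) {
  counts <- c(loss_m, total_m, loss_f, total_f)
  if (any(counts < 0) || loss_m > total_m || loss_f > total_f) {
    stop("fisher_sex_compare: inconsistent counts")
  }
  tab <- matrix(c(loss_m, total_m - loss_m, loss_f, total_f - loss_f),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Breakdown of window calls by compartment
#'
#' @param calls a [call_windows()] result.
#' @param call which call class to tabulate (default `"loss"`).
#' @return data frame `compartment`, `n`, `percent` (percentages sum to 100
#'   over compartments within the call class); zero rows for an empty class.
#' @export
compartment_breakdown <- function(calls, call = "loss") {
  stopifnot(inherits(calls, "window_call_set"))
  sel <- calls[calls$call == call, ]
  if (!nrow(sel)) {
    return(data.frame(compartment = character(), n = integer(), percent = numeric()))
  }
  tab <- as.data.frame(table(compartment = sel$compartment), stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab$percent <- 100 * tab$n / sum(tab$n)
  tab
}

#' Aggregate a window signal into larger windows and subtract ages
#'
#' Re-bins per-window replicate-mean signal into coarser windows (mean of the
#' member windows) and returns the per-window difference young - old
#' (positive = loss with age), the display convention of the genome-wide
#' subtraction tracks.
#'
#' @param young,old window-aligned replicate-mean [enrichment_track()]s on the
#'   analysis grid.
#' @param agg_window coarser window size in bp (default 25000).
#' @return data frame `chrom`, `start`, `end`, `young`, `old`, `difference`.
#' @export
subtraction_track <- function(young, old, agg_window = 25000) {
  stopifnot(inherits(young, "enrichment_track"), inherits(old, "enrichment_track"))
  w <- young$windows
  bin_start <- (w$start %/% agg_window) * agg_window
  key <- paste(w$chrom, bin_start, sep = ":")
  agg <- function(x) tapply(x, key, mean, na.rm = TRUE)
  ym <- agg(young$signal)
  om <- agg(old$signal)
  starts <- tapply(bin_start, key, `[`, 1)
  ends <- tapply(w$end, key, max)
  chroms <- tapply(w$chrom, key, `[`, 1)
  out <- data.frame(chrom = as.character(chroms), start = as.numeric(starts),
                    end = as.numeric(ends), young = as.numeric(ym),
                    old = as.numeric(om), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out$difference <- out$young - out$old
  out
}

#' Mean enrichment binned by repeat fraction, per chromosome class
#'
#' Groups windows by chromosome class, bins them by repeat fraction and
#' reports per-bin mean signal with standard error — the summary used to
#' contrast the neo-Y against other chromosomes at matched repeat content
#' (e.g. the 30% deficit in windows >70% repeat-masked). Empty bins are
#' reported as missing, not zero.
#'
#' @param track an [enrichment_track()].
#' @param group_by character vector, one class label per window (e.g. the
#'   chromosome or compartment grouping).
#' @param bin_edges repeat-fraction bin edges partitioning `[0,1]`.
#' @return data frame `group`, `bin` (factor label), `bin_lo`, `bin_hi`, `n`,
#'   `mean`, `se` (sd/sqrt(n); NA for n < 2).
#' @export
repeat_binned_profile <- function(track, group_by,
                                  bin_edges = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(track, "enrichment_track"))
  w <- track$windows
  stopifnot(length(group_by) == nrow(w))
  if (bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1) {
    stop("repeat_binned_profile: bin edges must partition [0,1]")
  }
  bins <- cut(w$repeat_fraction, bin_edges, include.lowest = TRUE)
  grid <- expand.grid(group = unique(group_by), bin = levels(bins),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- group_by == grid$group[i] & !is.na(bins) & bins == grid$bin[i] &
      !is.na(track$signal)
    x <- track$signal[sel]
    lo <- bin_edges[match(grid$bin[i], levels(bins))]
    hi <- bin_edges[match(grid$bin[i], levels(bins)) + 1]
    data.frame(group = grid$group[i], bin = grid$bin[i], bin_lo = lo, bin_hi = hi,
               n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               se = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_)
  })
  do.call(rbind, res)
}

#' Average enrichment profile around transcription start sites
#'
#' Builds a strand-oriented metaprofile of signal at 100-bp resolution in a
#' +/- `flank` bp window around each TSS: minus-strand genes are reflected so
#' offsets always run promoter-upstream to downstream. Genes whose flank
#' exceeds the chromosome bounds contribute only their in-bounds bins. The
#' per-offset mean is taken across genes within each group.
#'
#' @param track an [enrichment_track()] on a 100-bp window grid.
#' @param genes a [gene_annotation()] with `chrom`, `tss_bp`, `strand` and a
#'   grouping column named by `group_col` (ignored if `group_col` is NULL).
#' @param flank half-width of the profile in bp (default 5000).
#' @param group_col optional column of `genes` defining profile groups.
#' @return data frame `group`, `offset` (bp relative to TSS, bin centers at
#'   100-bp steps; 101 bins for the default flank), `n`, `mean`.
#' @export
tss_metaprofile <- function(track, genes, flank = 5000, group_col = NULL) {
  stopifnot(inherits(track, "enrichment_track"))
  w <- track$windows
  res <- attr(w, "window_size")
  if (is.null(res)) res <- stats::median(w$end - w$start)
  offsets <- seq(-flank, flank, by = res)
  groups <- if (is.null(group_col)) rep("all", nrow(genes)) else genes[[group_col]]
  if (!nrow(genes)) stop("tss_metaprofile: no genes supplied")
  # index of the window containing a position, per chromosome
  out <- list()
  for (g in unique(groups)) {
    gsel <- genes[groups == g, , drop = FALSE]
    if (!nrow(gsel)) stop("tss_metaprofile: empty gene group ", g)
    acc_sum <- numeric(length(offsets))
    acc_n <- integer(length(offsets))
    for (i in seq_len(nrow(gsel))) {
      chrom <- gsel$chrom[i]
      widx <- which(w$chrom == chrom)
      if (!length(widx)) next
      strand_sign <- if (gsel$strand[i] == "+") 1 else -1
      pos <- gsel$tss_bp[i] + strand_sign * offsets
      bin <- findInterval(pos, c(w$start[widx], w$end[widx[length(widx)]]),
                          left.open = FALSE)
      inb <- bin >= 1 & bin <= length(widx) & pos >= w$start[widx[1]] &
        pos < w$end[widx[length(widx)]]
      vals <- rep(NA_real_, length(offsets))
      vals[inb] <- track$signal[widx[bin[inb]]]
      ok <- !is.na(vals)
      acc_sum[ok] <- acc_sum[ok] + vals[ok]
      acc_n[ok] <- acc_n[ok] + 1L
    }
    out[[g]] <- data.frame(group = g, offset = offsets, n = acc_n,
                           mean = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_))
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Overlap of the top signal quantile between two tracks
#'
#' Fraction of track A's top-`q` windows (within a domain, e.g. euchromatin)
#' that are also in track B's top-`q` set, as a percentage — the concordance
#' summary used to compare normalization methods.
#'
#' @param track_a,track_b window-aligned [enrichment_track()]s.
#' @param q upper quantile (default 0.20).
#' @param domain logical/integer index of windows to consider (default all).
#' @return percent of shared windows.
#' @export
top_quantile_overlap <- function(track_a, track_b, q = 0.20, domain = NULL) {
  stopifnot(inherits(track_a, "enrichment_track"), inherits(track_b, "enrichment_track"))
  idx <- seq_len(nrow(track_a$windows))
  if (!is.null(domain)) idx <- if (is.logical(domain)) which(domain) else domain
  a <- track_a$signal[idx]
  b <- track_b$signal[idx]
  ok <- !is.na(a) & !is.na(b)
  idx <- idx[ok]; a <- a[ok]; b <- b[ok]
  k <- max(1, floor(length(idx) * q))
  top_a <- idx[order(a, decreasing = TRUE)[seq_len(k)]]
  top_b <- idx[order(b, decreasing = TRUE)[seq_len(k)]]
  100 * length(intersect(top_a, top_b)) / length(top_a)
}

#' Pairwise Pearson correlation between replicate tracks
#'
#' @param tracks list of window-aligned [enrichment_track()]s.
#' @param domain logical/integer index of windows to use (conventionally the
#'   autosome + X 5-kb windows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicate_concordance <- function(tracks, domain = NULL) {
  stopifnot(length(tracks) >= 2)
  sig <- sapply(tracks, function(t) t$signal)
  if (!is.null(domain)) sig <- sig[if (is.logical(domain)) which(domain) else domain, ]
  nm <- vapply(seq_along(tracks), function(i) {
    m <- tracks[[i]]$meta
    if (length(m)) paste(m$sex, m$age, m$replicate, sep = "_") else paste0("track", i)
  }, character(1))
  colnames(sig) <- nm
  stats::cor(sig, use = "pairwise.complete.obs", method = "pearson")
}
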