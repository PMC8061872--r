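# shared fixtures: all built in code, no files

one_chrom_layout <- function(len, linkage = "autosome", side = "left",
                             name = "chrA", muller = "B") {
  genome_layout(data.frame(
    name = name, muller = muller, length_bp = len,
    centromere_side = side, linkage = linkage
  ))
}

# window table over a single chromosome with given repeat fractions
windows_with_rf <- function(rf, window_size, layout) {
  w <- partition_windows(layout, window_size)
  stopifnot(nrow(w) == length(rf))
  w$repeat_fraction <- rf
  w
}

# a minimal aligned track pair over n windows, all in one compartment
toy_windows <- function(n, window_size = 5000, compartment = "euchromatin") {
  layout <- one_chrom_layout(n * window_size)
  w <- partition_windows(layout, window_size)
  w$compartment <- compartment
  w$repeat_fraction <- 0.1
  w
}

toy_track <- function(counts, windows = toy_windows(length(counts)),
                      library_total = sum(counts), species = "sample",
                      meta = list()) {
  coverage_track(windows, counts, library_total, species = species, meta = meta)
}

toy_enrichment <- function(signal, windows = toy_windows(length(signal)),
                           meta = list()) {
  enrichment_track(windows, signal, method = "no_spike", meta = meta)
}

# independent brute-force two-sided Fisher p: enumerate every table with the
# observed margins, sum hypergeometric probabilities <= observed (with a
# small tolerance for ties, as the conventional definition requires)
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[a_range == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent hand product-limit estimator (deaths precede censorings at ties)
km_oracle <- function(time, death) {
  ut <- sort(unique(time[death]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & death)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}
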