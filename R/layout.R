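#' Genome layout
#'
#' A `genome_layout` is a data frame describing the chromosome complement of a
#' male/female diploid genome with a differentiated (neo-)Y: one row per
#' chromosome with its Muller element label, assembled length, the side of the
#' scaffold carrying the centromere, and its sex-linkage class. Optional
#' per-chromosome bookkeeping columns (`assembly_mb`, `euchromatic_mb`,
#' `pericentric_mb`, `repeatmasked_mb`) carry published one-decimal megabase
#' figures used by [karyotype_sum()].
#'
#' Sex-specific copy numbers implied by the linkage class:
#' males carry one X, one neo-X and one Y/neo-Y plus two copies of each
#' autosome and the dot; females carry two X, two neo-X, two of each autosome
#' and the dot, and no Y/neo-Y.
#'
#' @param chromosomes data frame with columns `name`, `muller`, `length_bp`,
#'   `centromere_side` (`"left"` or `"right"`) and `linkage` (one of `"X"`,
#'   `"neoX"`, `"Y_neoY"`, `"autosome"`, `"dot"`); extra columns are kept.
#' @return A `genome_layout` data frame.
#' @export
genome_layout <- function(chromosomes) {
  stopifnot(is.data.frame(chromosomes))
  req <- c("name", "muller", "length_bp", "centromere_side", "linkage")
  missing_cols <- setdiff(req, names(chromosomes))
  if (length(missing_cols)) {
    stop("genome_layout: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(chromosomes$name)) stop("genome_layout: chromosome names must be unique")
  if (any(chromosomes$length_bp <= 0)) stop("genome_layout: chromosome lengths must be positive")
  if (!all(chromosomes$centromere_side %in% c("left", "right"))) {
    stop("genome_layout: centromere_side must be 'left' or 'right'")
  }
  linkages <- c("X", "neoX", "Y_neoY", "autosome", "dot")
  if (!all(chromosomes$linkage %in% linkages)) {
    stop("genome_layout: linkage must be one of ", paste(linkages, collapse = ", "))
  }
  structure(as.data.frame(chromosomes), class = c("genome_layout", "data.frame"))
}

#' Published *D. miranda* karyotype
#'
#' The assembled MSH22 karyotype: per-chromosome assembled length, euchromatic
#' arm length, pericentric heterochromatin and repeat-masked bases (Mb, one
#' decimal), together with Muller labels and sex-linkage. The dot chromosome is
#' entirely pericentric (zero euchromatic arm). Lengths in bp are derived from
#' the Mb figures, optionally scaled down for simulation.
#'
#' @param scale multiplicative factor applied to chromosome lengths (e.g.
#'   `1/500` for a miniature simulated genome). The Mb bookkeeping columns are
#'   left at published scale.
#' @return A [genome_layout()].
#' @export
miranda_layout <- function(scale = 1) {
  stopifnot(scale > 0)
  chr <- data.frame(
    name            = c("chrX", "chrNeoX", "chrY", "chr4", "chr2", "dot"),
    muller          = c("A-AD", "C", "Y-neoY", "B", "E", "F"),
    linkage         = c("X", "neoX", "Y_neoY", "autosome", "autosome", "dot"),
    centromere_side = c("right", "right", "right", "right", "right", "right"),
    assembly_mb     = c(77.6, 25.3, 92.1, 32.5, 35.3, 2.4),
    euchromatic_mb  = c(57.1, 21.9, NA, 29.1, 33.3, 0),
    pericentric_mb  = c(20.5, 3.4, NA, 3.4, 2.0, 2.4),
    repeatmasked_mb = c(28.9, 6.1, 76.8, 6.6, 6.2, 1.3),
    stringsAsFactors = FALSE
  )
  chr$length_bp <- round(chr$assembly_mb * 1e6 * scale)
  genome_layout(chr)
}

sex_copy_number <- function(linkage, sex) {
  sex <- match.arg(sex, c("male", "female", "haploid"))
  # "haploid" is the assembly view: one of each element, the Y/neo-Y not
  # double-counted against its X/neo-X homologs
  if (sex == "haploid") return(ifelse(linkage == "Y_neoY", 0L, 1L))
  cn <- ifelse(linkage %in% c("autosome", "dot"), 2L, 1L)
  if (sex == "female") {
    cn <- ifelse(linkage == "Y_neoY", 0L, ifelse(linkage %in% c("X", "neoX"), 2L, cn))
  }
  cn
}

#' Karyotype sums over a sex's chromosome complement
#'
#' Sums a per-chromosome megabase column over the copy numbers of a sex's
#' karyotype (male 2n, female 2n, or the haploid assembly). Published
#' per-chromosome values are one-decimal Mb, so sums inherit that precision.
#'
#' @param layout a [genome_layout()] carrying the Mb bookkeeping columns.
#' @param sex `"male"`, `"female"` or `"haploid"`.
#' @param column one of `"length"`, `"repeatmasked"`, `"euchromatic"`,
#'   `"pericentric"`.
#' @return Total in Mb. `NA` entries (e.g. the Y has no defined euchromatic
#'   arm) contribute zero with a warning.
#' @export
karyotype_sum <- function(layout, sex, column = c("length", "repeatmasked", "euchromatic", "pericentric")) {
  stopifnot(inherits(layout, "genome_layout"))
  column <- match.arg(column)
  col <- switch(column,
    length = "assembly_mb", repeatmasked = "repeatmasked_mb",
    euchromatic = "euchromatic_mb", pericentric = "pericentric_mb"
  )
  if (!col %in% names(layout)) stop("karyotype_sum: layout lacks column ", col)
  cn <- sex_copy_number(layout$linkage, sex)
  vals <- layout[[col]]
  if (anyNA(vals[cn > 0])) {
    warning("karyotype_sum: NA entries in '", column, "' treated as 0")
    vals[is.na(vals)] <- 0
  }
  sum(vals * cn)
}

#' Gene density in genes per Mb
#'
#' @param n_genes gene count.
#' @param span_mb span in Mb, must be positive.
#' @return `n_genes / span_mb`, rounded to the nearest integer (the convention
#'   used when quoting densities like "61 genes/Mb").
#' @export
gene_density <- function(n_genes, span_mb) {
  stopifnot(n_genes >= 0)
  if (span_mb <= 0) stop("gene_density: span must be positive")
  round(n_genes / span_mb)
}

#' Tile chromosomes into fixed-size windows
#'
#' Partitions every chromosome of a layout into non-overlapping half-open
#' windows (0-based, BED convention) of `window_size` bp; the terminal window
#' of each chromosome may be shorter. Tiling is delegated to
#' [GenomicRanges::tileGenome()].
#'
#' @param layout a [genome_layout()].
#' @param window_size window width in bp (>= 100; 5000 for the standard
#'   analysis grid, 25000 for display tracks, 100 for TSS profiles).
#' @return A `window_table`: data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `repeat_fraction` (`NA` until populated) and `compartment`
#'   (`NA` until assigned); the window size is kept as an attribute.
#' @export
partition_windows <- function(layout, window_size = 5000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(window_size) || window_size < 100) {
    stop("partition_windows: window_size must be >= 100 bp")
  }
  lens <- stats::setNames(layout$length_bp, layout$name)
  gr <- GenomicRanges::tileGenome(lens, tilewidth = window_size,
                                  cut.last.tile.in.chrom = TRUE)
  win <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    repeat_fraction = NA_real_,
    compartment = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(win, class = c("window_table", "data.frame"), window_size = window_size)
}

window_chrom_distance <- function(windows, layout) {
  # midpoint distance of each window from the centromere-bearing chromosome end
  side <- stats::setNames(layout$centromere_side, layout$name)
  len <- stats::setNames(layout$length_bp, layout$name)
  mid <- (windows$start + windows$end) / 2
  ifelse(side[windows$chrom] == "left", mid, len[windows$chrom] - mid)
}

#' Label windows as pericentromeric by repeat density
#'
#' Applies the boundary rule used to separate euchromatic chromosome arms from
#' pericentromeric heterochromatin: starting at the centromere end of each
#' chromosome, repeat fraction is averaged over a sliding `scan_window` (100 kb
#' by default, stepping by the analysis window size); the boundary is placed at
#' the first offset, moving away from the centromere, where the sliding average
#' drops below `threshold` (a window exactly at the threshold counts as
#' pericentromeric). All windows centromere-side of the boundary are labelled
#' `pericentromere`; the rest of the arm is `euchromatin`. Dot-chromosome
#' windows are labelled `dot` (the dot has no euchromatic arm). Y/neo-Y windows
#' are labelled `neoY_arm`, except a configured pericentromeric span at the
#' centromere end of the scaffold labelled `neoY_pericentromere` (the neo-Y
#' boundary is set from independent evidence, not from the repeat scan).
#'
#' @param windows a `window_table` with populated `repeat_fraction`.
#' @param layout the [genome_layout()] the windows tile.
#' @param threshold repeat-masked fraction cutoff (default 0.40).
#' @param scan_window sliding-window width in bp (default 100000).
#' @param neoy_pericentromere_bp span (bp) at the centromere end of the Y/neo-Y
#'   scaffold to label `neoY_pericentromere`; 0 for none.
#' @return The window table with `compartment` filled in.
#' @export
assign_pericentromere <- function(windows, layout, threshold = 0.40,
                                  scan_window = 100000,
                                  neoy_pericentromere_bp = 0) {
  stopifnot(inherits(windows, "window_table"), inherits(layout, "genome_layout"))
  if (anyNA(windows$repeat_fraction)) stop("assign_pericentromere: repeat fractions missing")
  if (any(windows$repeat_fraction < 0 | windows$repeat_fraction > 1)) {
    stop("assign_pericentromere: repeat fractions must lie in [0,1]")
  }
  step <- attr(windows, "window_size")
  comp <- rep(NA_character_, nrow(windows))
  dist <- window_chrom_distance(windows, layout)
  for (i in seq_len(nrow(layout))) {
    chrom <- layout$name[i]
    idx <- which(windows$chrom == chrom)
    if (!length(idx)) next
    if (layout$linkage[i] == "dot") {
      comp[idx] <- "dot"
      next
    }
    if (layout$linkage[i] == "Y_neoY") {
      comp[idx] <- ifelse(dist[idx] < neoy_pericentromere_bp,
                          "neoY_pericentromere", "neoY_arm")
      next
    }
    d <- dist[idx]
    w <- windows$end[idx] - windows$start[idx]
    rf <- windows$repeat_fraction[idx]
    len <- layout$length_bp[i]
    boundary <- 0
    k <- 0
    repeat {
      lo <- k * step
      if (lo >= len) { boundary <- len; break }
      hi <- lo + scan_window
      in_scan <- d > lo & d <= min(hi, len)
      if (!any(in_scan)) { boundary <- lo; break }
      m <- sum(rf[in_scan] * w[in_scan]) / sum(w[in_scan])
      if (m < threshold) { boundary <- lo; break }
      k <- k + 1
    }
    comp[idx] <- ifelse(d <= boundary & boundary > 0, "pericentromere", "euchromatin")
  }
  windows$compartment <- comp
  windows
}

#' Gene annotation table
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `tss_bp`, `strand`
#'   (`"+"`/`"-"`), and optionally `compartment` and `expression_level`.
#' @param layout layout used to bound-check TSS coordinates.
#' @return validated data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, layout = NULL) {
  req <- c("gene_id", "chrom", "tss_bp", "strand")
  if (!all(req %in% names(genes))) stop("gene_annotation: need columns ", paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene_annotation: gene_id must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene_annotation: strand must be '+' or '-'")
  if (!is.null(layout)) {
    len <- stats::setNames(layout$length_bp, layout$name)
    if (any(genes$tss_bp < 0 | genes$tss_bp > len[genes$chrom])) {
      stop("gene_annotation: TSS outside chromosome bounds")
    }
  }
  structure(as.data.frame(genes), class = c("gene_annotation", "data.frame"))
}
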