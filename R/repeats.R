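#' Per-family ChIP enrichment, copy-number aware
#'
#' Enrichment of a repeat family is the ratio of its autosome-median-scaled
#' ChIP coverage to its autosome-median-scaled Input coverage:
#' `(chip/chip_med) / (input/input_med)`. Because the Input carries each
#' family's genomic copy number, dividing ChIP by Input cancels copy number:
#' doubling a family's copies (doubling both ChIP and Input coverage) leaves
#' enrichment unchanged, as does rescaling either library's depth.
#'
#' @param chip_counts,input_counts named numeric vectors of mean coverage per
#'   family for one ChIP/Input pair.
#' @param chip_auto_median,input_auto_median the per-library median autosome
#'   coverage scalars used for depth normalization.
#' @return named vector of enrichment; `NA` where Input coverage is zero.
#' @export
repeat_chip_enrichment <- function(chip_counts, input_counts,
                                   chip_auto_median, input_auto_median) {
  if (length(chip_counts) != length(input_counts)) {
    stop("repeat_chip_enrichment: family vectors differ in length")
  }
  if (chip_auto_median <= 0 || input_auto_median <= 0) {
    stop("repeat_chip_enrichment: autosome median scalars must be positive")
  }
  chip_n <- chip_counts / chip_auto_median
  input_n <- input_counts / input_auto_median
  out <- ifelse(input_n > 0, chip_n / input_n, NA_real_)
  names(out) <- names(chip_counts)
  out
}

#' Per-family enrichment split by chromosome class
#'
#' Applies [repeat_chip_enrichment()] within each chromosome class (e.g.
#' `autosome_X` vs `neoY`), supporting the contrast of a family's neo-Y copies
#' against its copies elsewhere. A family absent from a class (zero Input
#' there) is reported missing, not zero.
#'
#' @param chip_by_class,input_by_class named lists of per-family coverage
#'   vectors, one element per chromosome class.
#' @param chip_auto_median,input_auto_median depth scalars (shared across
#'   classes — they come from whole-library autosome coverage).
#' @return data frame `family`, `class`, `enrichment`.
#' @export
per_chromosome_enrichment <- function(chip_by_class, input_by_class,
                                      chip_auto_median, input_auto_median) {
  stopifnot(identical(names(chip_by_class), names(input_by_class)))
  res <- lapply(names(chip_by_class), function(cl) {
    e <- repeat_chip_enrichment(chip_by_class[[cl]], input_by_class[[cl]],
                                chip_auto_median, input_auto_median)
    data.frame(family = names(e), class = cl, enrichment = unname(e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify repeat families as Y-enriched from gDNA coverage
#'
#' Ranks families by depth-normalized log2(male/female) genomic coverage and
#' flags those at or above a log-ratio threshold as Y-enriched. Depth
#' normalization divides each sex's family coverage by a single-copy
#' (non-repeat) depth scalar, since total repeat coverage itself differs
#' between the sexes.
#'
#' @param gdna_male,gdna_female named per-family coverage vectors.
#' @param male_depth,female_depth single-copy depth scalars.
#' @param threshold_log2 log2 ratio cutoff (default 0.585, i.e. 1.5-fold).
#' @return data frame `family`, `log2_mf`, `y_enriched`.
#' @export
classify_y_enrichment <- function(gdna_male, gdna_female,
                                  male_depth = 1, female_depth = 1,
                                  threshold_log2 = 0.585) {
  if (length(gdna_male) != length(gdna_female)) {
    stop("classify_y_enrichment: coverage vectors differ in length")
  }
  if (any(gdna_male <= 0) || any(gdna_female <= 0)) {
    stop("classify_y_enrichment: zero coverage; families must have positive coverage in both sexes")
  }
  lr <- log2((gdna_male / male_depth) / (gdna_female / female_depth))
  data.frame(
    family = if (!is.null(names(gdna_male))) names(gdna_male) else seq_along(gdna_male),
    log2_mf = unname(lr),
    y_enriched = unname(lr >= threshold_log2),
    stringsAsFactors = FALSE
  )
}

#' Remove rRNA features before normalization
#'
#' rRNA abundance differences between total-RNA libraries are technical, so
#' rRNA-flagged rows are dropped before size-factor estimation.
#'
#' @param counts features x samples count matrix.
#' @param is_rrna logical vector over rows.
#' @return the filtered matrix; error if nothing remains.
#' @export
filter_rrna <- function(counts, is_rrna) {
  stopifnot(length(is_rrna) == nrow(counts))
  out <- counts[!is_rrna, , drop = FALSE]
  if (!nrow(out)) stop("filter_rrna: no features left after rRNA removal")
  out
}

#' Median-of-ratios library size factors
#'
#' For each sample, the size factor is the median over features of
#' count/geometric-mean, where the geometric mean is taken per feature across
#' samples and features containing any zero are excluded from the median.
#'
#' @param counts features x samples count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) stop("size_factors: no feature has all-positive counts")
  lg <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  sf
}

# NB log-likelihood for one feature under a two-group log-link GLM
# mu_j = sf_j * exp(b0 + b1 * x_j); variance mu + alpha mu^2.
nb_feature_fit <- function(k, sf, x, alpha_floor = 1e-8) {
  grp_mean <- function(g) max(sum(k[x == g]) / sum(sf[x == g]), 1e-8)
  q0 <- grp_mean(0); q1 <- grp_mean(1)
  z <- k / sf
  mom <- function(g) {
    zz <- z[x == g]
    if (length(zz) < 2) return(NA_real_)
    m <- max(mean(zz), 1e-8)
    (stats::var(zz) - m) / m^2
  }
  a0 <- stats::median(c(mom(0), mom(1)), na.rm = TRUE)
  if (!is.finite(a0) || a0 < 1e-4) a0 <- 1e-4
  # Cox-Reid adjusted likelihood: the 0.5*logdet(X'WX) term corrects the
  # downward bias of per-feature ML dispersion at few residual df
  nll <- function(th) {
    mu <- sf * exp(th[1] + th[2] * x)
    a <- exp(th[3])
    w <- mu / (1 + a * mu)
    cr <- 0.5 * determinant(crossprod(cbind(1, x) * sqrt(w)), logarithm = TRUE)$modulus
    -sum(stats::dnbinom(k, mu = mu, size = 1 / a, log = TRUE)) + as.numeric(cr)
  }
  start <- c(log(q0), log(q1) - log(q0), log(a0))
  fit <- try(stats::optim(start, nll, method = "L-BFGS-B",
                          lower = c(-30, -30, log(alpha_floor)),
                          upper = c(30, 30, 5)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    fit <- list(par = start, convergence = 1L)
  }
  b0 <- fit$par[1]; b1 <- fit$par[2]; alpha <- exp(fit$par[3])
  mu <- sf * exp(b0 + b1 * x)
  w <- mu / (1 + alpha * mu)
  X <- cbind(1, x)
  info <- t(X) %*% (w * X)
  se <- tryCatch(sqrt(solve(info)[2, 2]), error = function(e) NA_real_)
  list(b1 = b1, se = se, alpha = alpha)
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-feature NB GLM with log link on size-factor-normalized counts: group
#' means and a per-feature dispersion are fitted by maximum adjusted
#' (Cox-Reid) likelihood with a dispersion floor and no shrinkage across
#' features; the Wald statistic is the log2 fold change over its standard
#' error (from the Fisher information at the MLE), with two-sided p-values
#' from a t reference on the residual degrees of freedom.
#' BH-adjusted p-values are reported alongside, but the significance flag
#' follows the fold + raw-p convention: `|log2FC| >= lfc_threshold` and
#' `p < p_threshold`. All-zero features are excluded.
#'
#' @param counts features x samples integer matrix.
#' @param condition two-level factor/character vector over samples; fold
#'   changes are second level over first (by factor order).
#' @param sf optional size factors (computed by [size_factors()] if omitted).
#' @param lfc_threshold,p_threshold significance rule (defaults 0.58 and
#'   0.05, i.e. 1.5-fold at p < 0.05).
#' @param alpha_floor dispersion floor (default 1e-8).
#' @return data frame `feature`, `base_mean`, `log2fc`, `se`, `stat`, `p`,
#'   `padj`, `dispersion`, `significant`.
#' @export
nb_wald_de <- function(counts, condition, sf = NULL,
                       lfc_threshold = 0.58, p_threshold = 0.05,
                       alpha_floor = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("nb_wald_de: condition must have exactly two levels")
  if (min(table(condition)) < 2) stop("nb_wald_de: need >= 2 replicates per condition")
  if (is.null(sf)) sf <- size_factors(counts)
  x <- as.numeric(condition == levels(condition)[2])
  keep <- rowSums(counts) > 0
  res <- t(vapply(which(keep), function(i) {
    f <- nb_feature_fit(counts[i, ], sf, x, alpha_floor)
    c(f$b1, f$se, f$alpha)
  }, numeric(3)))
  log2fc <- res[, 1] / log(2)
  se_l2 <- res[, 2] / log(2)
  stat <- log2fc / se_l2
  # t reference on residual df: the Wald SE does not account for the
  # estimated dispersion, and the normal reference is anticonservative at
  # few replicates
  df_resid <- ncol(counts) - 2L
  p <- 2 * stats::pt(-abs(stat), df = df_resid)
  out <- data.frame(
    feature = rownames(counts)[keep],
    base_mean = rowMeans(sweep(counts[keep, , drop = FALSE], 2, sf, "/")),
    log2fc = log2fc, se = se_l2, stat = stat, p = p,
    padj = stats::p.adjust(p, method = "BH"),
    dispersion = res[, 3],
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$p) & abs(out$log2fc) >= lfc_threshold &
    out$p < p_threshold
  rownames(out) <- NULL
  out
}

#' Copy-number-normalized expression
#'
#' Divides each feature's expression in each sample by its copy number in
#' that sample's sex, isolating expression differences beyond genomic dosage:
#' if male/female expression is exactly proportional to male/female copies,
#' the normalized ratio is 1.
#'
#' @param expr features x samples matrix of (normalized) expression.
#' @param copies_male,copies_female per-feature copy numbers (positive).
#' @param sex character vector over samples (`"male"`/`"female"`).
#' @return matrix of expression per copy.
#' @export
copy_number_normalized_expression <- function(expr, copies_male, copies_female, sex) {
  expr <- as.matrix(expr)
  stopifnot(length(copies_male) == nrow(expr), length(copies_female) == nrow(expr),
            length(sex) == ncol(expr))
  if (any(copies_male <= 0) || any(copies_female <= 0)) {
    stop("copy_number_normalized_expression: copy numbers must be positive")
  }
  out <- expr
  for (j in seq_len(ncol(expr))) {
    cp <- if (sex[j] == "male") copies_male else copies_female
    out[, j] <- expr[, j] / cp
  }
  out
}

#' Fraction of transcripts derived from repeats
#'
#' Percentage of retained (non-rRNA) transcripts assigned to repeat features
#' (TEs + satellites), per sample, averaged within condition groups.
#'
#' @param counts features x samples matrix (rRNA already removed).
#' @param feature_type character per row: `"gene"`, `"TE"`, `"satellite"`.
#' @param group character per sample (e.g. `"male_young"`); per-sample values
#'   are averaged within group.
#' @return data frame `group`, `percent`.
#' @export
repeat_transcript_fraction <- function(counts, feature_type, group) {
  counts <- as.matrix(counts)
  stopifnot(length(feature_type) == nrow(counts), length(group) == ncol(counts))
  rep_rows <- feature_type %in% c("TE", "satellite")
  per_sample <- 100 * colSums(counts[rep_rows, , drop = FALSE]) / colSums(counts)
  agg <- tapply(per_sample, group, mean)
  data.frame(group = names(agg), percent = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Share of TE transcripts by chromosome class of origin
#'
#' @param origin_counts data frame with per-family transcript counts
#'   attributed per chromosome class, columns `neoY` and `autosome_X`
#'   (summed over families/samples).
#' @return data frame `class`, `percent` (sums to 100).
#' @export
origin_split_expression <- function(origin_counts) {
  tot <- c(autosome_X = sum(origin_counts$autosome_X),
           neoY = sum(origin_counts$neoY))
  if (sum(tot) == 0) stop("origin_split_expression: no counts")
  data.frame(class = names(tot), percent = as.numeric(100 * tot / sum(tot)),
             stringsAsFactors = FALSE)
}
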