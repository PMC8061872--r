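#' Kaplan-Meier survivorship curve
#'
#' Product-limit estimate of the survival function from right-censored
#' lifespan records, with Greenwood variance and log-log 95% confidence
#' bands (which stay inside [0,1]). Deaths precede censorings at tied times
#' (the standard convention). Computed through [survival::survfit()].
#'
#' @param records data frame with `time_days` (> 0) and `event` (`"death"` /
#'   `"censored"`).
#' @param conf_level confidence level (default 0.95).
#' @return A `survival_curve`: data frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se` (Greenwood SE of S), `lower`, `upper`, with the
#'   underlying `survfit` object as an attribute.
#' @export
kaplan_meier <- function(records, conf_level = 0.95) {
  if (!nrow(records)) stop("kaplan_meier: empty input")
  if (any(records$time_days <= 0)) stop("kaplan_meier: times must be positive")
  status <- as.integer(records$event == "death")
  if (!any(status == 1)) stop("kaplan_meier: no death events")
  fit <- survival::survfit(survival::Surv(records$time_days, status) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  out <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    se = fit$surv * fit$std.err,   # std.err is on the log-S scale
    lower = fit$lower, upper = fit$upper
  )
  structure(out, class = c("survival_curve", "data.frame"), fit = fit,
            n = nrow(records))
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest time at which the survival estimate falls to 0.5 or below.
#' When the curve never reaches 0.5 (heavy censoring or a stopped assay), the
#' median is unresolved and reported as exceeding the last observed time.
#'
#' @param curve a [kaplan_meier()] result.
#' @return numeric median in days; `NA` with attributes `gt` (the bound) and
#'   a `"> t"` label when unresolved.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- which(curve$surv <= 0.5)
  if (!length(idx)) {
    bound <- max(curve$time)
    return(structure(NA_real_, gt = bound, label = paste0("> ", bound)))
  }
  structure(curve$time[min(idx)], label = as.character(curve$time[min(idx)]))
}

#' Kaplan-Meier curves and medians by group
#'
#' @param records lifespan records with a `sex` (or other grouping) column.
#' @param by grouping column name (default `"sex"`).
#' @return named list of lists, one per group: `curve`, `median`,
#'   `median_label`.
#' @export
survivorship_by_group <- function(records, by = "sex") {
  groups <- unique(records[[by]])
  out <- lapply(groups, function(g) {
    cur <- kaplan_meier(records[records[[by]] == g, ])
    med <- median_survival(cur)
    list(curve = cur, median = as.numeric(med),
         median_label = attr(med, "label"))
  })
  stats::setNames(out, groups)
}
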