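# Kaplan-Meier estimation and log-rank comparison of carrier groups
# (thin, validated wrappers around the survival package).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; censored subjects leave the risk set without
#' a drop.  Ties are handled by the standard convention: a subject
#' censored at an event time remains in that time's risk set.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return Data frame with `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic, chi-square with
#' k - 1 degrees of freedom.  With `pairwise = TRUE` every pair of
#' groups is tested and the pairwise p-values are BH-adjusted.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param groups group labels (>= 2 nonempty groups).
#' @param pairwise also test all group pairs.
#' @return List with `chisq`, `df`, `p` and (if requested) a `pairwise`
#'   data frame with raw and BH-adjusted p-values.
#' @export
logrank_test <- function(times, events, groups, pairwise = FALSE) {
  if (any(times <= 0)) stop("times must be positive")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("at least two nonempty groups are required")
  groups <- droplevels(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  out <- list(chisq = sd$chisq, df = df,
              p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  if (pairwise) {
    lv <- levels(groups)
    prs <- utils::combn(lv, 2)
    praw <- apply(prs, 2L, function(pair) {
      sel <- groups %in% pair
      sdp <- survival::survdiff(
        survival::Surv(times[sel], events[sel]) ~ droplevels(groups[sel]))
      stats::pchisq(sdp$chisq, 1, lower.tail = FALSE)
    })
    out$pairwise <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                               p = praw, p_adj = bh_adjust(praw))
  }
  out
}

#' Compare survival of gene-set carriers against non-carriers
#'
#' The carrier group holds patients carrying at least one gene of
#' `gene_set` (`mode = "any"`, default) or all of them (`mode =
#' "all"`); survival is compared by log-rank and per-group median
#' survival is reported.
#'
#' @param surv data frame with `patient_id`, `time_days`, `event`.
#' @param burden a `burden_matrix` covering the same patients.
#' @param gene_set nonempty character vector of gene symbols.
#' @param mode `"any"` or `"all"`.
#' @return List with `test` (see [logrank_test()]), `medians` (named:
#'   carrier / noncarrier) and the logical `carrier` vector.
#' @export
compare_carriers <- function(surv, burden, gene_set,
                             mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (length(gene_set) == 0) stop("'gene_set' must not be empty")
  genes <- intersect(gene_set, rownames(burden$carrier))
  if (length(genes) == 0)
    stop("none of the genes in 'gene_set' are present in the burden matrix")
  idx <- match(surv$patient_id, burden$patients)
  if (any(is.na(idx)))
    stop("survival table contains patients absent from the burden matrix: ",
         paste(surv$patient_id[is.na(idx)], collapse = ", "))
  sub <- burden$carrier[genes, idx, drop = FALSE]
  carrier <- if (mode == "any") colSums(sub) > 0 else colSums(sub) == length(genes)
  if (all(carrier) || !any(carrier))
    stop("all patients fall in a single group; cannot compare")
  test <- logrank_test(surv$time_days, surv$event,
                       ifelse(carrier, "carrier", "noncarrier"))
  med <- vapply(c(carrier = TRUE, noncarrier = FALSE), function(g) {
    fit <- survival::survfit(
      survival::Surv(surv$time_days[carrier == g], surv$event[carrier == g]) ~ 1)
    unname(stats::quantile(fit, probs = 0.5)$quantile)
  }, 1)
  list(test = test, medians = med, carrier = carrier)
}
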