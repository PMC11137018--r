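# Feature heterogeneity summaries and recursive correlation pruning.

#' Coefficient of variation per feature
#'
#' Sample standard deviation (n - 1 denominator) divided by the absolute
#' mean, so sign conventions do not flip the heterogeneity ranking.
#' Features with zero mean get `Inf` and are flagged in the
#' `zero_mean` attribute.
#'
#' @param mat patients x features numeric matrix (>= 2 patients).
#' @return Named numeric vector of CVs.
#' @export
coefficient_of_variation <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("at least 2 patients are required")
  mu <- colMeans(mat)
  s <- apply(mat, 2L, stats::sd)
  cv <- ifelse(mu == 0, Inf, s / abs(mu))
  names(cv) <- colnames(mat)
  attr(cv, "zero_mean") <- names(cv)[mu == 0]
  cv
}

#' Recursive correlation pruning
#'
#' Repeatedly removes the feature with the most remaining partners at
#' `|Pearson r| > cutoff` (ties broken by larger mean `|r|` over the
#' remaining set, then lexicographically by name) until no pair exceeds
#' the cutoff.  Survivors are the representatives; every removed feature
#' is assigned to the surviving feature it correlates with most.
#' Constant features (undefined correlation) are treated as
#' uncorrelated, always retained, and reported in `flagged_constant`.
#'
#' @param mat patients x features numeric matrix.
#' @param cutoff absolute correlation cutoff in (0, 1) (default 0.8).
#' @return List with `retained` (character), `removed`, `assignment`
#'   (named character: removed -> representative) and
#'   `flagged_constant`.
#' @export
correlation_prune <- function(mat, cutoff = 0.8) {
  mat <- as.matrix(mat)
  if (cutoff <= 0 || cutoff >= 1) stop("'cutoff' must be in (0, 1)")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  sds <- apply(mat, 2L, stats::sd)
  constant <- colnames(mat)[sds == 0]
  r <- suppressWarnings(abs(stats::cor(mat)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  alive <- rep(TRUE, ncol(mat))
  names(alive) <- colnames(mat)
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    deg <- rowSums(sub > cutoff)
    if (!length(deg) || max(deg) == 0) break
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      meanr <- rowMeans(sub[cand, , drop = FALSE])
      cand <- cand[meanr == max(meanr)]
      cand <- sort(cand)[1]
    }
    alive[cand] <- FALSE
  }
  retained <- names(alive)[alive]
  removed <- names(alive)[!alive]
  assignment <- character(0)
  if (length(removed)) {
    assignment <- vapply(removed, function(f) {
      rr <- r[f, retained]
      retained[which.max(rr)]
    }, "")
  }
  list(retained = retained, removed = removed, assignment = assignment,
       flagged_constant = constant)
}
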