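# Variance-component (SKAT-type) association scan between radiomic
# features and per-gene somatic genotypes.
#
# For a quantitative trait y (one radiomic feature), covariates X
# (intercept + top mutation PCs) and a variants x patients 0/1 matrix G
# with weights w, the score statistic is
#     Q = r' G' W^2 G r,   r = residuals of y ~ X,
# and under the null Q ~ sum_i lambda_i chi^2_1 with lambda the
# eigenvalues of sigma^2 W G P G' W, P = I - X (X'X)^-1 X'.

#' Top principal components of the somatic mutation matrix
#'
#' Column-centers the patient x gene carrier matrix and takes the top-k
#' left singular vectors scaled by their singular values (patient
#' scores).  Signs are fixed so each component's largest-magnitude gene
#' loading is positive.  If the numerical rank of the centered matrix is
#' below `k`, the trailing components are ~0 and flagged with a warning
#' and a `deficient` attribute.
#'
#' @param carrier genes x patients 0/1 matrix (or a `burden_matrix`).
#' @param k number of components (default 2).
#' @return patients x k matrix of PC scores.
#' @export
mutation_pcs <- function(carrier, k = 2) {
  if (inherits(carrier, "burden_matrix")) carrier <- carrier$carrier
  M <- t(carrier)                          # patients x genes
  n <- nrow(M)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " patients")
  if (k > min(n - 1L, ncol(M)))
    stop("k = ", k, " exceeds the achievable rank ", min(n - 1L, ncol(M)))
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  signs <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% diag(signs, k)
  rownames(scores) <- rownames(M)
  colnames(scores) <- paste0("PC", seq_len(k))
  if (rank < k) {
    warning("mutation matrix has rank ", rank, " < k = ", k,
            "; trailing component(s) are numerically zero")
    attr(scores, "deficient") <- seq(rank + 1L, k)
  }
  scores
}

#' Tail probability of a nonnegative mixture of chi-squares
#'
#' `P(sum_i lambda_i chi^2_1 > q)`.  The default `"imhof"` method
#' numerically inverts the characteristic function (exact up to
#' quadrature error, with the exact scaled-chi-square closed form when
#' all eigenvalues coincide) and is accurate over the whole
#' distribution.  `"liu"` moment-matches a (noncentral) chi-square
#' surrogate on the mean, variance and skewness; it is fast and
#' accurate in the right tail but distorts the left tail when one
#' eigenvalue dominates.
#'
#' @param lambda nonnegative eigenvalues, not all zero.
#' @param q quantile (scalar).
#' @param method `"imhof"` or `"liu"`.
#' @return Tail probability in `[0, 1]`.
#' @export
mixture_chisq_pvalue <- function(lambda, q, method = c("imhof", "liu")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("'lambda' must contain a positive eigenvalue")
  if (diff(range(lambda)) <= 1e-12 * max(lambda))   # scaled chi-square
    return(stats::pchisq(q / max(lambda), df = length(lambda),
                         lower.tail = FALSE))
  if (method == "liu") {
    c1 <- sum(lambda); c2 <- sum(lambda^2)
    c3 <- sum(lambda^3); c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
      a <- 1 / (s1 - sqrt(s1^2 - s2))
      delta <- s1 * a^3 - a^2
      l <- a^2 - 2 * delta
    } else {
      delta <- 0
      a <- 1 / s1
      l <- a^2
    }
    mu_x <- l + delta; sigma_x <- sqrt(2) * a
    tstar <- (q - c1) / sqrt(2 * c2)
    stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                  lower.tail = FALSE)
  } else {
    integrand <- function(u) {
      theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
      rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
      sin(theta) / (u * rho)
    }
    val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-6,
                            abs.tol = 1e-8, subdivisions = 1000L,
                            stop.on.error = FALSE)$value
    min(1, max(0, 0.5 + val / pi))
  }
}

#' Variance-component score test for one gene
#'
#' Fits the linear null model `y ~ X`, forms the weighted quadratic
#' score statistic over the gene's genotypes and evaluates its
#' mixture-of-chi-square tail.
#'
#' @param y numeric trait vector (one radiomic feature), length n.
#' @param G variants x patients 0/1 genotype matrix (a single variant
#'   may be given as a vector).
#' @param X covariate matrix including an intercept; default intercept
#'   only.
#' @param weights per-variant weights (>= 0); default 1.
#' @param method tail method, see [mixture_chisq_pvalue()].
#' @return List with `Q`, `lambda` and `p`.
#' @export
skat_test <- function(y, G, X = NULL, weights = 1,
                      method = c("imhof", "liu")) {
  method <- match.arg(method)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  n <- length(y)
  if (ncol(G) != n) stop("'G' must have one column per patient")
  if (is.null(X)) X <- matrix(1, n, 1)
  if (qr(X)$rank < ncol(X)) stop("'X' is rank deficient")
  w <- rep_len(weights, nrow(G))
  if (any(w < 0)) stop("weights must be nonnegative")
  if (stats::sd(y) == 0) {
    warning("zero-variance trait; p = 1")
    return(list(Q = 0, lambda = numeric(0), p = 1))
  }
  qrX <- qr(X)
  r <- qr.resid(qrX, y)
  sigma2 <- sum(r^2) / (n - qrX$rank)
  if (all(G == 0)) return(list(Q = 0, lambda = numeric(0), p = 1))
  WG <- G * w
  Q <- sum((WG %*% r)^2)
  PGt <- qr.resid(qrX, t(WG))              # n x m
  A <- sigma2 * (WG %*% PGt)               # m x m
  lambda <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  list(Q = Q, lambda = lambda,
       p = mixture_chisq_pvalue(lambda, Q, method))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (a validated wrapper around
#' [stats::p.adjust()]).
#'
#' @param pvals p-values in `[0, 1]`.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Radiome-wide x gene-wide association scan
#'
#' Tests every (gene, feature) pair with the variance-component score
#' test.  Covariates default to an intercept plus the top-`k_pcs`
#' principal components of the gene-level carrier matrix.  `mode
#' "skat"` uses the per-gene variant x patient genotype matrices; `mode
#' "burden"` collapses each gene to its carrier indicator (a single
#' regressor, equivalent to a classical score test).
#'
#' @param features patients x features numeric matrix.
#' @param burden a `burden_matrix` (see [gene_carrier_matrix()],
#'   typically after [filter_genes()]).
#' @param covariates optional patients x q covariate matrix (no
#'   intercept column; one is added); `NULL` computes mutation PCs.
#' @param k_pcs number of mutation PCs when `covariates` is `NULL`.
#' @param alpha significance threshold on the raw p-value (default
#'   1e-4, the genome-wide calling rule); BH-adjusted p-values are
#'   reported alongside.
#' @param mode `"skat"` or `"burden"`.
#' @param weights per-variant weights for `mode = "skat"`.
#' @param method tail method, see [mixture_chisq_pvalue()].
#' @param trait_transform `"inverse_normal"` (default) maps each feature
#'   to normal scores by a rank-based (Blom) transform before testing;
#'   radiomic features are often heavily right-skewed (zone-size and
#'   cluster statistics), which breaks the Gaussian error model of the
#'   score test and miscalibrates its p-values.  `"none"` tests the raw
#'   values.
#' @return Data frame with one row per (gene, feature): `gene`,
#'   `feature`, `Q`, `p`, `p_adj`, `significant`.
#' @export
associate_all <- function(features, burden, covariates = NULL, k_pcs = 2,
                          alpha = 1e-4, mode = c("skat", "burden"),
                          weights = 1, method = c("imhof", "liu"),
                          trait_transform = c("inverse_normal", "none")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  trait_transform <- match.arg(trait_transform)
  features <- as.matrix(features)
  if (trait_transform == "inverse_normal") {
    rn <- rownames(features)
    features <- apply(features, 2L, function(v)
      stats::qnorm((rank(v) - 0.375) / (length(v) + 0.25)))
    rownames(features) <- rn
  }
  pats_f <- rownames(features)
  pats_b <- burden$patients
  if (!is.null(pats_f) && !setequal(pats_f, pats_b))
    stop("patient sets differ; only in features: ",
         paste(setdiff(pats_f, pats_b), collapse = ", "),
         "; only in burden: ",
         paste(setdiff(pats_b, pats_f), collapse = ", "))
  if (!is.null(pats_f)) features <- features[pats_b, , drop = FALSE]
  n <- nrow(features)
  if (is.null(covariates))
    covariates <- mutation_pcs(burden$carrier, k = k_pcs)
  X <- cbind(Intercept = 1, covariates)
  qrX <- qr(X)
  genes <- burden$genes
  feats <- colnames(features)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(features)))
  # residualize all traits once; per gene, the eigenvalues scale with
  # the trait's sigma^2, so the base spectrum is computed once per gene
  R <- qr.resid(qrX, features)
  sigma2 <- colSums(R^2) / (n - qrX$rank)
  res <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    G <- if (mode == "skat") burden$genotypes[[g]] else
      matrix(burden$carrier[g, ], nrow = 1)
    G <- G[, pats_b, drop = FALSE]
    WG <- G * rep_len(weights, nrow(G))
    Qs <- colSums((WG %*% R)^2)
    PGt <- qr.resid(qrX, t(WG))
    A <- WG %*% PGt
    base_lambda <- eigen((A + t(A)) / 2, symmetric = TRUE,
                         only.values = TRUE)$values
    base_lambda <- base_lambda[base_lambda > max(base_lambda, 0) * 1e-10]
    ps <- vapply(seq_along(feats), function(fi) {
      if (sigma2[fi] == 0 || !length(base_lambda)) return(1)
      mixture_chisq_pvalue(base_lambda * sigma2[fi], Qs[fi], method)
    }, 1)
    res[[gi]] <- data.frame(gene = g, feature = feats, Q = Qs, p = ps,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out
}
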