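# Variance-component score test, mixture tails, PCs and BH adjustment.

test_that("single-variant SKAT equals the classical score test", {
  set.seed(3)
  for (i in 1:5) {
    n <- 26
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n)
    g <- rbinom(n, 1, 0.4)
    if (sum(g) %in% c(0, n)) next
    st <- skat_test(y, g, X)
    qrX <- qr(X)
    r <- qr.resid(qrX, y)
    s2 <- sum(r^2) / (n - qrX$rank)
    z <- sum(g * r) / sqrt(s2 * sum(qr.resid(qrX, g)^2))
    expect_equal(st$p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-8)
  }
})

test_that("degenerate genotype and trait inputs return p = 1", {
  y <- rnorm(10)
  expect_equal(skat_test(y, matrix(0, 3, 10))$p, 1)
  expect_warning(st <- skat_test(rep(2, 10), matrix(rbinom(10, 1, .5), 1)),
                 "zero-variance")
  expect_equal(st$p, 1)
})

test_that("mixture tail matches chi-square closed forms", {
  expect_equal(mixture_chisq_pvalue(1, 3.841459), 0.05, tolerance = 1e-6)
  q2 <- stats::qchisq(0.95, 2)
  for (m in c("imhof", "liu"))
    expect_equal(mixture_chisq_pvalue(c(1, 1), q2, m),
                 0.05, tolerance = 1e-6)
  # monotone nonincreasing in q
  lam <- c(2, 1, 0.5)
  qs <- seq(0.1, 20, length.out = 30)
  ps <- vapply(qs, function(q) mixture_chisq_pvalue(lam, q), 1)
  expect_true(all(diff(ps) <= 1e-10))
  expect_error(mixture_chisq_pvalue(c(0, 0), 1), "positive eigenvalue")
})

test_that("mixture tail matches Monte-Carlo within 3 SE", {
  lam <- c(2, 1, 0.5)
  set.seed(7)
  nmc <- 200000
  draws <- colSums(lam * matrix(stats::rchisq(3 * nmc, 1), 3))
  for (q in c(1, 3, 6, 10)) {
    mc <- mean(draws > q)
    se <- sqrt(mc * (1 - mc) / nmc)
    expect_lt(abs(mixture_chisq_pvalue(lam, q) - mc), 3 * se)
  }
})

test_that("SKAT p agrees with a residual-permutation null", {
  # the permutation null conditions on the observed residuals, so it
  # differs from the Gaussian theory by O(1/n); n = 100 keeps that gap
  # below the Monte-Carlo allowance
  set.seed(21)
  n <- 100
  X <- cbind(1, rnorm(n))
  G <- matrix(rbinom(5 * n, 1, 0.2), 5, n)
  y <- rnorm(n)
  st <- skat_test(y, G, X)
  qrX <- qr(X)
  r <- qr.resid(qrX, y)
  B <- 50000
  perm <- replicate(B, sum((G %*% sample(r))^2))
  p_emp <- (sum(perm >= st$Q) + 1) / (B + 1)
  se <- sqrt(p_emp * (1 - p_emp) / B)
  expect_lt(abs(st$p - p_emp), 3 * se + 0.01)
})

test_that("Q is invariant to adding covariate-column multiples to y", {
  set.seed(22)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  G <- matrix(rbinom(4 * n, 1, 0.3), 4, n)
  y <- rnorm(n)
  a <- skat_test(y, G, X)
  b <- skat_test(y + 3 * X[, 2] - 1.5 * X[, 3] + 7, G, X)
  expect_equal(a$Q, b$Q, tolerance = 1e-10)
})

test_that("p-values are invariant to consistent patient reordering", {
  set.seed(23)
  n <- 24
  X <- cbind(1, rnorm(n))
  G <- matrix(rbinom(3 * n, 1, 0.3), 3, n)
  y <- rnorm(n)
  o <- sample(n)
  a <- skat_test(y, G, X)
  b <- skat_test(y[o], G[, o], X[o, ])
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("mutation PCs are orthogonal, sign-fixed and rank-checked", {
  set.seed(24)
  cm <- matrix(rbinom(30 * 15, 1, 0.3), 30, 15,
               dimnames = list(paste0("g", 1:30), paste0("P", 1:15)))
  pc <- mutation_pcs(cm, 2)
  expect_lt(abs(sum(pc[, 1] * pc[, 2])), 1e-10)
  expect_error(mutation_pcs(cm[1:3, ], 4), "achievable rank")
  expect_error(mutation_pcs(cm, 20), "at least")
  # rank-1 matrix: second component ~0 and flagged
  r1 <- outer(c(rep(1, 10), rep(0, 20)), rbinom(15, 1, 0.5))
  dimnames(r1) <- dimnames(cm)
  expect_warning(pc2 <- mutation_pcs(r1, 2), "rank")
  expect_lt(max(abs(pc2[, 2])), 1e-10)
  expect_equal(attr(pc2, "deficient"), 2)
})

test_that("PC1 separates a planted two-cluster structure beyond permutation", {
  set.seed(25)
  n <- 20
  grp <- rep(0:1, each = n / 2)
  cm <- t(vapply(1:40, function(g) rbinom(n, 1, 0.15 + 0.6 * grp), numeric(n)))
  dimnames(cm) <- list(paste0("g", 1:40), paste0("P", 1:n))
  v1 <- function(m) {
    sv <- svd(scale(t(m), center = TRUE, scale = FALSE))$d
    sv[1]^2 / sum(sv^2)
  }
  obs <- v1(cm)
  perm <- vapply(1:100, function(i)
    v1(t(apply(cm, 1, sample))), 1)
  expect_gt(obs, max(perm))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(26)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the scan covers every gene-feature pair and flags by raw p", {
  spec <- cohort_spec(n_patients = 12)
  vt <- generate_variant_table(spec, seed = 31)
  tab <- filter_consequence(filter_somatic(vt$variants))
  bm <- filter_genes(gene_carrier_matrix(tab), 3)
  set.seed(32)
  fm <- matrix(rnorm(12 * 4), 12, 4,
               dimnames = list(bm$patients, paste0("f", 1:4)))
  res <- associate_all(fm, bm, alpha = 0.5)
  expect_equal(nrow(res), length(bm$genes) * 4)
  expect_true(all(res$p_adj >= res$p))
  expect_equal(res$significant, res$p < 0.5)
  # mismatched patients are reported
  rownames(fm)[1] <- "NOPE"
  expect_error(associate_all(fm, bm), "NOPE")
})
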