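# Gray-level texture matrices (GLCM, GLRLM, GLSZM, NGTDM, GLDM) computed
# on a discretized VOI, and the statistics derived from them.
#
# All matrices aggregate the 13 unique 3D directions at distance 1 (the
# 26-neighbourhood modulo sign).  Degenerate inputs (a single voxel, a
# single gray level, empty pair sets, 0/0 ratios) yield 0 for every
# derived statistic except where a feature has a natural value there
# (e.g. Idmn of a constant VOI is 1); each such rule is applied in the
# feature function itself.

# 13 unique direction offsets: first nonzero component positive.
unique_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1L, function(o) o[which(o != 0)[1]] > 0)
  unname(g[keep, , drop = FALSE])
}

all_directions <- function() {
  u <- unique_directions()
  rbind(u, -u)
}

# Subarray index ranges such that voxel v and v + off are both in-grid.
offset_ranges <- function(dims, off) {
  a <- lapply(1:3, function(k) {
    lo <- max(1L, 1L - off[k]); hi <- min(dims[k], dims[k] - off[k])
    if (lo > hi) integer(0) else lo:hi
  })
  b <- lapply(1:3, function(k) a[[k]] + off[k])
  list(a = a, b = b)
}

texture_matrix <- function(kind, counts, n_levels, extra = list()) {
  s <- sum(counts)
  structure(c(list(kind = kind, counts = counts,
                   p = if (s > 0) counts / s else counts,
                   n_levels = n_levels, n_total = s), extra),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s, %d gray levels, %g entries\n",
              x$kind, x$n_levels, x$n_total))
  invisible(x)
}

#' Gray-level co-occurrence matrix
#'
#' Co-occurrence counts over the 13 unique directions at distance 1,
#' symmetrized and summed over directions; voxel pairs with either member
#' outside the mask are ignored.
#'
#' @param d a [discretize()]d VOI.
#' @return A `texture_matrix` of kind `"GLCM"` with counts and the
#'   normalized probabilities `p`.
#' @export
glcm_matrix <- function(d) {
  L <- d$levels
  dims <- dim(L)
  Ng <- d$n_levels
  counts <- matrix(0, Ng, Ng)
  for (i in seq_len(nrow(unique_directions()))) {
    off <- unique_directions()[i, ]
    r <- offset_ranges(dims, off)
    A <- L[r$a[[1]], r$a[[2]], r$a[[3]], drop = FALSE]
    B <- L[r$b[[1]], r$b[[2]], r$b[[3]], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (any(ok)) {
      tb <- tabulate((A[ok] - 1L) * Ng + B[ok], nbins = Ng * Ng)
      counts <- counts + matrix(tb, Ng, Ng, byrow = TRUE)
    }
  }
  counts <- counts + t(counts)
  texture_matrix("GLCM", counts, Ng)
}

#' Features of a normalized gray-level co-occurrence matrix
#'
#' Implements the 24 standard co-occurrence statistics (cluster moments,
#' contrast/homogeneity family, entropies, informational measures of
#' correlation, MCC, sum/difference statistics).
#'
#' @param M a `texture_matrix` of kind `"GLCM"`.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(M) {
  nm <- glcm_feature_names()
  out <- stats::setNames(numeric(length(nm)), nm)
  if (M$n_total == 0) return(out)              # single-voxel VOI: all 0
  p <- M$p
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM is not normalized")
  Ng <- M$n_levels
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sdx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  dk <- 0:(Ng - 1)
  pxmy <- vapply(dk, function(k) sum(p[abs(i - j) == k]), 1)
  sk <- 2:(2 * Ng)
  pxpy <- vapply(sk, function(k) sum(p[(i + j) == k]), 1)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  da <- sum(dk * pxmy)
  hx <- ent(px); hy <- ent(py); hxy <- ent(p)
  pp <- outer(px, py)
  pos <- p > 0 & pp > 0
  hxy1 <- -sum(p[pos] * log2(pp[pos]))
  hxy2 <- ent(pp)
  out["Autocorrelation"] <- sum(i * j * p)
  out["JointAverage"] <- mux
  out["ClusterProminence"] <- sum((i + j - mux - muy)^4 * p)
  out["ClusterShade"] <- sum((i + j - mux - muy)^3 * p)
  out["ClusterTendency"] <- sum((i + j - mux - muy)^2 * p)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlation"] <- if (sdx * sdy > 0)
    (sum(i * j * p) - mux * muy) / (sdx * sdy) else 1
  out["DifferenceAverage"] <- da
  out["DifferenceEntropy"] <- ent(pxmy)
  out["DifferenceVariance"] <- sum((dk - da)^2 * pxmy)
  out["Id"] <- sum(p / (1 + abs(i - j)))
  out["Idm"] <- sum(p / (1 + (i - j)^2))
  out["Idmn"] <- sum(p / (1 + (i - j)^2 / Ng^2))
  out["Idn"] <- sum(p / (1 + abs(i - j) / Ng))
  out["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  iv <- p / (i - j)^2
  out["InverseVariance"] <- sum(iv[i != j])
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- hxy
  out["MCC"] <- glcm_mcc(p, px, py)
  out["MaximumProbability"] <- max(p)
  out["SumAverage"] <- sum(sk * pxpy)
  out["SumEntropy"] <- ent(pxpy)
  out["SumSquares"] <- sum((i - mux)^2 * p)
  out
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue
# of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)); 1 when degenerate.
glcm_mcc <- function(p, px, py) {
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  ps <- p[keep, keep, drop = FALSE]
  pxs <- px[keep]; pys <- py[keep]
  Q <- (ps / pxs) %*% t(ps / rep(pys, each = nrow(ps)))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, min(ev[2], 1)))
}

glcm_feature_names <- function() c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

#' Gray-level run-length matrix
#'
#' Maximal runs of equal gray level along each of the 13 directions
#' (runs broken by out-of-mask voxels), counts summed over directions.
#'
#' @param d a [discretize()]d VOI.
#' @param directions integer matrix of direction offsets (rows), first
#'   nonzero component positive; default all 13 unique directions.
#' @return A `texture_matrix` of kind `"GLRLM"`; rows are gray levels,
#'   columns run lengths.
#' @export
glrlm_matrix <- function(d, directions = unique_directions()) {
  L <- d$levels
  dims <- dim(L)
  Ng <- d$n_levels
  idx <- which(!is.na(L), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty VOI")
  lev <- L[idx]
  K <- max(dims) + 2L
  dirs <- directions
  lev_all <- integer(0); len_all <- integer(0)
  for (i in seq_len(nrow(dirs))) {
    off <- dirs[i, ]
    a0 <- which(off != 0)[1]
    t <- idx[, a0]                       # increases by 1 per step (off[a0]=+1)
    key <- idx - t %o% off
    kk <- (key[, 1] + K) + (key[, 2] + K) * (3L * K) +
      (key[, 3] + K) * (3L * K)^2
    o <- order(kk, t)
    ks <- kk[o]; ts <- t[o]; ls <- lev[o]
    n <- length(ks)
    newrun <- if (n == 1) TRUE else
      c(TRUE, ks[-1] != ks[-n] | ts[-1] != ts[-n] + 1L | ls[-1] != ls[-n])
    rid <- cumsum(newrun)
    len_all <- c(len_all, tabulate(rid))
    lev_all <- c(lev_all, ls[newrun])
  }
  maxlen <- max(len_all)
  counts <- matrix(0, Ng, maxlen)
  tb <- tabulate((lev_all - 1L) * maxlen + len_all, nbins = Ng * maxlen)
  counts <- matrix(tb, Ng, maxlen, byrow = TRUE)
  texture_matrix("GLRLM", counts, Ng,
                 extra = list(n_voxels = nrow(idx),
                              n_directions = nrow(dirs)))
}

# Shared machinery for run-length / size-zone / dependence statistics:
# counts C(i, j) with gray level i and a size-like attribute j.
ij_stats <- function(M) {
  C <- M$counts
  N <- sum(C)
  p <- if (N > 0) C / N else C
  list(C = C, p = p, N = N, i = row(C), j = col(C),
       pi = rowSums(p), pj = colSums(p),
       si = rowSums(C), sj = colSums(C))
}

ent2 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }

#' Run-length features
#'
#' The 16 standard GLRLM statistics, computed on the direction-summed
#' run-length matrix.  `RunPercentage` uses the total number of possible
#' run starts, voxels x directions, as its denominator.
#'
#' @param M a `texture_matrix` from [glrlm_matrix()].
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(M) {
  nm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
          "RunLengthNonUniformityNormalized", "RunPercentage",
          "GrayLevelVariance", "RunVariance", "RunEntropy",
          "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
          "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
          "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  out <- stats::setNames(numeric(length(nm)), nm)
  s <- ij_stats(M)
  if (s$N == 0) return(out)
  mu_i <- sum(s$p * s$i); mu_j <- sum(s$p * s$j)
  out["ShortRunEmphasis"] <- sum(s$p / s$j^2)
  out["LongRunEmphasis"] <- sum(s$p * s$j^2)
  out["GrayLevelNonUniformity"] <- sum(s$si^2) / s$N
  out["GrayLevelNonUniformityNormalized"] <- sum(s$si^2) / s$N^2
  out["RunLengthNonUniformity"] <- sum(s$sj^2) / s$N
  out["RunLengthNonUniformityNormalized"] <- sum(s$sj^2) / s$N^2
  out["RunPercentage"] <- s$N / (M$n_voxels * M$n_directions)
  out["GrayLevelVariance"] <- sum(s$p * (s$i - mu_i)^2)
  out["RunVariance"] <- sum(s$p * (s$j - mu_j)^2)
  out["RunEntropy"] <- ent2(s$p)
  out["LowGrayLevelRunEmphasis"] <- sum(s$p / s$i^2)
  out["HighGrayLevelRunEmphasis"] <- sum(s$p * s$i^2)
  out["ShortRunLowGrayLevelEmphasis"] <- sum(s$p / (s$i^2 * s$j^2))
  out["ShortRunHighGrayLevelEmphasis"] <- sum(s$p * s$i^2 / s$j^2)
  out["LongRunLowGrayLevelEmphasis"] <- sum(s$p * s$j^2 / s$i^2)
  out["LongRunHighGrayLevelEmphasis"] <- sum(s$p * s$i^2 * s$j^2)
  out
}

#' Run variance of a run-length matrix
#'
#' Variance of the run-length distribution pooled over gray levels and
#' directions.
#'
#' @param M a `texture_matrix` from [glrlm_matrix()].
#' @export
run_variance <- function(M) unname(glrlm_features(M)["RunVariance"])

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level; `S(i, j)`
#' counts zones of level `i` and size `j` voxels.
#'
#' @param d a [discretize()]d VOI.
#' @return A `texture_matrix` of kind `"GLSZM"`.
#' @export
glszm_matrix <- function(d) {
  L <- d$levels
  dims <- dim(L)
  Ng <- d$n_levels
  lin <- array(seq_len(prod(dims)), dims)
  fg <- which(!is.na(L))
  if (length(fg) == 0) stop("empty VOI")
  vid <- match(seq_len(prod(dims)), fg)    # linear index -> vertex id
  edges <- NULL
  dirs <- unique_directions()
  for (i in seq_len(nrow(dirs))) {
    r <- offset_ranges(dims, dirs[i, ])
    A <- L[r$a[[1]], r$a[[2]], r$a[[3]], drop = FALSE]
    B <- L[r$b[[1]], r$b[[2]], r$b[[3]], drop = FALSE]
    la <- lin[r$a[[1]], r$a[[2]], r$a[[3]], drop = FALSE]
    lb <- lin[r$b[[1]], r$b[[2]], r$b[[3]], drop = FALSE]
    ok <- !is.na(A) & !is.na(B) & A == B
    if (any(ok)) edges <- rbind(edges, cbind(vid[la[ok]], vid[lb[ok]]))
  }
  g <- igraph::make_graph(if (is.null(edges)) integer(0) else t(edges),
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_level <- L[fg][!duplicated(comp$membership)][
    order(unique(comp$membership))]
  maxsz <- max(zone_size)
  tb <- tabulate((zone_level - 1L) * maxsz + zone_size, nbins = Ng * maxsz)
  counts <- matrix(tb, Ng, maxsz, byrow = TRUE)
  texture_matrix("GLSZM", counts, Ng, extra = list(n_voxels = length(fg)))
}

#' Size-zone features
#'
#' The 16 standard GLSZM statistics, including `LargeAreaEmphasis` and
#' `LargeAreaHighGrayLevelEmphasis`.
#'
#' @param M a `texture_matrix` from [glszm_matrix()].
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(M) {
  nm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
          "SizeZoneNonUniformityNormalized", "ZonePercentage",
          "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
          "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
          "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  out <- stats::setNames(numeric(length(nm)), nm)
  s <- ij_stats(M)
  if (s$N == 0) return(out)
  mu_i <- sum(s$p * s$i); mu_j <- sum(s$p * s$j)
  out["SmallAreaEmphasis"] <- sum(s$p / s$j^2)
  out["LargeAreaEmphasis"] <- sum(s$p * s$j^2)
  out["GrayLevelNonUniformity"] <- sum(s$si^2) / s$N
  out["GrayLevelNonUniformityNormalized"] <- sum(s$si^2) / s$N^2
  out["SizeZoneNonUniformity"] <- sum(s$sj^2) / s$N
  out["SizeZoneNonUniformityNormalized"] <- sum(s$sj^2) / s$N^2
  out["ZonePercentage"] <- s$N / M$n_voxels
  out["GrayLevelVariance"] <- sum(s$p * (s$i - mu_i)^2)
  out["ZoneVariance"] <- sum(s$p * (s$j - mu_j)^2)
  out["ZoneEntropy"] <- ent2(s$p)
  out["LowGrayLevelZoneEmphasis"] <- sum(s$p / s$i^2)
  out["HighGrayLevelZoneEmphasis"] <- sum(s$p * s$i^2)
  out["SmallAreaLowGrayLevelEmphasis"] <- sum(s$p / (s$i^2 * s$j^2))
  out["SmallAreaHighGrayLevelEmphasis"] <- sum(s$p * s$i^2 / s$j^2)
  out["LargeAreaLowGrayLevelEmphasis"] <- sum(s$p * s$j^2 / s$i^2)
  out["LargeAreaHighGrayLevelEmphasis"] <- sum(s$p * s$i^2 * s$j^2)
  out
}

# Zero-padded shift: out[v] = a[v + off] (0 outside the grid).
shift_array <- function(a, off, fill = 0) {
  dims <- dim(a)
  out <- array(fill, dims)
  r <- offset_ranges(dims, off)
  out[r$a[[1]], r$a[[2]], r$a[[3]]] <- a[r$b[[1]], r$b[[2]], r$b[[3]]]
  out
}

#' Neighbouring gray-tone difference matrix
#'
#' For each gray level `i` present in the VOI: the voxel count `n_i`, its
#' proportion `p_i`, and `s_i`, the summed absolute difference between
#' `i` and the mean level of each voxel's valid (in-mask) 26-neighbours.
#' Voxels with no in-mask neighbour are excluded.
#'
#' @param d a [discretize()]d VOI.
#' @return A list of class `ngtdm` with `n`, `p`, `s` (per level) and
#'   `n_voxels`.
#' @export
ngtdm_matrix <- function(d) {
  L <- d$levels
  Ng <- d$n_levels
  Lz <- L; Lz[is.na(Lz)] <- 0L
  W <- array(as.numeric(!is.na(L)), dim(L))
  nb_sum <- array(0, dim(L)); nb_cnt <- array(0, dim(L))
  dirs <- all_directions()
  for (i in seq_len(nrow(dirs))) {
    nb_sum <- nb_sum + shift_array(Lz * W, dirs[i, ])
    nb_cnt <- nb_cnt + shift_array(W, dirs[i, ])
  }
  valid <- !is.na(L) & nb_cnt > 0
  lev <- L[valid]
  diff <- abs(lev - nb_sum[valid] / nb_cnt[valid])
  n <- tabulate(lev, nbins = Ng)
  s <- vapply(seq_len(Ng), function(i) sum(diff[lev == i]), 1)
  structure(list(kind = "NGTDM", n = n, s = s,
                 p = if (sum(n) > 0) n / sum(n) else n,
                 n_levels = Ng, n_voxels = sum(n)),
            class = "ngtdm")
}

#' Neighbouring gray-tone difference features
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength.  Ratios with
#' zero denominators (flat regions, a single present level) return 0.
#'
#' @param M an `ngtdm` object from [ngtdm_matrix()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(M) {
  nm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  out <- stats::setNames(numeric(5), nm)
  Nv <- M$n_voxels
  if (Nv == 0) return(out)
  present <- which(M$n > 0)
  Ngp <- length(present)
  p <- M$p; s <- M$s
  i <- present
  ps <- sum(p[i] * s[i])
  out["Coarseness"] <- if (ps > 0) 1 / ps else 0
  if (Ngp > 1) {
    pi_ <- p[i]
    dmat <- outer(i, i, "-")
    out["Contrast"] <- (sum(outer(pi_, pi_) * dmat^2) / (Ngp * (Ngp - 1))) *
      (sum(s[i]) / Nv)
    den <- sum(abs(outer(i * pi_, i * pi_, "-")))
    out["Busyness"] <- if (den > 0) ps / den else 0
    psi <- pi_ * s[i]
    num <- abs(dmat) * (outer(psi, rep(1, Ngp)) + outer(rep(1, Ngp), psi)) /
      (outer(pi_, pi_, "+"))
    out["Complexity"] <- sum(num[dmat != 0]) / Nv
    ssum <- sum(s[i])
    if (ssum > 0)
      out["Strength"] <- sum((outer(pi_, pi_, "+") * dmat^2)[dmat != 0]) / ssum
  }
  out
}

#' Gray-level dependence matrix
#'
#' The dependence of a voxel is 1 plus the number of in-mask 26-neighbours
#' whose gray level differs by at most `alpha` (default 0, exact
#' equality); `D(i, j)` counts voxels of level `i` with dependence `j`.
#'
#' @param d a [discretize()]d VOI.
#' @param alpha gray-level tolerance for dependence (default 0).
#' @return A `texture_matrix` of kind `"GLDM"`.
#' @export
gldm_matrix <- function(d, alpha = 0) {
  L <- d$levels
  Ng <- d$n_levels
  Lz <- L; Lz[is.na(Lz)] <- -10L * Ng     # never within alpha of a real level
  cnt <- array(0L, dim(L))
  dirs <- all_directions()
  for (i in seq_len(nrow(dirs))) {
    nb <- shift_array(Lz, dirs[i, ], fill = -10L * Ng)
    cnt <- cnt + (abs(nb - Lz) <= alpha)
  }
  fg <- !is.na(L)
  lev <- L[fg]
  dep <- cnt[fg] + 1L
  maxdep <- max(dep)
  tb <- tabulate((lev - 1L) * maxdep + dep, nbins = Ng * maxdep)
  counts <- matrix(tb, Ng, maxdep, byrow = TRUE)
  texture_matrix("GLDM", counts, Ng, extra = list(n_voxels = sum(fg)))
}

#' Gray-level dependence features
#'
#' The 14 standard GLDM statistics.
#'
#' @param M a `texture_matrix` from [gldm_matrix()].
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(M) {
  nm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
          "GrayLevelNonUniformity", "DependenceNonUniformity",
          "DependenceNonUniformityNormalized", "GrayLevelVariance",
          "DependenceVariance", "DependenceEntropy",
          "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
          "SmallDependenceLowGrayLevelEmphasis",
          "SmallDependenceHighGrayLevelEmphasis",
          "LargeDependenceLowGrayLevelEmphasis",
          "LargeDependenceHighGrayLevelEmphasis")
  out <- stats::setNames(numeric(length(nm)), nm)
  s <- ij_stats(M)
  if (s$N == 0) return(out)
  mu_i <- sum(s$p * s$i); mu_j <- sum(s$p * s$j)
  out["SmallDependenceEmphasis"] <- sum(s$p / s$j^2)
  out["LargeDependenceEmphasis"] <- sum(s$p * s$j^2)
  out["GrayLevelNonUniformity"] <- sum(s$si^2) / s$N
  out["DependenceNonUniformity"] <- sum(s$sj^2) / s$N
  out["DependenceNonUniformityNormalized"] <- sum(s$sj^2) / s$N^2
  out["GrayLevelVariance"] <- sum(s$p * (s$i - mu_i)^2)
  out["DependenceVariance"] <- sum(s$p * (s$j - mu_j)^2)
  out["DependenceEntropy"] <- ent2(s$p)
  out["LowGrayLevelEmphasis"] <- sum(s$p / s$i^2)
  out["HighGrayLevelEmphasis"] <- sum(s$p * s$i^2)
  out["SmallDependenceLowGrayLevelEmphasis"] <- sum(s$p / (s$i^2 * s$j^2))
  out["SmallDependenceHighGrayLevelEmphasis"] <- sum(s$p * s$i^2 / s$j^2)
  out["LargeDependenceLowGrayLevelEmphasis"] <- sum(s$p * s$j^2 / s$i^2)
  out["LargeDependenceHighGrayLevelEmphasis"] <- sum(s$p * s$i^2 * s$j^2)
  out
}
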