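# Independent brute-force oracles for the texture statistics: plain
# per-voxel enumeration, no texture matrices, used to cross-check the
# vectorized implementations on small VOIs.

oracle_dirs <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  unname(g[apply(g, 1, function(o) o[which(o != 0)[1]] > 0), , drop = FALSE])
}

in_grid <- function(v, dims) all(v >= 1) && all(v <= dims)

# all ordered co-occurring level pairs (both directions of the 13 offsets)
oracle_glcm_pairs <- function(levels) {
  dims <- dim(levels)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  pairs <- NULL
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(levels[x, y, z])) next
    for (k in seq_len(nrow(dirs))) {
      w <- c(x, y, z) + dirs[k, ]
      if (in_grid(w, dims) && !is.na(levels[w[1], w[2], w[3]]))
        pairs <- rbind(pairs, c(levels[x, y, z], levels[w[1], w[2], w[3]]))
    }
  }
  pairs
}

# list of all runs (level, length) for the 13 directions
oracle_runs <- function(levels) {
  dims <- dim(levels)
  out <- NULL
  for (k in seq_len(nrow(oracle_dirs()))) {
    off <- oracle_dirs()[k, ]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      v <- c(x, y, z)
      if (is.na(levels[x, y, z])) next
      prev <- v - off
      lv <- levels[x, y, z]
      starts <- !in_grid(prev, dims) || is.na(levels[prev[1], prev[2], prev[3]]) ||
        levels[prev[1], prev[2], prev[3]] != lv
      if (!starts) next
      len <- 0L
      w <- v
      while (in_grid(w, dims) && !is.na(levels[w[1], w[2], w[3]]) &&
             levels[w[1], w[2], w[3]] == lv) {
        len <- len + 1L
        w <- w + off
      }
      out <- rbind(out, c(lv, len))
    }
  }
  out
}

# list of all zones (level, size): recursive 26-connected flood fill
oracle_zones <- function(levels) {
  dims <- dim(levels)
  seen <- array(FALSE, dims)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  zones <- NULL
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(levels[x, y, z]) || seen[x, y, z]) next
    lv <- levels[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(dirs))) {
        w <- v + dirs[k, ]
        if (in_grid(w, dims) && !seen[w[1], w[2], w[3]] &&
            !is.na(levels[w[1], w[2], w[3]]) &&
            levels[w[1], w[2], w[3]] == lv) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    zones <- rbind(zones, c(lv, size))
  }
  zones
}

# per-voxel absolute difference to the mean of its valid neighbours,
# plus the per-voxel level, for NGTDM statistics
oracle_ngtdm_voxels <- function(levels) {
  dims <- dim(levels)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  lev <- NULL; dif <- NULL
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(levels[x, y, z])) next
    nb <- c()
    for (k in seq_len(nrow(dirs))) {
      w <- c(x, y, z) + dirs[k, ]
      if (in_grid(w, dims) && !is.na(levels[w[1], w[2], w[3]]))
        nb <- c(nb, levels[w[1], w[2], w[3]])
    }
    if (!length(nb)) next
    lev <- c(lev, levels[x, y, z])
    dif <- c(dif, abs(levels[x, y, z] - mean(nb)))
  }
  list(lev = lev, dif = dif)
}

oracle_ngtdm_features <- function(levels) {
  vx <- oracle_ngtdm_voxels(levels)
  Nv <- length(vx$lev)
  present <- sort(unique(vx$lev))
  Ngp <- length(present)
  p <- vapply(present, function(i) mean(vx$lev == i), 1)
  s <- vapply(present, function(i) sum(vx$dif[vx$lev == i]), 1)
  ps <- sum(p * s)
  contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  if (Ngp > 1) {
    acc_c <- 0; acc_b <- 0; acc_x <- 0; acc_s <- 0
    for (a in seq_len(Ngp)) for (b in seq_len(Ngp)) {
      acc_c <- acc_c + p[a] * p[b] * (present[a] - present[b])^2
      acc_b <- acc_b + abs(present[a] * p[a] - present[b] * p[b])
      if (a != b) {
        acc_x <- acc_x + abs(present[a] - present[b]) *
          (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
        acc_s <- acc_s + (p[a] + p[b]) * (present[a] - present[b])^2
      }
    }
    contrast <- acc_c / (Ngp * (Ngp - 1)) * sum(s) / Nv
    busy <- if (acc_b > 0) ps / acc_b else 0
    complexity <- acc_x / Nv
    strength <- if (sum(s) > 0) acc_s / sum(s) else 0
  }
  c(Coarseness = if (ps > 0) 1 / ps else 0, Contrast = contrast,
    Busyness = busy, Complexity = complexity, Strength = strength)
}

# per-voxel dependence counts (1 + equal-level in-mask neighbours)
oracle_gldm_voxels <- function(levels, alpha = 0) {
  dims <- dim(levels)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  lev <- NULL; dep <- NULL
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(levels[x, y, z])) next
    cnt <- 0L
    for (k in seq_len(nrow(dirs))) {
      w <- c(x, y, z) + dirs[k, ]
      if (in_grid(w, dims) && !is.na(levels[w[1], w[2], w[3]]) &&
          abs(levels[w[1], w[2], w[3]] - levels[x, y, z]) <= alpha)
        cnt <- cnt + 1L
    }
    lev <- c(lev, levels[x, y, z])
    dep <- c(dep, cnt + 1L)
  }
  list(lev = lev, dep = dep)
}

# random discretized VOI on a small grid
random_voi <- function(n = 5, n_levels = 4, p_mask = 0.8, seed = 1) {
  set.seed(seed)
  m <- array(stats::runif(n^3) < p_mask, c(n, n, n))
  if (!any(m)) m[1, 1, 1] <- TRUE
  lv <- array(NA_integer_, c(n, n, n))
  lv[m] <- sample.int(n_levels, sum(m), replace = TRUE)
  structure(list(levels = lv, mask = m, n_levels = max(lv[m]),
                 bin_width = 1, spacing = c(1, 1, 1)),
            class = "discretized_voi")
}

# weighted-mean helpers for pair/run/zone lists
pair_stat <- function(pairs, f) mean(f(pairs[, 1], pairs[, 2]))
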