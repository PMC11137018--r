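# Texture matrices: hand-worked examples and brute-force oracle
# equivalence on small random VOIs (the full 200-VOI sweep runs in the
# acceptance suite).

mk_voi <- function(levels) {
  lv <- as.array(levels)
  structure(list(levels = lv, mask = !is.na(lv),
                 n_levels = max(lv, na.rm = TRUE), bin_width = 1,
                 spacing = c(1, 1, 1)),
            class = "discretized_voi")
}

test_that("GLCM of a two-voxel VOI is the symmetric pair", {
  d <- mk_voi(array(c(1L, 2L), c(1, 1, 2)))
  M <- glcm_matrix(d)
  expect_equal(M$p, matrix(c(0, 0.5, 0.5, 0), 2))
})

test_that("GLCM of a single-voxel VOI yields all-zero features", {
  d <- mk_voi(array(1L, c(1, 1, 1)))
  fe <- glcm_features(glcm_matrix(d))
  expect_true(all(fe == 0))
})

test_that("checkerboard has no equal-level axial co-occurrences", {
  lv <- array(NA_integer_, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) lv[x, y, 1] <- 1L + (x + y) %% 2L
  M <- glcm_matrix(mk_voi(lv))
  # axial offsets always change parity; only diagonal offsets hit equals
  ax <- radscan:::offset_ranges(c(4, 4, 1), c(1, 0, 0))
  expect_equal(M$counts[1, 1] + M$counts[2, 2],
               2 * (2 * 3 * 3))              # the two in-plane diagonals
  d_ax <- 0
  for (off in list(c(1, 0, 0), c(0, 1, 0))) {
    A <- lv[radscan:::offset_ranges(c(4,4,1), off)$a[[1]],
            radscan:::offset_ranges(c(4,4,1), off)$a[[2]], 1]
    B <- lv[radscan:::offset_ranges(c(4,4,1), off)$b[[1]],
            radscan:::offset_ranges(c(4,4,1), off)$b[[2]], 1]
    d_ax <- d_ax + sum(A == B)
  }
  expect_equal(d_ax, 0)
})

test_that("GLCM features reproduce hand evaluation on a symmetric matrix", {
  M <- structure(list(kind = "GLCM", counts = matrix(1, 2, 2),
                      p = matrix(0.25, 2, 2), n_levels = 2L, n_total = 4),
                 class = "texture_matrix")
  fe <- glcm_features(M)
  expect_equal(unname(fe["ClusterShade"]), 0)
  expect_equal(unname(fe["Idmn"]), 0.5 + 0.5 / (1 + 1 / 4))  # = 0.9
  expect_equal(unname(fe["InverseVariance"]), 0.5)
  expect_error(glcm_features(structure(list(kind = "GLCM",
    counts = matrix(2, 2, 2), p = matrix(2, 2, 2), n_levels = 2L,
    n_total = 8), class = "texture_matrix")), "normalized")
})

test_that("constant VOI: Idmn is 1, contrast-type features are 0", {
  d <- mk_voi(array(1L, c(3, 3, 3)))
  fe <- glcm_features(glcm_matrix(d))
  expect_equal(unname(fe["Idmn"]), 1)
  expect_equal(unname(fe["Contrast"]), 0)
  expect_equal(unname(fe["ClusterShade"]), 0)
  expect_equal(unname(fe["ClusterProminence"]), 0)
})

test_that("single-direction runs match hand enumeration", {
  d <- mk_voi(array(c(1L, 1L, 2L, 2L), c(1, 1, 4)))
  M <- glrlm_matrix(d, directions = matrix(c(0, 0, 1), 1))
  expect_equal(M$counts, rbind(c(0, 1), c(0, 1)))  # runs {2, 2}
  expect_equal(run_variance(M), 0)
})

test_that("a constant line VOI gives one long run along its axis", {
  d <- mk_voi(array(1L, c(1, 1, 4)))
  M <- glrlm_matrix(d)
  # 12 off-axis directions give 4 unit runs each; the line axis gives 1 run of 4
  expect_equal(sum(M$counts), 12 * 4 + 1)
  expect_equal(M$counts[1, 4], 1)
})

test_that("all-distinct neighbours give all runs of length 1", {
  lv <- array(NA_integer_, c(2, 2, 2))
  lv[] <- 1:8
  M <- glrlm_matrix(mk_voi(lv))
  expect_equal(ncol(M$counts), 1L)
  expect_equal(run_variance(M), 0)
})

test_that("GLSZM hand examples", {
  # constant 3x3x3: one zone of 27
  fz <- glszm_features(glszm_matrix(mk_voi(array(1L, c(3, 3, 3)))))
  expect_equal(unname(fz["LargeAreaEmphasis"]), 729)
  expect_equal(unname(fz["LargeAreaHighGrayLevelEmphasis"]), 729)
  # all-distinct levels: every zone is a single voxel
  lv <- array(1:8, c(2, 2, 2))
  fz2 <- glszm_features(glszm_matrix(mk_voi(lv)))
  expect_equal(unname(fz2["LargeAreaEmphasis"]), 1)
  # two zones, sizes {1, 3}, levels {2, 1}
  lv3 <- array(NA_integer_, c(1, 1, 4))
  lv3[1, 1, ] <- c(2L, 1L, 1L, 1L)
  fz3 <- glszm_features(glszm_matrix(mk_voi(lv3)))
  expect_equal(unname(fz3["LargeAreaEmphasis"]), (1 + 9) / 2)
  expect_equal(unname(fz3["LargeAreaHighGrayLevelEmphasis"]),
               (4 * 1 + 1 * 9) / 2)
})

test_that("NGTDM degenerate rules and brute-force line example", {
  fe <- ngtdm_features(ngtdm_matrix(mk_voi(array(1L, c(3, 3, 3)))))
  expect_equal(unname(fe["Contrast"]), 0)
  expect_equal(unname(fe["Busyness"]), 0)
  d <- mk_voi(array(c(1L, 2L, 1L), c(1, 1, 3)))
  fe2 <- ngtdm_features(ngtdm_matrix(d))
  fo <- oracle_ngtdm_features(d$levels)
  expect_equal(fe2, fo, tolerance = 1e-12)
})

test_that("all matrices match brute-force enumeration on random VOIs", {
  for (s in 1:12) {
    d <- random_voi(5, 4, 0.8, seed = s)
    Ng <- d$n_levels
    pairs <- oracle_glcm_pairs(d$levels)
    Cm <- matrix(0, Ng, Ng)
    for (r in seq_len(nrow(pairs)))
      Cm[pairs[r, 1], pairs[r, 2]] <- Cm[pairs[r, 1], pairs[r, 2]] + 1
    expect_equal(glcm_matrix(d)$counts, Cm)
    runs <- oracle_runs(d$levels)
    Mr <- glrlm_matrix(d)
    expect_equal(sum(Mr$counts), nrow(runs))
    expect_equal(run_variance(Mr), mean((runs[, 2] - mean(runs[, 2]))^2),
                 tolerance = 1e-12)
    zones <- oracle_zones(d$levels)
    Mz <- glszm_matrix(d)
    expect_equal(sum(Mz$counts), nrow(zones))
    expect_equal(unname(glszm_features(Mz)["LargeAreaEmphasis"]),
                 mean(zones[, 2]^2), tolerance = 1e-12)
    expect_equal(ngtdm_features(ngtdm_matrix(d)),
                 oracle_ngtdm_features(d$levels), tolerance = 1e-12)
    vox <- oracle_gldm_voxels(d$levels)
    Md <- gldm_matrix(d)
    Cd <- matrix(0, Ng, max(vox$dep))
    for (r in seq_along(vox$lev))
      Cd[vox$lev[r], vox$dep[r]] <- Cd[vox$lev[r], vox$dep[r]] + 1
    expect_equal(Md$counts, Cd)
  }
})

test_that("normalized matrices sum to one", {
  for (s in 1:5) {
    d <- random_voi(5, 4, 0.7, seed = 100 + s)
    expect_equal(sum(glcm_matrix(d)$p), 1, tolerance = 1e-12)
    expect_equal(sum(glrlm_matrix(d)$p), 1, tolerance = 1e-12)
    expect_equal(sum(glszm_matrix(d)$p), 1, tolerance = 1e-12)
    expect_equal(sum(gldm_matrix(d)$p), 1, tolerance = 1e-12)
  }
})

test_that("direction-aggregated features are invariant to 90-degree rotation", {
  for (s in 1:3) {
    d <- random_voi(5, 4, 0.8, seed = 200 + s)
    rot <- function(a) aperm(a[, rev(seq_len(dim(a)[2])), , drop = FALSE],
                             c(2, 1, 3))   # 90 deg about z
    dr <- structure(list(levels = rot(d$levels), mask = rot(d$mask),
                         n_levels = d$n_levels, bin_width = 1,
                         spacing = c(1, 1, 1)), class = "discretized_voi")
    expect_equal(glcm_features(glcm_matrix(d)),
                 glcm_features(glcm_matrix(dr)), tolerance = 1e-9)
    expect_equal(glrlm_features(glrlm_matrix(d)),
                 glrlm_features(glrlm_matrix(dr)), tolerance = 1e-9)
    expect_equal(glszm_features(glszm_matrix(d)),
                 glszm_features(glszm_matrix(dr)), tolerance = 1e-9)
    expect_equal(ngtdm_features(ngtdm_matrix(d)),
                 ngtdm_features(ngtdm_matrix(dr)), tolerance = 1e-9)
    expect_equal(gldm_features(gldm_matrix(d)),
                 gldm_features(gldm_matrix(dr)), tolerance = 1e-9)
  }
})
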