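# Feature catalog structure and the extraction driver.

test_that("catalog enumerates the full canonical identifier set", {
  cat_df <- feature_catalog()
  expect_equal(nrow(cat_df), 944)
  expect_equal(sum(cat_df$filter == "original"), 107)
  expect_equal(sum(startsWith(cat_df$filter, "log.sigma")), 93)
  expect_equal(sum(startsWith(cat_df$filter, "wavelet")), 744)
  cls <- table(cat_df$class[cat_df$filter == "original"])
  expect_equal(as.integer(cls[c("shape", "firstorder", "glcm", "gldm",
                                "glrlm", "glszm", "ngtdm")]),
               c(14L, 18L, 24L, 14L, 16L, 16L, 5L))
  expect_true(all(c("wavelet.LHL.ngtdm.Contrast",
                    "original.glrlm.RunVariance",
                    "wavelet.LHH.firstorder.Skewness",
                    "wavelet.HHL.glszm.LargeAreaHighGrayLevelEmphasis",
                    "original.shape.Sphericity",
                    "original.glcm.Idmn") %in% cat_df$feature))
  expect_false(any(duplicated(cat_df$feature)))
  # shape only under the original filter
  expect_true(all(cat_df$filter[cat_df$class == "shape"] == "original"))
})

const_phantom <- function(n = 12) {
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  c0 <- (n + 1) / 2
  m <- array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= (n / 3)^2,
             c(n, n, n))
  list(image = volume_image(array(100, c(n, n, n)), c(2, 2, 2)),
       mask = voi_mask(m, c(2, 2, 2)))
}

test_that("a constant phantom yields the degenerate feature values", {
  ph <- const_phantom()
  fv <- extract_features(ph$image, ph$mask, feature_config(
    computed_features = c("original.firstorder.Skewness",
                          "original.glcm.Idmn",
                          "original.glcm.Contrast",
                          "original.ngtdm.Contrast",
                          "original.glszm.GrayLevelVariance")))
  expect_equal(unname(fv["original.firstorder.Skewness"]), 0)
  expect_equal(unname(fv["original.glcm.Idmn"]), 1)
  expect_equal(unname(fv["original.glcm.Contrast"]), 0)
  expect_equal(unname(fv["original.ngtdm.Contrast"]), 0)
  expect_equal(unname(fv["original.glszm.GrayLevelVariance"]), 0)
})

test_that("extraction is deterministic and shift-invariant", {
  tv <- generate_tumor_volume(phantom_params(grid_shape = c(14, 14, 14),
                                             ellipsoid_semi_axes = c(10, 9, 8)),
                              seed = 9)
  cfg <- feature_config(computed_features = default_scan_panel())
  f1 <- extract_features(tv$image, tv$mask, cfg)
  f2 <- extract_features(tv$image, tv$mask, cfg)
  expect_identical(f1, f2)
  # shifting intensities by a multiple of the bin width leaves every
  # discretized feature unchanged
  img2 <- volume_image(tv$image$values + 3 * 25, tv$image$spacing)
  f3 <- extract_features(img2, tv$mask, cfg)
  disc <- setdiff(names(f1), c("original.firstorder.Mean"))
  keep <- !grepl("firstorder", disc) | grepl("Skewness|Variance", disc)
  expect_equal(f1[disc[keep]], f3[disc[keep]], tolerance = 1e-9)
})

test_that("unknown feature names and misaligned masks are rejected", {
  ph <- const_phantom()
  expect_error(extract_features(ph$image, ph$mask,
    feature_config(computed_features = "original.glcm.NoSuchThing")),
    "unknown feature")
  bad <- voi_mask(array(TRUE, c(3, 3, 3)), c(2, 2, 2))
  expect_error(extract_features(ph$image, bad), "shapes differ")
})

test_that("feature matrices round-trip through TSV", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("P01", "P02"),
                              c("original.glcm.Idmn", "a.b.c", "d.e.f")))
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(m, f)
  expect_equal(read_feature_matrix(f), m, tolerance = 1e-12)
})
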