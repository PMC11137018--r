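# Synthetic cohort generators: determinism, calibration against their
# sampling models, and the texture response of the phantom.

test_that("phantom generation is a pure function of (params, seed)", {
  p <- phantom_params(grid_shape = c(12, 12, 12),
                      ellipsoid_semi_axes = c(8, 7, 6))
  a <- generate_tumor_volume(p, seed = 3)
  b <- generate_tumor_volume(p, seed = 3)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$mask$values, b$mask$values)
  c <- generate_tumor_volume(p, seed = 4)
  expect_false(identical(a$image$values, c$image$values))
})

test_that("oversized ellipsoids are rejected with the offending axis", {
  expect_error(phantom_params(grid_shape = c(10, 24, 24),
                              ellipsoid_semi_axes = c(16, 13, 11)),
               "axis 1")
})

test_that("a symmetric field has near-zero masked skewness", {
  p <- phantom_params(grid_shape = c(28, 28, 28),
                      ellipsoid_semi_axes = c(24, 22, 20),
                      skew_parameter = 0)
  sk <- vapply(1:8, function(s) {
    tv <- generate_tumor_volume(p, seed = s)
    skewness(tv$image$values[tv$mask$values])
  }, 1)
  expect_lt(abs(mean(sk)), 0.15)
  # positive skew parameter right-skews the masked intensities
  p2 <- phantom_params(grid_shape = c(28, 28, 28),
                       ellipsoid_semi_axes = c(24, 22, 20),
                       skew_parameter = 1)
  tv2 <- generate_tumor_volume(p2, seed = 1)
  expect_gt(skewness(tv2$image$values[tv2$mask$values]), 0.5)
})

test_that("finer texture raises NGTDM contrast (Monte-Carlo ordering)", {
  cfg <- feature_config(computed_features = "original.ngtdm.Contrast",
                        target_spacing = NULL)
  contrast <- function(l, s) {
    p <- phantom_params(correlation_length = l)
    tv <- generate_tumor_volume(p, seed = s)
    extract_features(tv$image, tv$mask, cfg)[1]
  }
  wins <- sum(vapply(1:20, function(s) contrast(2, s) > contrast(4, s), TRUE))
  expect_gte(wins, 15)   # majority over 20 paired seeds
})

test_that("carrier sampling matches its binomial model", {
  spec <- cohort_spec(gene_pool = c(ALW = 1.0, KRAS = 0.85, RARE = 0.1))
  vt <- generate_variant_table(spec, seed = 1)
  expect_equal(sum(vt$truth$carrier["ALW", ]), 26)
  # mean carrier count over many seeds within the binomial 99% CI of 22.1
  counts <- vapply(1:500, function(s)
    sum(generate_variant_table(spec, seed = s)$truth$carrier["KRAS", ]), 1)
  se <- sqrt(26 * 0.85 * 0.15 / 500)
  expect_lt(abs(mean(counts) - 26 * 0.85), 2.58 * se)
})

test_that("per-patient record counts follow the Poisson model", {
  spec <- cohort_spec()
  totals <- unlist(lapply(1:20, function(s) {
    vt <- generate_variant_table(spec, seed = 200 + s)
    as.numeric(table(vt$variants$patient_id))
  }))
  se <- sqrt(51 / length(totals))   # Poisson SE of the mean
  expect_lt(abs(mean(totals) - 51), 3 * se)
})

test_that("carriers always have at least one qualifying record", {
  spec <- cohort_spec(n_patients = 12)
  vt <- generate_variant_table(spec, seed = 77)
  qual <- filter_consequence(filter_somatic(vt$variants))
  bm <- gene_carrier_matrix(qual, patients = colnames(vt$truth$carrier))
  tr <- vt$truth$carrier[bm$genes, bm$patients]
  expect_true(all(bm$carrier == tr))
  # and every gene with a carrier in truth appears after filtering
  expect_setequal(bm$genes,
                  rownames(vt$truth$carrier)[rowSums(vt$truth$carrier) > 0])
})

test_that("empty gene pool is rejected", {
  expect_error(cohort_spec(gene_pool = numeric(0)), "empty")
})

test_that("survival generation respects censoring and hazard settings", {
  spec <- cohort_spec(censoring_rate = 0)
  s0 <- generate_survival(spec, rep(c(TRUE, FALSE), 13), seed = 1)
  expect_true(all(s0$event == 1))
  expect_error(generate_survival(spec, logical(0)), "empty")
  spec2 <- cohort_spec(censoring_rate = 0.3)
  s2 <- generate_survival(spec2, rep(FALSE, 2000), seed = 2)
  expect_gt(mean(s2$event == 0), 0.2)
  expect_lt(mean(s2$event == 0), 0.4)
})

test_that("a null hazard ratio yields calibrated log-rank rejections", {
  spec <- cohort_spec(hazard_ratio = 1, censoring_rate = 0.1)
  carr <- rep(c(TRUE, FALSE), each = 250)
  rej <- vapply(1:100, function(s) {
    sv <- generate_survival(spec, carr, seed = 300 + s)
    logrank_test(sv$time_days, sv$event, sv$carrier)$p < 0.05
  }, TRUE)
  expect_gte(mean(!rej), 0.9)
})

test_that("a hazard ratio of 3 shortens carrier survival almost surely", {
  spec <- cohort_spec(hazard_ratio = 3, censoring_rate = 0)
  carr <- rep(c(TRUE, FALSE), each = 200)
  worse <- vapply(1:100, function(s) {
    sv <- generate_survival(spec, carr, seed = 400 + s)
    median(sv$time_days[sv$carrier]) < median(sv$time_days[!sv$carrier])
  }, TRUE)
  expect_gte(sum(worse), 95)
})

test_that("simulated cohorts are reproducible and carry coherent truth", {
  spec <- cohort_spec(n_patients = 6)
  a <- simulate_cohort(spec, seed = 5)
  b <- simulate_cohort(spec, seed = 5)
  expect_identical(a$images[[3]]$values, b$images[[3]]$values)
  expect_identical(a$variants, b$variants)
  expect_identical(a$survival, b$survival)
  expect_equal(dim(a$truth$carrier), c(length(spec$gene_pool), 6))
  expect_equal(nrow(a$truth$params), 6)
  # planted driver effect shifts the carrier parameter distribution
  spec2 <- cohort_spec(n_patients = 40, driver_effects = list(
    list(gene = "KRAS", parameter = "correlation_length", delta = 3)))
  co <- simulate_cohort(spec2, seed = 6)
  carr <- co$truth$carrier["KRAS", ] == 1
  expect_gt(mean(co$truth$params$correlation_length[carr]),
            mean(co$truth$params$correlation_length[!carr]))
})

test_that("cohorts write to disk in the documented formats", {
  spec <- cohort_spec(n_patients = 3,
                      phantom = phantom_params(grid_shape = c(10, 10, 10),
                                               ellipsoid_semi_axes = c(7, 6, 5)))
  co <- simulate_cohort(spec, seed = 8)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "P01_image.nii.gz")))
  expect_true(file.exists(file.path(dir, "variants.vcf")))
  img <- read_volume(file.path(dir, "P02_image.nii.gz"))
  expect_equal(img$values, co$images[["P02"]]$values, tolerance = 1e-6)
  tsv <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(nrow(tsv), nrow(co$variants))
  sv <- utils::read.delim(file.path(dir, "survival.tsv"))
  expect_equal(sv$time_days, co$survival$time_days)
})
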