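# End-to-end orchestration: simulate -> extract -> burden -> prune ->
# associate -> survive, with a manifest for reproducibility.

#' Simulate a cohort and run the association scan in memory
#'
#' Convenience wrapper for validation studies: simulates a cohort,
#' extracts the requested features, builds the filtered burden matrix
#' and runs the radiome x genome scan, without touching disk.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param computed_features features to extract (default: a compact
#'   panel covering every texture family plus first-order statistics).
#' @param mode,alpha,min_carriers see [associate_all()] and
#'   [filter_genes()].
#' @return List with `cohort`, `features`, `burden`, `associations`.
#' @export
cohort_association_scan <- function(spec, seed = 1,
                                    computed_features = default_scan_panel(),
                                    mode = "skat", alpha = 1e-4,
                                    min_carriers = 3) {
  co <- simulate_cohort(spec, seed = seed)
  fm <- extract_feature_matrix(
    co$images, co$masks,
    feature_config(computed_features = computed_features))
  filt <- filter_consequence(filter_somatic(co$variants))
  bm <- filter_genes(gene_carrier_matrix(filt, patients = rownames(fm)),
                     min_carriers)
  assoc <- associate_all(fm, bm, alpha = alpha, mode = mode)
  list(cohort = co, features = fm, burden = bm, associations = assoc)
}

#' Compact radiomic panel covering every texture family
#'
#' The features the synthetic validation studies scan: the
#' spatial-correlation-sensitive statistics of each texture family plus
#' the hotspot features named in pancreatic radiogenomics work
#' (RunVariance, Skewness, LargeArea(HighGrayLevel)Emphasis, Busyness,
#' Contrast, ClusterShade/Prominence).
#'
#' @export
default_scan_panel <- function() c(
  "original.glcm.Correlation", "original.glcm.Imc1",
  "original.glcm.ClusterShade", "original.glcm.ClusterProminence",
  "original.glcm.Idmn", "original.glcm.InverseVariance",
  "original.glrlm.RunVariance", "original.glrlm.LongRunEmphasis",
  "original.glszm.GrayLevelNonUniformity",
  "original.glszm.LargeAreaEmphasis",
  "original.glszm.LargeAreaHighGrayLevelEmphasis",
  "original.gldm.SmallDependenceEmphasis",
  "original.ngtdm.Coarseness", "original.ngtdm.Contrast",
  "original.ngtdm.Busyness",
  "original.firstorder.Skewness", "original.firstorder.Mean",
  "original.firstorder.Variance")

#' Texture families expected to respond to a planted parameter
#'
#' Maps a [phantom_params()] texture parameter to the feature classes
#' that measure it: the spatial-arrangement (texture-matrix) classes for
#' `correlation_length`, first-order statistics for `intensity_sd` and
#' `skew_parameter`.
#'
#' @param parameter one of `"correlation_length"`, `"intensity_sd"`,
#'   `"skew_parameter"`.
#' @export
planted_feature_families <- function(parameter) {
  switch(parameter,
         correlation_length = c("glcm", "glrlm", "glszm", "ngtdm", "gldm"),
         intensity_sd = "firstorder",
         skew_parameter = "firstorder",
         stop("unknown texture parameter: ", parameter))
}

#' Pipeline configuration
#'
#' All stage parameters in one place.  Defaults are the analysis
#' conventions used throughout the package: 25-unit gray-level bins,
#' 2 mm isotropic resampling, correlation-pruning cutoff 0.8, genes with
#' at least 3 carriers, raw-p calling threshold 1e-4, somatic
#' adjusted-P cutoff 1e-5, and 2 mutation PCs as covariates.
#'
#' @param cohort a [cohort_spec()] for the simulate stage (ignored when
#'   `input_dir` is given).
#' @param input_dir optional directory with pre-existing cohort files
#'   (as written by [write_cohort()]); `NULL` simulates.
#' @param bin_width,target_spacing,log_sigma,wavelet_family see
#'   [feature_config()].
#' @param computed_features features to extract; `NULL` = full catalog.
#' @param prune_cutoff correlation cutoff for [correlation_prune()].
#' @param min_carriers gene filter threshold for [filter_genes()].
#' @param alpha raw-p significance threshold for [associate_all()].
#' @param somatic_cutoff adjusted-P cutoff for [filter_somatic()].
#' @param k_pcs number of mutation-PC covariates.
#' @param mode association mode, `"skat"` or `"burden"`.
#' @param survival_genes carrier gene set for the survival contrast;
#'   `NULL` uses the cohort spec's.
#' @param seed integer seed for the simulate stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_dir = NULL,
                            bin_width = 25, target_spacing = c(2, 2, 2),
                            log_sigma = 3, wavelet_family = "coif1",
                            computed_features = NULL, prune_cutoff = 0.8,
                            min_carriers = 3, alpha = 1e-4,
                            somatic_cutoff = 1e-5, k_pcs = 2,
                            mode = "skat", survival_genes = NULL,
                            seed = 1) {
  stopifnot(prune_cutoff > 0, prune_cutoff < 1, min_carriers >= 1,
            alpha > 0, alpha < 1, somatic_cutoff > 0, k_pcs >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; cohort parameters
#' go under a `cohort:` block (passed to [cohort_spec()]).
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(pipeline_config, y)
}

stage_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full radiome x genome pipeline
#'
#' Executes simulate (or load), extract-features, burden, prune,
#' associate and survive in order, writing one TSV per stage plus a
#' JSON manifest (seed, package version, per-stage dimensions, output
#' file MD5 sums) into `out_dir`.  A rerun with the same configuration
#' and seed reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("radscan")),
                   stages = list())
  # --- stage 1: cohort -------------------------------------------------
  if (is.null(config$input_dir)) {
    stage_msg("simulate: ", config$cohort$n_patients, " patients")
    cohort <- simulate_cohort(config$cohort, seed = config$seed)
    surv <- cohort$survival
    images <- cohort$images; masks <- cohort$masks
    variants <- cohort$variants
  } else {
    stage_msg("load: ", config$input_dir)
    imgf <- sort(list.files(config$input_dir, "_image\\.nii", full.names = TRUE))
    mskf <- sort(list.files(config$input_dir, "_mask\\.nii", full.names = TRUE))
    if (!length(imgf)) stop("stage load: no *_image.nii* files in ",
                            config$input_dir)
    images <- lapply(imgf, read_volume)
    masks <- lapply(mskf, read_volume, mask = TRUE)
    names(images) <- names(masks) <- sub("_image\\.nii.*$", "", basename(imgf))
    variants <- read_variants(file.path(config$input_dir, "variants.tsv"))
    surv <- utils::read.delim(file.path(config$input_dir, "survival.tsv"))
  }
  write_variants_tsv(variants, file.path(out_dir, "variants.tsv"))
  utils::write.table(surv, file.path(out_dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$cohort <- list(n_patients = length(images),
                                 n_variant_records = nrow(variants))
  # --- stage 2: radiomic features -------------------------------------
  fc <- feature_config(bin_width = config$bin_width,
                       target_spacing = config$target_spacing,
                       wavelet_family = config$wavelet_family,
                       log_sigma = config$log_sigma,
                       computed_features = config$computed_features)
  stage_msg("extract-features: ",
            if (is.null(config$computed_features)) "full catalog"
            else length(config$computed_features), " on ",
            length(images), " volumes")
  fm <- extract_feature_matrix(images, masks, fc)
  write_feature_matrix(fm, file.path(out_dir, "features.tsv"))
  manifest$stages$features <- list(n_patients = nrow(fm),
                                   n_features = ncol(fm))
  # --- stage 3: burden -------------------------------------------------
  stage_msg("burden")
  filtered <- filter_consequence(filter_somatic(variants,
                                                config$somatic_cutoff))
  burden <- gene_carrier_matrix(filtered, patients = rownames(fm))
  burden <- filter_genes(burden, config$min_carriers)
  if (length(burden$genes) == 0)
    stop("stage burden: no gene passes the min_carriers filter")
  utils::write.table(
    data.frame(gene = rownames(burden$carrier), burden$carrier),
    file.path(out_dir, "carrier_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- snv_recurrence(filtered)
  utils::write.table(rec, file.path(out_dir, "snv_recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$burden <- list(n_genes = length(burden$genes),
                                 n_records_after_filter = nrow(filtered))
  # --- stage 4: heterogeneity + pruning -------------------------------
  stage_msg("prune: cutoff ", config$prune_cutoff)
  cv <- coefficient_of_variation(fm)
  pr <- correlation_prune(fm, cutoff = config$prune_cutoff)
  utils::write.table(
    data.frame(feature = names(cv), cv = as.numeric(cv),
               retained = names(cv) %in% pr$retained),
    file.path(out_dir, "feature_cv.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$prune <- list(n_retained = length(pr$retained),
                                n_cv_gt_1 = sum(is.finite(cv) & cv > 1))
  # --- stage 5: association scan --------------------------------------
  stage_msg("associate: ", length(burden$genes), " genes x ", ncol(fm),
            " features (", config$mode, ")")
  assoc <- associate_all(fm, burden, k_pcs = config$k_pcs,
                         alpha = config$alpha, mode = config$mode)
  utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- assoc[assoc$significant, , drop = FALSE]
  utils::write.table(sig, file.path(out_dir, "significant_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$associate <- list(n_tests = nrow(assoc),
                                    n_significant = nrow(sig))
  # --- stage 6: survival ----------------------------------------------
  genes_surv <- config$survival_genes
  if (is.null(genes_surv)) genes_surv <- config$cohort$survival_genes
  surv_res <- tryCatch(
    compare_carriers(surv, burden, genes_surv),
    error = function(e) {
      stage_msg("survive: skipped (", conditionMessage(e), ")")
      NULL
    })
  if (!is.null(surv_res)) {
    stage_msg("survive: log-rank p = ", format(surv_res$test$p, digits = 3))
    utils::write.table(
      data.frame(group = names(surv_res$medians),
                 median_days = as.numeric(surv_res$medians),
                 chisq = surv_res$test$chisq, p = surv_res$test$p),
      file.path(out_dir, "survival_test.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$survive <- list(p = surv_res$test$p)
  }
  # --- manifest --------------------------------------------------------
  outs <- list.files(out_dir, "\\.tsv$", full.names = TRUE)
  manifest$md5 <- as.list(tools::md5sum(outs))
  names(manifest$md5) <- basename(outs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = fm, burden = burden, cv = cv, prune = pr,
                 associations = assoc, survival = surv_res,
                 manifest = manifest))
}
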