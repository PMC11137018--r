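# The canonical feature catalog and the per-VOI extraction driver.
#
# Canonical feature identifiers have the form `filter.class.name`, e.g.
# `original.glrlm.RunVariance`, `wavelet.LHL.ngtdm.Contrast` or
# `log.sigma.3.0.firstorder.Skewness`.  Shape features exist only under
# the `original` filter; every other class is repeated under one
# Laplacian-of-Gaussian sigma and under each of the 8 wavelet bands.

texture_class_names <- function() {
  list(firstorder = first_order_names(),
       glcm = glcm_feature_names(),
       gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis"),
       glrlm = names(glrlm_features(texture_matrix("GLRLM", matrix(0, 1, 1), 1,
                                                   extra = list(n_voxels = 1,
                                                                n_directions = 13)))),
       glszm = names(glszm_features(texture_matrix("GLSZM", matrix(0, 1, 1), 1,
                                                   extra = list(n_voxels = 1)))),
       ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength"))
}

#' Extraction configuration
#'
#' Bundles the tunable parameters of the feature-extraction pipeline.
#'
#' @param bin_width fixed gray-level bin width (intensity units).
#' @param target_spacing isotropic resampling spacing in mm (scalar or
#'   length 3); `NULL` disables resampling.
#' @param wavelet_family wavelet family for the band decomposition.
#' @param log_sigma Laplacian-of-Gaussian scale in mm (a single sigma).
#' @param computed_features canonical feature names to compute; `NULL`
#'   means the full catalog.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(bin_width = 25, target_spacing = c(2, 2, 2),
                           wavelet_family = "coif1", log_sigma = 3,
                           computed_features = NULL) {
  structure(list(bin_width = bin_width, target_spacing = target_spacing,
                 wavelet_family = wavelet_family, log_sigma = log_sigma,
                 computed_features = computed_features),
            class = "feature_config")
}

log_filter_label <- function(sigma) {
  sprintf("log.sigma.%s", gsub("[.]", ".", format(sigma, nsmall = 1)))
}

#' Enumerate the canonical feature catalog
#'
#' All feature identifiers produced by the extraction pipeline: 107
#' original features (14 shape, 18 first-order, 24 GLCM, 14 GLDM, 16
#' GLRLM, 16 GLSZM, 5 NGTDM), 93 Laplacian-of-Gaussian features (all
#' non-shape classes under one sigma) and 744 wavelet features (the same
#' 93 under each of the 8 bands), 944 in total.
#'
#' @param config a [feature_config()].
#' @return A data frame with columns `filter`, `class`, `name` and the
#'   canonical identifier `feature`.
#' @export
feature_catalog <- function(config = feature_config()) {
  classes <- texture_class_names()
  rows <- list()
  add <- function(filter, class, names)
    rows[[length(rows) + 1L]] <<- data.frame(
      filter = filter, class = class, name = names,
      stringsAsFactors = FALSE)
  add("original", "shape", shape_names())
  for (cl in names(classes)) add("original", cl, classes[[cl]])
  for (cl in names(classes))
    add(log_filter_label(config$log_sigma), cl, classes[[cl]])
  bands <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")),
                 1L, paste0, collapse = "")
  for (b in sort(bands))
    for (cl in names(classes))
      add(paste0("wavelet.", b), cl, classes[[cl]])
  out <- do.call(rbind, rows)
  out$feature <- paste(out$filter, out$class, out$name, sep = ".")
  out
}

texture_class_features <- function(d, class) {
  switch(class,
         glcm = glcm_features(glcm_matrix(d)),
         glrlm = glrlm_features(glrlm_matrix(d)),
         glszm = glszm_features(glszm_matrix(d)),
         ngtdm = ngtdm_features(ngtdm_matrix(d)),
         gldm = gldm_features(gldm_matrix(d)),
         stop("unknown texture class: ", class))
}

#' Extract radiomic features from one image/mask pair
#'
#' Runs the full extraction pipeline: resampling to the target spacing,
#' then per filter (original, Laplacian-of-Gaussian, 8 wavelet bands)
#' fixed-bin-width discretization of the masked voxels followed by the
#' per-class feature computations.  Only the features requested in
#' `config$computed_features` (default: the whole catalog) are computed;
#' anything not requested is absent from the result.
#'
#' @param image a [volume_image()].
#' @param mask an aligned [voi_mask()].
#' @param config a [feature_config()].
#' @return Named numeric vector, names from [feature_catalog()].
#' @export
extract_features <- function(image, mask, config = feature_config()) {
  check_aligned(image, mask)
  cat_df <- feature_catalog(config)
  wanted <- config$computed_features
  if (is.null(wanted)) wanted <- cat_df$feature
  unknown <- setdiff(wanted, cat_df$feature)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(utils::head(unknown, 5),
                                            collapse = ", "))
  cat_df <- cat_df[cat_df$feature %in% wanted, , drop = FALSE]
  if (!is.null(config$target_spacing)) {
    rs <- resample_volume(image, mask, config$target_spacing)
    image <- rs$image; mask <- rs$mask
  }
  out <- stats::setNames(rep(NA_real_, length(wanted)), wanted)
  wb <- NULL   # wavelet bands are computed once and reused across filters
  filtered_image <- function(filter) {
    if (filter == "original") return(image)
    if (startsWith(filter, "log.sigma")) return(log_filter(image, config$log_sigma))
    if (is.null(wb)) wb <<- wavelet_bands(image, config$wavelet_family)
    wb[[sub("^wavelet\\.", "", filter)]]
  }
  vv <- prod(image$spacing)
  for (filter in unique(cat_df$filter)) {
    sub <- cat_df[cat_df$filter == filter, , drop = FALSE]
    img_f <- filtered_image(filter)
    d <- NULL
    need_disc <- any(sub$class != "shape")
    if (need_disc) d <- discretize(img_f, mask, config$bin_width)
    for (cl in unique(sub$class)) {
      want_names <- sub$name[sub$class == cl]
      vals <- if (cl == "shape") {
        shape_features(mask)
      } else if (cl == "firstorder") {
        first_order_features(img_f$values[mask$values],
                             levels = d$levels[d$mask], voxel_volume = vv)
      } else texture_class_features(d, cl)
      full <- paste(filter, cl, want_names, sep = ".")
      out[full] <- vals[want_names]
    }
  }
  out
}

#' Extract a feature matrix for a cohort
#'
#' @param images list of [volume_image()]s, one per patient.
#' @param masks list of aligned [voi_mask()]s.
#' @param config a [feature_config()].
#' @param patient_ids row names; defaults to names of `images`.
#' @return Numeric matrix, patients x features.
#' @export
extract_feature_matrix <- function(images, masks,
                                   config = feature_config(),
                                   patient_ids = names(images)) {
  stopifnot(length(images) == length(masks))
  rows <- lapply(seq_along(images), function(i)
    extract_features(images[[i]], masks[[i]], config))
  out <- do.call(rbind, rows)
  rownames(out) <- if (is.null(patient_ids))
    sprintf("P%02d", seq_along(images)) else patient_ids
  out
}

#' Write / read a feature matrix as TSV
#'
#' Rows are patients, columns canonical feature names.
#' @param x patients x features matrix.
#' @param path output TSV path.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(patient_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
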