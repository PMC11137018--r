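# Synthetic tumor cohorts with known ground truth: textured ellipsoid
# phantoms, somatic variant tables and survival times.  Every generator
# is a pure function of its parameters and a seed.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom parameters for a synthetic tumor volume
#'
#' The phantom is a stationary Gaussian random field (white noise
#' convolved with an isotropic Gaussian of width `correlation_length`)
#' inside an ellipsoidal mask, optionally skewed by a monotone
#' exponential transform, then scaled to the requested intensity mean and
#' standard deviation.
#'
#' @param grid_shape voxels per axis (length 3 or scalar).
#' @param spacing mm per axis.
#' @param ellipsoid_semi_axes semi-axes of the tumor ellipsoid, mm.
#' @param correlation_length Gaussian correlation scale of the texture,
#'   mm; larger values give smoother (coarser) texture.
#' @param intensity_mean,intensity_sd intensity scale (HU-like units).
#' @param skew_parameter controls first-order gray-level asymmetry; 0
#'   gives a symmetric field, positive values right-skew.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(24, 24, 24), spacing = c(2, 2, 2),
                           ellipsoid_semi_axes = c(16, 13, 11),
                           correlation_length = 3,
                           intensity_mean = 80, intensity_sd = 50,
                           skew_parameter = 0) {
  p <- list(grid_shape = rep_len(as.integer(grid_shape), 3L),
            spacing = rep_len(as.numeric(spacing), 3L),
            ellipsoid_semi_axes = rep_len(as.numeric(ellipsoid_semi_axes), 3L),
            correlation_length = correlation_length,
            intensity_mean = intensity_mean, intensity_sd = intensity_sd,
            skew_parameter = skew_parameter)
  if (any(p$spacing <= 0) || any(p$ellipsoid_semi_axes <= 0) ||
      p$correlation_length <= 0 || p$intensity_sd <= 0)
    stop("all lengths and scales must be positive")
  extent <- (p$grid_shape - 1) * p$spacing / 2
  too_big <- p$ellipsoid_semi_axes > extent
  if (any(too_big))
    stop("ellipsoid exceeds the grid along axis ",
         paste(which(too_big), collapse = ", "))
  class(p) <- "phantom_params"
  p
}

#' Generate a synthetic tumor volume and mask
#'
#' @param params a [phantom_params()].
#' @param shift additive shift applied to `shift_parameter` before
#'   generation (used to plant carrier effects).
#' @param seed integer seed; the output is a pure function of
#'   `(params, shift, seed)`.
#' @param shift_parameter which texture parameter `shift` perturbs.
#' @return List with `image` ([volume_image()]) and `mask`
#'   ([voi_mask()]).
#' @export
generate_tumor_volume <- function(params, shift = 0, seed = 1,
                                  shift_parameter = c("correlation_length",
                                                      "intensity_sd",
                                                      "skew_parameter")) {
  shift_parameter <- match.arg(shift_parameter)
  p <- unclass(params)
  p[[shift_parameter]] <- p[[shift_parameter]] + shift
  params <- do.call(phantom_params, p)
  dims <- params$grid_shape
  with_seed(seed, {
    noise <- array(stats::rnorm(prod(dims)), dims)
    field <- noise
    for (a in 1:3) {
      h <- params$spacing[a]
      sv <- params$correlation_length / h
      r <- max(1L, ceiling(3 * sv))
      k <- exp(-((-r:r) * h)^2 / (2 * params$correlation_length^2))
      field <- conv_axis(field, k / sqrt(sum(k^2)), a, mode = "periodic")
    }
    field <- (field - mean(field)) / stats::sd(field)
    s <- params$skew_parameter
    if (abs(s) > 1e-12) {
      field <- (exp(s * field) - 1) / s       # monotone, -> identity as s -> 0
      field <- (field - mean(field)) / stats::sd(field)
    }
    vals <- params$intensity_mean + params$intensity_sd * field
    centre <- (dims - 1) / 2 * params$spacing
    ax <- lapply(1:3, function(a)
      ((seq_len(dims[a]) - 1) * params$spacing[a] - centre[a]) /
        params$ellipsoid_semi_axes[a])
    mask <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+") <= 1
    list(image = volume_image(vals, params$spacing),
         mask = voi_mask(mask, params$spacing))
  })
}

default_gene_pool <- function() {
  # carrier probabilities patterned on per-gene carrier counts seen in
  # small pancreatic-cancer WES cohorts (a few near-ubiquitous drivers,
  # a long tail of genes carried by ~3-9 of 26 patients)
  c(KRAS = 0.85, TP53 = 0.65, KMT2C = 0.65, LRP1B = 0.54, FGFR2 = 0.50,
    RGPD3 = 0.42, EWSR1 = 0.38, RGPD4 = 0.38, CDKN2A = 0.35, RGPD6 = 0.30,
    POTEF = 0.27, EGF = 0.23, KMT2B = 0.23, SDHAP1 = 0.23, KDR = 0.19,
    RANBP2 = 0.19, SPEN = 0.15, UBC = 0.15, FANCB = 0.15, NOTCH1 = 0.15,
    BCORL1 = 0.15, ARID1A = 0.12, EPHB3 = 0.12, EGFR = 0.12, POTEJ = 0.12,
    CHD2 = 0.12, EPOR = 0.12, JUN = 0.12, KIT = 0.12, GFRA2 = 0.12,
    FUBP1 = 0.12, RBM10 = 0.12, ATM = 0.12, SMAD4 = 0.19, GNAS = 0.12,
    RNF43 = 0.12, TGFBR2 = 0.12, ARID2 = 0.12, PRKG1 = 0.12, POLQ = 0.12)
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the structure of a 26-patient rapid-autopsy
#' pancreatic-cancer cohort: ~51 somatic SNVs per patient over a gene
#' pool whose carrier counts range from ~3 to ~22 of 26, one planted
#' driver effect on a texture parameter, and exponential survival with a
#' median of 331 days for non-carriers.
#'
#' @param n_patients number of patients (>= 2).
#' @param gene_pool named numeric vector of per-gene carrier
#'   probabilities in `[0, 1]`.
#' @param mean_snvs_per_patient Poisson mean of the per-patient somatic
#'   SNV count.
#' @param driver_effects list of planted effects, each a list with
#'   `gene`, `parameter` (a [phantom_params()] texture parameter) and
#'   `delta` (shift in units of the between-patient SD of that
#'   parameter).
#' @param survival_genes carrier group for the survival contrast
#'   (carrier of any gene in the set).
#' @param hazard_ratio carrier hazard multiplier (> 0).
#' @param median_survival_days non-carrier median survival.
#' @param censoring_rate expected fraction of censored patients in
#'   `[0, 1)`.
#' @param phantom baseline [phantom_params()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 26,
                        gene_pool = default_gene_pool(),
                        mean_snvs_per_patient = 51,
                        driver_effects = list(
                          list(gene = "CDKN2A",
                               parameter = "correlation_length",
                               delta = 2)),
                        survival_genes = c("CDKN2A", "PRKG1", "BCORL1"),
                        hazard_ratio = 2,
                        median_survival_days = 331,
                        censoring_rate = 0,
                        phantom = phantom_params()) {
  if (n_patients < 2) stop("'n_patients' must be at least 2")
  if (length(gene_pool) == 0) stop("'gene_pool' must not be empty")
  if (is.null(names(gene_pool)) || anyDuplicated(names(gene_pool)))
    stop("'gene_pool' must have unique gene names")
  if (any(gene_pool < 0 | gene_pool > 1))
    stop("carrier probabilities must lie in [0, 1]")
  if (mean_snvs_per_patient <= 0) stop("'mean_snvs_per_patient' must be > 0")
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("'censoring_rate' must be in [0, 1)")
  for (eff in driver_effects) {
    if (!all(c("gene", "parameter", "delta") %in% names(eff)))
      stop("each driver effect needs 'gene', 'parameter' and 'delta'")
    if (!is.finite(eff$delta)) stop("driver effect size must be finite")
  }
  structure(list(n_patients = as.integer(n_patients), gene_pool = gene_pool,
                 mean_snvs_per_patient = mean_snvs_per_patient,
                 driver_effects = driver_effects,
                 survival_genes = survival_genes,
                 hazard_ratio = hazard_ratio,
                 median_survival_days = median_survival_days,
                 censoring_rate = censoring_rate, phantom = phantom),
            class = "cohort_spec")
}

consequence_classes_retained <- function()
  c("missense_variant", "stop_gained", "start_lost", "sequence_feature",
    "splice_donor_variant", "intron_variant")

consequence_vocabulary <- function()
  c(consequence_classes_retained(),
    "synonymous_variant", "stop_lost", "splice_acceptor_variant",
    "frameshift_variant", "inframe_deletion", "inframe_insertion",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "upstream_gene_variant", "downstream_gene_variant")

#' Generate a somatic variant table with known carrier ground truth
#'
#' Each patient's carrier status per gene is an independent Bernoulli
#' draw with the gene's carrier probability; every carried gene receives
#' at least one "qualifying" record (a retained consequence class with
#' adjusted somatic-call P below 1e-5).  The total per-patient record
#' count is Poisson with mean `mean_snvs_per_patient` (floored at the
#' number of carried genes); extra records are spread multinomially over
#' the carried genes, a fraction of them non-qualifying (filtered
#' consequence classes or non-significant adjusted P) so the downstream
#' filters have work to do.  Each gene has a fixed pool of six hotspot
#' sites with Zipf-like recurrence weights -- qualifying records are
#' drawn from the hotspots (without replacement within a patient), so
#' variants recur across patients the way driver hotspots do -- while
#' non-qualifying passenger records get uniform positions in the gene's
#' 100-kb block on a toy contig.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return List with `variants` (the variant table, one row per record)
#'   and `truth` (list with the sampled `carrier` gene x patient matrix).
#' @export
generate_variant_table <- function(spec, seed = 1) {
  genes <- names(spec$gene_pool)
  n <- spec$n_patients
  patients <- sprintf("P%02d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  n_hot <- 6L
  hot_w <- (1 / seq_len(n_hot)) / sum(1 / seq_len(n_hot))
  hot_pos <- function(gi) gi * 100000L + 1000L * seq_len(n_hot)
  with_seed(seed, {
    carrier <- matrix(stats::rbinom(length(genes) * n, 1L,
                                    rep(spec$gene_pool, n)),
                      nrow = length(genes), ncol = n,
                      dimnames = list(genes, patients))
    # fixed per-site alleles so a hotspot is the same variant everywhere
    hot_ref <- matrix(sample(bases, length(genes) * n_hot, replace = TRUE),
                      length(genes), n_hot)
    hot_alt <- matrix(vapply(hot_ref, function(r)
      sample(setdiff(bases, r), 1L), ""), length(genes), n_hot)
    hot_csq <- matrix(sample(consequence_classes_retained(),
                             length(genes) * n_hot, replace = TRUE),
                      length(genes), n_hot)
    rows <- vector("list", n)
    for (p in seq_len(n)) {
      carried_i <- which(carrier[, p] == 1L)
      n_carried <- length(carried_i)
      if (n_carried == 0L) next
      total <- max(stats::rpois(1L, spec$mean_snvs_per_patient), n_carried)
      extra_of <- tabulate(sample(seq_len(n_carried), total - n_carried,
                                  replace = TRUE), nbins = n_carried)
      gi_v <- integer(0); pos_v <- integer(0); ref_v <- character(0)
      alt_v <- character(0); csq_v <- character(0); qual_v <- logical(0)
      for (k in seq_len(n_carried)) {
        gi <- carried_i[k]
        cnt <- 1L + extra_of[k]
        n_q <- min(cnt, n_hot)               # qualifying, from hotspots
        sites <- sample.int(n_hot, n_q, prob = hot_w)
        n_pass <- cnt - n_q                  # passengers, uniform positions
        gi_v <- c(gi_v, rep(gi, cnt))
        pos_v <- c(pos_v, hot_pos(gi)[sites],
                   if (n_pass) gi * 100000L + 10000L +
                     sample.int(89999L, n_pass, replace = TRUE))
        ref_v <- c(ref_v, hot_ref[gi, sites],
                   if (n_pass) sample(bases, n_pass, replace = TRUE))
        alt_tail <- if (n_pass)
          vapply(utils::tail(ref_v, n_pass), function(r)
            sample(setdiff(bases, r), 1L), "") else character(0)
        alt_v <- c(alt_v, hot_alt[gi, sites], alt_tail)
        csq_v <- c(csq_v, hot_csq[gi, sites],
                   if (n_pass) sample(c("synonymous_variant",
                                        "3_prime_UTR_variant",
                                        "upstream_gene_variant",
                                        "missense_variant"),
                                      n_pass, replace = TRUE))
        qual_v <- c(qual_v, rep(TRUE, n_q), rep(FALSE, n_pass))
      }
      # qualifying records are significant somatic calls; passengers are
      # non-significant (and mostly non-consequential as sampled above)
      adj_p <- ifelse(qual_v, 10^stats::runif(length(qual_v), -12, -6),
                      10^stats::runif(length(qual_v), -4.9, -2))
      rows[[p]] <- data.frame(patient_id = patients[p], chrom = "chrS",
                              pos = pos_v, ref = ref_v, alt = alt_v,
                              gene = genes[gi_v], consequence = csq_v,
                              adj_p = adj_p, stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, rows)
    rownames(variants) <- NULL
    list(variants = variants, truth = list(carrier = carrier))
  })
}

#' Generate survival times for a cohort
#'
#' Exponential event times with non-carrier rate `log(2) /
#' median_survival_days` and carrier rate multiplied by `hazard_ratio`.
#' Censoring is an independent exponential time calibrated so that the
#' expected censored fraction in the non-carrier group equals
#' `censoring_rate` (0 disables censoring entirely).
#'
#' @param spec a [cohort_spec()].
#' @param carriers logical or 0/1 vector: membership in the designated
#'   carrier group, one entry per patient.
#' @param seed integer seed.
#' @return Data frame with `patient_id`, `time_days`, `event`, `carrier`.
#' @export
generate_survival <- function(spec, carriers, seed = 1) {
  n <- length(carriers)
  if (n == 0) stop("empty cohort")
  carriers <- as.logical(carriers)
  lam0 <- log(2) / spec$median_survival_days
  lam <- ifelse(carriers, lam0 * spec$hazard_ratio, lam0)
  with_seed(seed, {
    t_event <- stats::rexp(n, lam)
    if (spec$censoring_rate > 0) {
      lam_c <- lam0 * spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- stats::rexp(n, lam_c)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    data.frame(patient_id = sprintf("P%02d", seq_len(n)),
               time_days = time, event = as.integer(t_event <= t_cens),
               carrier = carriers, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete cohort
#'
#' Draws the variant table (and with it the carrier ground truth), then
#' per-patient phantom parameters with log-normal between-patient
#' variation (25% coefficient of variation on `correlation_length` and
#' `intensity_sd`, additive normal variation on `skew_parameter` and
#' `intensity_mean`), applies each planted driver effect as a
#' `delta`-SD shift of the named parameter for carriers of the driver
#' gene, generates the tumor volumes, and draws survival for the
#' designated carrier group.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return List of class `synthetic_cohort` with `images`, `masks`,
#'   `variants`, `survival`, `truth` (carrier matrix, per-patient texture
#'   parameters, planted `(gene, parameter)` pairs) and the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  vt <- generate_variant_table(spec, seed = seed)
  carrier <- vt$truth$carrier
  n <- spec$n_patients
  ph <- spec$phantom
  cv <- 0.25
  params <- with_seed(seed + 1000L, data.frame(
    correlation_length = ph$correlation_length *
      exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2)))),
    intensity_sd = ph$intensity_sd *
      exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2)))),
    intensity_mean = ph$intensity_mean + stats::rnorm(n, 0, 8),
    skew_parameter = ph$skew_parameter + stats::rnorm(n, 0, 0.15)))
  sd_of <- c(correlation_length = ph$correlation_length * cv,
             intensity_sd = ph$intensity_sd * cv,
             skew_parameter = 0.15)
  for (eff in spec$driver_effects) {
    if (!eff$gene %in% rownames(carrier)) next
    is_c <- carrier[eff$gene, ] == 1L
    params[[eff$parameter]] <- params[[eff$parameter]] +
      eff$delta * sd_of[[eff$parameter]] * is_c
  }
  params$correlation_length <- pmax(params$correlation_length,
                                    min(ph$spacing) / 2)
  params$intensity_sd <- pmax(params$intensity_sd, 1e-3)
  images <- vector("list", n); masks <- vector("list", n)
  for (p in seq_len(n)) {
    pp <- phantom_params(grid_shape = ph$grid_shape, spacing = ph$spacing,
                         ellipsoid_semi_axes = ph$ellipsoid_semi_axes,
                         correlation_length = params$correlation_length[p],
                         intensity_mean = params$intensity_mean[p],
                         intensity_sd = params$intensity_sd[p],
                         skew_parameter = params$skew_parameter[p])
    tv <- generate_tumor_volume(pp, seed = seed + 2000L + p)
    images[[p]] <- tv$image; masks[[p]] <- tv$mask
  }
  pats <- sprintf("P%02d", seq_len(n))
  names(images) <- names(masks) <- pats
  surv_car <- colSums(carrier[intersect(spec$survival_genes,
                                        rownames(carrier)), ,
                              drop = FALSE]) > 0
  surv <- generate_survival(spec, surv_car, seed = seed + 3000L)
  structure(list(images = images, masks = masks, variants = vt$variants,
                 survival = surv,
                 truth = list(carrier = carrier, params = params,
                              planted = spec$driver_effects,
                              survival_carriers = surv_car),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d variant records, %d genes\n",
              x$spec$n_patients, nrow(x$variants), nrow(x$truth$carrier)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Images and masks as NIfTI, variants as both TSV and VCF, survival as
#' TSV, and the ground-truth carrier matrix as TSV.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(cohort$images)) {
    write_volume(cohort$images[[p]], file.path(dir, paste0(p, "_image.nii.gz")))
    write_volume(cohort$masks[[p]], file.path(dir, paste0(p, "_mask.nii.gz")))
  }
  write_variants_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_variants_vcf(cohort$variants, file.path(dir, "variants.vcf"))
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(cohort$truth$carrier), cohort$truth$carrier),
    file.path(dir, "carrier_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
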