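# Somatic variant records and the gene x patient burden construction.
#
# A variant table is a data frame with one row per (patient, variant):
# patient_id, chrom, pos (1-based), ref, alt, gene, consequence, adj_p
# (the adjusted somatic-call P-value of the record).

variant_columns <- function()
  c("patient_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
    "adj_p")

validate_variant_table <- function(tab) {
  miss <- setdiff(variant_columns(), names(tab))
  if (length(miss))
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) && any(tab$pos < 1)) stop("positions must be >= 1")
  bad <- which(is.na(tab$gene) | tab$gene == "" |
                 is.na(tab$consequence) | tab$consequence == "")
  if (length(bad))
    stop("missing gene/consequence annotation in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(tab)
}

#' Read somatic variant calls
#'
#' Supports the flat TSV dialect (columns `patient_id`, `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `consequence`, `adj_p`) and annotated VCF with
#' `GENE`, `CSQ` and `ADJP` INFO keys, per-patient genotypes in `GT` and
#' optional per-patient adjusted P-values in a `AP` FORMAT field.
#' Multi-allelic VCF rows are split into one record per alternate
#' allele; a patient yields a record for every alternate allele its
#' genotype carries.
#'
#' @param path input file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"tsv"` or `"vcf"`.
#' @return A variant table (one row per patient-variant record).
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(validate_variant_table(tab[variant_columns()]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- matrix(fixm, nrow = 1,
                                         dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  fix[] <- lapply(fix, as.character)
  info_field <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (all(is.na(x))) stop("VCF lacks required INFO key ", key)
    x
  }
  gene <- info_field("GENE")
  csq <- info_field("CSQ")
  adjp_site <- suppressWarnings(as.numeric(vcfR::extract.info(v, "ADJP")))
  gt <- vcfR::extract.gt(v, element = "GT")
  ap <- tryCatch(vcfR::extract.gt(v, element = "AP"), error = function(e) NULL)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      has <- vapply(gt[i, ], function(g) {
        if (is.na(g)) return(FALSE)
        any(strsplit(g, "[/|]")[[1]] == as.character(ai))
      }, TRUE)
      if (!any(has)) next
      pats <- colnames(gt)[has]
      padj <- if (!is.null(ap)) suppressWarnings(as.numeric(ap[i, pats]))
              else rep(adjp_site[i], length(pats))
      padj[is.na(padj)] <- adjp_site[i]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pats, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[ai],
        gene = gene[i], consequence = csq[i], adj_p = padj,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = 8, nrow = 0)), variant_columns())
  rownames(tab) <- NULL
  validate_variant_table(tab)
}

#' Write a variant table as TSV
#' @param tab a variant table.
#' @param path output path.
#' @export
write_variants_tsv <- function(tab, path) {
  validate_variant_table(tab)
  utils::write.table(tab[variant_columns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as annotated VCF
#'
#' One row per distinct (chrom, pos, ref, alt, gene, consequence); INFO
#' carries `GENE`, `CSQ` and `ADJP` (the minimum adjusted P over
#' patients), FORMAT `GT:AP` carries per-patient genotype and adjusted
#' P.  Duplicate records for the same patient and variant collapse to
#' one genotype.
#'
#' @param tab a variant table.
#' @param path output path.
#' @export
write_variants_vcf <- function(tab, path) {
  validate_variant_table(tab)
  patients <- sort(unique(tab$patient_id))
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, tab$gene,
               tab$consequence, sep = "\r")
  idx <- split(seq_len(nrow(tab)), key)
  idx <- idx[order(vapply(idx, function(i) tab$pos[i[1]], 1))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=ADJP,Number=1,Type=Float,Description=\"Minimum adjusted somatic-call P-value\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AP,Number=1,Type=Float,Description=\"Per-patient adjusted somatic-call P-value\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", patients), collapse = "\t")), con)
  for (rows in idx) {
    r1 <- tab[rows[1], ]
    ap <- stats::setNames(rep(NA_real_, length(patients)), patients)
    ap[tab$patient_id[rows]] <- tab$adj_p[rows]
    gtap <- ifelse(is.na(ap), "0/0:.", sprintf("0/1:%.6g", ap))
    writeLines(paste(c(
      r1$chrom, r1$pos, ".", r1$ref, r1$alt, ".", "PASS",
      sprintf("GENE=%s;CSQ=%s;ADJP=%.6g", r1$gene, r1$consequence,
              min(tab$adj_p[rows])),
      "GT:AP", gtap), collapse = "\t"), con)
  }
  invisible(path)
}

#' Keep significant somatic calls
#'
#' Retains records whose adjusted somatic-call P-value is strictly below
#' the cutoff.
#'
#' @param tab a variant table.
#' @param cutoff significance cutoff on `adj_p` (default 1e-5).
#' @export
filter_somatic <- function(tab, cutoff = 1e-5) {
  validate_variant_table(tab)
  tab[tab$adj_p < cutoff, , drop = FALSE]
}

#' Keep translationally consequential variants
#'
#' Retains records whose consequence class is in `classes` (default: the
#' six retained classes: missense, stop gain, start loss, sequence
#' feature, splice donor, intron).  Labels outside the closed vocabulary
#' raise an error.
#'
#' @param tab a variant table.
#' @param classes consequence classes to keep.
#' @export
filter_consequence <- function(tab, classes = consequence_classes_retained()) {
  validate_variant_table(tab)
  unknown <- setdiff(unique(tab$consequence), consequence_vocabulary())
  if (length(unknown))
    stop("unknown consequence class(es): ", paste(unknown, collapse = ", "))
  bad <- setdiff(classes, consequence_vocabulary())
  if (length(bad))
    stop("unknown consequence class(es) requested: ",
         paste(bad, collapse = ", "))
  tab[tab$consequence %in% classes, , drop = FALSE]
}

#' Per-variant patient recurrence
#'
#' Counts distinct patients per variant, either at allele resolution
#' (`by = "variant"`: key chrom/pos/alt) or pooled over alternate
#' alleles at a site (`by = "position"`: key chrom/pos, the convention
#' under which G12D and G12V mutations at one position pool).  Duplicate
#' records of one patient for the same key count once.
#'
#' @param tab a variant table.
#' @param by `"variant"` or `"position"`.
#' @return Data frame sorted by decreasing `n_patients`.
#' @export
snv_recurrence <- function(tab, by = c("variant", "position")) {
  by <- match.arg(by)
  validate_variant_table(tab)
  key <- if (by == "variant")
    paste(tab$chrom, tab$pos, tab$alt, sep = ":") else
      paste(tab$chrom, tab$pos, sep = ":")
  cnt <- tapply(tab$patient_id, key, function(p) length(unique(p)))
  out <- data.frame(key = names(cnt), n_patients = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene x patient carrier (burden) matrix
#'
#' `carrier[g, p] = 1` iff patient `p` has at least one record in gene
#' `g`.  The per-gene variant x patient 0/1 genotype matrices (variant
#' key chrom:pos:alt) are retained for kernel association tests.
#'
#' @param tab a (filtered) variant table.
#' @param patients optional full patient set (columns), so that patients
#'   with no qualifying records still appear as non-carriers.
#' @return An object of class `burden_matrix` with elements `carrier`
#'   (genes x patients) and `genotypes` (list of variant x patient
#'   matrices).
#' @export
gene_carrier_matrix <- function(tab, patients = NULL) {
  validate_variant_table(tab)
  if (is.null(patients)) patients <- sort(unique(tab$patient_id))
  genes <- sort(unique(tab$gene))
  carrier <- matrix(0L, length(genes), length(patients),
                    dimnames = list(genes, patients))
  genotypes <- vector("list", length(genes))
  names(genotypes) <- genes
  for (g in genes) {
    sub <- tab[tab$gene == g, , drop = FALSE]
    vkey <- paste(sub$chrom, sub$pos, sub$alt, sep = ":")
    vu <- unique(vkey)
    G <- matrix(0L, length(vu), length(patients),
                dimnames = list(vu, patients))
    G[cbind(match(vkey, vu), match(sub$patient_id, patients))] <- 1L
    genotypes[[g]] <- G
    carrier[g, ] <- as.integer(colSums(G) > 0)
  }
  structure(list(carrier = carrier, genotypes = genotypes,
                 genes = genes, patients = patients),
            class = "burden_matrix")
}

#' @export
print.burden_matrix <- function(x, ...) {
  cat(sprintf("<burden_matrix> %d genes x %d patients\n",
              length(x$genes), length(x$patients)))
  invisible(x)
}

#' Keep recurrently mutated genes
#'
#' Retains genes carried by at least `min_carriers` patients.
#'
#' @param burden a [gene_carrier_matrix()].
#' @param min_carriers minimum carrier count (default 3).
#' @export
filter_genes <- function(burden, min_carriers = 3) {
  keep <- rowSums(burden$carrier) >= min_carriers
  structure(list(carrier = burden$carrier[keep, , drop = FALSE],
                 genotypes = burden$genotypes[keep],
                 genes = burden$genes[keep], patients = burden$patients),
            class = "burden_matrix")
}
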