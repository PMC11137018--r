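# Variant table IO, filters, recurrence and the carrier matrix.

toy_table <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P3"),
    chrom = "chr1",
    pos = c(100L, 200L, 100L, 100L, 300L, 300L),
    ref = c("C", "G", "C", "C", "A", "A"),
    alt = c("T", "A", "T", "T", "G", "G"),
    gene = c("KRAS", "TP53", "KRAS", "KRAS", "TP53", "TP53"),
    consequence = c("missense_variant", "stop_gained", "missense_variant",
                    "missense_variant", "intron_variant", "intron_variant"),
    adj_p = c(1e-8, 1e-9, 1e-7, 1e-6, 1e-10, 1e-10),
    stringsAsFactors = FALSE)
}

test_that("TSV round trip is lossless", {
  f <- tempfile(fileext = ".tsv")
  write_variants_tsv(toy_table(), f)
  expect_equal(read_variants(f), toy_table())
})

test_that("VCF round trip preserves record content", {
  tab <- generate_variant_table(cohort_spec(n_patients = 5), seed = 3)$variants
  f <- tempfile(fileext = ".vcf")
  write_variants_vcf(tab, f)
  back <- read_variants(f)
  key <- function(t) sort(paste(t$patient_id, t$chrom, t$pos, t$ref, t$alt,
                                t$gene, t$consequence, signif(t$adj_p, 6)))
  expect_equal(key(back), key(unique(tab)))
})

test_that("multi-allelic VCF rows split into one record per alternate", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=ADJP,Number=1,Type=Float,Description=\"p\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste("chr12", 25245350, ".", "C", "T,A", ".", "PASS",
          "GENE=KRAS;CSQ=missense_variant;ADJP=1e-8", "GT", "0/1", "1/2",
          sep = "\t")), f)
  tab <- read_variants(f)
  expect_equal(nrow(tab), 3)              # S1:T, S2:T, S2:A
  expect_setequal(paste(tab$patient_id, tab$alt),
                  c("S1 T", "S2 T", "S2 A"))
  expect_true(all(tab$adj_p == 1e-8))
})

test_that("missing annotations are reported with offending rows", {
  bad <- toy_table()
  bad$gene[2] <- ""
  expect_error(validate_variant_table <- write_variants_tsv(bad, tempfile()),
               "row\\(s\\): 2")
})

test_that("somatic filter applies a strict inequality", {
  tab <- toy_table()
  tab$adj_p <- c(1e-6, 1e-5, 1e-4, 1, 1, 1)
  expect_equal(nrow(filter_somatic(tab, 1e-5)), 1)
  expect_equal(nrow(filter_somatic(tab[0, ], 1e-5)), 0)
  expect_equal(nrow(filter_somatic(tab, cutoff = 1.01)), 6)
})

test_that("consequence filter keeps the retained classes and rejects junk", {
  tab <- toy_table()
  tab$consequence[1] <- "synonymous_variant"
  kept <- filter_consequence(tab)
  expect_false("synonymous_variant" %in% kept$consequence)
  expect_equal(nrow(kept), 5)
  expect_equal(nrow(filter_consequence(tab, classes = character(0))), 0)
  tab$consequence[2] <- "made_up_class"
  expect_error(filter_consequence(tab), "unknown consequence")
})

test_that("somatic and consequence filters commute", {
  tab <- generate_variant_table(cohort_spec(n_patients = 8), seed = 11)$variants
  a <- filter_consequence(filter_somatic(tab))
  b <- filter_somatic(filter_consequence(tab))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("recurrence counts distinct patients and de-duplicates", {
  tab <- toy_table()
  rec <- snv_recurrence(tab)
  expect_equal(rec$n_patients[rec$key == "chr1:100:T"], 3)
  expect_equal(rec$n_patients[rec$key == "chr1:300:G"], 1)  # dup collapses
  expect_true(all(diff(rec$n_patients) <= 0))
  # position-level pooling merges alternates at one site
  tab2 <- rbind(toy_table(),
                data.frame(patient_id = "P4", chrom = "chr1", pos = 100L,
                           ref = "C", alt = "A", gene = "KRAS",
                           consequence = "missense_variant", adj_p = 1e-8))
  recp <- snv_recurrence(tab2, by = "position")
  expect_equal(recp$n_patients[recp$key == "chr1:100"], 4)
})

test_that("carrier matrix matches hand enumeration and ignores duplicates", {
  bm <- gene_carrier_matrix(toy_table())
  expect_equal(bm$carrier["KRAS", ], c(P1 = 1L, P2 = 1L, P3 = 1L))
  expect_equal(bm$carrier["TP53", ], c(P1 = 1L, P2 = 0L, P3 = 1L))
  dup <- rbind(toy_table(), toy_table())
  expect_equal(gene_carrier_matrix(dup)$carrier, bm$carrier)
  # genotype matrices are variant x patient indicators
  expect_equal(dim(bm$genotypes[["TP53"]]), c(2L, 3L))
})

test_that("gene filter applies a carrier-count threshold of at-least", {
  bm <- gene_carrier_matrix(toy_table())
  expect_equal(filter_genes(bm, 3)$genes, "KRAS")
  expect_setequal(filter_genes(bm, 2)$genes, c("KRAS", "TP53"))
  expect_setequal(filter_genes(bm, 1)$genes, c("KRAS", "TP53"))
})
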