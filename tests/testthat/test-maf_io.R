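test_that("a written MAF round-trips field-exactly through read_maf", {
  mut <- make_mut(gene = c("TP53", "KRAS", "TP53"),
                  patient = c("P1", "P1", "P2"),
                  classification = c("missense", "silent", "indel"),
                  vaf = c(0.4, 0.1, 0.25), purity = c(0.9, 0.9, 0.8),
                  impact_raw = c(22, 3, 30))
  path <- withr::local_tempfile(fileext = ".maf")
  write_test_maf(mut, path)
  got <- read_maf(path)
  expect_equal(nrow(got), 3)
  for (col in c("gene", "patient", "classification", "vaf", "purity",
                "copy_number", "impact_raw")) {
    expect_equal(got[[col]], mut[[col]], info = col)
  }
})

test_that("MAF dialect values map onto the seven model classes", {
  raw <- tibble::tibble(
    Hugo_Symbol = "G1", Tumor_Sample_Barcode = "P1",
    Variant_Classification = c("Silent", "Missense_Mutation",
                               "Nonsense_Mutation", "Splice_Site",
                               "Translation_Start_Site", "Nonstop_Mutation",
                               "Frame_Shift_Ins", "In_Frame_Del"),
    VAF = 0.3
  )
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(raw, path, progress = FALSE)
  got <- suppressMessages(read_maf(path))
  expect_equal(got$classification,
               c("silent", "missense", "nonsense", "splice", "TSS",
                 "nonstop", "indel", "indel"))
})

test_that("non-coding classifications are dropped with a count, unknown ones raise", {
  raw <- tibble::tibble(
    Hugo_Symbol = c("G1", "G2"), Tumor_Sample_Barcode = "P1",
    Variant_Classification = c("Missense_Mutation", "Intron"), VAF = 0.3)
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(raw, path, progress = FALSE)
  expect_message(got <- read_maf(path), "Dropping 1")
  expect_equal(got$gene, "G1")

  raw$Variant_Classification[2] <- "Made_Up_Class"
  readr::write_tsv(raw, path, progress = FALSE)
  expect_error(read_maf(path), "Made_Up_Class")
})

test_that("missing mandatory columns and out-of-range VAF are hard errors", {
  raw <- tibble::tibble(Hugo_Symbol = "G1", Tumor_Sample_Barcode = "P1",
                        Variant_Classification = "Missense_Mutation")
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(raw, path, progress = FALSE)
  expect_error(read_maf(path), "VAF")

  raw$VAF <- 1.2
  readr::write_tsv(raw, path, progress = FALSE)
  expect_error(read_maf(path), "row")
})

test_that("missing optional columns get documented defaults", {
  raw <- tibble::tibble(Hugo_Symbol = "G1", Tumor_Sample_Barcode = "P1",
                        Variant_Classification = "Missense_Mutation",
                        VAF = 0.5)
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(raw, path, progress = FALSE)
  got <- suppressMessages(read_maf(path))
  expect_equal(got$purity, 1)
  expect_equal(got$copy_number, 2)
  expect_true(is.na(got$cnv_ccf))
})

test_that("column_map resolves nonstandard column names", {
  raw <- tibble::tibble(Hugo_Symbol = "G1", Tumor_Sample_Barcode = "P1",
                        Variant_Classification = "Missense_Mutation",
                        i_tumor_f = 0.25)
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(raw, path, progress = FALSE)
  got <- suppressMessages(read_maf(path, column_map = c(vaf = "i_tumor_f")))
  expect_equal(got$vaf, 0.25)
})

test_that("precomputed ccf/damage columns are preserved on read", {
  raw <- tibble::tibble(Hugo_Symbol = "G1", Tumor_Sample_Barcode = "P1",
                        Variant_Classification = "Missense_Mutation",
                        VAF = 0.1, ccf = 0.77, damage = 0.9)
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(raw, path, progress = FALSE)
  got <- suppressMessages(read_maf(path))
  annotated <- add_damage(add_ccf(got))
  expect_equal(annotated$ccf, 0.77)
  expect_equal(annotated$damage, 0.9)
  # recomputation on request overrides the stored values
  expect_equal(add_ccf(got, recompute = TRUE)$ccf, 0.2)
})

test_that("gene context reader validates genes and site counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ctx <- tibble::tibble(gene = c("A", "B", "C", "D", "E"), N_a = 3000,
                        N_s = 1000, length = 1500, ncmr = 1e-6)
  readr::write_tsv(ctx, path, progress = FALSE)
  got <- read_gene_context(path)
  expect_equal(nrow(got), 5)
  expect_equal(got$n_sites_nonsyn, rep(3000, 5))

  readr::write_tsv(ctx[c(1, 1, 2), ], path, progress = FALSE)
  expect_error(read_gene_context(path), "Duplicate")

  ctx$N_s[2] <- 0
  readr::write_tsv(ctx, path, progress = FALSE)
  expect_error(read_gene_context(path), "positive")
})

test_that("write_results produces a rank-ordered TSV that round-trips", {
  res <- tibble::tibble(gene = c("B", "A"), posterior_hazard = c(0.2, 0.9),
                        posterior_driver = c(0.1, 0.8), rank = c(2L, 1L),
                        fdr = c(0.5, 0.01), significant = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  lines <- readLines(path)
  expect_length(lines, 3)            # header + 2 rows
  back <- read_results(path)
  expect_equal(back$gene, c("A", "B"))
  expect_equal(back$rank, c(1L, 2L))

  write_results(res[0, ], path)
  expect_length(readLines(path), 1)  # header only
})
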