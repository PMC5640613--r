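# in-code fixture builders shared across test files

# minimal mutation tibble; defaults give a clean clonal missense record
make_mut <- function(gene = "TP53", patient = "P1",
                     classification = "missense", vaf = 0.4, purity = 1,
                     copy_number = 2, cnv_ccf = NA_real_, impact_raw = 20,
                     ccf = NA_real_, damage = NA_real_) {
  tibble::tibble(gene = gene, patient = patient,
                 classification = classification, vaf = vaf, purity = purity,
                 copy_number = copy_number, cnv_ccf = cnv_ccf,
                 impact_raw = impact_raw, ccf = ccf, damage = damage)
}

make_context <- function(gene = c("TP53", "KRAS", "EGFR", "PTEN", "BRAF"),
                         N_a = 3000, N_s = 1000, length = 1500,
                         ncmr = 1e-6) {
  tibble::tibble(gene = gene, n_sites_nonsyn = N_a, n_sites_syn = N_s,
                 length = length, ncmr = ncmr)
}

# write a MAF-dialect file for a mutation tibble (standard column names)
write_test_maf <- function(mut, path) {
  rev_class <- c(missense = "Missense_Mutation",
                 nonsense = "Nonsense_Mutation", splice = "Splice_Site",
                 TSS = "Translation_Start_Site", nonstop = "Nonstop_Mutation",
                 indel = "Frame_Shift_Del", silent = "Silent")
  out <- tibble::tibble(
    Hugo_Symbol = mut$gene, Tumor_Sample_Barcode = mut$patient,
    Variant_Classification = unname(rev_class[mut$classification]),
    VAF = mut$vaf, purity = mut$purity, ploidy = mut$copy_number,
    CNV_CCF = mut$cnv_ccf, CADD = mut$impact_raw
  )
  readr::write_tsv(out, path, progress = FALSE)
  path
}

# brute-force two-sided Fisher p-value: sum hypergeometric probabilities of
# all tables (fixed margins) no more likely than the observed one
fisher_oracle <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  xs <- max(0, k - n2):min(n1, k)
  probs <- stats::dhyper(xs, n1, n2, k)
  obs <- stats::dhyper(k1, n1, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
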