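#' Read an extended MAF somatic mutation table
#'
#' Reads a tab-separated MAF-style file (v2.4 column names) extended with the
#' per-mutation columns the model needs: variant allele frequency (`VAF`),
#' tumor `purity`, local total copy number (`ploidy`), the CCF of an
#' overlapping CNV (`CNV_CCF`) and a raw CADD-like functional impact score
#' (`CADD`). Variant classifications are mapped onto the seven classes the
#' model distinguishes: `indel`, `missense`, `nonsense`, `splice`, `TSS`,
#' `nonstop` and `silent`; rows with any other classification (introns, UTRs,
#' flanks, RNA) are dropped with a message reporting the count.
#'
#' Missing optional columns get documented defaults: `purity = 1` (no purity
#' correction), `copy_number = 2` (diploid), `cnv_ccf = NA` (no overlapping
#' CNV), `impact_raw = NA`. If the file already carries derived `ccf` /
#' `damage` columns they are preserved; otherwise they are left `NA` for
#' [add_ccf()] / [add_damage()] to fill.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector mapping the standard
#'   column names used here to the names in the file, e.g.
#'   `c(vaf = "i_tumor_f", purity = "abs_purity")`. Names are the canonical
#'   names (`gene`, `patient`, `classification`, `vaf`, `purity`,
#'   `copy_number`, `cnv_ccf`, `impact_raw`, `ccf`, `damage`), values the
#'   file's column names.
#' @return A tibble of mutation records with columns `gene`, `patient`,
#'   `classification`, `vaf`, `purity`, `copy_number`, `cnv_ccf`,
#'   `impact_raw`, `ccf`, `damage`, plus any extra file columns passed
#'   through untouched (genomic coordinates are never reinterpreted).
#' @examples
#' maf <- system.file("extdata", "toy_cohort.maf", package = "clonedriver")
#' read_maf(maf)
#' @export
read_maf <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("MAF file not found: ", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  defaults <- c(
    gene = "Hugo_Symbol", patient = "Tumor_Sample_Barcode",
    classification = "Variant_Classification", vaf = "VAF",
    purity = "purity", copy_number = "ploidy", cnv_ccf = "CNV_CCF",
    impact_raw = "CADD", ccf = "ccf", damage = "damage"
  )
  cmap <- defaults
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(defaults))
    if (length(bad) > 0) {
      abort(paste0("Unknown column_map entries: ", paste(bad, collapse = ", ")))
    }
    cmap[names(column_map)] <- column_map
  }

  mandatory <- c("gene", "patient", "classification", "vaf")
  for (field in mandatory) {
    if (!cmap[[field]] %in% names(raw)) {
      abort(paste0("Mandatory MAF column missing: '", cmap[[field]],
                   "' (needed for field '", field, "')"))
    }
  }

  out <- tibble(
    gene = as.character(raw[[cmap[["gene"]]]]),
    patient = as.character(raw[[cmap[["patient"]]]]),
    classification = as.character(raw[[cmap[["classification"]]]])
  )
  opt_default <- c(purity = 1, copy_number = 2, cnv_ccf = NA_real_,
                   impact_raw = NA_real_, ccf = NA_real_, damage = NA_real_)
  for (field in c("vaf", names(opt_default))) {
    col <- cmap[[field]]
    if (col %in% names(raw)) {
      out[[field]] <- as.numeric(raw[[col]])
    } else if (field != "vaf") {
      out[[field]] <- unname(opt_default[[field]])
      inform(paste0("Column '", col, "' absent; using default ", field, " = ",
                    opt_default[[field]]))
    }
  }

  bad_vaf <- which(!is.na(out$vaf) & (out$vaf < 0 | out$vaf > 1))
  if (length(bad_vaf) > 0) {
    abort(paste0("VAF out of [0, 1] at data row(s): ",
                 paste(head(bad_vaf, 5), collapse = ", ")))
  }

  out$classification <- map_classification(out$classification)
  dropped <- is.na(out$classification)
  if (any(dropped)) {
    inform(paste0("Dropping ", sum(dropped),
                  " mutation(s) with non-coding/unsupported classification"))
    out <- out[!dropped, , drop = FALSE]
    raw <- raw[!dropped, , drop = FALSE]
  }

  # pass through any extra columns (positions etc.) untouched
  extra <- setdiff(names(raw), unname(cmap))
  for (col in extra) out[[col]] <- raw[[col]]
  out
}

# MAF Variant_Classification -> model classes; NA for dropped dialect values
map_classification <- function(x) {
  dict <- c(
    Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
    Splice_Site = "splice", Translation_Start_Site = "TSS",
    Nonstop_Mutation = "nonstop", Frame_Shift_Del = "indel",
    Frame_Shift_Ins = "indel", In_Frame_Del = "indel", In_Frame_Ins = "indel",
    Silent = "silent",
    # already-mapped values round-trip unchanged
    indel = "indel", missense = "missense", nonsense = "nonsense",
    splice = "splice", TSS = "TSS", nonstop = "nonstop", silent = "silent"
  )
  droppable <- c("Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR",
                 "RNA", "lincRNA", "De_novo_Start_InFrame",
                 "De_novo_Start_OutOfFrame", "Start_Codon_SNP", "Targeted_Region")
  mapped <- unname(dict[x])
  unknown <- is.na(mapped) & !(x %in% droppable)
  if (any(unknown)) {
    abort(paste0("Unknown Variant_Classification value(s): ",
                 paste(unique(x[unknown]), collapse = ", ")))
  }
  mapped
}

#' Classes counted as nonsilent (protein-altering)
#'
#' @return Character vector of the six nonsilent classes.
#' @export
nonsilent_classes <- function() {
  c("indel", "missense", "nonsense", "splice", "TSS", "nonstop")
}

#' Read a per-gene context table
#'
#' The context table supplies the constants the background models need for
#' each gene: the number of nonsynonymous sites `N_a`, synonymous sites
#' `N_s`, the coding length in bp and the non-coding mutation rate per bp
#' (`ncmr`, e.g. published per-gene rates from exome-wide background studies).
#'
#' @param path Path to a tab-separated file with header columns `gene`,
#'   `N_a`, `N_s`, `length`, `ncmr`.
#' @return A tibble with columns `gene`, `n_sites_nonsyn`, `n_sites_syn`,
#'   `length`, `ncmr`.
#' @export
read_gene_context <- function(path) {
  if (!file.exists(path)) abort(paste0("Gene context file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "N_a", "N_s", "length", "ncmr")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Gene context table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(raw$gene) > 0) {
    abort(paste0("Duplicate gene symbol(s) in context table: ",
                 paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", ")))
  }
  if (any(raw$N_a <= 0) || any(raw$N_s <= 0)) {
    abort("N_a and N_s must be strictly positive for every gene")
  }
  if (any(raw$ncmr < 0)) abort("ncmr must be nonnegative")
  tibble(
    gene = as.character(raw$gene),
    n_sites_nonsyn = as.numeric(raw$N_a),
    n_sites_syn = as.numeric(raw$N_s),
    length = as.numeric(raw$length),
    ncmr = as.numeric(raw$ncmr)
  )
}

#' Read a gold-standard gene list
#'
#' @param path Plain-text file, one HUGO symbol per line; blank lines and
#'   lines starting with `#` are ignored.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("Gene list file not found: ", path))
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write ranked gene results
#'
#' Writes the per-gene result table as TSV ordered by rank, with columns
#' `gene`, `posterior_hazard`, `posterior_driver`, `rank`, `fdr`,
#' `significant`.
#'
#' @param results Tibble of ranked gene results (from [driver_scan()] or
#'   [rank_genes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  need <- c("gene", "posterior_hazard", "posterior_driver", "rank")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0) {
    abort(paste0("Results missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(results)
  if (!"fdr" %in% names(out)) out$fdr <- NA_real_
  if (!"significant" %in% names(out)) out$significant <- NA
  out <- out |>
    select(all_of(c("gene", "posterior_hazard", "posterior_driver",
                    "rank", "fdr", "significant"))) |>
    arrange(.data$rank)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return Tibble with the result columns.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
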