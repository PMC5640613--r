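#' Configuration for the synthetic cohort simulator
#'
#' The simulator emulates the clonal structure the driver model exploits:
#' driver genes accumulate recurrent, early (clonal, CCF near 1), damaging
#' nonsilent mutations, while passengers accumulate neutrally — a mixture of
#' a small clonal component (hitch-hikers that predate transformation) and a
#' subclonal component — with broad, mostly benign impact scores. Silent
#' mutations arise in proportion to each gene's synonymous site share
#' `N_s / (N_a + N_s)`. Per-gene mutation rates are heterogeneous
#' (log-normal), and the same heterogeneity drives the per-gene non-coding
#' mutation rate so the background models see realistic rate variation.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_patients Cohort size (default 200).
#' @param driver_genes Number of driver genes, or an explicit character
#'   vector of gene names to spike (default 10).
#' @param driver_hit_rate Per-patient probability that each driver gene
#'   receives a driver mutation (default 0.15).
#' @param mut_per_patient Mean passenger mutations (all classes) per patient
#'   (default 30).
#' @param rate_dispersion Log-normal sdlog of per-gene rate heterogeneity
#'   (default 0.5).
#' @param driver_ccf_shape Beta parameters `c(alpha, beta)` of driver
#'   mutation CCFs (default `c(30, 2)`: mass above 0.85).
#' @param passenger_clonal_weight Probability a passenger mutation is clonal
#'   (drawn from the driver CCF component; default 0.35).
#' @param passenger_ccf_shape Beta parameters of the subclonal passenger
#'   CCF component (default `c(2, 5)`: mass below 0.5).
#' @param driver_impact Normal mean/sd of driver raw impact scores (default
#'   `c(30, 5)`, truncated at 0).
#' @param passenger_impact Gamma shape/scale of nonsilent passenger raw
#'   impact scores (default `c(2, 5)`, mean 10).
#' @param silent_impact Gamma shape/scale of silent raw impact scores
#'   (default `c(2, 2.5)`, mean 5).
#' @param purity_shape Beta parameters of per-patient tumor purity (default
#'   `c(8, 2)`, mean 0.8).
#' @param indel_fraction Fraction of nonsilent passenger mutations that are
#'   indels (default 0.05).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000, n_patients = 200,
                              driver_genes = 10, driver_hit_rate = 0.15,
                              mut_per_patient = 30, rate_dispersion = 0.5,
                              driver_ccf_shape = c(30, 2),
                              passenger_clonal_weight = 0.35,
                              passenger_ccf_shape = c(2, 5),
                              driver_impact = c(30, 5),
                              passenger_impact = c(2, 5),
                              silent_impact = c(2, 2.5),
                              purity_shape = c(8, 2),
                              indel_fraction = 0.05) {
  n_drivers <- if (is.character(driver_genes)) length(driver_genes)
               else driver_genes
  if (n_drivers > n_genes) abort("more driver genes than genes")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a somatic mutation cohort with known ground truth
#'
#' Generates a MAF-compatible extended mutation table, the matching per-gene
#' context table and per-mutation truth labels. VAFs are derived from the
#' drawn CCFs by inverting the diploid purity correction, so re-estimating
#' CCF from the table recovers the generating values.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `sim_cohort` with `mutations` (tibble with
#'   `gene`, `patient`, `classification`, `vaf`, `purity`, `copy_number`,
#'   `cnv_ccf`, `impact_raw`, `ccf`, `damage`, `origin`), `gene_context`,
#'   `driver_genes` (character vector of true drivers) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  drivers <- if (is.character(cfg$driver_genes)) cfg$driver_genes
             else genes[seq_len(cfg$driver_genes)]
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  purity <- setNames(rbeta(cfg$n_patients, cfg$purity_shape[1],
                           cfg$purity_shape[2]), patients)
  purity <- pmax(purity, 0.1)

  # per-gene context: length and site counts; ~3 possible substitutions/bp,
  # ~3:1 nonsynonymous:synonymous site ratio
  len <- round(rlnorm(cfg$n_genes, log(1500), 0.5))
  n_a_sites <- 0.75 * 3 * len
  n_s_sites <- 0.25 * 3 * len
  rate_het <- rlnorm(cfg$n_genes, 0, cfg$rate_dispersion)
  ncmr <- 1e-6 * rate_het
  gene_context <- tibble(gene = genes, n_sites_nonsyn = n_a_sites,
                         n_sites_syn = n_s_sites, length = as.numeric(len),
                         ncmr = ncmr)

  # passenger load: per-gene rates proportional to ncmr x length, scaled to
  # the configured per-patient mean
  lambda_g <- ncmr * len
  lambda_g <- lambda_g / sum(lambda_g) * cfg$mut_per_patient
  counts <- rpois(cfg$n_genes * cfg$n_patients,
                  rep(lambda_g, times = cfg$n_patients))
  idx <- which(counts > 0)
  reps <- counts[idx]
  p_gene <- rep(rep(genes, times = cfg$n_patients)[idx], reps)
  p_patient <- rep(rep(patients, each = cfg$n_genes)[idx], reps)
  n_pass <- length(p_gene)

  silent_frac <- setNames(n_s_sites / (n_a_sites + n_s_sites), genes)
  is_silent <- runif(n_pass) < silent_frac[p_gene]
  is_indel <- !is_silent & runif(n_pass) < cfg$indel_fraction
  classification <- if_else(is_silent, "silent",
                            if_else(is_indel, "indel",
                                    sample(c("missense", "nonsense", "splice",
                                             "TSS", "nonstop"), n_pass,
                                           replace = TRUE,
                                           prob = c(0.82, 0.08, 0.06,
                                                    0.02, 0.02))))
  clonal <- runif(n_pass) < cfg$passenger_clonal_weight
  ccf <- if_else(clonal,
                 rbeta(n_pass, cfg$driver_ccf_shape[1], cfg$driver_ccf_shape[2]),
                 rbeta(n_pass, cfg$passenger_ccf_shape[1],
                       cfg$passenger_ccf_shape[2]))
  impact <- if_else(is_silent,
                    stats::rgamma(n_pass, cfg$silent_impact[1],
                                  scale = cfg$silent_impact[2]),
                    stats::rgamma(n_pass, cfg$passenger_impact[1],
                                  scale = cfg$passenger_impact[2]))
  passengers <- tibble(gene = p_gene, patient = p_patient,
                       classification = classification,
                       ccf = ccf, impact_raw = impact,
                       origin = "passenger")

  # driver hits: clonal, damaging, nonsilent
  hit <- matrix(rbinom(length(drivers) * cfg$n_patients, 1,
                       cfg$driver_hit_rate),
                nrow = length(drivers))
  d_idx <- which(hit == 1, arr.ind = TRUE)
  n_drv <- nrow(d_idx)
  driver_muts <- tibble(
    gene = drivers[d_idx[, 1]],
    patient = patients[d_idx[, 2]],
    classification = sample(c("missense", "nonsense", "indel", "splice"),
                            n_drv, replace = TRUE,
                            prob = c(0.6, 0.2, 0.1, 0.1)),
    ccf = rbeta(n_drv, cfg$driver_ccf_shape[1], cfg$driver_ccf_shape[2]),
    impact_raw = pmax(rnorm(n_drv, cfg$driver_impact[1],
                            cfg$driver_impact[2]), 0),
    origin = "driver"
  )

  mut <- bind_rows(passengers, driver_muts)
  mut$purity <- unname(purity[mut$patient])
  mut$copy_number <- 2
  mut$cnv_ccf <- NA_real_
  # diploid inversion: VAF observed for a mutation at this CCF and purity
  mut$vaf <- mut$ccf * mut$purity / 2
  mut$damage <- damage_score(mut$impact_raw)
  mut <- mut |>
    select(all_of(c("gene", "patient", "classification", "vaf", "purity",
                    "copy_number", "cnv_ccf", "impact_raw", "ccf", "damage",
                    "origin"))) |>
    arrange(.data$patient, .data$gene)

  structure(list(mutations = mut, gene_context = gene_context,
                 driver_genes = drivers, patients = patients,
                 config = cfg, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$mutations), "mutations,",
      length(x$patients), "patients,", nrow(x$gene_context), "genes,",
      length(x$driver_genes), "true driver(s)\n")
  invisible(x)
}

#' Write the canonical fixture files for a simulated cohort
#'
#' Emits the small plain-text file set used by the documentation and tests:
#' a spiked cohort MAF, a neutral cohort MAF, a 3-mutation toy MAF, the
#' gene-context table and the true-driver gold-standard list, plus the
#' truth labels.
#'
#' @param outdir Writable output directory (created if needed).
#' @param spiked A `sim_cohort` to write (default: a small spiked cohort).
#' @param neutral A `sim_cohort` with no drivers (default: small neutral
#'   cohort).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture_suite <- function(outdir,
                                spiked = simulate_cohort(
                                  simulation_config(n_genes = 80,
                                                    n_patients = 30,
                                                    driver_genes = 4,
                                                    mut_per_patient = 12),
                                  seed = 11),
                                neutral = simulate_cohort(
                                  simulation_config(n_genes = 80,
                                                    n_patients = 30,
                                                    driver_genes = 0,
                                                    mut_per_patient = 12),
                                  seed = 12)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(df, path, progress = FALSE)
    files <<- c(files, path)
    path
  }
  emit(as_maf(spiked$mutations), "spiked_cohort.maf")
  emit(as_maf(neutral$mutations), "neutral_cohort.maf")
  emit(as_maf(spiked$mutations[c(1, 2, 3), ]), "toy_cohort.maf")
  emit(spiked$gene_context |>
         rename(N_a = "n_sites_nonsyn", N_s = "n_sites_syn"),
       "gene_context.tsv")
  emit(spiked$mutations |> select(all_of(c("gene", "patient", "origin"))),
       "truth_labels.tsv")
  writeLines(spiked$driver_genes, file.path(outdir, "gold_standard.txt"))
  files <- c(files, file.path(outdir, "gold_standard.txt"))
  invisible(files)
}

# internal-format tibble -> MAF v2.4-style column names
as_maf <- function(mutations) {
  rev_class <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
                 splice = "Splice_Site", TSS = "Translation_Start_Site",
                 nonstop = "Nonstop_Mutation", indel = "Frame_Shift_Del",
                 silent = "Silent")
  tibble(
    Hugo_Symbol = mutations$gene,
    Tumor_Sample_Barcode = mutations$patient,
    Variant_Classification = unname(rev_class[mutations$classification]),
    VAF = mutations$vaf,
    purity = mutations$purity,
    ploidy = mutations$copy_number,
    CNV_CCF = mutations$cnv_ccf,
    CADD = mutations$impact_raw
  )
}
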