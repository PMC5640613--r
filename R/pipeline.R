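#' Scan a cohort for positively selected driver genes
#'
#' Runs the full analysis on an in-memory mutation table: derives any
#' missing CCF and damage values, fits both background mutation models,
#' scores every gene with the cancer-hazard and driver-inference Bayesian
#' models, builds the gene-label resampling null, estimates the per-rank
#' FDR and flags the genes within the suggested rank cutoff.
#'
#' @param mutations Mutation tibble (see [read_maf()]); first argument so
#'   calls pipe naturally.
#' @param gene_context Per-gene context tibble ([read_gene_context()]).
#' @param driver_genes Known driver gene list (gold standard) for the
#'   driver model.
#' @param incidence Prior cancer incidence for the hazard model.
#' @param impact Parameters from [impact_params()].
#' @param clonal_threshold Clonal CCF cutoff for the background rate `r`.
#' @param alpha FDR threshold for the rank cutoff (default 0.1).
#' @param n_reps Null-model replicates (default 100).
#' @param seed Seed for the resampling null.
#' @param n_genes_total Total protein-coding genes for the driver prior.
#' @param p_ns_given_d Optional override of the driver mutation likelihood.
#' @param n_patients Total cohort size; defaults to the number of distinct
#'   patients in `mutations` (pass explicitly if some patients have no
#'   mutations).
#' @param recompute_ccf Recompute CCF even where present (default `FALSE`).
#' @return An object of class `driver_scan`: a list with `results` (ranked
#'   tibble: gene, m, n, posterior_hazard, posterior_driver, rank, fdr,
#'   significant), `background`, `null`, `fdr` (per-rank tibble for both
#'   models), `cutoff` (list from [optimal_rank()]) and the call
#'   parameters. Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_genes = 60, n_patients = 30,
#'                                          driver_genes = 3,
#'                                          mut_per_patient = 8), seed = 7)
#' scan <- driver_scan(sim$mutations, sim$gene_context,
#'                     driver_genes = sim$driver_genes, n_reps = 20)
#' head(tidy(scan))
#' glance(scan)
#' @export
driver_scan <- function(mutations, gene_context, driver_genes,
                        incidence = 0.1, impact = impact_params(),
                        clonal_threshold = 0.85, alpha = 0.1, n_reps = 100,
                        seed = 1, n_genes_total = 20000,
                        p_ns_given_d = NULL,
                        n_patients = NULL, recompute_ccf = FALSE) {
  mut <- as_tibble(mutations) |>
    add_ccf(recompute = recompute_ccf) |>
    add_damage(params = impact)
  n_patients <- n_patients %||% length(unique(mut$patient))

  params <- bayes_params(incidence = incidence, driver_genes = driver_genes,
                         n_genes = n_genes_total,
                         p_ns_given_d = p_ns_given_d)
  patients <- unique(mut$patient)
  if (n_patients > length(patients)) {
    # placeholder ids so unmutated patients enter the cohort averages
    patients <- c(patients,
                  paste0(".unmutated", seq_len(n_patients - length(patients))))
  }
  bg <- compute_background(mut, gene_context, patients = patients,
                           clonal_threshold = clonal_threshold)
  results <- score_genes(bg, params)

  null <- null_rank_profile(bg, params, n_reps = n_reps, seed = seed)
  fdr_h <- estimate_fdr(sort(results$posterior_hazard, decreasing = TRUE),
                        null$null_hazard)
  fdr_d <- estimate_fdr(sort(results$posterior_driver, decreasing = TRUE),
                        null$null_driver)
  cutoff <- optimal_rank(fdr_h, fdr_d, alpha = alpha)

  # results are ranked by the driver model; attach that model's FDR by rank
  results$fdr <- fdr_d[results$rank]
  results$significant <- results$rank <= cutoff$rank_combined

  structure(
    list(results = results, background = bg, null = null,
         fdr = tibble(rank = seq_along(fdr_h), fdr_hazard = fdr_h,
                      fdr_driver = fdr_d),
         cutoff = cutoff,
         params = params, alpha = alpha, seed = seed,
         n_patients = length(bg$patients)),
    class = "driver_scan"
  )
}

#' @export
print.driver_scan <- function(x, ...) {
  cat("Driver gene scan:", nrow(x$results), "genes,", x$n_patients,
      "patients\n")
  cat("Clonal rate r =", format(x$background$r, digits = 4),
      "| FDR alpha =", x$alpha, "\n")
  cat("Rank cutoffs: hazard", x$cutoff$rank_hazard, "| driver",
      x$cutoff$rank_driver, "| combined", x$cutoff$rank_combined, "\n")
  cat("Significant genes:", sum(x$results$significant), "\n\n")
  print(head(x$results, 10))
  invisible(x)
}

#' @rdname driver_scan
#' @param x,object A `driver_scan` object.
#' @param ... Unused.
#' @method tidy driver_scan
#' @export
tidy.driver_scan <- function(x, ...) x$results

#' @rdname driver_scan
#' @method glance driver_scan
#' @export
glance.driver_scan <- function(object, ...) {
  tibble(
    n_genes = nrow(object$results),
    n_patients = object$n_patients,
    clonal_rate = object$background$r,
    alpha = object$alpha,
    rank_hazard = object$cutoff$rank_hazard,
    rank_driver = object$cutoff$rank_driver,
    rank_combined = object$cutoff$rank_combined,
    n_significant = sum(object$results$significant)
  )
}

#' @rdname driver_scan
#' @param top_n Number of top-ranked genes to display.
#' @method autoplot driver_scan
#' @export
autoplot.driver_scan <- function(object, top_n = 20, ...) {
  df <- object$results |>
    arrange(.data$rank) |>
    head(top_n) |>
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$posterior_driver,
                                   y = .data$gene,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "driver posterior", y = NULL,
                  title = "Top-ranked candidate driver genes") +
    ggplot2::theme_minimal()
}

#' Run the full pipeline on files
#'
#' File-level wrapper around [driver_scan()]: reads the extended MAF, the
#' gene-context table and the driver gene list, runs the scan, and writes
#' the ranked results, the background table, the null/FDR table and a run
#' log recording every applied default and the seed.
#'
#' @param maf_path Extended MAF file.
#' @param gene_context_path Gene-context TSV.
#' @param driver_list_path Plain-text gold-standard gene list.
#' @param outdir Output directory (created if needed).
#' @param ... Passed to [driver_scan()].
#' @param seed Seed for the resampling null.
#' @return The `driver_scan` object, invisibly.
#' @export
run_pipeline <- function(maf_path, gene_context_path, driver_list_path,
                         outdir, seed = 1, ...) {
  for (p in c(maf_path, gene_context_path, driver_list_path)) {
    if (!file.exists(p)) abort(paste0("[input] file not found: ", p))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("clonedriver run ", format(Sys.time())),
                 paste0("seed: ", seed),
                 paste0("maf: ", maf_path),
                 paste0("gene_context: ", gene_context_path),
                 paste0("driver_list: ", driver_list_path))
  msgs <- character(0)
  scan <- withCallingHandlers(
    driver_scan(read_maf(maf_path), read_gene_context(gene_context_path),
                driver_genes = read_gene_list(driver_list_path),
                seed = seed, ...),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  write_results(scan$results, file.path(outdir, "results.tsv"))
  readr::write_tsv(scan$background$genes, file.path(outdir, "background.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    dplyr::bind_cols(scan$null$profile,
                     scan$fdr |> select(-all_of("rank"))),
    file.path(outdir, "null_fdr.tsv"), progress = FALSE)
  writeLines(c(log_lines, trimws(msgs)), file.path(outdir, "run_log.txt"))
  invisible(scan)
}
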