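#' Resample gene labels to build a null cohort
#'
#' Draws a new gene label for every mutation, i.i.d. with replacement, with
#' gene `g` chosen with probability proportional to its background mutation
#' probability. Everything else about each mutation (patient, CCF, damage,
#' classification) is kept, so the null preserves the cohort's mutational
#' load and clonality structure while destroying any gene-specific
#' recurrence signal beyond the background.
#'
#' @param mutations Mutation tibble.
#' @param bmp Named per-gene background probability vector (names are the
#'   gene universe to sample from); must have a positive sum.
#' @param seed Optional integer seed for reproducibility.
#' @return The mutation tibble with resampled `gene` labels.
#' @export
sample_null_cohort <- function(mutations, bmp, seed = NULL) {
  if (is.null(names(bmp))) abort("bmp must be a named per-gene vector")
  if (sum(bmp) <= 0) abort("bmp vector sums to zero; cannot sample")
  if (!is.null(seed)) set.seed(seed)
  m <- as_tibble(mutations)
  m$gene <- sample(names(bmp), nrow(m), replace = TRUE, prob = bmp / sum(bmp))
  m
}

#' Null posterior profile by rank
#'
#' Repeats the label-resampling null `n_reps` times; in each replicate both
#' Bayesian models are re-run on the relabelled cohort (with the observed
#' background probabilities and likelihood parameters held fixed — the bmp
#' vector defines the null) and the posteriors are sorted in decreasing
#' order. The profile stores, for each rank, the median posterior across
#' replicates, separately per model, plus the full per-replicate matrices
#' used by [estimate_fdr()].
#'
#' @param background A `cohort_background` object.
#' @param params A [bayes_params()] object.
#' @param n_reps Number of null replicates (default 100).
#' @param seed Master seed; per-replicate seeds are drawn from it so
#'   replicates are reproducible independently of evaluation order.
#' @return A list of class `null_model` with elements `profile` (tibble:
#'   rank, median_hazard, median_driver), `null_hazard` and `null_driver`
#'   (rank x replicate matrices of sorted posteriors), `n_reps`, `seed`.
#' @export
null_rank_profile <- function(background, params, n_reps = 100, seed = 1) {
  stopifnot(inherits(background, "cohort_background"))
  if (n_reps < 1) abort("n_reps must be at least 1")
  g <- background$genes
  n_patients <- length(background$patients)
  bmp <- setNames(g$bmp, g$gene)
  p_ns_d <- driver_likelihood(background$mutations, params,
                              n_patients = n_patients)
  prior_d <- driver_prior(params)

  mut <- as_tibble(background$mutations)
  mut <- mut[mut$classification %in% nonsilent_classes(), , drop = FALSE]
  weight <- mut$ccf * mut$damage
  patient <- mut$patient
  n_mut <- nrow(mut)
  prob <- bmp / sum(bmp)
  gene_pool <- names(bmp)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  G <- length(gene_pool)
  null_h <- matrix(0, nrow = G, ncol = n_reps)
  null_d <- matrix(0, nrow = G, ncol = n_reps)
  for (j in seq_len(n_reps)) {
    set.seed(rep_seeds[j])
    new_gene <- sample(gene_pool, n_mut, replace = TRUE, prob = prob)
    # per (gene, patient) keep the max CCF x damage contribution
    ord <- order(new_gene, patient, -weight)
    keep <- !duplicated(paste(new_gene[ord], patient[ord], sep = "\r"))
    mvec <- evidence_mass_fast(new_gene[ord][keep], weight[ord][keep],
                               gene_pool)
    null_h[, j] <- sort(hazard_posterior(mvec, n_patients, bmp,
                                         params$incidence),
                        decreasing = TRUE)
    null_d[, j] <- sort(driver_posterior(mvec, n_patients, p_ns_d, bmp,
                                         prior_d),
                        decreasing = TRUE)
  }
  profile <- tibble(
    rank = seq_len(G),
    median_hazard = apply(null_h, 1, median),
    median_driver = apply(null_d, 1, median)
  )
  structure(list(profile = profile, null_hazard = null_h,
                 null_driver = null_d, n_reps = n_reps, seed = seed),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("Resampling null model:", x$n_reps, "replicates,",
      nrow(x$profile), "ranks\n")
  print(head(x$profile))
  invisible(x)
}

#' Per-rank empirical FDR from the resampling null
#'
#' For the observed posterior at rank `k`, each null replicate yields an
#' exceedance count (how many of its posteriors are at least as large); the
#' FDR at rank `k` is the median exceedance across replicates divided by
#' `k`, capped at 1 and made nondecreasing in `k` by a cumulative maximum.
#'
#' @param observed Observed posterior vector sorted in decreasing order.
#' @param null_matrix Rank x replicate matrix of sorted null posteriors
#'   (`null_hazard` or `null_driver` from [null_rank_profile()]).
#' @return Numeric FDR vector over ranks `1..length(observed)`.
#' @export
estimate_fdr <- function(observed, null_matrix) {
  if (is.unsorted(rev(observed))) {
    abort("observed posteriors must be sorted in decreasing order")
  }
  k <- seq_along(observed)
  exceed <- vapply(seq_len(ncol(null_matrix)), function(j) {
    nd <- null_matrix[, j]                      # already decreasing
    # count of null posteriors >= observed[k], via ascending findInterval
    findInterval(-observed, sort(-nd))
  }, numeric(length(observed)))
  exceed <- matrix(exceed, nrow = length(observed))
  fdr <- apply(exceed, 1, median) / k
  cummax(pmin(fdr, 1))
}

#' Optimal significance rank from both models' FDR curves
#'
#' Per model the cutoff is the largest rank whose FDR does not exceed
#' `alpha` (0 when no rank qualifies); the suggested combined cutoff is the
#' floored mean of the two model cutoffs.
#'
#' @param fdr_hazard,fdr_driver Per-rank FDR vectors of equal length.
#' @param alpha FDR threshold (default 0.1).
#' @return A list with `rank_hazard`, `rank_driver` and `rank_combined`.
#' @export
optimal_rank <- function(fdr_hazard, fdr_driver, alpha = 0.1) {
  if (length(fdr_hazard) != length(fdr_driver)) {
    abort("FDR vectors must have equal length")
  }
  last_ok <- function(fdr) {
    ok <- which(fdr <= alpha)
    if (length(ok) == 0) 0L else max(ok)
  }
  rh <- last_ok(fdr_hazard)
  rd <- last_ok(fdr_driver)
  list(rank_hazard = rh, rank_driver = rd,
       rank_combined = as.integer(floor((rh + rd) / 2)))
}
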