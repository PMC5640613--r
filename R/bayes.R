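#' Bayesian model parameters
#'
#' @param incidence Prior probability of developing the cancer (population
#'   incidence of the tumor type), in `(0, 1)`.
#' @param driver_genes Character vector of known driver genes (a gold
#'   standard) used to estimate the driver-model prior and likelihood.
#' @param n_genes Total number of protein-coding genes (default 20000).
#' @param n_known_drivers Number of known drivers for the prior; defaults to
#'   `length(driver_genes)`.
#' @param p_ns_given_d Optional user-supplied value for the probability that
#'   a driver gene is mutated in a patient, overriding the cohort estimate.
#' @return A list of class `bayes_params`.
#' @export
bayes_params <- function(incidence = 0.1, driver_genes = character(0),
                         n_genes = 20000,
                         n_known_drivers = length(driver_genes),
                         p_ns_given_d = NULL) {
  if (incidence <= 0 || incidence >= 1) abort("incidence must be in (0, 1)")
  if (n_known_drivers <= 0 && is.null(p_ns_given_d)) {
    abort("need a nonempty driver gene list (or p_ns_given_d override)")
  }
  if (n_known_drivers >= n_genes) {
    abort("n_known_drivers must be smaller than n_genes")
  }
  structure(list(incidence = incidence, driver_genes = driver_genes,
                 n_genes = n_genes, n_known_drivers = n_known_drivers,
                 p_ns_given_d = p_ns_given_d),
            class = "bayes_params")
}

#' Per-gene evidence mass
#'
#' For each gene, patients contribute the product CCF x damage of their
#' single retained nonsilent mutation (the highest-CCF one, see
#' [collapse_per_patient()]); patients without a nonsilent mutation in the
#' gene contribute zero. The evidence mass `m` is the sum over the whole
#' cohort and `n` is the full cohort size, so `m / n` is the per-patient
#' likelihood of a damaging clonal hit.
#'
#' @param mutations Mutation tibble with derived `ccf` and `damage`.
#' @param genes Gene universe for the output (genes without mutations get
#'   `m = 0`).
#' @param n_patients Total cohort size, including patients with no mutation.
#' @return Tibble with columns `gene`, `m`, `n`.
#' @export
evidence_mass <- function(mutations, genes = NULL,
                          n_patients = length(unique(mutations$patient))) {
  m <- collapse_per_patient(mutations)
  genes <- genes %||% sort(unique(as_tibble(mutations)$gene))
  mass <- evidence_mass_fast(m$gene, m$ccf * m$damage, genes)
  tibble(gene = genes, m = unname(mass), n = n_patients)
}

# rowsum-based core shared with the resampling null (already collapsed input)
evidence_mass_fast <- function(gene, weight, genes) {
  out <- setNames(numeric(length(genes)), genes)
  if (length(gene) == 0) return(out)
  s <- rowsum(weight, gene)
  out[rownames(s)] <- as.numeric(s)
  out
}

#' Cancer-hazard posterior
#'
#' Posterior probability that an individual develops the cancer given a
#' nonsilent mutation in the gene: the likelihood of the mutation under the
#' cancer branch is the evidence mass rate `L = m / n`, under the healthy
#' branch the background mutation probability, and the prior is the
#' population incidence.
#'
#' @param m Evidence mass (vectorised).
#' @param n Cohort size.
#' @param bmp Per-gene background mutation probability.
#' @param incidence Prior incidence in `(0, 1)`.
#' @return Posterior probabilities in `[0, 1]`; defined as 0 when both
#'   likelihood channels are 0 (no evidence either way).
#' @export
hazard_posterior <- function(m, n, bmp, incidence) {
  if (incidence <= 0 || incidence >= 1) abort("incidence must be in (0, 1)")
  L <- m / n
  num <- L * incidence
  den <- num + bmp * (1 - incidence)
  out <- if_else(den > 0, num / den, 0)
  out
}

#' Driver-model prior
#'
#' @param params A [bayes_params()] object.
#' @return `n_known_drivers / n_genes`.
#' @export
driver_prior <- function(params) {
  if (params$n_known_drivers <= 0) abort("driver prior requires > 0 known drivers")
  params$n_known_drivers / params$n_genes
}

#' Driver-model likelihood of mutation
#'
#' Probability that a known driver gene carries a nonsilent mutation in a
#' patient, estimated from the cohort as the count of nonsilent mutations in
#' listed driver genes divided by (number of patients x number of listed
#' drivers); all drivers are assumed equally likely to be hit. A
#' user-supplied override in `params` is returned verbatim.
#'
#' @param mutations Mutation tibble.
#' @param params A [bayes_params()] object.
#' @param n_patients Total cohort size.
#' @return A probability; capped at 1 with a warning if the raw ratio
#'   exceeds 1.
#' @export
driver_likelihood <- function(mutations, params,
                              n_patients = length(unique(mutations$patient))) {
  if (!is.null(params$p_ns_given_d)) return(params$p_ns_given_d)
  if (length(params$driver_genes) == 0) {
    abort("empty driver gene list and no p_ns_given_d override")
  }
  m <- as_tibble(mutations)
  hits <- sum(m$classification %in% nonsilent_classes() &
                m$gene %in% params$driver_genes)
  p <- hits / (n_patients * length(params$driver_genes))
  if (p > 1) {
    warn("driver likelihood estimate exceeds 1; capping at 1")
    p <- 1
  }
  if (p == 0) warn("no nonsilent mutations in listed driver genes; likelihood 0")
  p
}

#' Driver-inference posterior
#'
#' Posterior probability that a gene is a driver given the cohort evidence.
#' The evidence mass `m` (a real-valued CCF x damage weighted count) and its
#' complement `n - m` exponentiate the per-patient mutation probabilities of
#' the driver branch (`p_ns_d`) and the passenger branch (`bmp`); evaluation
#' is in log space so large cohorts do not underflow. Probabilities exactly
#' 0 or 1 are clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param m Evidence mass (vectorised over genes).
#' @param n Cohort size.
#' @param p_ns_d Probability a driver gene is mutated in a patient.
#' @param bmp Per-gene background mutation probability.
#' @param prior_d Prior probability that a gene is a driver.
#' @return Posterior probabilities in `[0, 1]`.
#' @export
driver_posterior <- function(m, n, p_ns_d, bmp, prior_d) {
  if (prior_d <= 0 || prior_d >= 1) abort("prior_d must be in (0, 1)")
  if (any(m < 0) || any(m > n)) abort("m must lie in [0, n]")
  p_d <- clamp_prob(p_ns_d)
  p_p <- clamp_prob(bmp)
  log_num <- m * log(p_d) + (n - m) * log1p(-p_d) + log(prior_d)
  log_alt <- m * log(p_p) + (n - m) * log1p(-p_p) + log1p(-prior_d)
  # posterior = exp(log_num) / (exp(log_num) + exp(log_alt)), stably:
  1 / (1 + exp(log_alt - log_num))
}

#' Score and rank all genes with both Bayesian models
#'
#' Computes the per-gene evidence mass, both posteriors (cancer-hazard and
#' driver-inference) and the default ranking: by driver posterior
#' descending, ties broken by hazard posterior, then evidence mass, then
#' gene symbol.
#'
#' @param background A `cohort_background` object from
#'   [compute_background()].
#' @param params A [bayes_params()] object.
#' @return Tibble with columns `gene`, `m`, `n`, `posterior_hazard`,
#'   `posterior_driver`, `rank`.
#' @export
score_genes <- function(background, params) {
  stopifnot(inherits(background, "cohort_background"))
  g <- background$genes
  n_patients <- length(background$patients)
  ev <- evidence_mass(background$mutations, genes = g$gene,
                      n_patients = n_patients)
  p_ns_d <- driver_likelihood(background$mutations, params,
                              n_patients = n_patients)
  prior_d <- driver_prior(params)
  res <- tibble(
    gene = g$gene, m = ev$m, n = n_patients,
    posterior_hazard = hazard_posterior(ev$m, n_patients, g$bmp,
                                        params$incidence),
    posterior_driver = driver_posterior(ev$m, n_patients, p_ns_d, g$bmp,
                                        prior_d)
  )
  rank_genes(res)
}

#' Rank a gene result table
#'
#' @param results Tibble with `posterior_driver`, `posterior_hazard`, `m`
#'   and `gene` columns.
#' @param by Ranking model: `"driver"` (default), `"hazard"`, or
#'   `"average"` (mean of the two models' ranks, ties by driver rank).
#' @return The tibble sorted with a `rank` column `1..G`.
#' @export
rank_genes <- function(results, by = c("driver", "hazard", "average")) {
  by <- match.arg(by)
  r <- as_tibble(results)
  ord_driver <- order(-r$posterior_driver, -r$posterior_hazard, -r$m, r$gene)
  if (by == "driver") {
    ord <- ord_driver
  } else if (by == "hazard") {
    ord <- order(-r$posterior_hazard, -r$posterior_driver, -r$m, r$gene)
  } else {
    rk_d <- rk_h <- integer(nrow(r))
    rk_d[ord_driver] <- seq_len(nrow(r))
    ord_h <- order(-r$posterior_hazard, -r$posterior_driver, -r$m, r$gene)
    rk_h[ord_h] <- seq_len(nrow(r))
    ord <- order((rk_d + rk_h) / 2, rk_d)
  }
  r <- r[ord, , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  r
}
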