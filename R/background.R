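#' CCF-adjusted mutation counts per gene
#'
#' The classical Ka/Ks selection test counts nonsynonymous and synonymous
#' substitutions; here each mutation contributes its CCF instead of a unit
#' count, so subclonal mutations (late, more likely neutral) are
#' down-weighted. Sums run over all mutations of the gene across the cohort
#' with no per-patient collapse. With all CCF = 1 this reduces to the raw
#' count model.
#'
#' @param mutations Mutation tibble with derived `ccf`.
#' @param genes Character vector defining the gene universe of the output;
#'   genes with no mutations get counts `(0, 0)`.
#' @return Tibble with columns `gene`, `n_a_ccf` (CCF sum over nonsilent
#'   mutations) and `n_s_ccf` (CCF sum over silent mutations).
#' @export
ccf_adjusted_counts <- function(mutations, genes = NULL) {
  m <- as_tibble(mutations)
  if (!"ccf" %in% names(m) || anyNA(m$ccf)) {
    abort("all mutations need a derived ccf; run add_ccf() first")
  }
  genes <- genes %||% sort(unique(m$gene))
  nonsil <- m$classification %in% nonsilent_classes()
  sum_by <- function(keep) {
    out <- setNames(numeric(length(genes)), genes)
    if (!any(keep)) return(out)
    s <- rowsum(m$ccf[keep], m$gene[keep])
    out[rownames(s)] <- as.numeric(s)
    out
  }
  tibble(gene = genes,
         n_a_ccf = unname(sum_by(nonsil)[genes]),
         n_s_ccf = unname(sum_by(!nonsil)[genes]))
}

#' Floor silent counts so one nonsilent mutation is never a selection signal
#'
#' Under neutrality (Ka/Ks = 1) a single nonsilent mutation corresponds to a
#' silent CCF sum of `N_s / N_a`. Genes with fewer observed silent mutations
#' than that floor would make any lone nonsilent mutation look positively
#' selected, so the silent count is raised to the floor:
#' `max(n_s_ccf, N_s / N_a)`.
#'
#' @param n_s_ccf CCF-adjusted silent count(s).
#' @param n_sites_nonsyn Nonsynonymous site count(s) `N_a`.
#' @param n_sites_syn Synonymous site count(s) `N_s`.
#' @return Corrected silent counts, vectorised.
#' @export
correct_silent_counts <- function(n_s_ccf, n_sites_nonsyn, n_sites_syn) {
  if (any(n_sites_nonsyn <= 0) || any(n_sites_syn <= 0)) {
    abort("site counts must be strictly positive")
  }
  pmax(n_s_ccf, n_sites_syn / n_sites_nonsyn)
}

#' Expected nonsilent count under the CCF-adjusted Ka/Ks model
#'
#' Neutral expectation: `n_s' * N_a / N_s`.
#'
#' @param n_s_corrected Corrected silent count(s) from
#'   [correct_silent_counts()].
#' @inheritParams correct_silent_counts
#' @return Expected nonsilent counts, vectorised.
#' @export
expected_nonsilent_kaks <- function(n_s_corrected, n_sites_nonsyn,
                                    n_sites_syn) {
  if (any(n_sites_syn <= 0)) abort("N_s must be strictly positive")
  n_s_corrected * n_sites_nonsyn / n_sites_syn
}

#' Expected nonsilent count under the non-coding mutation-rate model
#'
#' The per-gene non-coding mutation rate times coding length gives the
#' expected total mutation count `n_t`; under neutrality the nonsilent share
#' is `n_t / (1 + N_s / N_a)`.
#'
#' @param ncmr Non-coding mutation rate(s) per bp.
#' @param length Coding length(s) in bp.
#' @inheritParams correct_silent_counts
#' @return Expected nonsilent counts, vectorised.
#' @export
expected_nonsilent_ncmr <- function(ncmr, length, n_sites_nonsyn,
                                    n_sites_syn) {
  if (any(ncmr < 0)) abort("ncmr must be nonnegative")
  n_t <- ncmr * length
  n_t / (1 + n_sites_syn / n_sites_nonsyn)
}

#' Cohort clonal mutation rate
#'
#' Approximates the pre-tumor mutation load: clonal mutations (CCF at or
#' above the threshold) are assumed to have been passengers acquired before
#' transformation, so the cohort mean per-patient count of clonal nonsilent
#' mutations plays the number of binomial trials in the background model.
#' Patients with no clonal mutation contribute zero to the mean. SNVs only
#' by default.
#'
#' @param mutations Mutation tibble with derived `ccf`.
#' @param patients Character vector of all patient identifiers in the cohort
#'   (defaults to the patients present in `mutations`; pass explicitly if
#'   some patients carry no mutation at all).
#' @param threshold Clonality CCF cutoff (default 0.85, inclusive).
#' @param include_indels Also count clonal indels (default `FALSE`).
#' @return The scalar clonal rate `r >= 0`.
#' @export
clonal_mutation_rate <- function(mutations, patients = NULL, threshold = 0.85,
                                 include_indels = FALSE) {
  m <- as_tibble(mutations)
  patients <- patients %||% unique(m$patient)
  if (length(patients) == 0) abort("empty cohort: no patients")
  classes <- setdiff(nonsilent_classes(), if (include_indels) character(0) else "indel")
  keep <- m$classification %in% classes & !is.na(m$ccf) & m$ccf >= threshold
  counts <- table(factor(m$patient[keep], levels = patients))
  mean(as.numeric(counts))
}

#' Background mutation probability from expected counts
#'
#' Each of the `r` pre-tumor nonsilent mutation events falls in gene `g`
#' with probability `p_g = expected_g / sum(expected)`; the probability the
#' gene is hit at least once is `1 - (1 - p_g)^r` (binomial, zero-class
#' complement). `r` is a cohort mean and is used directly as a real-valued
#' exponent.
#'
#' @param expected Named or unnamed vector of per-gene expected nonsilent
#'   counts; must have a positive sum.
#' @param r Clonal rate from [clonal_mutation_rate()].
#' @return Vector of per-gene background mutation probabilities in `[0, 1]`.
#' @export
background_probability <- function(expected, r) {
  if (any(expected < 0)) abort("expected counts must be nonnegative")
  total <- sum(expected)
  if (total <= 0) abort("all expected counts are zero; cannot normalise")
  if (r < 0) abort("r must be nonnegative")
  p <- expected / total
  1 - (1 - p)^r
}

#' Average two background mutation probability vectors
#'
#' @param bmp_kaks,bmp_ncmr Per-gene probability vectors over the same gene
#'   set (compared by names when both are named).
#' @return Per-gene arithmetic mean.
#' @export
combine_bmp <- function(bmp_kaks, bmp_ncmr) {
  if (length(bmp_kaks) != length(bmp_ncmr)) {
    abort("bmp vectors cover different gene sets (lengths differ)")
  }
  if (!is.null(names(bmp_kaks)) && !is.null(names(bmp_ncmr)) &&
      !identical(names(bmp_kaks), names(bmp_ncmr))) {
    abort("bmp vectors cover different gene sets (names differ)")
  }
  (bmp_kaks + bmp_ncmr) / 2
}

#' Compute the full cohort background model
#'
#' Runs both background models gene by gene — the CCF-adjusted Ka/Ks model
#' built from the cohort's silent mutations and the non-coding mutation-rate
#' model built from published per-gene rates — converts each expected count
#' vector into a background mutation probability via the binomial model with
#' the cohort clonal rate `r`, and averages the two probabilities.
#'
#' Mutations in genes absent from the context table are dropped with a
#' warning (the background models are undefined without site counts).
#'
#' @param mutations Mutation tibble with derived `ccf`.
#' @param gene_context Gene context tibble from [read_gene_context()].
#' @param patients Optional full cohort patient vector (see
#'   [clonal_mutation_rate()]).
#' @param clonal_threshold CCF cutoff defining clonal mutations (default
#'   0.85).
#' @param include_indels Count clonal indels in `r` (default `FALSE`).
#' @return A list of class `cohort_background` with elements `genes` (tibble:
#'   gene, n_a_ccf, n_s_ccf, n_s_corrected, expected_nonsilent_kaks,
#'   expected_total_ncmr, expected_nonsilent_ncmr, bmp_kaks, bmp_ncmr, bmp),
#'   `r` (clonal rate), `clonal_threshold` and `mutations` (the retained
#'   mutation tibble).
#' @export
compute_background <- function(mutations, gene_context, patients = NULL,
                               clonal_threshold = 0.85,
                               include_indels = FALSE) {
  m <- as_tibble(mutations)
  ctx <- as_tibble(gene_context)
  orphan <- setdiff(unique(m$gene), ctx$gene)
  if (length(orphan) > 0) {
    warn(paste0("Dropping ", sum(m$gene %in% orphan), " mutation(s) in ",
                length(orphan), " gene(s) absent from the gene-context table"))
    m <- m[!m$gene %in% orphan, , drop = FALSE]
  }
  patients <- patients %||% unique(m$patient)

  counts <- ccf_adjusted_counts(m, genes = ctx$gene)
  g <- left_join(counts, ctx, by = "gene")
  g$n_s_corrected <- correct_silent_counts(g$n_s_ccf, g$n_sites_nonsyn,
                                           g$n_sites_syn)
  g$expected_nonsilent_kaks <- expected_nonsilent_kaks(
    g$n_s_corrected, g$n_sites_nonsyn, g$n_sites_syn)
  g$expected_total_ncmr <- g$ncmr * g$length
  g$expected_nonsilent_ncmr <- expected_nonsilent_ncmr(
    g$ncmr, g$length, g$n_sites_nonsyn, g$n_sites_syn)

  r <- clonal_mutation_rate(m, patients = patients,
                            threshold = clonal_threshold,
                            include_indels = include_indels)
  g$bmp_kaks <- background_probability(g$expected_nonsilent_kaks, r)
  g$bmp_ncmr <- if (sum(g$expected_nonsilent_ncmr) > 0) {
    background_probability(g$expected_nonsilent_ncmr, r)
  } else {
    # no ncmr information: fall back on the Ka/Ks model alone
    g$bmp_kaks
  }
  g$bmp <- combine_bmp(g$bmp_kaks, g$bmp_ncmr)

  structure(
    list(genes = g |> select(-all_of(c("n_sites_nonsyn", "n_sites_syn",
                                       "length", "ncmr"))),
         r = r, clonal_threshold = clonal_threshold,
         mutations = m, patients = patients),
    class = "cohort_background"
  )
}

#' @export
print.cohort_background <- function(x, ...) {
  cat("Cohort background model:", nrow(x$genes), "genes,",
      length(x$patients), "patients\n")
  cat("Clonal rate r =", format(x$r, digits = 4),
      "(CCF >=", x$clonal_threshold, ")\n")
  print(head(x$genes))
  invisible(x)
}

#' @rdname compute_background
#' @param x A `cohort_background` object.
#' @param ... Unused.
#' @method tidy cohort_background
#' @export
tidy.cohort_background <- function(x, ...) x$genes
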