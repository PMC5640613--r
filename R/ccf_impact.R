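#' Sigmoid damage transform parameters
#'
#' The raw CADD-like impact score is mapped to a damage probability with the
#' logistic function `1 / (1 + exp(-(x - mu) / scale))`. The defaults
#' (midpoint 15, scale 2) place scores around 15 at damage 0.5 and saturate
#' quickly above ~25, matching the conventional "likely deleterious" range of
#' scaled CADD scores.
#'
#' @param mu Sigmoid midpoint on the raw impact scale.
#' @param scale Sigmoid scale factor; must be positive.
#' @return A list with elements `mu` and `scale`.
#' @export
impact_params <- function(mu = 15, scale = 2) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("impact scale must be a single positive number")
  }
  list(mu = mu, scale = scale)
}

#' Damage probability from a raw impact score
#'
#' @param impact_raw Nonnegative raw impact score(s), CADD-like scale.
#' @param params Parameters from [impact_params()].
#' @return Damage probabilities in `[0, 1]`, same length as `impact_raw`;
#'   `NA` inputs stay `NA`.
#' @examples
#' damage_score(15)            # 0.5 at the midpoint
#' damage_score(c(5, 25, 35))
#' @export
damage_score <- function(impact_raw, params = impact_params()) {
  if (params$scale <= 0) abort("impact scale must be positive")
  1 / (1 + exp(-(impact_raw - params$mu) / params$scale))
}

#' Estimate the cancer cell fraction of a mutation
#'
#' In a pure diploid tumor a clonal heterozygous SNV is carried on one of two
#' alleles, so its expected VAF is 1/2: CCF is the VAF multiplied by two and
#' corrected for purity. In general, with tumor purity `p`, local tumor total
#' copy number `c` and mutation multiplicity 1, the expected VAF of a
#' mutation present in a fraction `CCF` of tumor cells is
#' `CCF * p / (p * c + 2 * (1 - p))`, which inverts to
#' `CCF = vaf * (p * c + 2 * (1 - p)) / p`. When only a fraction `cnv_ccf`
#' of cancer cells carries the overlapping CNV, the effective copy number is
#' the CCF-weighted average `2 * (1 - cnv_ccf) + c * cnv_ccf`. The result is
#' clipped to `[0, 1]` as a last step.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param copy_number Local tumor total copy number (positive; default 2).
#' @param cnv_ccf Fraction of cancer cells carrying the overlapping CNV, or
#'   `NA` when no CNV overlaps (then `copy_number` is used as-is).
#' @return CCF values in `[0, 1]`, vectorised over the inputs.
#' @examples
#' estimate_ccf(0.5, purity = 1)            # clonal het SNV, pure diploid -> 1
#' estimate_ccf(0.25, purity = 0.5)         # half-pure sample -> 1
#' estimate_ccf(0.1, purity = 0.8, copy_number = 4, cnv_ccf = 1)
#' @export
estimate_ccf <- function(vaf, purity = 1, copy_number = 2, cnv_ccf = NA_real_) {
  if (any(!is.na(purity) & purity <= 0)) abort("purity must be > 0")
  if (any(!is.na(vaf) & (vaf < 0 | vaf > 1))) abort("vaf must be in [0, 1]")
  if (any(!is.na(copy_number) & copy_number <= 0)) {
    abort("copy_number must be positive")
  }
  cn_eff <- if_else(!is.na(cnv_ccf) & cnv_ccf < 1,
                    2 * (1 - cnv_ccf) + copy_number * cnv_ccf,
                    copy_number)
  ccf <- vaf * (purity * cn_eff + 2 * (1 - purity)) / purity
  pmin(pmax(ccf, 0), 1)
}

#' Add derived CCF values to a mutation table
#'
#' @param mutations Mutation tibble (see [read_maf()]).
#' @param recompute Recompute CCF even for rows that already carry one
#'   (default `FALSE`: precomputed CCFs, e.g. from a clonal-deconvolution
#'   tool, are preserved).
#' @return The tibble with its `ccf` column filled.
#' @export
add_ccf <- function(mutations, recompute = FALSE) {
  m <- as_tibble(mutations)
  if (!"ccf" %in% names(m)) m$ccf <- NA_real_
  if (!"purity" %in% names(m)) m$purity <- 1
  if (!"copy_number" %in% names(m)) m$copy_number <- 2
  if (!"cnv_ccf" %in% names(m)) m$cnv_ccf <- NA_real_
  todo <- if (recompute) rep(TRUE, nrow(m)) else is.na(m$ccf)
  if (any(todo)) {
    m$ccf[todo] <- estimate_ccf(m$vaf[todo], m$purity[todo],
                                m$copy_number[todo], m$cnv_ccf[todo])
  }
  m
}

#' Add damage probabilities to a mutation table
#'
#' @inheritParams add_ccf
#' @param params Parameters from [impact_params()].
#' @param missing_damage Damage assigned to mutations without a raw impact
#'   score (default 0.5: uninformative).
#' @return The tibble with its `damage` column filled.
#' @export
add_damage <- function(mutations, params = impact_params(), recompute = FALSE,
                       missing_damage = 0.5) {
  m <- as_tibble(mutations)
  if (!"damage" %in% names(m)) m$damage <- NA_real_
  if (!"impact_raw" %in% names(m)) m$impact_raw <- NA_real_
  todo <- if (recompute) rep(TRUE, nrow(m)) else is.na(m$damage)
  if (any(todo)) {
    d <- damage_score(m$impact_raw[todo], params)
    d[is.na(d)] <- missing_damage
    m$damage[todo] <- d
  }
  m
}

#' Keep one mutation per patient and gene
#'
#' When a patient carries several nonsilent mutations in the same gene, the
#' evidence mass uses only the mutation with the highest CCF. Ties are broken
#' by the highest damage probability, then by the lexicographically smallest
#' position string (if a `position` column is present), then by input order.
#'
#' @param mutations Mutation tibble with derived `ccf` and `damage`; silent
#'   mutations are excluded before collapsing.
#' @return Tibble with one row per (gene, patient) pair that has at least one
#'   nonsilent mutation.
#' @export
collapse_per_patient <- function(mutations) {
  m <- as_tibble(mutations)
  m <- m[m$classification %in% nonsilent_classes(), , drop = FALSE]
  if (nrow(m) == 0) return(m)
  pos <- if ("position" %in% names(m)) as.character(m$position)
         else rep("", nrow(m))
  ord <- order(m$gene, m$patient, -m$ccf, -m$damage, pos)
  m <- m[ord, , drop = FALSE]
  m[!duplicated(paste(m$gene, m$patient, sep = "\r")), , drop = FALSE]
}

#' Compare CCF distributions across mutation groups
#'
#' Splits the cohort's mutations into four groups — nonsilent or silent,
#' crossed with driver or passenger gene — and compares the CCF distribution
#' of every unordered pair of groups with a two-sided Wilcoxon-Mann-Whitney
#' rank-sum test. In cohorts under positive selection, nonsilent mutations in
#' driver genes are expected to be shifted towards clonality (CCF near 1)
#' relative to all three other groups.
#'
#' @param mutations Mutation tibble with derived `ccf`.
#' @param driver_genes Character vector of driver gene symbols.
#' @return A list of class `ccf_group_comparison` with elements `groups`
#'   (tibble: group, n, median_ccf) and `pairs` (tibble: group1, group2,
#'   statistic, p_value). Pairs where either group has fewer than 2
#'   mutations get `NA` p-values rather than an error.
#' @export
ccf_group_comparison <- function(mutations, driver_genes) {
  m <- as_tibble(mutations)
  if (!"ccf" %in% names(m) || anyNA(m$ccf)) {
    abort("all mutations need a derived ccf; run add_ccf() first")
  }
  grp <- paste0(
    if_else(m$classification %in% nonsilent_classes(), "nonsilent", "silent"),
    "_",
    if_else(m$gene %in% driver_genes, "driver", "passenger")
  )
  levels <- c("nonsilent_driver", "nonsilent_passenger",
              "silent_driver", "silent_passenger")
  ccf_by <- split(m$ccf, factor(grp, levels = levels))
  groups <- tibble(
    group = levels,
    n = vapply(ccf_by, length, integer(1)),
    median_ccf = vapply(ccf_by, function(x) {
      if (length(x) == 0) NA_real_ else median(x)
    }, numeric(1))
  )
  pair_idx <- utils::combn(levels, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(j) {
    g1 <- pair_idx[1, j]; g2 <- pair_idx[2, j]
    x <- ccf_by[[g1]]; y <- ccf_by[[g2]]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(group1 = g1, group2 = g2,
                    statistic = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(wilcox.test(x, y))
    p <- wt$p.value
    # zero rank variance (all values tied across both groups): no separation
    if (is.nan(p)) p <- 1
    tibble(group1 = g1, group2 = g2,
           statistic = unname(wt$statistic), p_value = p)
  })
  structure(list(groups = groups, pairs = pairs),
            class = "ccf_group_comparison")
}

#' @export
print.ccf_group_comparison <- function(x, ...) {
  cat("CCF distribution comparison (Wilcoxon-Mann-Whitney, two-sided)\n\n")
  print(x$groups)
  cat("\n")
  print(x$pairs)
  invisible(x)
}

#' @rdname ccf_group_comparison
#' @param x A `ccf_group_comparison` object.
#' @param ... Unused.
#' @method tidy ccf_group_comparison
#' @export
tidy.ccf_group_comparison <- function(x, ...) x$pairs

#' @rdname ccf_group_comparison
#' @param object A `ccf_group_comparison` object.
#' @method autoplot ccf_group_comparison
#' @export
autoplot.ccf_group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$median_ccf)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "median CCF",
                  title = "Median CCF by mutation group") +
    ggplot2::theme_minimal()
}
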