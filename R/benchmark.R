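#' Precision / recall / F-score curve against a gold standard
#'
#' Evaluates a ranked gene list against a gold-standard gene set at every
#' rank cutoff `k`: precision is the gold-standard fraction of the top-k,
#' recall the recovered fraction of the gold standard, and the F-score their
#' harmonic mean (0 when both are 0).
#'
#' @param ranked_genes Character vector of gene symbols, best first, or a
#'   results tibble with `gene` and `rank` columns.
#' @param gold_standard Nonempty character vector of gold-standard genes.
#' @return A list of class `evaluation_curve` with `curve` (tibble: rank,
#'   precision, recall, fscore), `gs_size`, `peak_fscore`, `peak_rank`,
#'   and `display_limit` (twice the gold-standard size, the conventional
#'   plotting truncation; the full curve is retained).
#' @export
precision_recall_fscore <- function(ranked_genes, gold_standard) {
  if (is.data.frame(ranked_genes)) {
    ranked_genes <- ranked_genes |> arrange(.data$rank) |> pull("gene")
  }
  if (length(ranked_genes) == 0) abort("empty ranking")
  gold_standard <- unique(gold_standard)
  if (length(gold_standard) == 0) abort("empty gold standard")
  hit <- cumsum(ranked_genes %in% gold_standard)
  k <- seq_along(ranked_genes)
  precision <- hit / k
  recall <- hit / length(gold_standard)
  fscore <- if_else(precision + recall > 0,
                    2 * precision * recall / (precision + recall), 0)
  curve <- tibble(rank = k, precision = precision, recall = recall,
                  fscore = fscore)
  structure(list(curve = curve, gs_size = length(gold_standard),
                 peak_fscore = max(fscore),
                 peak_rank = which.max(fscore),
                 display_limit = 2L * length(gold_standard)),
            class = "evaluation_curve")
}

#' @export
print.evaluation_curve <- function(x, ...) {
  cat("Evaluation curve vs", x$gs_size, "gold-standard genes\n")
  cat("Peak F-score", format(x$peak_fscore, digits = 3),
      "at rank", x$peak_rank, "\n")
  invisible(x)
}

#' @rdname precision_recall_fscore
#' @param x An `evaluation_curve` object.
#' @param ... Unused.
#' @method tidy evaluation_curve
#' @export
tidy.evaluation_curve <- function(x, ...) x$curve

#' @rdname precision_recall_fscore
#' @param object An `evaluation_curve` object.
#' @method glance evaluation_curve
#' @export
glance.evaluation_curve <- function(object, ...) {
  tibble(gs_size = object$gs_size, peak_fscore = object$peak_fscore,
         peak_rank = object$peak_rank)
}

#' @rdname precision_recall_fscore
#' @method autoplot evaluation_curve
#' @export
autoplot.evaluation_curve <- function(object, ...) {
  df <- object$curve |>
    filter(.data$rank <= object$display_limit) |>
    tidyr::pivot_longer(all_of(c("precision", "recall", "fscore")),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank cutoff", y = NULL,
                  title = "Precision / recall / F-score") +
    ggplot2::theme_minimal()
}

#' Truncated Borda count rank aggregation
#'
#' Combines several ranked gene lists into a consensus. Ranks beyond the
#' truncation are set to `truncation + 1` (genes absent from a list are
#' treated the same way), each gene scores `truncation + 1 - rank` per list,
#' and only the `top_n_methods` lists giving the gene its best (lowest)
#' ranks contribute. Genes are sorted by total score, ties alphabetical.
#'
#' @param rank_lists List of at least one character vector of gene symbols
#'   (best first) or results tibbles with `gene` and `rank`.
#' @param truncation Positive rank limit, conventionally twice the
#'   gold-standard size.
#' @param top_n_methods How many lists (the best ones per gene) contribute
#'   to each gene's score; if fewer lists are supplied, all are used with a
#'   warning.
#' @return Tibble with `gene`, `score`, `rank`.
#' @export
borda_ensemble <- function(rank_lists, truncation, top_n_methods = 3) {
  if (truncation <= 0) abort("truncation must be positive")
  lists <- purrr::map(rank_lists, function(x) {
    if (is.data.frame(x)) x <- x |> arrange(.data$rank) |> pull("gene")
    as.character(x)
  })
  if (length(lists) < 1) abort("need at least one ranked list")
  if (length(lists) < top_n_methods) {
    warn(paste0("only ", length(lists), " list(s) supplied; using all"))
    top_n_methods <- length(lists)
  }
  genes <- sort(unique(unlist(lists)))
  rank_mat <- vapply(lists, function(l) {
    r <- match(genes, l)
    r[is.na(r) | r > truncation] <- truncation + 1
    r
  }, numeric(length(genes)))
  rank_mat <- matrix(rank_mat, nrow = length(genes))
  score <- apply(rank_mat, 1, function(r) {
    best <- sort(r)[seq_len(top_n_methods)]
    sum(truncation + 1 - best)
  })
  out <- tibble(gene = genes, score = score) |>
    arrange(desc(.data$score), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}

#' Fisher enrichment test for a gene-set overlap
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[k1, n1 - k1], [k2, n2 - k2]]` (two-sided by summation of tables with
#' probability at most that of the observed table); used e.g. to test
#' whether chromatin modifiers are over-represented among novel driver
#' genes relative to a curated cancer gene census.
#'
#' @param k1,n1 Successes and size of group 1.
#' @param k2,n2 Successes and size of group 2.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Tibble with `estimate` (odds ratio), `p_value` and the table
#'   margins.
#' @export
enrichment_test <- function(k1, n1, k2, n2,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(c(k1, n1, k2, n2) < 0)) abort("counts must be nonnegative")
  if (k1 > n1 || k2 > n2) abort("successes cannot exceed group size")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = alternative)
  tibble(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
         estimate = unname(ft$estimate), p_value = ft$p.value,
         alternative = alternative)
}
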