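# Hypergeometric term enrichment with BH correction.

#' Hypergeometric term enrichment
#'
#' Tests each term for over-representation in the study set relative to the
#' background: with `N` annotated background genes, `K` of them carrying the
#' term, and `s` annotated study genes of which `k` carry it,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, s)`, computed from the 2x2
#' margins only. p-values are BH-corrected across all tested terms.
#'
#' The universe is the background restricted to genes with at least one
#' term; unannotated genes are counted and reported but take no part in the
#' test, so adding an unannotated gene to both sets changes nothing. By
#' default a term is tested only when it has at least one background and one
#' study hit, mirroring common GO-enrichment practice.
#'
#' @param study Character vector of study genes; must be a subset of
#'   `background` (after annotation restriction this is re-checked and a
#'   violation lists the offending genes).
#' @param background Character vector of background genes.
#' @param term_map Tibble with gene_id, term.
#' @param q_threshold Optional q-value filter applied to the result.
#' @param min_k,min_K Minimum study/background hits for a term to be tested
#'   (defaults 1 and 1).
#' @return Tibble sorted by q: term, k, s, K, N, p_value, q_value; the
#'   number of unannotated study/background genes is attached as the
#'   `"unannotated"` attribute.
#' @export
enrich <- function(study, background, term_map, q_threshold = NULL,
                   min_k = 1L, min_K = 1L) {
  assert_cols(term_map, c("gene_id", "term"))
  outside <- setdiff(study, background)
  if (length(outside) > 0) {
    abort(sprintf(
      "study genes missing from the background: %s",
      paste(utils::head(outside, 10), collapse = ", ")
    ))
  }
  annotated <- unique(term_map$gene_id)
  uni <- intersect(unique(background), annotated)
  stu <- intersect(unique(study), uni)
  unannotated <- c(
    study = length(unique(study)) - length(stu),
    background = length(unique(background)) - length(uni)
  )
  if (sum(unannotated) > 0) {
    inform(sprintf(
      "enrich: %d study and %d background gene(s) lack annotation",
      unannotated[["study"]], unannotated[["background"]]
    ))
  }
  N <- length(uni)
  s <- length(stu)
  tm <- dplyr::filter(term_map, .data$gene_id %in% uni)
  res <- tm |>
    dplyr::distinct(.data$gene_id, .data$term) |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% stu),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K >= min_K, .data$k >= min_k) |>
    dplyr::mutate(
      s = s, N = N,
      p_value = stats::phyper(.data$k - 1L, .data$K, .data$N - .data$K,
                              .data$s, lower.tail = FALSE),
      q_value = stats::p.adjust(.data$p_value, "BH")
    ) |>
    dplyr::select("term", "k", "s", "K", "N", "p_value", "q_value") |>
    dplyr::arrange(.data$q_value, .data$p_value)
  if (!is.null(q_threshold)) {
    res <- dplyr::filter(res, .data$q_value < q_threshold)
  }
  attr(res, "unannotated") <- unannotated
  res
}
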