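# pN/pS polymorphism ratios from the panel of parental alleles and the
# methylation-selection association model.

#' pN/pS from one gene's allele panel
#'
#' A CDS site is polymorphic when at least two distinct bases segregate
#' across the alleles. The site is synonymous when every observed allele
#' codon at its codon translates to the same amino acid, otherwise
#' non-synonymous (a substitution creating a stop is non-synonymous by
#' construction: the amino acids differ). pN and pS are counts of such
#' sites; the ratio is `pN / pS`, defined only when `pS > 0`. By the raw
#' polymorphism-count definition the ratio is not normalised by the number
#' of non-synonymous/synonymous opportunities; `mode = "site_normalized"`
#' divides each count by the mean number of non-synonymous (respectively
#' synonymous) sites across alleles first.
#'
#' @param alleles Character vector of >= 2 equal-length CDS sequences (the
#'   study design contributes 12: two identical alleles per diploid queen
#'   and one per haploid male).
#' @param mode `"raw"` (count ratio, the default) or `"site_normalized"`.
#' @return One-row tibble: n_alleles, p_n, p_s, ratio, selection_class
#'   (`positive` ratio > 1, `stable` < 1, `neutral` == 1, NA when
#'   undefined), excluded (TRUE when any allele carries an internal stop).
#' @export
compute_pnps <- function(alleles, mode = c("raw", "site_normalized")) {
  mode <- match.arg(mode)
  alleles <- as.character(alleles)
  if (length(alleles) < 2) abort("need at least 2 alleles")
  lens <- nchar(alleles)
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "allele CDS lengths differ (%s); indels are not supported",
      paste(unique(lens), collapse = ", ")
    ))
  }
  len <- lens[1]
  codon_mat <- vapply(alleles, codons_of, character(len / 3))
  codon_mat <- matrix(codon_mat, nrow = len / 3)
  aa_mat <- matrix(translate_codons(codon_mat), nrow = nrow(codon_mat))
  internal_stop <- any(aa_mat[-nrow(aa_mat), , drop = FALSE] == "*")
  if (internal_stop) {
    return(tibble(n_alleles = length(alleles), p_n = NA_integer_,
                  p_s = NA_integer_, ratio = NA_real_,
                  selection_class = NA_character_, excluded = TRUE))
  }

  base_mat <- vapply(strsplit(alleles, ""), identity, character(len))
  poly_sites <- which(apply(base_mat, 1, function(b) {
    length(unique(b[b %in% c("A", "C", "G", "T")])) > 1
  }))
  p_n <- p_s <- 0L
  for (s in poly_sites) {
    ci <- (s - 1L) %/% 3L + 1L
    aas <- setdiff(unique(aa_mat[ci, ]), "X")  # untypeable codons don't vote
    if (length(aas) <= 1L) p_s <- p_s + 1L else p_n <- p_n + 1L
  }

  if (mode == "site_normalized") {
    deg <- codon_degeneracy_table()
    syn_of <- setNames(deg$syn_count / 3, paste(deg$codon, deg$codon_pos))
    syn_sites <- mean(apply(codon_mat, 2, function(cod) {
      keys <- paste(rep(cod, each = 3), 1:3)
      sum(syn_of[keys], na.rm = TRUE)
    }))
    nonsyn_sites <- len - 3 - syn_sites  # exclude the stop codon's 3 bases
    pn_v <- p_n / nonsyn_sites
    ps_v <- p_s / syn_sites
  } else {
    pn_v <- p_n
    ps_v <- p_s
  }
  ratio <- if (ps_v > 0) pn_v / ps_v else NA_real_
  tibble(
    n_alleles = length(alleles), p_n = p_n, p_s = p_s, ratio = ratio,
    selection_class = dplyr::case_when(
      is.na(ratio) ~ NA_character_,
      ratio > 1 ~ "positive",
      ratio < 1 ~ "stable",
      TRUE ~ "neutral"
    ),
    excluded = FALSE
  )
}

#' pN/pS across many genes
#'
#' @param allele_sets Named list; each element is the allele vector of one
#'   gene, as for [compute_pnps()].
#' @inheritParams compute_pnps
#' @return Tibble with one row per gene (gene_id first column).
#' @export
compute_pnps_genes <- function(allele_sets, mode = c("raw",
                                                     "site_normalized")) {
  mode <- match.arg(mode)
  res <- purrr::imap(allele_sets, function(a, g) {
    dplyr::bind_cols(tibble(gene_id = g), compute_pnps(a, mode))
  })
  out <- dplyr::bind_rows(res)
  n_excl <- sum(out$excluded)
  if (n_excl > 0) {
    inform(sprintf("compute_pnps_genes: %d gene(s) excluded (internal stop)",
                   n_excl))
  }
  out
}

#' Association between gene methylation level and pN/pS
#'
#' Ordinary least squares of the per-gene weighted methylation level on the
#' pN/pS ratio. Genes without a defined ratio (pS = 0) or level are dropped.
#' For the single-predictor model the overall F equals the slope t squared.
#'
#' @param data Tibble with one row per gene.
#' @param w_col,ratio_col Column names of the methylation level and ratio.
#' @return A `meth_selection_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods; key quantities: slope, t, F(1, n-2), p.
#' @export
methylation_vs_pnps <- function(data, w_col = "w", ratio_col = "ratio") {
  assert_cols(data, c(w_col, ratio_col))
  d <- data |>
    dplyr::filter(is.finite(.data[[w_col]]), is.finite(.data[[ratio_col]]))
  if (nrow(d) < 3) {
    abort(sprintf("need at least 3 genes with defined %s and %s (have %d)",
                  w_col, ratio_col, nrow(d)))
  }
  fit <- stats::lm(stats::reformulate(ratio_col, w_col), data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(
      fit = fit,
      slope = co[2, 1], t = co[2, 3], p_value = co[2, 4],
      se = co[2, 2],
      f = unname(sm$fstatistic[1]),
      df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
      n = nrow(d), data = d, w_col = w_col, ratio_col = ratio_col
    ),
    class = "meth_selection_fit"
  )
}

#' @export
print.meth_selection_fit <- function(x, ...) {
  cat(sprintf(
    "Methylation ~ pN/pS: slope = %.4g, t = %.3f, F(%d,%d) = %.3f, p = %.3g\n",
    x$slope, x$t, x$df1, x$df2, x$f, x$p_value
  ))
  invisible(x)
}

#' @describeIn methylation_vs_pnps Coefficient table.
#' @param x A `meth_selection_fit`.
#' @param ... Unused.
#' @export
tidy.meth_selection_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' @describeIn methylation_vs_pnps One-row model summary (slope, t, F, df,
#'   p, n).
#' @export
glance.meth_selection_fit <- function(x, ...) {
  tibble(slope = x$slope, statistic_t = x$t, statistic_f = x$f,
         df1 = x$df1, df2 = x$df2, p.value = x$p_value, nobs = x$n)
}
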