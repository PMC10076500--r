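# Differential methylation: per-CpG binomial logistic regression with a
# covariate, DM-CpG and DM-gene calling, goodness-of-fit on hypermethylated
# counts, and upset-style gene-set overlaps.

#' Per-CpG logistic regression between two groups
#'
#' For every CpG with sufficient coverage, fits a binomial GLM with logit
#' link on per-sample (methylated, total) counts,
#' `logit(pi) = b0 + b1 group + b2 covariate`, and tests `b1 = 0` with a
#' 1-df likelihood-ratio test against the covariate-only null. The reported
#' methylation difference is the count-pooled group difference in percentage
#' points (`group1 - group2`). Sites where either model fails to converge
#' get `p_value = NA` and are excluded downstream; if the covariate is
#' perfectly confounded with group the design is non-identifiable and no
#' site is tested.
#'
#' @param counts Destranded counts: sample, contig, pos, m, n.
#' @param sample_sheet Tibble with sample, group and the covariate column.
#' @param comparison Length-2 character: (group1, group2).
#' @param covariate Covariate column name in `sample_sheet`, or `NULL` for
#'   no covariate.
#' @param min_per_group Minimum samples with coverage per group for a site
#'   to be tested; `NULL` (default) requires every sample of each group.
#' @return Tibble: contig, pos, comparison, group1, group2, n_samples,
#'   prop_g1, prop_g2, meth_diff (percentage points), statistic (LRT),
#'   p_value.
#' @export
dm_test_cpgs <- function(counts, sample_sheet,
                         comparison = c("queen", "male"),
                         covariate = "subspecies",
                         min_per_group = NULL) {
  assert_cols(counts, c("sample", "contig", "pos", "m", "n"))
  assert_cols(sample_sheet, c("sample", "group"))
  stopifnot(length(comparison) == 2)
  sheet <- dplyr::filter(sample_sheet, .data$group %in% comparison)
  sizes <- table(factor(sheet$group, levels = comparison))
  if (any(sizes == 0)) {
    abort(sprintf("no samples for group '%s'",
                  comparison[which(sizes == 0)[1]]))
  }
  need <- if (is.null(min_per_group)) as.integer(sizes) else
    rep_len(min_per_group, 2)

  use_cov <- !is.null(covariate) && covariate %in% names(sheet) &&
    dplyr::n_distinct(sheet[[covariate]]) > 1
  if (use_cov) {
    mm <- stats::model.matrix(
      ~ grp + cov,
      data.frame(grp = factor(sheet$group, levels = comparison),
                 cov = factor(sheet[[covariate]]))
    )
    if (qr(mm)$rank < ncol(mm)) {
      warn(paste0("covariate '", covariate, "' is confounded with group; ",
                  "no site can be tested"))
      return(dm_fit_empty(comparison))
    }
  }

  x <- counts |>
    dplyr::inner_join(sheet %just% c("sample", "group", covariate),
                      by = "sample") |>
    dplyr::filter(.data$n > 0)
  covered <- x |>
    dplyr::group_by(.data$contig, .data$pos) |>
    dplyr::summarise(
      n1 = sum(.data$group == comparison[1]),
      n2 = sum(.data$group == comparison[2]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n1 >= need[1], .data$n2 >= need[2])
  x <- dplyr::semi_join(x, covered, by = c("contig", "pos"))
  if (nrow(x) == 0) return(dm_fit_empty(comparison))

  fits <- x |>
    dplyr::group_by(.data$contig, .data$pos) |>
    dplyr::group_modify(function(d, key) {
      fit_one_cpg(d, comparison, if (use_cov) covariate else NULL)
    }) |>
    dplyr::ungroup()
  cmp_name <- paste(comparison, collapse = "_vs_")
  g1_name <- comparison[1]
  g2_name <- comparison[2]
  fits |>
    dplyr::mutate(
      comparison = cmp_name, group1 = g1_name, group2 = g2_name
    ) |>
    dplyr::select("contig", "pos", "comparison", "group1", "group2",
                  "n_samples", "prop_g1", "prop_g2", "meth_diff",
                  "statistic", "p_value")
}

comparison_levels <- function(comparison) {
  if (length(comparison) == 2) comparison else
    strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
}

dm_fit_empty <- function(comparison) {
  tibble(
    contig = character(0), pos = integer(0),
    comparison = character(0), group1 = character(0), group2 = character(0),
    n_samples = integer(0), prop_g1 = numeric(0), prop_g2 = numeric(0),
    meth_diff = numeric(0), statistic = numeric(0), p_value = numeric(0)
  )
}

fit_one_cpg <- function(d, comparison, covariate) {
  grp <- factor(d$group, levels = comparison)
  p1 <- sum(d$m[grp == comparison[1]]) / sum(d$n[grp == comparison[1]])
  p2 <- sum(d$m[grp == comparison[2]]) / sum(d$n[grp == comparison[2]])
  df <- data.frame(m = d$m, u = d$n - d$m, grp = grp)
  if (!is.null(covariate)) {
    df$cov <- factor(d[[covariate]])
    if (nlevels(droplevels(df$cov)) < 2) covariate <- NULL
  }
  stat <- p <- NA_real_
  fit <- tryCatch({
    if (is.null(covariate)) {
      full <- stats::glm(cbind(m, u) ~ grp, family = stats::binomial(),
                         data = df)
      null <- stats::glm(cbind(m, u) ~ 1, family = stats::binomial(),
                         data = df)
    } else {
      full <- stats::glm(cbind(m, u) ~ grp + cov, family = stats::binomial(),
                         data = df)
      null <- stats::glm(cbind(m, u) ~ cov, family = stats::binomial(),
                         data = df)
    }
    list(full = full, null = null)
  }, error = function(e) NULL)
  grp_coef <- if (is.null(fit)) NA_real_ else
    unname(stats::coef(fit$full)[paste0("grp", comparison[2])])
  if (!is.null(fit) && fit$full$converged && fit$null$converged &&
      !is.na(grp_coef)) {
    stat <- max(0, fit$null$deviance - fit$full$deviance)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble(
    n_samples = nrow(d), prop_g1 = p1, prop_g2 = p2,
    meth_diff = 100 * (p1 - p2), statistic = stat, p_value = p
  )
}

#' Call differentially methylated CpGs
#'
#' Benjamini-Hochberg corrects the per-site p-values within the comparison
#' and flags a CpG as differentially methylated when the absolute pooled
#' methylation difference is at least `min_diff` percentage points and the
#' q-value is below `q_threshold`. Direction is the hypermethylated group.
#'
#' @param fits Tibble from [dm_test_cpgs()].
#' @param min_diff Minimum absolute difference in percentage points
#'   (default 10).
#' @param q_threshold q-value cut (default 0.01).
#' @return `fits` plus q_value, dm (logical), hyper_in.
#' @export
call_dm_cpgs <- function(fits, min_diff = 10, q_threshold = 0.01) {
  fits |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$comparison) |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      dm = abs(.data$meth_diff) >= min_diff & .data$q_value < q_threshold,
      hyper_in = dplyr::if_else(.data$meth_diff > 0, .data$group1,
                                .data$group2)
    )
}

#' Call differentially methylated genes
#'
#' A gene is differentially methylated when at least one of its exons
#' carries `min_cpgs` or more DM CpGs (a CpG counts for an exon when either
#' base of its dyad overlaps it; overlapping exons of two genes both count)
#' and the exon's weighted-methylation difference between the two groups
#' exceeds `min_dw`. The per-gene direction pattern is `consistent` when all
#' qualifying exons shift the same way, otherwise `mixed`. Exons with DM
#' CpGs but a missing weighted level in either group are skipped and
#' counted in the `"skipped_exons"` attribute.
#'
#' @param dm_cpgs Tibble from [call_dm_cpgs()].
#' @param exons Tibble: feature_id, gene_id, contig, start, end.
#' @param exon_w Weighted methylation per exon and group: feature_id, group,
#'   w (as from [weighted_methylation()] with `by = "group"`).
#' @param min_cpgs Minimum DM CpGs on one exon (default 2).
#' @param min_dw Minimum absolute exon weighted-methylation difference
#'   (default 0.15, i.e. 15 percentage points).
#' @return Tibble: gene_id, comparison, dm, n_qualifying_exons,
#'   direction_pattern, exons (nested qualifying-exon details).
#' @export
call_dm_genes <- function(dm_cpgs, exons, exon_w, min_cpgs = 2,
                          min_dw = 0.15) {
  assert_cols(exons, c("feature_id", "gene_id", "contig", "start", "end"))
  assert_cols(exon_w, c("feature_id", "group", "w"))
  dm_sites <- dplyr::filter(dm_cpgs, .data$dm)
  if (nrow(dm_sites) == 0) {
    return(tibble(gene_id = character(0), comparison = character(0),
                  dm = logical(0), n_qualifying_exons = integer(0),
                  direction_pattern = character(0)))
  }
  g1 <- dm_sites$group1[1]
  g2 <- dm_sites$group2[1]
  dm_sites$pos_end <- dm_sites$pos + 1L  # either base of the dyad
  per_exon <- overlap_join(dm_sites, exons, x_start = "pos",
                           x_end = "pos_end") |>
    dplyr::group_by(.data$comparison, .data$gene_id, .data$feature_id) |>
    dplyr::summarise(n_dm_cpgs = dplyr::n_distinct(.data$pos),
                     .groups = "drop")

  w_wide <- exon_w |>
    dplyr::filter(.data$group %in% c(g1, g2)) |>
    dplyr::select("feature_id", "group", "w") |>
    tidyr::pivot_wider(names_from = "group", values_from = "w")
  per_exon <- per_exon |>
    dplyr::left_join(w_wide, by = "feature_id") |>
    dplyr::mutate(dw = .data[[g1]] - .data[[g2]])
  skipped <- sum(is.na(per_exon$dw))
  if (skipped > 0) {
    inform(sprintf(
      "call_dm_genes: skipped %d exon(s) lacking a weighted level", skipped
    ))
  }
  per_exon <- dplyr::filter(per_exon, !is.na(.data$dw))
  qual <- per_exon |>
    dplyr::filter(.data$n_dm_cpgs >= min_cpgs, abs(.data$dw) > min_dw)
  if (nrow(qual) == 0) {
    out <- tibble(comparison = character(0), gene_id = character(0),
                  n_qualifying_exons = integer(0),
                  direction_pattern = character(0), hyper_in = character(0),
                  max_abs_dw = numeric(0), dm = logical(0))
    attr(out, "skipped_exons") <- skipped
    return(out)
  }
  out <- qual |>
    dplyr::group_by(.data$comparison, .data$gene_id) |>
    dplyr::summarise(
      n_qualifying_exons = dplyr::n(),
      direction_pattern = dplyr::if_else(
        dplyr::n_distinct(sign(.data$dw)) == 1L, "consistent", "mixed"
      ),
      hyper_in = dplyr::if_else(sum(sign(.data$dw)) >= 0, g1, g2),
      max_abs_dw = max(abs(.data$dw)),
      .groups = "drop"
    ) |>
    dplyr::mutate(dm = TRUE) |>
    dplyr::left_join(
      qual |>
        dplyr::select("comparison", "gene_id", "feature_id", "n_dm_cpgs",
                      "dw") |>
        tidyr::nest(exons = c("feature_id", "n_dm_cpgs", "dw")),
      by = c("comparison", "gene_id")
    )
  attr(out, "skipped_exons") <- skipped
  out
}

#' Goodness-of-fit test on hypermethylated-site counts
#'
#' Pearson chi-square test of the two hypermethylated-CpG counts of a
#' comparison against equal expected counts, 1 df.
#'
#' @param n_a,n_b Counts hypermethylated in each group.
#' @return Tibble: statistic, df, p_value, n_a, n_b.
#' @export
gof_hypermethylated <- function(n_a, n_b) {
  if (n_a + n_b <= 0) abort("gof_hypermethylated: zero total count")
  ht <- stats::chisq.test(c(n_a, n_b), p = c(0.5, 0.5))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), n_a = n_a, n_b = n_b)
}

#' Upset-style exclusive overlaps of gene sets
#'
#' @param sets Named list of character vectors (e.g. hypermethylated gene
#'   sets keyed by comparison and direction).
#' @return Tibble with one row per non-empty membership pattern: `sets`
#'   (ampersand-joined set names), `degree`, `n` (exclusive count). The
#'   exclusive counts of the patterns containing a set sum to that set's
#'   size.
#' @export
overlap_dm_gene_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- unique(unlist(sets))
  if (length(genes) == 0) {
    return(tibble(sets = character(0), degree = integer(0), n = integer(0)))
  }
  member <- vapply(sets, function(s) genes %in% s,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(sets)))
  pattern <- unname(apply(member, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  }))
  tibble(gene = genes, pattern = pattern) |>
    dplyr::count(.data$pattern, name = "n") |>
    dplyr::mutate(
      degree = stringr::str_count(.data$pattern, stringr::fixed("&")) + 1L
    ) |>
    dplyr::select(sets = "pattern", "degree", "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}
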