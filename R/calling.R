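# Destranding, coverage filtering, binomial methylation-status calling
# against the lambda non-conversion null, weighted methylation and gene
# methylation bins.

#' Destrand CpG counts
#'
#' Merges the two cytosines of a CpG dyad — the + strand C at position `i`
#' and the - strand C (a G on the + strand) at `i + 1` — into a single site
#' keyed at `i`, summing methylated and total read counts. A - strand record
#' with no + partner still yields a site at `i - 1`; the number of such
#' orphans is reported via a message and the `"orphans"` attribute.
#'
#' @param counts Tibble with contig, pos, strand, m, n and optionally a
#'   sample column (kept and respected in the merge).
#' @return Destranded tibble: (sample,) contig, pos, m, n.
#' @export
destrand <- function(counts) {
  assert_cols(counts, c("contig", "pos", "strand", "m", "n"))
  keyed <- counts |>
    dplyr::mutate(site = dplyr::if_else(.data$strand == "-",
                                        .data$pos - 1L, .data$pos))
  grp <- intersect(c("sample", "contig", "site"), names(keyed))
  orphans <- keyed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(orph = all(.data$strand == "-"), .groups = "drop") |>
    dplyr::summarise(n = sum(.data$orph)) |>
    dplyr::pull(.data$n)
  if (orphans > 0) {
    inform(sprintf("destrand: %d minus-strand record(s) had no plus partner",
                   orphans))
  }
  out <- keyed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(m = sum(.data$m), n = sum(.data$n), .groups = "drop") |>
    dplyr::rename(pos = "site") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(setdiff(grp, "site"))),
                   .data$pos)
  attr(out, "orphans") <- orphans
  out
}

#' Filter CpG sites on read coverage
#'
#' Per sample, removes sites covered by fewer than `min_cov` reads and
#' coverage outliers above the `pct`-th percentile of that sample's coverage
#' distribution (linear-interpolation quantile). Sites exactly at `min_cov`
#' are kept; sites exactly at the percentile are kept.
#'
#' @param sites Destranded tibble with (sample,) contig, pos, m, n.
#' @param min_cov Minimum reads per site (default 10).
#' @param pct Upper percentile cut, in percent (default 99.9).
#' @return Filtered tibble; per-sample removal counts in the `"log"`
#'   attribute.
#' @export
filter_coverage <- function(sites, min_cov = 10, pct = 99.9) {
  assert_cols(sites, c("contig", "pos", "m", "n"))
  if (nrow(sites) == 0) return(sites)
  grp <- intersect("sample", names(sites))
  out <- sites |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.cut = stats::quantile(.data$n, pct / 100, type = 7)) |>
    dplyr::ungroup()
  keep <- out$n >= min_cov & out$n <= out$.cut
  res <- out[keep, setdiff(names(out), ".cut"), drop = FALSE]
  attr(res, "log") <- c(low_coverage = sum(sites$n < min_cov),
                        outlier = sum(!keep & sites$n >= min_cov))
  res
}

#' Estimate per-sample bisulfite non-conversion rates
#'
#' The lambda spike is fully unmethylated, so its methylated-read fraction
#' estimates the non-conversion error used as the binomial null success
#' probability.
#'
#' @param lambda Tibble with sample, meth, total.
#' @return Tibble with sample, error.
#' @export
conversion_rate <- function(lambda) {
  assert_cols(lambda, c("sample", "meth", "total"))
  lambda |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(error = sum(.data$meth) / sum(.data$total),
                     .groups = "drop")
}

#' Call per-CpG methylation status against the non-conversion null
#'
#' For each site and sample, tests the observed methylated count against
#' `Binomial(n, e)` where `e` is that sample's lambda non-conversion rate:
#' `p = P(X >= m)` (one-sided upper tail — only an excess of unconverted
#' cytosines is evidence of methylation). p-values are Benjamini-Hochberg
#' corrected within each sample (`scope = "sample"`, the default) or across
#' all site/sample pairs (`scope = "global"`); a site is `methylated` when
#' its q-value is below `fdr`.
#'
#' @param sites Destranded, coverage-filtered tibble with sample, contig,
#'   pos, m, n.
#' @param error Tibble from [conversion_rate()] or a single numeric rate.
#' @param fdr q-value threshold (default 0.05).
#' @param scope BH correction scope.
#' @return Tibble: sample, contig, pos, m, n, error, p_value, q_value,
#'   status ("methylated"/"unmethylated"). Sites with `n == 0` are skipped.
#' @export
call_methylation <- function(sites, error, fdr = 0.05,
                             scope = c("sample", "global")) {
  scope <- match.arg(scope)
  assert_cols(sites, c("sample", "contig", "pos", "m", "n"))
  x <- dplyr::filter(sites, .data$n > 0)
  if (is.numeric(error)) {
    x$error <- error
  } else {
    assert_cols(error, c("sample", "error"))
    x <- dplyr::left_join(x, error, by = "sample")
    if (anyNA(x$error)) {
      abort("call_methylation: no conversion-rate estimate for some samples")
    }
  }
  x$p_value <- stats::pbinom(x$m - 1L, x$n, x$error, lower.tail = FALSE)
  x <- if (scope == "sample") {
    x |>
      dplyr::group_by(.data$sample) |>
      dplyr::mutate(q_value = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(x, q_value = stats::p.adjust(.data$p_value, "BH"))
  }
  x |>
    dplyr::mutate(status = dplyr::if_else(.data$q_value < fdr,
                                          "methylated", "unmethylated"))
}

#' Restrict calls to sites methylated in at least one sample
#'
#' The analysis set drops every CpG that did not return as methylated in any
#' sample.
#'
#' @param calls Tibble from [call_methylation()].
#' @return Filtered calls; the number of dropped sites is attached as the
#'   `"dropped_sites"` attribute.
#' @export
drop_never_methylated <- function(calls) {
  keep <- calls |>
    dplyr::group_by(.data$contig, .data$pos) |>
    dplyr::summarise(any_meth = any(.data$status == "methylated"),
                     .groups = "drop")
  out <- calls |>
    dplyr::inner_join(dplyr::filter(keep, .data$any_meth),
                      by = c("contig", "pos")) |>
    dplyr::select(-"any_meth")
  attr(out, "dropped_sites") <- sum(!keep$any_meth)
  out
}

#' Weighted methylation level per feature
#'
#' The weighted methylation level of a feature is the sum of methylated read
#' counts over the sum of total read counts across all CpGs inside the
#' feature (Schultz-style weighting). Features with no covered CpG are
#' absent from the result rather than reported as 0/0.
#'
#' @param sites Destranded counts with contig, pos, m, n and the grouping
#'   column named by `by`.
#' @param features Tibble with feature_id, contig, start, end (1-based
#'   closed) plus any annotation columns to carry through.
#' @param by Column of `sites` to aggregate within (e.g. "sample" or
#'   "group").
#' @return Tibble: feature_id, carried feature columns, `by` column, w,
#'   covered_cpgs.
#' @export
weighted_methylation <- function(sites, features, by = "sample") {
  assert_cols(sites, c("contig", "pos", "m", "n", by))
  assert_cols(features, c("feature_id", "contig", "start", "end"))
  joined <- overlap_join(sites, features, x_start = "pos", x_end = "pos")
  carry <- setdiff(names(features), c("contig", "start", "end"))
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(carry, by)))) |>
    dplyr::summarise(
      w = sum(.data$m) / sum(.data$n),
      covered_cpgs = dplyr::n_distinct(.data$pos),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$w))
}

#' Bin gene methylation levels
#'
#' A gene counts as methylated when its weighted level exceeds the bisulfite
#' conversion error floor (`meth_floor`, default 0.05). Methylated genes are
#' binned as low (`meth_floor < w < 0.3`), medium (`0.3 <= w <= 0.7`) or
#' high (`w > 0.7`, strict); everything at or below the floor is
#' unmethylated, and missing levels are unclassified (`NA`).
#'
#' @param w Numeric vector of weighted methylation levels.
#' @param meth_floor Conversion-error floor (default 0.05).
#' @param edges Lower edges of the medium and high bins (default 0.3, 0.7).
#' @return Factor with levels unmethylated, low, medium, high.
#' @export
bin_methylation <- function(w, meth_floor = 0.05, edges = c(0.3, 0.7)) {
  lab <- dplyr::case_when(
    is.na(w) ~ NA_character_,
    w > edges[2] ~ "high",
    w >= edges[1] ~ "medium",
    w > meth_floor ~ "low",
    TRUE ~ "unmethylated"
  )
  factor(lab, levels = c("unmethylated", "low", "medium", "high"))
}
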