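# Codon fold-degeneracy labelling and its intersection with methylation.

degeneracy_env <- new.env(parent = emptyenv())

#' Synonymous-substitution counts for every sense codon position
#'
#' For each of the 61 sense codons and each codon position, counts how many
#' of the three alternative nucleotides leave the encoded amino acid
#' unchanged under the standard genetic code. Substitutions that create a
#' stop codon are counted as non-synonymous; stop codons themselves are not
#' tabulated. Fold classes map syn_count 0/1/2/3 to zero/two/three/four.
#'
#' @return Tibble: codon, codon_pos, syn_count, fold_class.
#' @export
codon_degeneracy_table <- function() {
  if (!is.null(degeneracy_env$table)) return(degeneracy_env$table)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (codon in names(code)) {
    aa <- code[[codon]]
    if (aa == "*") next
    for (p in 1:3) {
      alt <- setdiff(bases, substr(codon, p, p))
      mut <- vapply(alt, function(b) {
        m <- codon
        substr(m, p, p) <- b
        m
      }, character(1))
      syn <- sum(code[mut] == aa & code[mut] != "*")
      rows[[length(rows) + 1L]] <- tibble(
        codon = codon, codon_pos = p, syn_count = syn
      )
    }
  }
  tab <- dplyr::bind_rows(rows) |>
    dplyr::mutate(fold_class = factor(
      c("zero", "two", "three", "four")[.data$syn_count + 1L],
      levels = c("zero", "two", "three", "four")
    ))
  degeneracy_env$table <- tab
  tab
}

#' Label every CDS base with its codon fold degeneracy
#'
#' Splits the CDS into codons and labels each base with how many of its
#' three possible substitutions are synonymous (0 = zero-fold … 3 =
#' four-fold). The terminal stop codon is excluded; codons containing N (or
#' any non-ACGT letter, e.g. under a mask) are untypeable and skipped with
#' their count reported in the `"skipped_codons"` attribute.
#'
#' @param cds CDS sequence (character scalar, length a multiple of 3), as
#'   from [extract_cds()].
#' @param map Coordinate map from [extract_cds()] (cds_index, contig, pos,
#'   strand); optional — omit for sequence-only labelling.
#' @param gene_id Gene id attached to the output.
#' @return Tibble: gene_id, contig, pos, strand, cds_index, codon,
#'   codon_pos, syn_count, fold_class (one row per typeable coding base).
#' @export
label_degeneracy <- function(cds, map = NULL, gene_id = NA_character_) {
  codons <- codons_of(cds)
  n_cod <- length(codons)
  aa <- translate_codons(codons)
  if (any(aa[-n_cod] == "*")) {
    abort(sprintf("gene '%s': internal stop codon; exclude the gene upstream",
                  gene_id))
  }
  keep <- aa != "*" & !stringr::str_detect(codons, "[^ACGT]")
  skipped <- sum(!keep & aa != "*")

  idx <- rep(which(keep), each = 3L)
  codon_pos <- rep(1:3, times = sum(keep))
  base_tbl <- tibble(
    gene_id = gene_id,
    cds_index = (idx - 1L) * 3L + codon_pos,
    codon = codons[idx],
    codon_pos = codon_pos
  )

  out <- dplyr::left_join(base_tbl, codon_degeneracy_table(),
                          by = c("codon", "codon_pos"))
  if (!is.null(map)) {
    out <- dplyr::left_join(
      out, map %just% c("cds_index", "contig", "pos", "strand"),
      by = "cds_index"
    )
  } else {
    out$contig <- NA_character_
    out$pos <- NA_integer_
    out$strand <- NA_character_
  }
  out <- out |>
    dplyr::select("gene_id", "contig", "pos", "strand", "cds_index",
                  "codon", "codon_pos", "syn_count", "fold_class")
  if (skipped > 0) {
    inform(sprintf("label_degeneracy: %d untypeable codon(s) skipped",
                   skipped))
  }
  attr(out, "skipped_codons") <- skipped
  out
}

# Key a degenerate site to the destranded CpG site it can belong to: the
# coding base of a + strand gene is the + strand C itself (key = pos); the
# coding base of a - strand gene is the - strand C, i.e. the + strand G at
# pos, so the dyad is keyed at pos - 1. Methylation at a CpG dyad is
# symmetric, so either dyad base in the CDS links the site.
deg_cpg_key <- function(deg_sites) {
  dplyr::mutate(deg_sites, cpg_pos = dplyr::if_else(
    .data$strand == "-", .data$pos - 1L, .data$pos
  ))
}

#' Proportion of degenerate sites methylated, by fold class
#'
#' Joins per-individual degeneracy labels with that individual's methylation
#' calls (degenerate site to CpG dyad, strand-aware) and tabulates, per
#' sample and fold class (or any other `by` columns, e.g. codon position),
#' how many CpG-overlapping degenerate sites were called methylated.
#'
#' @param deg_sites Degeneracy tibble with a `sample` column (rbind of
#'   per-individual [label_degeneracy()] outputs).
#' @param calls Methylation calls from [call_methylation()] for the same
#'   samples.
#' @param by Grouping columns of the output (default `fold_class`).
#' @param sample_sheet Optional sample sheet joined onto the result (adds
#'   sex/group columns).
#' @return Tibble: sample, `by` columns, n_sites, n_methylated, proportion.
#' @export
fold_methylation_proportions <- function(deg_sites, calls,
                                         by = "fold_class",
                                         sample_sheet = NULL) {
  assert_cols(deg_sites, c("sample", "contig", "pos", "strand", by))
  assert_cols(calls, c("sample", "contig", "pos", "status"))
  joined <- deg_cpg_key(deg_sites) |>
    dplyr::inner_join(
      calls %just% c("sample", "contig", "pos", "status"),
      by = c("sample", "contig", cpg_pos = "pos")
    )
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample", by)))) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_methylated = sum(.data$status == "methylated"),
      .groups = "drop"
    ) |>
    dplyr::mutate(proportion = .data$n_methylated / .data$n_sites)
  if (!is.null(sample_sheet)) {
    out <- dplyr::left_join(out, sample_sheet, by = "sample")
  }
  out
}

#' Hypergeometric enrichment of a gene set across methylation bins
#'
#' Tests, for each methylation-level bin, whether the study set (e.g. genes
#' carrying at least one methylated zero-fold degenerate site) overlaps the
#' bin more than expected, with the universe of all methylated genes as
#' background; upper-tail hypergeometric p, BH-corrected across bins.
#'
#' @param study_genes Character vector of study genes.
#' @param gene_bins Tibble: gene_id, bin (e.g. from [bin_methylation()]).
#' @param universe Character vector of background genes; defaults to all
#'   genes in `gene_bins`.
#' @return Tibble: bin, k (study hits), K (bin size), s (study size), N
#'   (universe size), p_value, q_value.
#' @export
fold_bin_enrichment <- function(study_genes, gene_bins, universe = NULL) {
  assert_cols(gene_bins, c("gene_id", "bin"))
  universe <- universe %||% unique(gene_bins$gene_id)
  if (length(universe) == 0) abort("fold_bin_enrichment: empty universe")
  study <- intersect(unique(study_genes), universe)
  bins <- gene_bins |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$gene_id, .data$bin)
  res <- bins |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(
      k = sum(.data$gene_id %in% study),
      K = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      s = length(study), N = length(universe),
      p_value = stats::phyper(.data$k - 1L, .data$K, .data$N - .data$K,
                              .data$s, lower.tail = FALSE),
      q_value = stats::p.adjust(.data$p_value, "BH")
    )
  res
}

#' Count differentially methylated CpGs per fold class
#'
#' Cross-tabulates DM CpGs (e.g. queen vs male) against codon fold classes,
#' alongside the background counts of all methylated CpGs per class, so the
#' DM distribution can be compared with where methylation sits generally.
#' CpGs outside any labelled CDS base fall in the `non_CDS` row.
#'
#' @param dm_cpgs Tibble from [call_dm_cpgs()]; only rows with `dm == TRUE`
#'   are counted.
#' @param deg_sites Degeneracy labels with genomic coordinates (any
#'   individual set or their union; a CpG is counted once per fold class).
#' @param methylated_sites Tibble of background methylated CpGs (contig,
#'   pos), e.g. distinct methylated calls.
#' @return Tibble: fold_class (zero/two/three/four/non_CDS), n_dm,
#'   n_methylated_background.
#' @export
dm_sites_by_fold <- function(dm_cpgs, deg_sites, methylated_sites) {
  key <- deg_cpg_key(deg_sites) |>
    dplyr::distinct(.data$contig, .data$cpg_pos, .data$fold_class)
  lv <- c("zero", "two", "three", "four", "non_CDS")
  classify <- function(sites) {
    sites |>
      dplyr::distinct(.data$contig, .data$pos) |>
      dplyr::left_join(key, by = c("contig", pos = "cpg_pos"),
                       relationship = "many-to-many") |>
      dplyr::mutate(fold_class = factor(
        dplyr::coalesce(as.character(.data$fold_class), "non_CDS"),
        levels = lv
      )) |>
      dplyr::count(.data$fold_class, .drop = FALSE)
  }
  dm <- classify(dplyr::filter(dm_cpgs, .data$dm))
  bg <- classify(methylated_sites)
  dplyr::full_join(dm, bg, by = "fold_class",
                   suffix = c("_dm", "_bg")) |>
    dplyr::transmute(
      fold_class = .data$fold_class,
      n_dm = dplyr::coalesce(.data$n_dm, 0L),
      n_methylated_background = dplyr::coalesce(.data$n_bg, 0L)
    )
}
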