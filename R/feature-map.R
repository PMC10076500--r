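# Genomic feature map: a single label per bp.

#' Partition the genome into genomic features
#'
#' Labels every bp of every contig with exactly one of `promoter`, `utr5`,
#' `exon`, `intron`, `utr3`, `intergenic`:
#'
#' * `exon` — coding (CDS) parts of exons;
#' * `utr5`/`utr3` — exon parts outside the CDS, assigned 5'/3' by gene
#'   strand;
#' * `intron` — within-gene gaps between exons;
#' * `promoter` — up to `promoter_size` bp immediately upstream of a gene
#'   start (strand-aware), truncated wherever it would overlap any
#'   gene-derived feature of any gene, clipped at contig edges, and kept only
#'   while it still abuts the gene start ("no overlap with any other genomic
#'   feature");
#' * `intergenic` — everything else.
#'
#' Where overlapping genes claim the same bp, precedence is
#' exon > utr5 > utr3 > intron.
#'
#' @param models Gene-model tibble as from [read_gene_models()].
#' @param contig_lengths Named vector of contig lengths (or a
#'   [Biostrings::DNAStringSet], whose widths are used).
#' @param promoter_size Putative promoter length upstream of the gene start
#'   (default 500 bp).
#' @return Tibble with columns contig, start, end, feature (1-based closed;
#'   the rows partition every contig).
#' @export
build_feature_map <- function(models, contig_lengths, promoter_size = 500) {
  if (methods::is(contig_lengths, "DNAStringSet")) {
    contig_lengths <- setNames(Biostrings::width(contig_lengths),
                               names(contig_lengths))
  }
  genes <- dplyr::filter(models, .data$type == "gene")
  bad <- genes$end > contig_lengths[genes$contig] | genes$start < 1
  if (any(bad, na.rm = TRUE) || any(is.na(bad))) {
    i <- which(bad | is.na(bad))[1]
    abort(sprintf("gene %s (%s:%d-%d) extends past its contig",
                  genes$gene_id[i], genes$contig[i], genes$start[i],
                  genes$end[i]))
  }

  out <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    g <- dplyr::filter(genes, .data$contig == ct)
    full <- IRanges::IRanges(1L, len)
    if (nrow(g) == 0) {
      return(tbl_of_iranges(full, ct, "intergenic"))
    }
    exons <- dplyr::filter(models, .data$contig == ct, .data$type == "exon")
    cds <- dplyr::filter(models, .data$contig == ct, .data$type == "CDS")

    exon_lbl <- IRanges::reduce(iranges_of(cds))
    # UTRs: exon minus CDS, 5'/3' by position relative to the CDS span.
    utr5 <- utr3 <- IRanges::IRanges()
    for (gid in unique(g$gene_id)) {
      ex_g <- iranges_of(dplyr::filter(exons, .data$gene_id == gid))
      cds_g <- iranges_of(dplyr::filter(cds, .data$gene_id == gid))
      strand_g <- g$strand[g$gene_id == gid][1]
      u <- IRanges::setdiff(ex_g, cds_g)
      if (length(u) == 0) next
      if (length(cds_g) == 0) {
        utr5 <- c(utr5, u)  # non-coding gene: call it 5' UTR-like
        next
      }
      before <- IRanges::end(u) < min(IRanges::start(cds_g))
      if (strand_g == "-") before <- !before
      utr5 <- c(utr5, u[before])
      utr3 <- c(utr3, u[!before])
    }
    utr5_lbl <- IRanges::setdiff(IRanges::reduce(utr5), exon_lbl)
    utr3_lbl <- IRanges::setdiff(IRanges::reduce(utr3),
                                 IRanges::union(exon_lbl, utr5_lbl))

    spans <- IRanges::reduce(iranges_of(g))
    claimed <- Reduce(IRanges::union, list(exon_lbl, utr5_lbl, utr3_lbl))
    intron_lbl <- IRanges::setdiff(spans, claimed)
    gene_features <- IRanges::union(spans, claimed)

    # Promoters: upstream windows, minus gene features, fragment abutting the
    # gene start only.
    prom <- IRanges::IRanges()
    for (i in seq_len(nrow(g))) {
      if (g$strand[i] == "+") {
        w_start <- max(1L, g$start[i] - promoter_size)
        w_end <- g$start[i] - 1L
        anchor <- w_end
      } else {
        w_start <- g$end[i] + 1L
        w_end <- min(len, g$end[i] + promoter_size)
        anchor <- w_start
      }
      if (w_end < w_start) next
      frag <- IRanges::setdiff(IRanges::IRanges(w_start, w_end),
                               gene_features)
      if (g$strand[i] == "+") {
        frag <- frag[IRanges::end(frag) == anchor]
      } else {
        frag <- frag[IRanges::start(frag) == anchor]
      }
      prom <- c(prom, frag)
    }
    prom_lbl <- IRanges::setdiff(IRanges::reduce(prom), gene_features)
    intergenic <- IRanges::setdiff(full,
                                   IRanges::union(gene_features, prom_lbl))

    res <- dplyr::bind_rows(
      tbl_of_iranges(prom_lbl, ct, "promoter"),
      tbl_of_iranges(utr5_lbl, ct, "utr5"),
      tbl_of_iranges(exon_lbl, ct, "exon"),
      tbl_of_iranges(intron_lbl, ct, "intron"),
      tbl_of_iranges(utr3_lbl, ct, "utr3"),
      tbl_of_iranges(intergenic, ct, "intergenic")
    ) |>
      dplyr::arrange(.data$start)
    covered <- sum(res$end - res$start + 1)
    if (covered != len) {
      abort(sprintf(
        "internal error: feature map covers %d of %d bp on %s",
        covered, len, ct
      ))
    }
    res
  })
  dplyr::bind_rows(out)
}
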