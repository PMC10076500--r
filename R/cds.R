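# CDS extraction with per-base genomic coordinate maps.

#' Extract a gene's coding sequence with a coordinate map
#'
#' Concatenates the gene's CDS segments in translation order
#' (reverse-complementing minus-strand genes), honours the phase of the first
#' segment by dropping that many leading bases, and returns, for every CDS
#' base, its 1-based genomic position and strand.
#'
#' @param genome A [Biostrings::DNAStringSet] (reference or individualised).
#' @param models Gene-model tibble as from [read_gene_models()].
#' @param gene_id Gene to extract.
#' @return List with `gene_id`, `seq` (character CDS), `map` (tibble:
#'   cds_index, contig, pos, strand) and `internal_stop` (TRUE when the
#'   translation contains a premature stop; such genes should be excluded
#'   from codon-level analyses).
#' @export
extract_cds <- function(genome, models, gene_id) {
  seg <- models |>
    dplyr::filter(.data$type == "CDS", .data$gene_id == !!gene_id) |>
    dplyr::arrange(.data$start)
  if (nrow(seg) == 0) {
    abort(sprintf("gene '%s' has no CDS segments", gene_id))
  }
  strand <- seg$strand[1]
  if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]

  if (!seg$contig[1] %in% names(genome)) {
    abort(sprintf("contig '%s' (gene '%s') not found in the genome",
                  seg$contig[1], gene_id))
  }
  chr <- as.character(genome[[seg$contig[1]]])
  pieces <- character(nrow(seg))
  pos_list <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- stringr::str_sub(chr, seg$start[i], seg$end[i])
    if (strand == "-") {
      pieces[i] <- revcomp(s)
      pos_list[[i]] <- seg$end[i]:seg$start[i]
    } else {
      pieces[i] <- s
      pos_list[[i]] <- seg$start[i]:seg$end[i]
    }
  }
  seq <- paste(pieces, collapse = "")
  pos <- unlist(pos_list)

  phase <- seg$phase[1]
  if (!is.na(phase) && phase > 0) {
    seq <- stringr::str_sub(seq, phase + 1L)
    pos <- pos[-seq_len(phase)]
  }
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    warn(sprintf("gene '%s': CDS length %d not a multiple of 3 after phase",
                 gene_id, n))
  }

  aa <- translate_codons(codons_of(stringr::str_sub(seq, 1L, n - n %% 3L)))
  internal_stop <- any(aa[-length(aa)] == "*")

  list(
    gene_id = gene_id,
    seq = seq,
    map = tibble(
      cds_index = seq_len(n), contig = seg$contig[1], pos = pos,
      strand = strand
    ),
    internal_stop = internal_stop
  )
}

#' Extract every gene's CDS
#'
#' Genes whose translation carries an internal stop codon are dropped with a
#' message; their ids are attached as the `"dropped"` attribute.
#'
#' @inheritParams extract_cds
#' @return Named list of [extract_cds()] results for the retained genes.
#' @export
extract_all_cds <- function(genome, models) {
  ids <- unique(models$gene_id[models$type == "CDS"])
  res <- lapply(ids, function(g) extract_cds(genome, models, g))
  names(res) <- ids
  bad <- vapply(res, `[[`, logical(1), "internal_stop")
  if (any(bad)) {
    inform(sprintf("extract_all_cds: excluded %d gene(s) with internal stops",
                   sum(bad)))
  }
  out <- res[!bad]
  attr(out, "dropped") <- ids[bad]
  out
}

# Translate codons with the standard code; codons containing anything but
# ACGT (e.g. N under a mask) give "X".
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}
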