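# Synthetic genome + annotation generation.

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Simulate a genome and gene annotation
#'
#' Generates random contigs carrying non-overlapping protein-coding genes on
#' both strands. Every CDS starts with ATG, ends with a stop codon, contains
#' no internal stop (coding codons are drawn from the 61 sense codons) and is
#' a multiple of 3 long. A configurable fraction of coding codons is drawn
#' from the CpG-containing codon set so exons are guaranteed to carry CpG
#' dinucleotides.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (a named
#'   [Biostrings::DNAStringSet]), `annotation` (a tibble of gene/mRNA/exon/CDS
#'   records with 1-based closed coordinates, `exon_rank` in translation
#'   order, and `phase`), and `layout` (per-gene placement truth).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genome"))

  exon_len <- config$codons_per_exon * 3L
  gene_len <- config$exons_per_gene * exon_len +
    (config$exons_per_gene - 1L) * config$intron_length
  cap_per_contig <- (config$contig_length - config$min_gap) %/%
    (gene_len + config$min_gap)
  if (cap_per_contig * config$n_contigs < config$n_genes) {
    abort(sprintf(
      paste0("cannot place %d genes of %d bp with %d bp gaps on %d contig(s) ",
             "of %d bp (capacity %d); increase contig_length or n_contigs"),
      config$n_genes, gene_len, config$min_gap, config$n_contigs,
      config$contig_length, cap_per_contig * config$n_contigs
    ))
  }

  sense <- sense_codons()
  cpg_cod <- sense[stringr::str_detect(sense, "CG")]
  plain_cod <- setdiff(sense, cpg_cod)
  bases <- c("A", "C", "G", "T")

  # Assign genes to contigs round-robin.
  contig_of_gene <- rep_len(seq_len(config$n_contigs), config$n_genes)
  contig_names <- sprintf("contig%d", seq_len(config$n_contigs))

  contig_seqs <- character(config$n_contigs)
  ann <- list()
  layout <- list()
  gene_idx <- 0L

  for (ci in seq_len(config$n_contigs)) {
    k <- sum(contig_of_gene == ci)
    seq_chr <- paste(sample(bases, config$contig_length, replace = TRUE),
                     collapse = "")
    if (k > 0L) {
      slack <- config$contig_length - k * gene_len - (k + 1L) * config$min_gap
      extra <- if (slack > 0L) {
        as.integer(stats::rmultinom(1L, slack, rep(1, k + 1L)))
      } else {
        integer(k + 1L)
      }
      gaps <- config$min_gap + extra
      starts <- cumsum(c(gaps[1L] + 1L,
                         rep(gene_len, k - 1L) + gaps[2:k][seq_len(k - 1L)]))
      for (j in seq_len(k)) {
        gene_idx <- gene_idx + 1L
        gid <- sprintf("g%03d", gene_idx)
        strand <- if (gene_idx %% 2L == 0L) "-" else "+"
        g <- build_gene(config, gid, contig_names[ci], starts[j], strand,
                        cpg_cod, plain_cod)
        seq_chr <- paste0(
          substr(seq_chr, 1L, starts[j] - 1L), g$seq,
          substr(seq_chr, starts[j] + gene_len, config$contig_length)
        )
        ann[[gene_idx]] <- g$annotation
        layout[[gene_idx]] <- g$layout
      }
    }
    contig_seqs[ci] <- seq_chr
  }

  genome <- Biostrings::DNAStringSet(setNames(contig_seqs, contig_names))
  list(
    genome = genome,
    annotation = dplyr::bind_rows(ann),
    layout = dplyr::bind_rows(layout)
  )
}

# Build one gene: transcript-ordered exon blocks separated by GT..AG introns,
# reverse-complemented into the genome when placed on the minus strand.
build_gene <- function(config, gene_id, contig, start, strand,
                       cpg_cod, plain_cod) {
  exon_len <- config$codons_per_exon * 3L
  n_body <- config$exons_per_gene * config$codons_per_exon - 2L
  use_cpg <- stats::runif(n_body) < config$cpg_codon_prob
  body <- character(n_body)
  body[use_cpg] <- sample(cpg_cod, sum(use_cpg), replace = TRUE)
  body[!use_cpg] <- sample(plain_cod, sum(!use_cpg), replace = TRUE)
  cds_codons <- c("ATG", body, "TAA")
  cds <- paste(cds_codons, collapse = "")

  introns <- replicate(config$exons_per_gene - 1L, {
    mid <- paste(sample(c("A", "C", "G", "T"), config$intron_length - 4L,
                        replace = TRUE), collapse = "")
    paste0("GT", mid, "AG")
  })

  exon_seqs <- substring(cds,
                         (seq_len(config$exons_per_gene) - 1L) * exon_len + 1L,
                         seq_len(config$exons_per_gene) * exon_len)
  parts <- character(0)
  tx_start <- integer(config$exons_per_gene)
  pos <- 0L
  for (i in seq_len(config$exons_per_gene)) {
    tx_start[i] <- pos + 1L
    parts <- c(parts, exon_seqs[i])
    pos <- pos + exon_len
    if (i < config$exons_per_gene) {
      parts <- c(parts, introns[i])
      pos <- pos + config$intron_length
    }
  }
  transcript <- paste(parts, collapse = "")
  tx_len <- nchar(transcript)
  genomic_seq <- if (strand == "+") transcript else revcomp(transcript)

  # Map transcript-interval [a, b] to genomic coordinates.
  tx_end <- tx_start + exon_len - 1L
  if (strand == "+") {
    gstart <- start + tx_start - 1L
    gend <- start + tx_end - 1L
  } else {
    gstart <- start + (tx_len - tx_end)
    gend <- start + (tx_len - tx_start)
  }
  gene_end <- start + tx_len - 1L

  mk <- function(type, s, e, rank = NA_integer_, phase = NA_integer_) {
    tibble(contig = contig, type = type, start = s, end = e, strand = strand,
           phase = phase, gene_id = gene_id, exon_rank = rank)
  }
  annotation <- dplyr::bind_rows(
    mk("gene", start, gene_end),
    mk("mRNA", start, gene_end),
    mk("exon", gstart, gend, rank = seq_along(gstart)),
    mk("CDS", gstart, gend, rank = seq_along(gstart), phase = 0L)
  )
  list(
    seq = genomic_seq,
    annotation = annotation,
    layout = tibble(gene_id = gene_id, contig = contig, start = start,
                    end = gene_end, strand = strand, cds = cds)
  )
}
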