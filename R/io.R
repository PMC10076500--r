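# Readers and writers for the standard file formats at the package boundary.
# FASTA goes through Biostrings, GFF3 through rtracklayer, VCF reading
# through vcfR. Coverage/lambda/sample-sheet/term-map tables are plain TSV
# via readr.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- stringr::str_split_i(names(g), "\\s+", 1)
  g
}

#' Write a genome FASTA
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write a gene annotation as GFF3
#'
#' @param annotation Tibble with columns contig, type (gene/mRNA/exon/CDS),
#'   start, end, strand, phase, gene_id and optionally exon_rank (1-based
#'   closed coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  assert_cols(annotation, c("contig", "type", "start", "end", "strand",
                            "gene_id"))
  ann <- annotation
  id <- dplyr::case_when(
    ann$type == "gene" ~ paste0("gene:", ann$gene_id),
    ann$type == "mRNA" ~ paste0("mRNA:", ann$gene_id),
    TRUE ~ NA_character_
  )
  parent <- dplyr::case_when(
    ann$type == "mRNA" ~ paste0("gene:", ann$gene_id),
    ann$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR") ~
      paste0("mRNA:", ann$gene_id),
    TRUE ~ NA_character_
  )
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$type <- ann$type
  S4Vectors::mcols(gr)$ID <- id
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (is.na(p)) character(0) else p)
  )
  S4Vectors::mcols(gr)$phase <- if ("phase" %in% names(ann)) {
    as.integer(ann$phase)
  } else {
    NA_integer_
  }
  S4Vectors::mcols(gr)$gene_id <- ann$gene_id
  if ("exon_rank" %in% names(ann)) {
    S4Vectors::mcols(gr)$exon_rank <- as.integer(ann$exon_rank)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 file.
#' @return Tibble with columns contig, type, start, end, strand, phase,
#'   gene_id, exon_rank (NA where not annotated). `gene_id` is taken from a
#'   `gene_id` attribute when present, otherwise derived from the ID/Parent
#'   chain.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  tb <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if ("phase" %in% names(mc)) as.integer(mc$phase) else NA_integer_,
    id = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
    parent = if ("Parent" %in% names(mc)) {
      vapply(mc$Parent, function(p) {
        if (length(p) == 0) NA_character_ else p[[1]]
      }, character(1))
    } else {
      NA_character_
    }
  )
  if ("gene_id" %in% names(mc)) {
    tb$gene_id <- as.character(mc$gene_id)
  } else {
    # Resolve ID/Parent chains: feature -> mRNA -> gene.
    parent_of <- setNames(tb$parent, tb$id)
    strip <- function(x) sub("^(gene|mRNA|transcript):", "", x)
    tb$gene_id <- strip(dplyr::case_when(
      tb$type == "gene" ~ tb$id,
      tb$type %in% c("mRNA", "transcript") ~ tb$parent,
      TRUE ~ unname(parent_of[tb$parent])
    ))
  }
  tb$exon_rank <- if ("exon_rank" %in% names(mc)) {
    as.integer(mc$exon_rank)
  } else {
    NA_integer_
  }
  tb <- tb |>
    dplyr::filter(.data$type %in% c("gene", "mRNA", "exon", "CDS",
                                    "five_prime_UTR", "three_prime_UTR")) |>
    dplyr::select("contig", "type", "start", "end", "strand", "phase",
                  "gene_id", "exon_rank")
  # Assign translation-order exon ranks where the file did not provide them.
  tb |>
    dplyr::group_by(.data$gene_id, .data$type) |>
    dplyr::mutate(exon_rank = dplyr::if_else(
      is.na(.data$exon_rank) & .data$type %in% c("exon", "CDS"),
      as.integer(ifelse(.data$strand == "-",
                        rank(-.data$start), rank(.data$start))),
      .data$exon_rank
    )) |>
    dplyr::ungroup()
}

#' Read a Bismark-dialect coverage file
#'
#' Six tab-separated columns without header: chrom, start, end, methylation
#' percentage, methylated count, unmethylated count (1-based positions).
#'
#' @param path Coverage file.
#' @param sample Sample id attached as a column.
#' @return Tibble with columns sample, contig, pos, m, n.
#' @export
read_bismark_cov <- function(path, sample = NA_character_) {
  tb <- readr::read_tsv(
    path,
    col_names = c("contig", "start", "end", "pct", "count_m", "count_u"),
    col_types = "ciidii", progress = FALSE
  )
  tibble(
    sample = sample, contig = tb$contig, pos = tb$start,
    m = tb$count_m, n = tb$count_m + tb$count_u
  )
}

#' Write a Bismark-dialect coverage file
#' @param counts Tibble with contig, pos, m, n.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(counts, path) {
  assert_cols(counts, c("contig", "pos", "m", "n"))
  out <- tibble(
    contig = counts$contig, start = counts$pos, end = counts$pos,
    pct = round(100 * counts$m / counts$n, 6),
    count_m = counts$m, count_u = counts$n - counts$m
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Annotate coverage records with their CpG strand
#'
#' Bismark coverage files carry no strand column; in CpG context the strand
#' is recoverable from the reference base: a record sitting on a C is the
#' + strand cytosine of the dyad, a record on a G is the - strand cytosine.
#' Records on any other base (e.g. under an N mask) are dropped with a
#' message.
#'
#' @param counts Tibble with contig, pos (and any other columns).
#' @param genome Reference [Biostrings::DNAStringSet].
#' @return `counts` with a `strand` column added.
#' @export
annotate_cpg_strand <- function(counts, genome) {
  assert_cols(counts, c("contig", "pos"))
  chr <- as.character(genome)
  base <- stringr::str_sub(chr[counts$contig], counts$pos, counts$pos)
  strand <- dplyr::case_when(base == "C" ~ "+", base == "G" ~ "-",
                             TRUE ~ NA_character_)
  dropped <- sum(is.na(strand))
  if (dropped > 0) {
    inform(sprintf(
      "annotate_cpg_strand: dropped %d record(s) not on a C or G base",
      dropped
    ))
  }
  out <- counts
  out$strand <- strand
  dplyr::filter(out, !is.na(.data$strand))
}

#' Write parental variant calls as a minimal VCF v4.2 file
#'
#' One sample column; genotypes may be haploid (`1`) or diploid (`0/1`,
#' `1/1`). Mean depth is stored in INFO/DP.
#'
#' @param calls Tibble with contig, pos, ref, alt, qual, depth, gt.
#' @param path Output file.
#' @param sample_id Sample column header.
#' @param contig_lengths Optional named vector for ##contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "sample",
                      contig_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Mean read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  body <- if (nrow(calls) > 0) {
    calls <- dplyr::arrange(calls, .data$contig, .data$pos)
    sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\tDP=%d\tGT\t%s",
            calls$contig, as.integer(calls$pos), calls$ref, calls$alt,
            calls$qual, as.integer(calls$depth), calls$gt)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-sample VCF into a tibble
#'
#' @param path VCF file.
#' @param parent Optional label ("mother"/"father") attached as a column.
#' @return Tibble with contig, pos, ref, alt, qual, depth, gt (the GT
#'   subfield), parent.
#' @export
read_vcf <- function(path, parent = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(contig = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  qual = numeric(0), depth = numeric(0), gt = character(0),
                  parent = character(0)))
  }
  gt <- if (ncol(v@gt) >= 2) {
    fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)
    val <- strsplit(v@gt[, 2], ":", fixed = TRUE)
    vapply(seq_along(fmt), function(i) {
      k <- match("GT", fmt[[i]])
      if (is.na(k)) NA_character_ else val[[i]][k]
    }, character(1))
  } else {
    rep(NA_character_, nrow(fix))
  }
  dp <- suppressWarnings(as.numeric(
    stringr::str_match(fix$INFO, "DP=([0-9.]+)")[, 2]
  ))
  tibble(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)), depth = dp,
    gt = gt, parent = parent
  )
}

#' Read per-sample lambda spike counts
#'
#' Two tab-separated integers (methylated, total), no header.
#' @param path Lambda counts file.
#' @param sample Sample id attached as a column.
#' @return Tibble with sample, meth, total.
#' @export
read_lambda <- function(path, sample = NA_character_) {
  tb <- readr::read_tsv(path, col_names = c("meth", "total"),
                        col_types = "ii", progress = FALSE)
  tibble(sample = sample, meth = tb$meth, total = tb$total)
}

#' Read a sample sheet TSV (sample, group, sex, colony, subspecies)
#' @param path Sample sheet file with header.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a two-column gene-to-term map TSV
#' @param path TSV with header columns gene_id, term.
#' @return Tibble with gene_id, term.
#' @export
read_term_map <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(tb, c("gene_id", "term"), "term map")
  tb
}

#' Export a feature map as BED (0-based half-open)
#' @param feature_map Tibble from [build_feature_map()].
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_feature_bed <- function(feature_map, path) {
  out <- tibble(
    contig = feature_map$contig,
    start = feature_map$start - 1L,
    end = feature_map$end,
    name = as.character(feature_map$feature)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
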