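# Shared fixtures, built in code and cached for the session.

the_cache <- new.env(parent = emptyenv())

tiny_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_contigs = 1L, contig_length = 9000L,
             n_genes = 6L, ...)
}

# One small written study + pipeline run reused by several test files.
tiny_study <- function() {
  if (is.null(the_cache$study)) {
    dir <- file.path(tempdir(), "beemethyl-tiny-study")
    the_cache$study <- suppressMessages(simulate_study(tiny_cfg(), dir))
    the_cache$study_dir <- dir
  }
  the_cache$study
}

tiny_pipeline <- function() {
  if (is.null(the_cache$pipeline)) {
    study <- tiny_study()
    out <- file.path(tempdir(), "beemethyl-tiny-out")
    the_cache$pipeline <- suppressMessages(
      run_pipeline(study$pipeline_config, out, quiet = TRUE)
    )
    the_cache$pipeline_dir <- out
  }
  the_cache$pipeline
}

# Hand-built single-contig genome + models for CDS / feature-map tests.
toy_gene_models <- function(cds_segments, strand = "+", gene_id = "gX",
                            contig = "c1", phase = NULL) {
  seg <- tibble::tibble(
    contig = contig, type = "CDS",
    start = vapply(cds_segments, `[[`, numeric(1), 1),
    end = vapply(cds_segments, `[[`, numeric(1), 2),
    strand = strand,
    phase = phase %||% rep(0L, length(cds_segments)),
    gene_id = gene_id, exon_rank = seq_along(cds_segments)
  )
  gene <- tibble::tibble(
    contig = contig, type = "gene", start = min(seg$start),
    end = max(seg$end), strand = strand, phase = NA_integer_,
    gene_id = gene_id, exon_rank = NA_integer_
  )
  exon <- dplyr::mutate(seg, type = "exon", phase = NA_integer_)
  dplyr::bind_rows(gene, exon, seg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random clean CDS (sense codons only) of n_codons coding codons + stop.
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE), "TAA"),
        collapse = "")
}
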