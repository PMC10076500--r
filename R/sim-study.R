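# End-to-end synthetic study: generate everything and write it to disk in
# the standard formats, returning a ready-to-run pipeline configuration.

#' Generate and write a complete synthetic study
#'
#' Runs [simulate_genome()], [simulate_parent_variants()],
#' [simulate_gene_truth()], [simulate_methylation()] and
#' [simulate_term_map()] and writes the result as a directory of standard
#' files: genome FASTA, GFF3 annotation, per-parent VCFs, per-sample
#' Bismark-dialect coverage files, per-sample lambda count TSVs, sample
#' sheet, gene-to-GO-term map and truth tables. Identical configurations
#' produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `annotation`, `variants`, `methylation`, `term_map`, truth tables) and
#'   `pipeline_config`, a [pipeline_config()] pointing at the written files.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("vcf", "cov", "lambda", "truth")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }

  sg <- simulate_genome(config)
  truth <- simulate_gene_truth(config, sg)
  vars <- simulate_parent_variants(config, sg)
  meth <- simulate_methylation(config, sg, truth)
  term_map <- simulate_term_map(config, truth)

  genome_path <- file.path(dir, "genome.fa")
  gff_path <- file.path(dir, "annotation.gff3")
  write_genome_fasta(sg$genome, genome_path)
  write_gff3(sg$annotation, gff_path)

  contig_lengths <- setNames(Biostrings::width(sg$genome), names(sg$genome))
  vcf_tbl <- tidyr::crossing(colony = seq_len(config$n_colonies),
                             parent = c("mother", "father")) |>
    dplyr::mutate(path = file.path(
      dir, "vcf", sprintf("%s_colony%d.vcf", .data$parent, .data$colony)
    ))
  for (i in seq_len(nrow(vcf_tbl))) {
    calls_i <- if (nrow(vars$calls) > 0) {
      dplyr::filter(vars$calls, .data$colony == vcf_tbl$colony[i],
                    .data$parent == vcf_tbl$parent[i])
    } else {
      tibble(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), qual = numeric(0), depth = integer(0),
             gt = character(0))
    }
    write_vcf(calls_i, vcf_tbl$path[i],
              sample_id = sprintf("%s_colony%d", vcf_tbl$parent[i],
                                  vcf_tbl$colony[i]),
              contig_lengths = contig_lengths)
  }

  cov_tbl <- tibble(
    sample = names(meth$counts),
    path = file.path(dir, "cov", paste0(names(meth$counts), ".cov"))
  )
  for (i in seq_len(nrow(cov_tbl))) {
    write_bismark_cov(meth$counts[[cov_tbl$sample[i]]], cov_tbl$path[i])
  }

  lambda_tbl <- tibble(
    sample = meth$lambda$sample,
    path = file.path(dir, "lambda", paste0(meth$lambda$sample, ".lambda.tsv"))
  )
  for (i in seq_len(nrow(lambda_tbl))) {
    row <- meth$lambda[i, c("meth", "total")]
    readr::write_tsv(row, lambda_tbl$path[i], col_names = FALSE,
                     progress = FALSE)
  }

  sheet_path <- file.path(dir, "sample_sheet.tsv")
  readr::write_tsv(meth$sample_sheet, sheet_path, progress = FALSE)
  terms_path <- file.path(dir, "go_map.tsv")
  readr::write_tsv(term_map, terms_path, progress = FALSE)

  readr::write_tsv(meth$truth_genes, file.path(dir, "truth", "genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(meth$truth_dm, file.path(dir, "truth", "dm.tsv"),
                   progress = FALSE)
  readr::write_tsv(meth$truth_sites, file.path(dir, "truth", "sites.tsv"),
                   progress = FALSE)
  if (nrow(vars$truth) > 0) {
    readr::write_tsv(vars$truth, file.path(dir, "truth", "snps.tsv"),
                     progress = FALSE)
  }

  cfg <- pipeline_config(
    genome = genome_path, gff = gff_path, vcfs = vcf_tbl,
    coverage = cov_tbl, lambda = lambda_tbl, sample_sheet = sheet_path,
    term_map = terms_path, seed = config$seed
  )
  invisible(list(
    genome = sg$genome, annotation = sg$annotation, layout = sg$layout,
    variants = vars, methylation = meth, term_map = term_map,
    truth_genes = meth$truth_genes, truth_dm = meth$truth_dm,
    truth_sites = meth$truth_sites, truth_snps = vars$truth,
    pipeline_config = cfg
  ))
}
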