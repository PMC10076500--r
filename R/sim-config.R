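#' Configuration for the synthetic WGBS study generator
#'
#' Builds the parameter set that drives [simulate_study()] and the individual
#' `simulate_*()` stages. Defaults reproduce a miniature version of the study
#' design the package targets: four colonies, each contributing a diploid
#' queen (the colony mother), a haploid male (the father) and one
#' pooled-worker sample mixing three latent reproductive workers, with two
#' subspecies cross directions as a colony-level covariate and a 1% lambda
#' spike emulated by an unmethylated control read set.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param n_contigs,contig_length Number and length (bp) of contigs.
#' @param n_genes Genes to place; an error is raised if they cannot fit.
#' @param n_colonies Colonies (default 4, the study design).
#' @param exons_per_gene,codons_per_exon,intron_length Gene structure. Exons
#'   are whole codon blocks so every CDS is a multiple of 3, starts with ATG
#'   and ends with a stop codon.
#' @param min_gap Minimum intergenic gap (bp) between genes, sized so 500 bp
#'   putative promoters survive.
#' @param cpg_codon_prob Probability a coding codon is drawn from the
#'   CpG-containing codon set, guaranteeing CpG density inside exons.
#' @param coverage_mean,coverage_dispersion Per-CpG read depth is negative
#'   binomial with this mean and `size` dispersion, so the 99.9th-percentile
#'   coverage filter has genuine outliers to remove.
#' @param conversion_error Bisulfite non-conversion probability `e`; observed
#'   methylated reads at a site with true proportion `p` are
#'   `Binomial(n, p + (1 - p) e)`.
#' @param group_effect Methylation difference, in percentage points, imposed
#'   at designated truth-DM exons between the contrasted groups.
#' @param n_dm_genes Truth-DM genes per pairwise comparison.
#' @param snp_rate Per-bp probability of a parental SNP candidate.
#' @param class_probs Named probabilities of the per-gene methylation classes
#'   `unmethylated`, `low`, `medium`, `high`.
#' @param class_levels True methylation proportions of the low/medium/high
#'   classes.
#' @param subspecies_labels One colony-level label per colony.
#' @param subspecies_logit_shift Additive shift, on the logit of the true
#'   methylation proportion, applied to colonies carrying the second label
#'   (default 0.25 logits, about 5 percentage points at mid-range
#'   proportions) so the covariate in the differential model is identifiable.
#' @param lambda_depth Total cytosine observations in the lambda spike-in per
#'   sample.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 20000L,
                       n_genes = 20L,
                       n_colonies = 4L,
                       exons_per_gene = 3L,
                       codons_per_exon = 40L,
                       intron_length = 100L,
                       min_gap = 650L,
                       cpg_codon_prob = 0.35,
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       conversion_error = 0.05,
                       group_effect = 30,
                       n_dm_genes = 4L,
                       snp_rate = 0.002,
                       class_probs = c(unmethylated = 0.6, low = 0.2,
                                       medium = 0.12, high = 0.08),
                       class_levels = c(low = 0.15, medium = 0.5, high = 0.85),
                       subspecies_labels = rep(c("audax_x_dal", "dal_x_audax"),
                                               length.out = n_colonies),
                       subspecies_logit_shift = 0.25,
                       lambda_depth = 50000L) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    n_colonies = as.integer(n_colonies),
    exons_per_gene = as.integer(exons_per_gene),
    codons_per_exon = as.integer(codons_per_exon),
    intron_length = as.integer(intron_length), min_gap = as.integer(min_gap),
    cpg_codon_prob = cpg_codon_prob, coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    conversion_error = conversion_error, group_effect = group_effect,
    n_dm_genes = as.integer(n_dm_genes), snp_rate = snp_rate,
    class_probs = class_probs, class_levels = class_levels,
    subspecies_labels = as.character(subspecies_labels),
    subspecies_logit_shift = subspecies_logit_shift,
    lambda_depth = as.integer(lambda_depth)
  )
  probs <- c(cfg$conversion_error, cfg$snp_rate, cfg$cpg_codon_prob,
             cfg$class_probs, cfg$class_levels)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities in a sim_config must lie in [0, 1]")
  }
  if (cfg$group_effect < 0 || cfg$group_effect > 100) {
    abort("group_effect is in percentage points and must lie in [0, 100]")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-8) {
    abort("class_probs must sum to 1")
  }
  if (length(cfg$subspecies_labels) != cfg$n_colonies) {
    abort("subspecies_labels must supply one label per colony")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d contig(s) x %d bp, %d genes\n",
              x$n_contigs, x$contig_length, x$n_genes))
  cat(sprintf("  design: %d colonies (queen, male, pooled workers each)\n",
              x$n_colonies))
  cat(sprintf("  coverage ~ NB(mean = %g, size = %g); non-conversion e = %g\n",
              x$coverage_mean, x$coverage_dispersion, x$conversion_error))
  cat(sprintf("  truth DM: %d genes/comparison at %g pp effect; seed = %d\n",
              x$n_dm_genes, x$group_effect, x$seed))
  invisible(x)
}

# Deterministic per-stage seeds derived from the config seed (kept < 2^31).
stage_seed <- function(config, stage) {
  offsets <- c(genome = 101L, variants = 211L, truth = 307L, counts = 401L,
               go = 503L)
  (config$seed %% 2000000000L) + offsets[[stage]]
}
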