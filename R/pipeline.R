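# Orchestration: run every stage from a single declarative configuration.

#' Pipeline configuration
#'
#' Collects the input paths and analysis thresholds for [run_pipeline()].
#' Threshold defaults are the study's: coverage >= 10 reads and <= the
#' 99.9th percentile, per-CpG call FDR 0.05, DM CpG at >= 10 percentage
#' points and q < 0.01, DM gene at >= 2 DM CpGs on an exon with > 15
#' percentage-point weighted difference, methylated-gene floor 0.05, bin
#' edges 0.3/0.7, 500 bp putative promoters.
#'
#' @param genome,gff,sample_sheet,term_map Input file paths.
#' @param vcfs Tibble with colony, parent ("mother"/"father"), path.
#' @param coverage,lambda Tibbles with sample, path.
#' @param min_cov,cov_pct Coverage filter settings.
#' @param call_fdr Methylation-call q threshold.
#' @param dm_diff,dm_q DM-CpG thresholds (percentage points; q).
#' @param gene_min_cpgs,gene_min_dw DM-gene thresholds.
#' @param meth_floor,bin_edges Gene methylation classification.
#' @param promoter_size Putative promoter length (bp).
#' @param pnps_mode "raw" or "site_normalized" (see [compute_pnps()]).
#' @param bh_scope BH scope for the status calls ("sample" or "global").
#' @param seed Seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome, gff, vcfs, coverage, lambda,
                            sample_sheet, term_map,
                            min_cov = 10, cov_pct = 99.9, call_fdr = 0.05,
                            dm_diff = 10, dm_q = 0.01, gene_min_cpgs = 2,
                            gene_min_dw = 0.15, meth_floor = 0.05,
                            bin_edges = c(0.3, 0.7), promoter_size = 500,
                            pnps_mode = "raw", bh_scope = "sample",
                            seed = 1L) {
  structure(
    list(
      genome = genome, gff = gff, vcfs = vcfs, coverage = coverage,
      lambda = lambda, sample_sheet = sample_sheet, term_map = term_map,
      min_cov = min_cov, cov_pct = cov_pct, call_fdr = call_fdr,
      dm_diff = dm_diff, dm_q = dm_q, gene_min_cpgs = gene_min_cpgs,
      gene_min_dw = gene_min_dw, meth_floor = meth_floor,
      bin_edges = bin_edges, promoter_size = promoter_size,
      pnps_mode = pnps_mode, bh_scope = bh_scope, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order — SNP filtering, genome
#' masking/individualisation, methylation calling, differential
#' methylation, codon degeneracy, pN/pS selection, GO enrichment — writing
#' per-stage TSVs and a manifest to `out_dir`. Any stage failure aborts with
#' the stage name; outputs written by earlier stages are left on disk for
#' inspection.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of the stage results plus `manifest` (tibble: stage,
#'   artifact, rows, path) and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, artifact, obj, path = NA_character_) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, artifact = artifact,
      rows = if (is.data.frame(obj)) nrow(obj) else length(obj),
      path = path
    )
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  save_tsv <- function(stage, artifact, tbl) {
    path <- file.path(out_dir, paste0(artifact, ".tsv"))
    keep <- !vapply(tbl, is.list, logical(1))
    readr::write_tsv(tbl[, keep, drop = FALSE], path, progress = FALSE)
    note(stage, artifact, tbl, path)
    tbl
  }

  ## --- inputs -------------------------------------------------------------
  say("stage inputs")
  inputs <- run_stage("inputs", {
    genome <- read_genome_fasta(config$genome)
    models <- read_gene_models(config$gff)
    sheet <- read_sample_sheet(config$sample_sheet)
    terms <- read_term_map(config$term_map)
    list(genome = genome, models = models, sheet = sheet, terms = terms)
  })
  note("inputs", "gene_models", inputs$models)

  ## --- snp_filtering ------------------------------------------------------
  say("stage snp_filtering")
  snps <- run_stage("snp_filtering", {
    colonies <- sort(unique(config$vcfs$colony))
    per_colony <- lapply(colonies, function(k) {
      path_of <- function(par) {
        p <- config$vcfs$path[config$vcfs$colony == k &
                                config$vcfs$parent == par]
        if (length(p) != 1) {
          abort(sprintf("colony %s needs exactly one %s VCF", k, par))
        }
        p
      }
      merged <- merge_parent_calls(read_vcf(path_of("mother"), "mother"),
                                   read_vcf(path_of("father"), "father"))
      out <- filter_parent_snps(merged)
      dplyr::mutate(out, colony = k)
    })
    dplyr::bind_rows(per_colony)
  })
  save_tsv("snp_filtering", "filtered_snps", snps)

  ## --- masking ------------------------------------------------------------
  say("stage masking")
  masked <- run_stage("masking", {
    colonies <- sort(unique(config$vcfs$colony))
    masked_paths <- character(0)
    alt_refs <- list()
    for (k in colonies) {
      sk <- dplyr::filter(snps, .data$colony == k)
      mg <- mask_genome(inputs$genome, sk)
      p <- file.path(out_dir, sprintf("masked_colony%s.fa", k))
      write_genome_fasta(mg, p)
      masked_paths <- c(masked_paths, p)
      queen_s <- paste0("queen_", k)
      male_s <- paste0("male_", k)
      alt_refs[[queen_s]] <- build_alternate_reference(
        inputs$genome, dplyr::filter(sk, .data$parent == "mother")
      )
      alt_refs[[male_s]] <- build_alternate_reference(
        inputs$genome, dplyr::filter(sk, .data$parent == "father")
      )
    }
    list(paths = masked_paths, alt_refs = alt_refs)
  })
  note("masking", "masked_genomes", masked$paths)

  ## --- methylation_calling ------------------------------------------------
  say("stage methylation_calling")
  calling <- run_stage("methylation_calling", {
    missing_lambda <- config$lambda$path[!file.exists(config$lambda$path)]
    if (length(missing_lambda) > 0) {
      abort(sprintf("missing lambda file(s): %s",
                    paste(missing_lambda, collapse = ", ")))
    }
    lambda <- dplyr::bind_rows(purrr::map2(
      config$lambda$path, config$lambda$sample, read_lambda
    ))
    error <- conversion_rate(lambda)
    raw <- dplyr::bind_rows(purrr::map2(
      config$coverage$path, config$coverage$sample, read_bismark_cov
    ))
    stranded <- annotate_cpg_strand(raw, inputs$genome)
    sites <- destrand(stranded)
    sites <- filter_coverage(sites, min_cov = config$min_cov,
                             pct = config$cov_pct)
    calls_all <- call_methylation(sites, error, fdr = config$call_fdr,
                                  scope = config$bh_scope)
    calls <- drop_never_methylated(calls_all)

    genes <- inputs$models |>
      dplyr::filter(.data$type == "gene") |>
      dplyr::transmute(feature_id = .data$gene_id, gene_id = .data$gene_id,
                       contig = .data$contig, start = .data$start,
                       end = .data$end)
    counts_grp <- dplyr::left_join(
      calls, inputs$sheet %just% c("sample", "group", "sex"), by = "sample"
    )
    gene_w_sample <- weighted_methylation(counts_grp, genes, by = "sample")
    gene_w_group <- weighted_methylation(counts_grp, genes, by = "group")
    gene_bins <- gene_w_group |>
      dplyr::mutate(bin = bin_methylation(.data$w, config$meth_floor,
                                          config$bin_edges))
    fmap <- build_feature_map(inputs$models, inputs$genome,
                              promoter_size = config$promoter_size)
    fmap_feats <- fmap |>
      dplyr::mutate(feature_id = paste0(.data$feature, "_", dplyr::row_number()))
    feature_w <- weighted_methylation(counts_grp, fmap_feats, by = "group") |>
      dplyr::group_by(.data$feature, .data$group) |>
      dplyr::summarise(w = sum(.data$w * .data$covered_cpgs) /
                         sum(.data$covered_cpgs),
                       .groups = "drop")
    list(lambda = lambda, error = error, calls_all = calls_all,
         calls = calls, gene_w_sample = gene_w_sample,
         gene_w_group = gene_w_group, gene_bins = gene_bins,
         feature_map = fmap, feature_w = feature_w)
  })
  save_tsv("methylation_calling", "methylation_calls", calling$calls)
  save_tsv("methylation_calling", "gene_weighted_methylation",
           calling$gene_w_group)
  save_tsv("methylation_calling", "gene_bins", calling$gene_bins)
  save_tsv("methylation_calling", "conversion_rates", calling$error)

  ## --- differential_methylation -------------------------------------------
  say("stage differential_methylation")
  dm <- run_stage("differential_methylation", {
    comps <- sim_comparisons()
    exons <- inputs$models |>
      dplyr::filter(.data$type == "exon") |>
      dplyr::transmute(
        feature_id = paste0(.data$gene_id, "_e", .data$exon_rank),
        gene_id = .data$gene_id, contig = .data$contig,
        start = .data$start, end = .data$end
      )
    counts_grp <- dplyr::left_join(
      calling$calls, inputs$sheet %just% c("sample", "group"), by = "sample"
    )
    exon_w <- weighted_methylation(counts_grp, exons, by = "group")
    per_comp <- lapply(seq_len(nrow(comps)), function(i) {
      fits <- dm_test_cpgs(calling$calls, inputs$sheet,
                           comparison = c(comps$group1[i], comps$group2[i]),
                           covariate = "subspecies")
      cpgs <- call_dm_cpgs(fits, min_diff = config$dm_diff,
                           q_threshold = config$dm_q)
      genes <- call_dm_genes(cpgs, exons, exon_w,
                             min_cpgs = config$gene_min_cpgs,
                             min_dw = config$gene_min_dw)
      list(cpgs = cpgs, genes = genes)
    })
    dm_cpgs <- dplyr::bind_rows(lapply(per_comp, `[[`, "cpgs"))
    dm_genes <- dplyr::bind_rows(lapply(per_comp, `[[`, "genes"))

    qm <- dplyr::filter(dm_cpgs, .data$comparison == "queen_vs_male",
                        .data$dm)
    gof <- if (nrow(qm) > 0) {
      gof_hypermethylated(sum(qm$hyper_in == "queen"),
                          sum(qm$hyper_in == "male"))
    } else {
      tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
             n_a = 0L, n_b = 0L)
    }
    hyper_sets <- dm_genes |>
      dplyr::mutate(set = paste0("hyper_", .data$hyper_in, "_in_",
                                 .data$comparison))
    sets <- split(hyper_sets$gene_id, hyper_sets$set)
    overlaps <- overlap_dm_gene_sets(sets)
    list(dm_cpgs = dm_cpgs, dm_genes = dm_genes, gof = gof,
         overlaps = overlaps, exon_w = exon_w)
  })
  save_tsv("differential_methylation", "dm_cpgs", dm$dm_cpgs)
  save_tsv("differential_methylation", "dm_genes", dm$dm_genes)
  save_tsv("differential_methylation", "gof_hypermethylated", dm$gof)
  save_tsv("differential_methylation", "dm_gene_overlaps", dm$overlaps)

  ## --- degeneracy ---------------------------------------------------------
  say("stage degeneracy")
  degen <- run_stage("degeneracy", {
    individuals <- names(masked$alt_refs)
    deg_sites <- dplyr::bind_rows(lapply(individuals, function(sm) {
      cds <- extract_all_cds(masked$alt_refs[[sm]], inputs$models)
      dplyr::bind_rows(lapply(cds, function(x) {
        label_degeneracy(x$seq, x$map, gene_id = x$gene_id)
      })) |>
        dplyr::mutate(sample = sm)
    }))
    sheet_sex <- inputs$sheet %just% c("sample", "sex")
    fold_tab <- fold_methylation_proportions(
      deg_sites, calling$calls, by = "fold_class", sample_sheet = sheet_sex
    )
    pos_tab <- fold_methylation_proportions(
      deg_sites, calling$calls, by = c("fold_class", "codon_pos"),
      sample_sheet = sheet_sex
    )
    fold_fit <- fit_beta_regression(
      proportion ~ fold + sex,
      fold_tab |>
        dplyr::mutate(fold = c(zero = 0, two = 2, three = 3, four = 4)[
          as.character(.data$fold_class)])
    )
    # genes with >= 1 methylated zero-fold site, per sex
    meth_calls <- dplyr::filter(calling$calls,
                                .data$status == "methylated")
    meth_zero <- deg_cpg_key(deg_sites) |>
      dplyr::filter(.data$fold_class == "zero") |>
      dplyr::inner_join(
        meth_calls %just% c("sample", "contig", "pos"),
        by = c("sample", "contig", cpg_pos = "pos")
      ) |>
      dplyr::left_join(inputs$sheet %just% c("sample", "sex"),
                       by = "sample") |>
      dplyr::distinct(.data$sex, .data$gene_id)
    meth_universe <- calling$gene_bins |>
      dplyr::filter(.data$bin != "unmethylated") |>
      dplyr::distinct(.data$gene_id) |>
      dplyr::pull(.data$gene_id)
    bin_enrich <- dplyr::bind_rows(lapply(
      split(meth_zero$gene_id, meth_zero$sex),
      function(g) fold_bin_enrichment(
        g,
        calling$gene_bins |>
          dplyr::distinct(.data$gene_id, .data$bin),
        universe = meth_universe
      )
    ), .id = "sex")
    meth_bg <- calling$calls |>
      dplyr::filter(.data$status == "methylated") |>
      dplyr::distinct(.data$contig, .data$pos)
    dm_fold <- dm_sites_by_fold(
      dplyr::filter(dm$dm_cpgs, .data$comparison == "queen_vs_male"),
      deg_sites, meth_bg
    )
    list(deg_sites = deg_sites, fold_tab = fold_tab, pos_tab = pos_tab,
         fold_fit = fold_fit, zero_fold_genes = meth_zero,
         bin_enrichment = bin_enrich, dm_by_fold = dm_fold)
  })
  save_tsv("degeneracy", "fold_methylation", degen$fold_tab)
  save_tsv("degeneracy", "fold_methylation_by_codon_pos", degen$pos_tab)
  save_tsv("degeneracy", "fold_beta_regression", tidy(degen$fold_fit))
  save_tsv("degeneracy", "zero_fold_bin_enrichment", degen$bin_enrichment)
  save_tsv("degeneracy", "dm_by_fold", degen$dm_by_fold)

  ## --- selection ----------------------------------------------------------
  say("stage selection")
  selection <- run_stage("selection", {
    queens <- grep("^queen_", names(masked$alt_refs), value = TRUE)
    males <- grep("^male_", names(masked$alt_refs), value = TRUE)
    cds_by_ind <- lapply(masked$alt_refs, extract_all_cds,
                         models = inputs$models)
    gene_ids <- Reduce(intersect, lapply(cds_by_ind, names))
    allele_sets <- lapply(setNames(gene_ids, gene_ids), function(g) {
      c(
        unlist(lapply(queens, function(q) {
          rep(cds_by_ind[[q]][[g]]$seq, 2)  # diploid: two identical alleles
        })),
        vapply(males, function(m) cds_by_ind[[m]][[g]]$seq, character(1))
      )
    })
    pnps <- compute_pnps_genes(allele_sets, mode = config$pnps_mode)
    w_sex <- calling$gene_w_group |>
      dplyr::filter(.data$group %in% c("queen", "male")) |>
      dplyr::select("gene_id", "group", "w")
    assoc <- lapply(split(w_sex, w_sex$group), function(d) {
      dat <- dplyr::inner_join(d, pnps, by = "gene_id")
      tryCatch(methylation_vs_pnps(dat), error = function(e) NULL)
    })
    list(pnps = pnps, assoc = assoc)
  })
  save_tsv("selection", "pnps", selection$pnps)
  assoc_tbl <- dplyr::bind_rows(
    lapply(selection$assoc, function(a) if (is.null(a)) NULL else glance(a)),
    .id = "group"
  )
  if (nrow(assoc_tbl) > 0) {
    save_tsv("selection", "methylation_pnps_model", assoc_tbl)
  }

  ## --- enrichment ---------------------------------------------------------
  say("stage enrichment")
  enrichment <- run_stage("enrichment", {
    meth_universe <- calling$gene_bins |>
      dplyr::filter(.data$bin != "unmethylated") |>
      dplyr::distinct(.data$gene_id) |>
      dplyr::pull(.data$gene_id)
    per_comp <- lapply(
      split(dm$dm_genes$gene_id, dm$dm_genes$comparison),
      function(g) {
        study <- intersect(unique(g), meth_universe)
        if (length(study) == 0) return(NULL)
        enrich(study, meth_universe, inputs$terms)
      }
    )
    dplyr::bind_rows(purrr::compact(per_comp), .id = "comparison")
  })
  if (nrow(enrichment) > 0) {
    save_tsv("enrichment", "go_enrichment", enrichment)
  }

  manifest_tbl <- dplyr::bind_rows(manifest)
  cfg_hash <- rlang::hash(unclass(config))
  readr::write_tsv(manifest_tbl, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  writeLines(cfg_hash, file.path(out_dir, "config_hash.txt"))

  list(
    inputs = inputs, snps = snps, masked = masked, calling = calling,
    dm = dm, degeneracy = degen, selection = selection,
    enrichment = enrichment, manifest = manifest_tbl,
    config_hash = cfg_hash
  )
}
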