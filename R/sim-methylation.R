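# Synthetic bisulfite CpG counts with known per-site truth.

sim_comparisons <- function() {
  tibble(
    comparison = c("queen_vs_male", "queen_vs_worker", "male_vs_worker"),
    group1 = c("queen", "queen", "male"),
    group2 = c("male", "worker", "worker")
  )
}

#' Assign per-gene methylation classes and truth-DM exons
#'
#' Each gene draws a methylation class (unmethylated / low / medium / high)
#' giving its true CpG methylation proportion. For every pairwise comparison,
#' `n_dm_genes` genes from the low/medium classes (so the configured effect
#' fits inside \[0, 1\]) receive a `group_effect` percentage-point shift on
#' one designated exon, alternating which group is hypermethylated. Genes are
#' assigned to at most one comparison so the truth table stays unambiguous.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [simulate_genome()].
#' @return List with `genes` (gene_id, class, p_base) and `dm` (gene_id,
#'   comparison, group1, group2, hyper_group, dm_exon, effect).
#' @export
simulate_gene_truth <- function(config, sim_genome) {
  set.seed(stage_seed(config, "truth"))
  genes <- unique(sim_genome$annotation$gene_id)
  cls <- sample(names(config$class_probs), length(genes), replace = TRUE,
                prob = config$class_probs)
  p_base <- dplyr::case_when(
    cls == "low" ~ config$class_levels[["low"]],
    cls == "medium" ~ config$class_levels[["medium"]],
    cls == "high" ~ config$class_levels[["high"]],
    TRUE ~ 0
  )
  gene_tbl <- tibble(gene_id = genes, class = cls, p_base = p_base)

  comps <- sim_comparisons()
  eligible <- genes[cls %in% c("low", "medium")]
  eligible <- sample(eligible)  # randomise assignment order
  dm <- list()
  taken <- 0L
  dm_exon <- max(1L, ceiling(config$exons_per_gene / 2))
  for (i in seq_len(nrow(comps))) {
    n_take <- min(config$n_dm_genes, length(eligible) - taken)
    if (n_take <= 0L) break
    ids <- eligible[taken + seq_len(n_take)]
    taken <- taken + n_take
    dm[[i]] <- tibble(
      gene_id = ids,
      comparison = comps$comparison[i],
      group1 = comps$group1[i],
      group2 = comps$group2[i],
      hyper_group = ifelse(seq_len(n_take) %% 2L == 1L,
                           comps$group1[i], comps$group2[i]),
      dm_exon = dm_exon,
      effect = config$group_effect / 100
    )
  }
  list(genes = gene_tbl, dm = dplyr::bind_rows(dm))
}

# Enumerate CpG dyads (1-based position of the + strand C) per contig.
cpg_positions <- function(genome) {
  chr <- as.character(genome)
  dplyr::bind_rows(lapply(names(chr), function(ct) {
    loc <- stringr::str_locate_all(chr[[ct]], "CG")[[1]]
    tibble(contig = ct, pos = loc[, 1])
  }))
}

#' Simulate per-sample CpG counts and lambda spike counts
#'
#' Enumerates every CpG dyad in the genome, derives its true methylation
#' proportion per group (gene-class proportion inside exons, zero elsewhere,
#' plus the truth-DM exon effect and the colony-level subspecies shift on the
#' logit scale), then draws strand-split read counts: per-strand depth is
#' negative binomial and methylated reads are
#' `Binomial(n, p + (1 - p) * conversion_error)`. Pooled-worker samples sum
#' the counts of three equally weighted latent workers. Lambda counts use a
#' true proportion of zero.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [simulate_genome()].
#' @param truth Output of [simulate_gene_truth()]; generated if `NULL`.
#' @return List with `counts` (named list of per-sample per-strand tibbles:
#'   contig, pos, strand, m, n), `lambda` (sample, meth, total),
#'   `sample_sheet`, `truth_genes`, `truth_dm`, and `truth_sites` (per-CpG
#'   true proportions per group, before the colony shift).
#' @export
simulate_methylation <- function(config, sim_genome, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- simulate_gene_truth(config, sim_genome)
  set.seed(stage_seed(config, "counts"))

  sites <- cpg_positions(sim_genome$genome)
  exons <- sim_genome$annotation |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::select("contig", "start", "end", "gene_id", "exon_rank")
  hit <- overlap_join(sites, exons, x_start = "pos", x_end = "pos") |>
    dplyr::distinct(.data$contig, .data$pos, .keep_all = TRUE)
  sites <- sites |>
    dplyr::left_join(hit, by = c("contig", "pos")) |>
    dplyr::left_join(truth$genes, by = "gene_id") |>
    dplyr::mutate(p_base = dplyr::coalesce(.data$p_base, 0))

  groups <- c("queen", "male", "worker")
  for (g in groups) sites[[paste0("p_", g)]] <- sites$p_base
  if (nrow(truth$dm) > 0) {
    for (i in seq_len(nrow(truth$dm))) {
      d <- truth$dm[i, ]
      sel <- !is.na(sites$gene_id) & sites$gene_id == d$gene_id &
        !is.na(sites$exon_rank) & sites$exon_rank == d$dm_exon
      col <- paste0("p_", d$hyper_group)
      sites[[col]][sel] <- pmin(sites[[col]][sel] + d$effect, 0.98)
    }
  }
  truth_sites <- sites |>
    dplyr::select("contig", "pos", "gene_id", "exon_rank",
                  "p_queen", "p_male", "p_worker")

  sub_lab <- config$subspecies_labels
  shift_on <- as.integer(factor(sub_lab, levels = unique(sub_lab))) - 1L
  sample_sheet <- tidyr::crossing(
    colony = seq_len(config$n_colonies), group = groups
  ) |>
    dplyr::mutate(
      sample = paste0(.data$group, "_", .data$colony),
      sex = dplyr::if_else(.data$group == "male", "male", "female"),
      subspecies = sub_lab[.data$colony]
    ) |>
    dplyr::select("sample", "group", "sex", "colony", "subspecies")

  e <- config$conversion_error
  shift <- config$subspecies_logit_shift
  n_sites <- nrow(sites)
  counts <- list()
  lambda <- list()

  for (si in seq_len(nrow(sample_sheet))) {
    sm <- sample_sheet[si, ]
    p <- sites[[paste0("p_", sm$group)]]
    if (shift_on[sm$colony] == 1L && shift != 0) {
      pos_p <- p > 0 & p < 1
      p[pos_p] <- stats::plogis(stats::qlogis(p[pos_p]) + shift)
    }
    pe <- p + (1 - p) * e
    draw_strand <- function(mu) {
      if (sm$group == "worker") {
        # three latent workers pooled in equal parts
        n <- m <- integer(n_sites)
        for (w in 1:3) {
          nw <- stats::rnbinom(n_sites, size = config$coverage_dispersion,
                               mu = mu / 3)
          n <- n + nw
          m <- m + stats::rbinom(n_sites, nw, pe)
        }
        list(n = n, m = m)
      } else {
        n <- stats::rnbinom(n_sites, size = config$coverage_dispersion,
                            mu = mu)
        list(n = n, m = stats::rbinom(n_sites, n, pe))
      }
    }
    plus <- draw_strand(config$coverage_mean / 2)
    minus <- draw_strand(config$coverage_mean / 2)
    tb <- dplyr::bind_rows(
      tibble(contig = sites$contig, pos = sites$pos, strand = "+",
             m = plus$m, n = plus$n),
      tibble(contig = sites$contig, pos = sites$pos + 1L, strand = "-",
             m = minus$m, n = minus$n)
    ) |>
      dplyr::filter(.data$n > 0) |>
      dplyr::arrange(.data$contig, .data$pos, .data$strand)
    counts[[sm$sample]] <- tb
    lambda[[sm$sample]] <- tibble(
      sample = sm$sample,
      meth = stats::rbinom(1L, config$lambda_depth, e),
      total = config$lambda_depth
    )
  }

  list(
    counts = counts,
    lambda = dplyr::bind_rows(lambda),
    sample_sheet = sample_sheet,
    truth_genes = truth$genes,
    truth_dm = truth$dm,
    truth_sites = truth_sites
  )
}

#' Simulate a gene-to-GO-term map
#'
#' Draws 1-4 terms per gene from a small pool; genes flagged as truth-DM
#' additionally share a common marker term so enrichment has signal to find.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_gene_truth()].
#' @return Tibble with columns `gene_id`, `term`.
#' @export
simulate_term_map <- function(config, truth) {
  set.seed(stage_seed(config, "go"))
  pool <- sprintf("GO:%07d", 1:30)
  genes <- truth$genes$gene_id
  map <- dplyr::bind_rows(lapply(genes, function(g) {
    tibble(gene_id = g, term = sample(pool, sample(1:4, 1L)))
  }))
  if (nrow(truth$dm) > 0) {
    map <- dplyr::bind_rows(
      map, tibble(gene_id = unique(truth$dm$gene_id), term = "GO:0000100")
    )
  }
  dplyr::distinct(map) |> dplyr::arrange(.data$gene_id, .data$term)
}
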